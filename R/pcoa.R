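#' Principal-coordinates embedding of a dissimilarity matrix ("trait space")
#'
#' Classical scaling (Gower double-centering and eigen-decomposition) of the
#' corrected dissimilarities. The default correction takes the element-wise
#' square root of the Gower dissimilarities before scaling, which makes
#' typical mixed-trait Gower matrices (near-)Euclidean so that convex-hull
#' and spanning-tree geometry is well defined. The species-pool trait space
#' is computed once over the full species set and held fixed for observed
#' and null communities alike, so standardized effect sizes are comparable.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (see
#'   [gower_dissimilarity()]).
#' @param correction `"sqrt"` (default) or `"none"`.
#' @param m_max maximum number of axes to retain (default: all positive
#'   axes).
#' @return a `trait_space` object: list with `species_ids`, `coordinates`
#'   (species x m), `eigenvalues` (all, descending), `m`, `correction` and
#'   `quality` (fraction of positive-eigenvalue variation in the m axes).
#' @export
pcoa_embed <- function(d, correction = c("sqrt", "none"), m_max = NULL) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop_fmt("d must be a symmetric matrix")
  if (any(diag(d) != 0)) stop_fmt("d must have a zero diagonal")
  n <- nrow(d)
  if (all(d == 0))
    stop_fmt(paste("all dissimilarities are zero (a single functional point);",
                   "deduplicate trait syndromes upstream"))
  dc <- if (correction == "sqrt") sqrt(d) else d
  A <- -0.5 * dc^2
  B <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  eg <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  npos <- sum(eg$values > tol)
  if (npos < 1) stop_fmt("no positive eigenvalues: degenerate dissimilarity matrix")
  m <- min(m_max %||% npos, npos)
  coords <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(m)]), m)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(m))
  neg <- sum(eg$values < -tol)
  if (neg > 0)
    log_stage("pcoa", neg, " negative eigenvalue(s); most negative ",
              format_num(min(eg$values)))
  structure(list(species_ids = rownames(d),
                 coordinates = coords,
                 eigenvalues = eg$values,
                 m = m,
                 correction = correction,
                 quality = sum(eg$values[seq_len(m)]) /
                   sum(eg$values[eg$values > tol])),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species, %d axes (%s correction), quality %.3f\n",
              length(x$species_ids), x$m, x$correction, x$quality))
  invisible(x)
}
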