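#' Simpson diversity
#'
#' D = 1 - sum(p_i^2) for a weight vector summing to one.
#'
#' @param p non-negative weights summing to 1.
#' @return D in [0, 1).
#' @export
simpson_diversity <- function(p) {
  if (length(p) == 0) stop_fmt("empty weight vector")
  if (abs(sum(p) - 1) > 1e-8) stop_fmt("weights must sum to 1")
  1 - sum(p^2)
}

#' Rao's quadratic entropy
#'
#' Q = sum_i sum_j p_i p_j d_ij, the expected trait dissimilarity between
#' two random draws. Uses the raw Gower dissimilarities by default, which
#' keeps Q <= D and the redundancy FRed = 1 - Q/D in [0, 1]; the d^2/2
#' convention is available for parity studies.
#'
#' @param d species x species dissimilarity matrix.
#' @param p weights aligned to the rows of `d`, summing to 1.
#' @param convention `"gower"` (raw d) or `"squared_halved"` (d^2/2).
#' @return Q >= 0.
#' @export
rao_quadratic_entropy <- function(d, p, convention = c("gower", "squared_halved")) {
  convention <- match.arg(convention)
  d <- as.matrix(d)
  if (length(p) != nrow(d)) stop_fmt("weights and dissimilarity matrix disagree in size")
  if (abs(sum(p) - 1) > 1e-8) stop_fmt("weights must sum to 1")
  if (convention == "squared_halved") d <- d^2 / 2
  drop(t(p) %*% d %*% p)
}

#' Functional redundancy
#'
#' FRed = 1 - RaoQ / D. NA for monocultures (D = 0). With dissimilarities
#' in [0, 1], RaoQ never exceeds D; a violation indicates corrupted inputs
#' and is an error.
#'
#' @param raoq Rao's quadratic entropy.
#' @param D Simpson diversity.
#' @return FRed in [0, 1], or NA when D = 0.
#' @export
functional_redundancy <- function(raoq, D) {
  if (D < 0) stop_fmt("negative Simpson diversity")
  if (D == 0) return(NA_real_)
  if (raoq > D + 1e-9)
    stop_fmt("RaoQ (%g) exceeds Simpson D (%g): upstream corruption", raoq, D)
  1 - raoq / D
}

#' Convex hull volume and vertices
#'
#' Thin wrapper around the compiled incremental hull. Degenerate inputs
#' (fewer than d+1 points, or points spanning fewer than d dimensions)
#' return `degenerate = TRUE` with an NA volume.
#'
#' @param points numeric matrix, points in rows.
#' @return list with `volume`, `vertices` (row indices) and `degenerate`.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  out <- .convhull_cpp(points)
  if (isTRUE(out$degenerate)) out$volume <- NA_real_
  out
}

#' Functional richness (convex hull volume)
#'
#' Volume of the convex hull of the present species in the first `m` axes
#' of the trait space. Duplicate trait syndromes (coincident coordinates)
#' collapse onto one point inside the hull routine; more than `m` distinct
#' points in general position are required, otherwise NA.
#'
#' @param space a [pcoa_embed()] trait space.
#' @param species character vector of present species ids.
#' @param m number of axes (default: all axes in `space`).
#' @return hull volume, or NA for degenerate configurations.
#' @export
functional_richness <- function(space, species, m = space$m) {
  X <- space_coords(space, species, m)
  convex_hull(X)$volume
}

#' Functional evenness
#'
#' Regularity of species (and their weights) along the minimum spanning
#' tree of the present species in the m-axis trait space. Edge weights
#' EW_l = dist(i,j)/(p_i + p_j) are rescaled to partial weights PEW and
#' FEve = (sum_l min(PEW_l, 1/(s-1)) - 1/(s-1)) / (1 - 1/(s-1)).
#' Needs at least 3 species.
#'
#' @inheritParams functional_richness
#' @param p weights over `species`, summing to 1.
#' @return FEve in [0, 1], or NA.
#' @export
functional_evenness <- function(space, species, p, m = space$m) {
  s <- length(species)
  if (s < 3) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-8) stop_fmt("weights must sum to 1")
  X <- space_coords(space, species, m)
  E <- mst_edges(X)
  ew <- E$len / (p[E$i] + p[E$j])
  tot <- sum(ew)
  if (tot <= 0) return(NA_real_)  # all species at one functional point
  pew <- ew / tot
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# Kruskal MST; edges sorted by (length, i, j) for deterministic tie-breaks
mst_edges <- function(X) {
  s <- nrow(X)
  cross <- tcrossprod(X)
  nn <- diag(cross)
  D2 <- pmax(outer(nn, nn, "+") - 2 * cross, 0)
  i <- rep(seq_len(s - 1), times = (s - 1):1)
  j <- sequence((s - 1):1) + i
  len <- sqrt(D2[cbind(i, j)])
  o <- order(len, i, j)
  parent <- seq_len(s)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  keep <- logical(length(o))
  got <- 0L
  for (e in o) {
    ra <- find(i[e]); rb <- find(j[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      got <- got + 1L
      if (got == s - 1L) break
    }
  }
  sel <- which(keep)
  list(i = i[sel], j = j[sel], len = len[sel])
}

#' Functional divergence
#'
#' Abundance-weighted deviation of species from the centroid G of the
#' convex-hull vertices: with dG_i = ||x_i - G||, mean_dG their unweighted
#' mean, delta_d = sum p_i (dG_i - mean_dG) and delta_ad the analogous
#' absolute sum, FDiv = (delta_d + mean_dG) / (delta_ad + mean_dG).
#' Needs >= 3 species and a computable hull.
#'
#' @inheritParams functional_evenness
#' @return FDiv in [0, 1], or NA.
#' @export
functional_divergence <- function(space, species, p, m = space$m) {
  s <- length(species)
  if (s < 3) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-8) stop_fmt("weights must sum to 1")
  X <- space_coords(space, species, m)
  h <- convex_hull(X)
  if (isTRUE(h$degenerate)) return(NA_real_)
  # hull vertices are one point per distinct position, so duplicated
  # syndromes do not bias the vertex centroid G
  G <- colMeans(X[h$vertices, , drop = FALSE])
  dG <- sqrt(colSums((t(X) - G)^2))
  mdG <- mean(dG)
  dev <- dG - mdG
  denom <- sum(p * abs(dev)) + mdG
  if (denom <= 0) return(NA_real_)
  (sum(p * dev) + mdG) / denom
}

#' Functional dispersion
#'
#' Weighted mean distance of species to their weighted centroid:
#' FDis = sum p_i ||x_i - c|| with c = sum p_i x_i. Zero for monocultures.
#'
#' @inheritParams functional_evenness
#' @return FDis >= 0.
#' @export
functional_dispersion <- function(space, species, p, m = space$m) {
  if (abs(sum(p) - 1) > 1e-8) stop_fmt("weights must sum to 1")
  X <- space_coords(space, species, m)
  ctr <- colSums(X * p)
  sum(p * sqrt(colSums((t(X) - ctr)^2)))
}

space_coords <- function(space, species, m) {
  if (m > space$m) stop_fmt("m = %d exceeds the %d axes of the trait space", m, space$m)
  miss <- setdiff(species, space$species_ids)
  if (length(miss))
    stop_fmt("species not in the trait space: %s", paste(miss, collapse = ", "))
  space$coordinates[species, seq_len(m), drop = FALSE]
}

#' Community-weighted means of trait categories
#'
#' For every sample and codebook category, the fraction of the sample's
#' total (relative) abundance carried by species with that category. Uses
#' raw relative biomass for biomass matrices and 1/S weights for incidence
#' matrices, so within one trait the categories always sum to 1.
#'
#' @param m a [community_matrix()].
#' @param traits species trait table covering all species of `m`.
#' @param codebook a [trait_codebook()].
#' @return long data.frame: `sample_id`, `trait`, `category`, `cwm`.
#' @export
community_weighted_means <- function(m, traits, codebook = default_codebook()) {
  traits <- validate_traits(traits, codebook)
  x <- as_cm_values(m)
  miss <- setdiff(colnames(x)[colSums(x) > 0], rownames(traits))
  if (length(miss))
    stop_fmt("species missing trait values: %s", paste(miss, collapse = ", "))
  tot <- rowSums(x)
  if (any(tot <= 0))
    stop_fmt("empty sample(s): %s", paste(rownames(x)[tot <= 0], collapse = ", "))
  if (cm_basis(m) == "incidence") x <- 1 * (x > 0)
  praw <- x / rowSums(x)
  ind <- category_indicator(colnames(x), traits, codebook)
  cw <- praw %*% ind   # samples x categories
  key <- attr(ind, "key")
  out <- data.frame(
    sample_id = rep(rownames(x), times = ncol(cw)),
    trait = rep(key$trait, each = nrow(cw)),
    category = rep(key$category, each = nrow(cw)),
    cwm = as.numeric(cw),
    stringsAsFactors = FALSE)
  out[order(match(out$sample_id, rownames(x)),
            match(out$trait, codebook_traits(codebook))), , drop = FALSE]
}

# species x category 0/1 indicator over the full codebook vocabulary
category_indicator <- function(species, traits, codebook) {
  key <- unique(codebook[, c("trait_name", "category")])
  names(key) <- c("trait", "category")
  ind <- matrix(0, length(species), nrow(key),
                dimnames = list(species, paste(key$trait, key$category, sep = ":")))
  for (k in seq_len(nrow(key)))
    ind[, k] <- 1 * (traits[species, key$trait[k]] == key$category[k])
  attr(ind, "key") <- key
  ind
}
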