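FD_METRICS <- c("S", "D", "FRic", "FEve", "FDiv", "FDis", "RaoQ", "FRed", "FD")

# Fast per-sample metric engine shared by fd_profile() and the null
# ensembles. x is a plain samples x species matrix; dmat and coords are
# aligned to colnames(x). Returns a samples x metrics numeric matrix; when
# reasons = TRUE an attribute "reasons" holds a long data.frame explaining
# every NA.
compute_fd_matrix <- function(x, basis, dmat, coords, metrics = FD_METRICS,
                              rao_convention = "gower", reasons = FALSE) {
  ns <- nrow(x); nsp <- ncol(x)
  m <- ncol(coords)
  tot <- rowSums(x)
  ok <- tot > 0
  pres <- x > 0
  S <- rowSums(pres)

  if (basis == "incidence") {
    praw <- pres / pmax(S, 1)
    P <- praw
  } else {
    praw <- x / pmax(tot, .Machine$double.xmin)
    h <- sqrt(praw)
    P <- h / pmax(rowSums(h), .Machine$double.xmin)
  }

  out <- matrix(NA_real_, ns, length(metrics),
                dimnames = list(rownames(x), metrics))
  rsn <- if (reasons) list() else NULL
  add_reason <- function(sample, metric, code) {
    if (reasons) rsn[[length(rsn) + 1L]] <<- data.frame(
      sample_id = sample, metric = metric, reason_code = code,
      stringsAsFactors = FALSE)
  }

  if ("S" %in% metrics) out[, "S"] <- S
  if (any(c("D", "FRed") %in% metrics)) {
    # D shares the FD weight vector so that RaoQ <= D and FRed = 1 - RaoQ/D
    # hold on every row (they fail under mixed weighting conventions)
    D <- ifelse(ok, 1 - rowSums(P^2), NA_real_)
    if ("D" %in% metrics) out[, "D"] <- D
  }
  if (any(c("RaoQ", "FRed", "FD") %in% metrics)) {
    dm <- if (rao_convention == "squared_halved") dmat^2 / 2 else dmat
    Q <- ifelse(ok, rowSums((P %*% dm) * P), NA_real_)
    if ("RaoQ" %in% metrics) out[, "RaoQ"] <- Q
  }
  if ("FRed" %in% metrics) {
    if (rao_convention == "gower" && max(dmat) <= 1 + 1e-12 &&
        any(Q > D + 1e-9, na.rm = TRUE))
      stop_fmt("RaoQ exceeds Simpson D for some sample: upstream corruption")
    out[, "FRed"] <- ifelse(!is.na(D) & D > 0, 1 - Q / D, NA_real_)
    if (reasons) for (k in which(ok & !is.na(D) & D == 0))
      add_reason(rownames(x)[k], "FRed", "monoculture")
  }
  if (any(c("FDis", "FD") %in% metrics)) {
    C <- P %*% coords                       # weighted centroids, samples x m
    cross <- coords %*% t(C)                # species x samples
    d2 <- outer(rowSums(coords^2), rep(1, ns)) - 2 * cross +
      outer(rep(1, nsp), rowSums(C^2))
    FDis <- ifelse(ok, colSums(sqrt(pmax(d2, 0)) * t(P)), NA_real_)
    if ("FDis" %in% metrics) out[, "FDis"] <- FDis
  }
  if ("FD" %in% metrics) out[, "FD"] <- (FDis + Q) / 2

  need_hull <- any(c("FRic", "FDiv") %in% metrics)
  need_mst <- "FEve" %in% metrics
  if (need_hull || need_mst) {
    for (k in seq_len(ns)) {
      if (!ok[k]) next
      sp <- which(pres[k, ])
      Xk <- coords[sp, , drop = FALSE]
      pk <- P[k, sp]
      if (need_mst) {
        if (length(sp) < 3) {
          add_reason(rownames(x)[k], "FEve", "fewer_than_3_species")
        } else {
          fe <- functional_evenness_raw(Xk, pk)
          out[k, "FEve"] <- fe
          if (is.na(fe)) add_reason(rownames(x)[k], "FEve", "zero_spanning_tree")
        }
      }
      if (need_hull) {
        h <- convex_hull(Xk)
        if (isTRUE(h$degenerate)) {
          # covers both collinear configurations and <= m distinct points
          if ("FRic" %in% metrics) add_reason(rownames(x)[k], "FRic", "degenerate_hull")
          if ("FDiv" %in% metrics) add_reason(rownames(x)[k], "FDiv", "degenerate_hull")
          next
        }
        if ("FRic" %in% metrics) out[k, "FRic"] <- h$volume
        if ("FDiv" %in% metrics && length(sp) >= 3) {
          G <- colMeans(Xk[h$vertices, , drop = FALSE])
          dG <- sqrt(colSums((t(Xk) - G)^2))
          mdG <- mean(dG)
          dev <- dG - mdG
          denom <- sum(pk * abs(dev)) + mdG
          out[k, "FDiv"] <- if (denom > 0) (sum(pk * dev) + mdG) / denom else NA_real_
        } else if ("FDiv" %in% metrics && reasons) {
          add_reason(rownames(x)[k], "FDiv", "fewer_than_3_species")
        }
      }
    }
  }
  if (reasons) {
    for (k in which(!ok)) add_reason(rownames(x)[k], "all", "empty_sample")
    attr(out, "reasons") <- if (length(rsn)) do.call(rbind, rsn) else
      data.frame(sample_id = character(0), metric = character(0),
                 reason_code = character(0), stringsAsFactors = FALSE)
  }
  out
}

# internal FEve on raw coordinates/weights (pk sums to 1)
functional_evenness_raw <- function(X, p) {
  s <- nrow(X)
  E <- mst_edges(X)
  ew <- E$len / (p[E$i] + p[E$j])
  tot <- sum(ew)
  if (tot <= 0) return(NA_real_)
  pew <- ew / tot
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Default number of trait-space axes for hull metrics
#'
#' m = min(4, s_min - 1, number of positive axes), where s_min is the
#' smallest richness among samples that can enter FRic (S >= 3). This keeps
#' every such sample's hull computable and comparable across samples.
#'
#' @param space a [pcoa_embed()] trait space.
#' @param richness integer vector of per-sample species richness.
#' @return integer number of axes, at least 1.
#' @export
default_m_axes <- function(space, richness) {
  rich <- richness[richness >= 3]
  s_min <- if (length(rich)) min(rich) else 3L
  max(1L, min(4L, s_min - 1L, space$m))
}

#' Per-sample functional diversity profile
#'
#' Computes, for each sample of the supplied incidence and/or biomass
#' community matrices, species richness S, Simpson diversity D, FRic, FEve,
#' FDiv, FDis, RaoQ, functional redundancy FRed = 1 - RaoQ/D and the
#' composite FD = (FDis + RaoQ)/2, plus community-weighted means of the
#' trait categories. All metrics use one fixed trait space built from the
#' full species pool. Incidence weights are 1/S; biomass weights for the FD
#' indices and Simpson diversity are Hellinger-transformed relative
#' biomasses renormalized to sum one (one weight vector per basis, so
#' RaoQ <= D and the FRed identity hold on every row); the CWMs use raw
#' relative biomass.
#' Metrics whose preconditions fail are NA with a reason code.
#'
#' @param incidence,biomass [community_matrix()] objects (at least one).
#' @param traits species x trait data.frame covering the pooled species.
#' @param codebook a [trait_codebook()].
#' @param m_axes axes used for hull/MST/dispersion geometry; default
#'   [default_m_axes()].
#' @param correction PCoA correction, `"sqrt"` or `"none"`.
#' @param rao_convention `"gower"` or `"squared_halved"`.
#' @return list with `fd` (wide data.frame, one row per sample per basis,
#'   NA reasons in `attr(,"reasons")`), `cwm` (long data.frame, one block
#'   per basis), `space`, `dissimilarity` and `m_axes`.
#' @export
fd_profile <- function(incidence = NULL, biomass = NULL, traits,
                       codebook = default_codebook(), m_axes = NULL,
                       correction = "sqrt", rao_convention = "gower") {
  if (is.null(incidence) && is.null(biomass))
    stop_fmt("supply at least one of 'incidence' and 'biomass'")
  comms <- Filter(Negate(is.null), list(incidence = incidence, biomass = biomass))
  for (nm in names(comms)) {
    if (cm_basis(comms[[nm]]) != nm)
      stop_fmt("'%s' argument has basis '%s'", nm, cm_basis(comms[[nm]]))
    if (any(rowSums(as_cm_values(comms[[nm]])) == 0))
      stop_fmt("empty sample(s) in %s matrix; apply drop_empty_samples() first", nm)
  }
  traits <- validate_traits(traits, codebook)
  for (nm in names(comms)) {
    miss <- setdiff(colnames(comms[[nm]]), rownames(traits))
    if (length(miss))
      stop_fmt("species lacking traits: %s", paste(miss, collapse = ", "))
  }

  dmat <- gower_dissimilarity(traits, codebook)
  space <- pcoa_embed(dmat, correction = correction)
  rich <- unlist(lapply(comms, species_richness), use.names = FALSE)
  m_axes <- m_axes %||% default_m_axes(space, rich)

  fd <- NULL; reasons <- NULL; cwm <- NULL
  for (nm in names(comms)) {
    cm <- comms[[nm]]
    x <- as_cm_values(cm)
    sp <- colnames(x)
    vals <- compute_fd_matrix(
      x, basis = nm, dmat = dmat[sp, sp],
      coords = space$coordinates[sp, seq_len(m_axes), drop = FALSE],
      rao_convention = rao_convention, reasons = TRUE)
    df <- data.frame(sample_id = rownames(x), basis = nm,
                     as.data.frame(vals), stringsAsFactors = FALSE,
                     row.names = NULL)
    rs <- attr(vals, "reasons")
    if (nrow(rs)) rs$basis <- nm
    fd <- rbind(fd, df)
    reasons <- rbind(reasons, rs)
    cw <- community_weighted_means(cm, traits, codebook)
    cw$basis <- nm
    cwm <- rbind(cwm, cw[, c("sample_id", "basis", "trait", "category", "cwm")])
  }
  attr(fd, "reasons") <- reasons
  attr(fd, "weights") <- c(fd_indices = "hellinger-renormalized (biomass) / 1-S (incidence)",
                           cwm = "raw relative abundance")
  list(fd = fd, cwm = cwm, space = space, dissimilarity = dmat, m_axes = m_axes)
}

# long format of the fd table, for SES joins and CSV export
fd_long <- function(fd) {
  metrics <- intersect(FD_METRICS, names(fd))
  out <- do.call(rbind, lapply(metrics, function(mm)
    data.frame(sample_id = fd$sample_id, basis = fd$basis, metric = mm,
               observed = fd[[mm]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# CWM table to the same long schema, metric = "cwm:<trait>:<category>"
cwm_long <- function(cwm) {
  data.frame(sample_id = cwm$sample_id, basis = cwm$basis,
             metric = paste("cwm", cwm$trait, cwm$category, sep = ":"),
             observed = cwm$cwm, stringsAsFactors = FALSE)
}
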