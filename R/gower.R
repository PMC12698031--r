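#' Gower dissimilarity over mixed ordinal/categorical traits
#'
#' Pairwise species dissimilarity averaged over the codebook traits, each
#' trait contributing a value in [0, 1]. Categorical traits contribute 0
#' (same category) or 1 (different). Ordinal traits use Podani's (1999)
#' tie-corrected rank method on the average ranks of the trait values over
#' the species set:
#' \deqn{d_{ij} = \frac{|r_i - r_j| - (T_i - 1)/2 - (T_j - 1)/2}
#'       {r_{max} - r_{min} - (T_{max} - 1)/2 - (T_{min} - 1)/2}}
#' where \eqn{T_i} is the number of species tied with species i. With no
#' ties this reduces to |rank_i - rank_j| / (rank_max - rank_min). A trait
#' with a single observed category contributes 0 for all pairs (logged).
#'
#' @param traits species x trait data.frame (validated against `codebook`).
#' @param codebook a [trait_codebook()].
#' @return symmetric species x species matrix of dissimilarities in [0, 1],
#'   zero diagonal.
#' @export
gower_dissimilarity <- function(traits, codebook = default_codebook()) {
  traits <- validate_traits(traits, codebook)
  n <- nrow(traits)
  if (n < 2) stop_fmt("need at least two species to form pairs")
  sp <- rownames(traits)
  trs <- codebook_traits(codebook)
  acc <- matrix(0, n, n, dimnames = list(sp, sp))
  for (tr in trs) {
    v <- traits[[tr]]
    if (codebook_kind(codebook, tr) == "categorical") {
      dmat <- 1 * outer(v, v, "!=")
    } else {
      dmat <- podani_ordinal(v, codebook_ranks(codebook, tr))
      if (is.null(dmat)) {
        log_stage("gower", "ordinal trait '", tr,
                  "' has a single observed category; contributes 0")
        dmat <- matrix(0, n, n)
      }
    }
    if (length(unique(v)) == 1L && codebook_kind(codebook, tr) == "categorical")
      log_stage("gower", "trait '", tr,
                "' has a single observed category; contributes 0")
    acc <- acc + dmat
  }
  d <- acc / length(trs)
  diag(d) <- 0
  d
}

# Podani (1999) tie-corrected ordinal dissimilarity; returns NULL when the
# trait has a single observed level (denominator zero).
podani_ordinal <- function(v, level_ranks) {
  ord <- level_ranks[v]                 # ordinal scores
  r <- rank(ord)                        # average ranks over the species set
  tab <- table(r)
  Ti <- as.numeric(tab[as.character(r)])
  rmax <- max(r); rmin <- min(r)
  Tmax <- as.numeric(tab[as.character(rmax)])
  Tmin <- as.numeric(tab[as.character(rmin)])
  denom <- (rmax - rmin) - (Tmax - 1) / 2 - (Tmin - 1) / 2
  if (denom <= 0) return(NULL)
  num <- abs(outer(r, r, "-")) - outer(Ti - 1, Ti - 1, "+") / 2
  d <- pmax(num, 0) / denom
  d[outer(r, r, "==")] <- 0
  pmin(d, 1)
}
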