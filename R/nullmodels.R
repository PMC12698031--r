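#' Constrained randomization of an incidence matrix ("c0")
#'
#' Each species column's presences are reassigned to a uniformly random
#' subset of samples of the same size, independently per column. Column
#' sums (species frequencies) are preserved exactly; row sums (sample
#' richness) are free to vary.
#'
#' @param m an incidence [community_matrix()].
#' @return a randomized `community_matrix` (incidence).
#' @export
randomize_c0 <- function(m) {
  if (cm_basis(m) != "incidence") stop_fmt("randomize_c0 expects an incidence matrix")
  x <- as_cm_values(m)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x), dimnames = dimnames(x))
  cs <- colSums(x)
  for (j in seq_len(ncol(x))) {
    if (cs[j] == 0) next
    if (cs[j] == n) { out[, j] <- 1; next }
    out[sample.int(n, cs[j]), j] <- 1
  }
  community_matrix(out, basis = "incidence")
}

#' Constrained randomization of a biomass matrix ("c0_samp")
#'
#' Each species column's values (zeros included) are permuted across
#' samples, independently per column: column totals, per-species occurrence
#' counts and the multiset of nonzero values are preserved exactly; row
#' totals and richness are free to vary.
#'
#' @param m a biomass [community_matrix()].
#' @return a randomized `community_matrix` (biomass).
#' @export
randomize_c0_samp <- function(m) {
  if (cm_basis(m) != "biomass") stop_fmt("randomize_c0_samp expects a biomass matrix")
  x <- as_cm_values(m)
  n <- nrow(x)
  out <- x
  for (j in seq_len(ncol(x))) out[, j] <- x[sample.int(n), j]
  community_matrix(out, basis = "biomass", transformed = attr(m, "transformed"))
}

#' Null ensemble of per-sample metrics under a constrained randomization
#'
#' Randomizes the whole community matrix once per iteration (c0 for
#' incidence, c0_samp for biomass) and recomputes the requested metrics per
#' sample on the fixed species-pool trait space. NA null values are
#' dropped; ensembles with fewer than `min_valid` valid values are marked
#' unusable.
#'
#' @param community a [community_matrix()].
#' @param traits,codebook trait table and codebook for the species pool.
#' @param metrics FD metric names (subset of S, D, FRic, FEve, FDiv, FDis,
#'   RaoQ, FRed, FD).
#' @param include_cwm also build ensembles for every CWM category.
#' @param n_iter number of randomizations (1000 in the reference design).
#' @param seed integer seed; required when `strict = TRUE`.
#' @param m_axes,correction,rao_convention see [fd_profile()].
#' @param space optional precomputed [pcoa_embed()] trait space over the
#'   pooled species (must match `traits`).
#' @param dissimilarity optional precomputed Gower matrix.
#' @param min_valid usability threshold for an ensemble.
#' @param strict error when no seed is given.
#' @param return_nulls retain the raw null values (`attr(, "nulls")`).
#' @return long data.frame: `sample_id`, `basis`, `metric`, `n_iter`
#'   (valid draws), `null_mean`, `null_sd`, `usable`.
#' @export
build_null_ensemble <- function(community, traits, codebook = default_codebook(),
                                metrics = c("FRic", "FEve", "FDiv", "FDis",
                                            "RaoQ", "FRed", "FD"),
                                include_cwm = FALSE, n_iter = 1000, seed = NULL,
                                m_axes = NULL, correction = "sqrt",
                                rao_convention = "gower", space = NULL,
                                dissimilarity = NULL, min_valid = 100,
                                strict = FALSE, return_nulls = FALSE) {
  if (strict && is.null(seed)) stop_fmt("seed is required in strict mode")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(metrics %in% FD_METRICS))
  basis <- cm_basis(community)
  x <- as_cm_values(community)
  traits <- validate_traits(traits, codebook)
  dmat <- dissimilarity %||% gower_dissimilarity(traits, codebook)
  space <- space %||% pcoa_embed(dmat, correction = correction)
  m_axes <- m_axes %||% default_m_axes(space, species_richness(x))
  sp <- colnames(x)
  dsub <- dmat[sp, sp]
  coords <- space$coordinates[sp, seq_len(m_axes), drop = FALSE]
  ind <- if (include_cwm) category_indicator(sp, traits, codebook) else NULL
  cwm_names <- if (include_cwm) {
    key <- attr(ind, "key")
    paste("cwm", key$trait, key$category, sep = ":")
  }
  cols <- c(metrics, cwm_names)
  ns <- nrow(x)

  sums <- matrix(0, ns, length(cols), dimnames = list(rownames(x), cols))
  sq <- sums
  cnt <- sums
  nulls <- if (return_nulls)
    array(NA_real_, c(ns, length(cols), n_iter),
          dimnames = list(rownames(x), cols, NULL))

  rand_fun <- if (basis == "incidence") randomize_c0 else randomize_c0_samp
  for (it in seq_len(n_iter)) {
    xr <- as_cm_values(rand_fun(community))
    vals <- compute_fd_matrix(xr, basis, dsub, coords, metrics = metrics,
                              rao_convention = rao_convention)
    if (include_cwm) {
      tot <- rowSums(xr)
      xx <- if (basis == "incidence") 1 * (xr > 0) else xr
      pr <- xx / pmax(rowSums(xx), .Machine$double.xmin)
      cw <- pr %*% ind
      cw[tot == 0, ] <- NA_real_
      colnames(cw) <- cwm_names
      vals <- cbind(vals, cw)
    }
    fin <- is.finite(vals)
    v0 <- ifelse(fin, vals, 0)
    sums <- sums + v0
    sq <- sq + v0^2
    cnt <- cnt + fin
    if (return_nulls) nulls[, , it] <- vals
  }

  nm <- sums / pmax(cnt, 1)
  nv <- pmax(sq - cnt * nm^2, 0) / pmax(cnt - 1, 1)
  nsd <- sqrt(nv)
  out <- data.frame(
    sample_id = rep(rownames(x), times = length(cols)),
    basis = basis,
    metric = rep(cols, each = ns),
    n_iter = as.integer(cnt),
    null_mean = as.numeric(ifelse(cnt > 0, nm, NA_real_)),
    null_sd = as.numeric(ifelse(cnt > 1, nsd, NA_real_)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$usable <- out$n_iter >= min_valid & !is.na(out$null_sd) & out$null_sd > 0
  if (return_nulls) attr(out, "nulls") <- nulls
  out
}

#' Standardized effect sizes
#'
#' SES = (observed - null mean) / null sd, joined per sample x basis x
#' metric. NA (with the `usable` flag carried through) when the ensemble is
#' unusable or the null sd is zero.
#'
#' @param observed long data.frame with `sample_id`, `basis`, `metric`,
#'   `observed` (see [fd_profile()] output passed through `fd_long`-style
#'   reshaping, or build your own).
#' @param ensemble output of [build_null_ensemble()].
#' @return long data.frame with `observed`, `null_mean`, `null_sd`, `ses`.
#' @export
standardized_effect_size <- function(observed, ensemble) {
  need <- c("sample_id", "basis", "metric", "observed")
  if (!all(need %in% names(observed)))
    stop_fmt("observed must have columns: %s", paste(need, collapse = ", "))
  out <- merge(observed, ensemble, by = c("sample_id", "basis", "metric"),
               sort = FALSE)
  out$ses <- ifelse(out$usable & !is.na(out$observed),
                    (out$observed - out$null_mean) / out$null_sd, NA_real_)
  out
}

#' Test whether a group of SES values differs from zero
#'
#' Shapiro-Wilk at alpha = 0.05 decides the branch: a two-sided one-sample
#' t-test when normality is not rejected, otherwise a two-sided Wilcoxon
#' signed-rank test (zeros dropped; exact p for n <= 25 where possible,
#' normal approximation with continuity correction otherwise). Direction is
#' the sign of the sample median when p < 0.05.
#'
#' @param x numeric SES values (NAs dropped); needs >= 3 non-NA values.
#' @param alpha significance level (default 0.05, two-sided).
#' @return list with `test_used` ("t" or "wilcoxon"), `p_value`,
#'   `direction` ("positive", "negative" or "none") and `n`.
#' @export
test_ses_zero <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop_fmt("need at least 3 non-NA SES values (got %d)", n)
  if (length(unique(x)) == 1L) {
    warning("all SES values identical; Shapiro test undefined, using Wilcoxon",
            call. = FALSE)
    normal <- FALSE
  } else {
    normal <- shapiro.test(x)$p.value >= 0.05
  }
  if (normal) {
    test_used <- "t"
    p <- t.test(x, mu = 0)$p.value
  } else {
    test_used <- "wilcoxon"
    xz <- x[x != 0]
    if (length(xz) == 0) {
      p <- 1
    } else {
      p <- suppressWarnings(
        wilcox.test(xz, mu = 0, exact = length(xz) <= 25,
                    correct = TRUE)$p.value)
    }
  }
  dir <- "none"
  if (!is.na(p) && p < alpha) {
    md <- median(x)
    if (md > 0) dir <- "positive" else if (md < 0) dir <- "negative"
  }
  list(test_used = test_used, p_value = p, direction = dir, n = n)
}

#' Map an SES test result to an assembly-rule verdict
#'
#' For FD indices, significantly negative SES indicates habitat filtering
#' and significantly positive SES limiting similarity; for CWM categories
#' the analogues are trait convergence and trait divergence. Non-significant
#' results are labelled random.
#'
#' @param metric_family `"fd"` or `"cwm"`.
#' @param test result of [test_ses_zero()].
#' @return list with `metric_family`, `test_used`, `p_value`, `direction`,
#'   `label`.
#' @export
classify_assembly <- function(metric_family = c("fd", "cwm"), test) {
  metric_family <- match.arg(metric_family)
  lab <- if (test$direction == "negative") {
    if (metric_family == "fd") "habitat_filtering" else "trait_convergence"
  } else if (test$direction == "positive") {
    if (metric_family == "fd") "limiting_similarity" else "trait_divergence"
  } else "random"
  list(metric_family = metric_family, test_used = test$test_used,
       p_value = test$p_value, direction = test$direction, label = lab)
}

#' Rank-correlation trend of SES along the eutrophication gradient
#'
#' Spearman correlation of SES against log10(TP); a lightweight trend test
#' standing in for smooth gradient models.
#'
#' @param ses numeric SES values.
#' @param tp total phosphorus (ug/L), paired with `ses`.
#' @return list with `rho`, `p_value`, `n`.
#' @export
ses_trend <- function(ses, tp) {
  keep <- !is.na(ses) & !is.na(tp)
  ses <- ses[keep]; tp <- tp[keep]
  if (length(ses) < 5) stop_fmt("need at least 5 paired values")
  if (length(unique(ses)) == 1L || length(unique(tp)) == 1L)
    stop_fmt("constant input: trend undefined")
  ct <- suppressWarnings(cor.test(ses, log10(tp), method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(ses))
}

#' Per-group assembly calls from an SES table
#'
#' Splits the SES records by group ("entire" plus each trophic state when
#' `env` is given), runs [test_ses_zero()] per basis x metric, and maps the
#' outcome with [classify_assembly()]. CWM metrics (named `cwm:...`) use
#' the cwm family, FD indices the fd family; S and D are excluded.
#'
#' @param ses_df output of [standardized_effect_size()].
#' @param env environment table with `trophic_state` (row names = sample
#'   ids), or NULL for the entire-dataset grouping only.
#' @param min_n minimum group size for a test (default 3).
#' @return data.frame: `group`, `basis`, `metric`, `metric_family`,
#'   `test_used`, `p_value`, `direction`, `label`, `n`.
#' @export
assembly_calls <- function(ses_df, env = NULL, min_n = 3) {
  ses_df <- ses_df[!(ses_df$metric %in% c("S", "D")), , drop = FALSE]
  groups <- list(entire = ses_df)
  if (!is.null(env)) {
    st <- as.character(env[ses_df$sample_id, "trophic_state"])
    for (g in levels(env$trophic_state))
      groups[[g]] <- ses_df[!is.na(st) & st == g, , drop = FALSE]
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    if (!nrow(sub)) next
    for (key in unique(paste(sub$basis, sub$metric, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      cell <- sub[sub$basis == parts[1] & sub$metric == parts[2], ]
      x <- cell$ses[!is.na(cell$ses)]
      if (length(x) < min_n) next
      fam <- if (grepl("^cwm:", parts[2])) "cwm" else "fd"
      res <- classify_assembly(fam, test_ses_zero(x))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, basis = parts[1], metric = parts[2], metric_family = fam,
        test_used = res$test_used, p_value = res$p_value,
        direction = res$direction, label = res$label, n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(0), basis = character(0),
                      metric = character(0), metric_family = character(0),
                      test_used = character(0), p_value = numeric(0),
                      direction = character(0), label = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
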