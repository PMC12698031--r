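#' Configuration for the synthetic fishpond generator
#'
#' The defaults reproduce the reference study design: nine ponds sampled
#' monthly March-September (63 qualitative samples), with quantitative
#' biomass samples July-September (27 samples), a 59-species pool over the
#' default trait codebook, and a TP gradient of 50-600 ug/L spanning
#' eutrophic to highly hypereutrophic states.
#'
#' @param n_ponds number of ponds.
#' @param months sampled months (calendar numbers).
#' @param quant_months months with quantitative (biomass) sampling.
#' @param pool_size species-pool size (>= 5).
#' @param regime assembly regime realized by the generator: `"neutral"`
#'   (traits ignored), `"filtering"` (Gaussian TP-tolerance kernel) or
#'   `"limiting_similarity"` (nearest-neighbour rejection at colonization).
#' @param filter_width sigma of the tolerance kernel on the log10 TP scale.
#' @param similarity_threshold theta in [0, 1): a colonist is rejected while
#'   its Gower distance to every resident is below theta.
#' @param tp_range pond-level TP range (ug/L), increasing.
#' @param base_occupancy two Beta shape parameters for species baseline
#'   occurrence probabilities.
#' @param biomass_meanlog,biomass_sdlog lognormal biomass parameters
#'   (ug/L); per-species mean offsets are drawn around `biomass_meanlog`.
#' @param seed integer seed (optional; sub-seeds are derived per stage).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_ponds = 9, months = 3:9, quant_months = 7:9,
                             pool_size = 59,
                             regime = c("neutral", "filtering",
                                        "limiting_similarity"),
                             filter_width = 0.3, similarity_threshold = 0.25,
                             tp_range = c(50, 600),
                             base_occupancy = c(4, 5),
                             biomass_meanlog = log(20), biomass_sdlog = 0.8,
                             seed = NULL) {
  regime <- match.arg(regime)
  if (pool_size < 5) stop_fmt("pool_size must be at least 5")
  if (length(tp_range) != 2 || diff(tp_range) <= 0 || any(tp_range <= 0))
    stop_fmt("tp_range must be increasing and positive")
  if (filter_width <= 0) stop_fmt("filter_width must be positive")
  if (similarity_threshold < 0 || similarity_threshold >= 1)
    stop_fmt("similarity_threshold must lie in [0, 1)")
  if (!all(quant_months %in% months))
    stop_fmt("quant_months must be a subset of months")
  structure(list(n_ponds = n_ponds, months = months,
                 quant_months = quant_months, pool_size = pool_size,
                 regime = regime, filter_width = filter_width,
                 similarity_threshold = similarity_threshold,
                 tp_range = tp_range, base_occupancy = base_occupancy,
                 biomass_meanlog = biomass_meanlog,
                 biomass_sdlog = biomass_sdlog, seed = seed),
            class = "synthetic_config")
}

#' Reference study design
#'
#' Convenience constructor for the default design: 9 ponds x 7 qualitative
#' months (n = 63), 3 quantitative months (n = 27), 59-species pool.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
default_study_design <- function(...) synthetic_config(...)

# archetype composition of the pool, proportional to a 59-species reference
# community (rotifer-dominated, with cladoceran filtration guilds and
# copepods); each feeding type implies distributions over the other traits
# and a baseline TP-optimum percentile.
POOL_ARCHETYPES <- list(
  microphagous = list(n59 = 20, size = c("<200" = 1),
                      trophic = c(herbivorous = .6, detritivorous = .25, omnivorous = .15),
                      habitat = c(pelagic = .6, littoral = .4), opt_q = .45),
  raptorial_rotifer = list(n59 = 10, size = c("<200" = 1),
                           trophic = c(omnivorous = .5, carnivorous = .3, herbivorous = .2),
                           habitat = c(pelagic = .7, littoral = .3), opt_q = .5),
  stationary_suspension = list(n59 = 2, size = c(">600" = 1),
                               trophic = c(herbivorous = 1),
                               habitat = c(pelagic = 1), opt_q = .05),
  tactile_raptorial = list(n59 = 8, size = c("200-600" = .4, ">600" = .6),
                           trophic = c(omnivorous = .6, carnivorous = .4),
                           habitat = c(pelagic = .8, littoral = .2), opt_q = .95),
  D_filtration = list(n59 = 6, size = c(">600" = .7, "200-600" = .3),
                      trophic = c(herbivorous = 1),
                      habitat = c(pelagic = .9, littoral = .1), opt_q = .15),
  B_filtration = list(n59 = 4, size = c("200-600" = .7, "<200" = .3),
                      trophic = c(herbivorous = 1),
                      habitat = c(pelagic = .8, littoral = .2), opt_q = .45),
  C_filtration = list(n59 = 5, size = c("200-600" = .6, "<200" = .4),
                      trophic = c(detritivorous = .5, herbivorous = .5),
                      habitat = c(littoral = .9, pelagic = .1), opt_q = .5),
  S_filtration = list(n59 = 4, size = c(">600" = .5, "200-600" = .5),
                      trophic = c(herbivorous = 1),
                      habitat = c(littoral = .6, pelagic = .4), opt_q = .4))

# directional adjustments mirroring the reported trait responses to TP:
# omnivores (and, weakly, carnivores) thrive towards hypereutrophy,
# herbivores decline; medium-sized taxa are slightly favoured over large.
TROPHIC_OPT_SHIFT <- c(herbivorous = -0.1, omnivorous = 0.15,
                       carnivorous = 0.1, detritivorous = 0)
SIZE_OPT_SHIFT <- c("<200" = 0, "200-600" = 0.05, ">600" = -0.05)

#' Generate a species pool with trait syndromes and TP optima
#'
#' Trait values are sampled over the 17-category codebook with group
#' frequencies loosely matching a rotifer-dominated fishpond community.
#' Each species gets a TP optimum on the log10 scale derived from its trait
#' syndrome: high for tactile-raptorial omnivores, low for
#' stationary-suspension herbivores and D-filtration feeders, intermediate
#' otherwise, plus seeded jitter. Baseline occurrence probabilities and
#' per-species biomass scales are also drawn here.
#'
#' @param config a [synthetic_config()].
#' @return a `species_pool` list: `traits`, `optimum` (log10 ug/L),
#'   `baseline_p`, `meanlog`.
#' @export
generate_species_pool <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- config$pool_size
  raw <- vapply(POOL_ARCHETYPES, function(a) a$n59, 0)
  counts <- floor(raw / 59 * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw / 59 * n - counts
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  feeding <- rep(names(POOL_ARCHETYPES), counts)
  pick <- function(tbl, k) sample(names(tbl), k, replace = TRUE, prob = tbl)
  size <- character(n); trophic <- character(n); habitat <- character(n)
  optq <- numeric(n)
  for (ft in names(POOL_ARCHETYPES)) {
    a <- POOL_ARCHETYPES[[ft]]
    idx <- which(feeding == ft)
    if (!length(idx)) next
    size[idx] <- pick(a$size, length(idx))
    trophic[idx] <- pick(a$trophic, length(idx))
    habitat[idx] <- pick(a$habitat, length(idx))
    optq[idx] <- a$opt_q
  }
  optq <- pmin(pmax(optq + TROPHIC_OPT_SHIFT[trophic] + SIZE_OPT_SHIFT[size],
                    0.02), 0.98)
  lo <- log10(config$tp_range[1]); hi <- log10(config$tp_range[2])
  opt <- lo + optq * (hi - lo) + rnorm(n, 0, 0.05)
  opt <- pmin(pmax(opt, lo - 0.3), hi + 0.3)
  ids <- sprintf("sp%02d", seq_len(n))
  traits <- data.frame(size_class = size, feeding_type = feeding,
                       trophic_group = trophic, habitat = habitat,
                       row.names = ids, stringsAsFactors = FALSE)
  structure(list(
    traits = traits,
    optimum = setNames(as.numeric(opt), ids),
    baseline_p = setNames(pmin(pmax(rbeta(n, config$base_occupancy[1],
                                          config$base_occupancy[2]),
                                    0.05), 0.95), ids),
    meanlog = setNames(config$biomass_meanlog + rnorm(n, 0, 0.5), ids)),
    class = "species_pool")
}

#' Pond-by-month total phosphorus gradient
#'
#' Pond baselines are spaced over the log10 TP range (quantile positions
#' with a small seeded jitter) and every month adds a shared seasonal
#' offset that increases from March to August and holds in September, so
#' the pond-mean ordering is preserved across months.
#'
#' @param config a [synthetic_config()].
#' @return environment data.frame: row names are sample ids, columns `TP`,
#'   `pond`, `month`, `quantitative`, `trophic_state`.
#' @export
tp_gradient <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  lo <- log10(config$tp_range[1]); hi <- log10(config$tp_range[2])
  np <- config$n_ponds
  base <- lo + (seq_len(np) - 0.5) / np * (hi - lo) + rnorm(np, 0, 0.05)
  ponds <- sprintf("pond%02d", seq_len(np))
  grid <- expand.grid(pond = seq_len(np), month = config$months)
  seas <- 0.18 * pmin(grid$month - min(config$months), 5) / 5
  logtp <- base[grid$pond] + seas
  ids <- sprintf("%s_M%02d", ponds[grid$pond], grid$month)
  env <- data.frame(TP = 10^logtp, pond = ponds[grid$pond],
                    month = grid$month,
                    quantitative = grid$month %in% config$quant_months,
                    row.names = ids, stringsAsFactors = FALSE)
  env$trophic_state <- suppressWarnings(classify_trophic_state(env$TP))
  env
}

#' Assemble synthetic communities under a known regime
#'
#' Occurrence follows the configured regime. Neutral: every species occurs
#' with its baseline probability, traits ignored. Filtering: occurrence
#' probability is the baseline multiplied by a Gaussian kernel
#' exp(-(log10 TP - opt)^2 / (2 sigma^2)); biomass means are scaled by the
#' same kernel. Limiting similarity: species are offered in random order
#' with baseline probabilities, and a colonist is rejected while its Gower
#' distance to every resident is below theta. Biomass is drawn lognormally
#' for present species in the quantitative months only. Samples that come
#' out empty are redrawn up to 10 times.
#'
#' @param pool a [generate_species_pool()] result.
#' @param env a [tp_gradient()] table.
#' @param config the [synthetic_config()].
#' @return list with `incidence` and `biomass` [community_matrix()] objects.
#' @export
assemble_communities <- function(pool, env, config) {
  if (!is.null(config$seed)) set.seed(config$seed + 3L)
  ids <- rownames(pool$traits)
  n_sp <- length(ids)
  logtp <- log10(env$TP)
  dmat <- if (config$regime == "limiting_similarity")
    gower_dissimilarity(pool$traits) else NULL
  inc <- matrix(0, nrow(env), n_sp, dimnames = list(rownames(env), ids))
  kern <- matrix(1, nrow(env), n_sp)
  if (config$regime == "filtering") {
    kern <- exp(-outer(logtp, pool$optimum, "-")^2 /
                  (2 * config$filter_width^2))
  }
  for (k in seq_len(nrow(env))) {
    for (attempt in 1:10) {
      row <- draw_sample_row(pool, config, kern[k, ], dmat)
      if (any(row > 0)) break
    }
    if (!any(row > 0))
      stop_fmt("sample %s came out empty after 10 redraws", rownames(env)[k])
    inc[k, ] <- row
  }
  qrows <- which(env$quantitative)
  bio <- matrix(0, length(qrows), n_sp,
                dimnames = list(rownames(env)[qrows], ids))
  for (r in seq_along(qrows)) {
    k <- qrows[r]
    pres <- inc[k, ] > 0
    mu <- pool$meanlog[pres]
    if (config$regime == "filtering")
      mu <- mu + log(pmax(kern[k, pres], 1e-12))
    bio[r, pres] <- rlnorm(sum(pres), mu, config$biomass_sdlog)
  }
  if (any(rowSums(bio) == 0)) {
    # a quantitative sample can only be empty if its incidence row is empty,
    # which the redraw loop already prevents
    stop_fmt("internal error: empty biomass sample")
  }
  list(incidence = community_matrix(inc, basis = "incidence"),
       biomass = community_matrix(bio, basis = "biomass"))
}

draw_sample_row <- function(pool, config, kern_row, dmat) {
  ids <- rownames(pool$traits)
  n_sp <- length(ids)
  if (config$regime == "limiting_similarity") {
    row <- setNames(numeric(n_sp), ids)
    order_sp <- sample(ids)
    residents <- character(0)
    for (s in order_sp) {
      if (runif(1) > pool$baseline_p[s]) next
      if (length(residents) &&
          min(dmat[s, residents]) < config$similarity_threshold) next
      residents <- c(residents, s)
    }
    row[residents] <- 1
    row
  } else {
    p <- pool$baseline_p * kern_row
    setNames(rbinom(n_sp, 1, pmin(p, 1)), ids)
  }
}

#' Simulate a complete synthetic dataset
#'
#' Runs [generate_species_pool()], [tp_gradient()] and
#' [assemble_communities()] from one config and bundles the result with a
#' truth manifest (regime, parameters, seed).
#'
#' @param config a [synthetic_config()].
#' @return list: `pool`, `traits`, `env`, `incidence`, `biomass`, `truth`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  pool <- generate_species_pool(config)
  env <- tp_gradient(config)
  comms <- assemble_communities(pool, env, config)
  truth <- list(regime = config$regime,
                filter_width = config$filter_width,
                similarity_threshold = config$similarity_threshold,
                tp_range = config$tp_range,
                pool_size = config$pool_size,
                n_ponds = config$n_ponds, months = config$months,
                quant_months = config$quant_months, seed = config$seed)
  list(pool = pool, traits = pool$traits, env = env,
       incidence = comms$incidence, biomass = comms$biomass, truth = truth)
}

#' Write a simulated dataset as loader-compatible CSV inputs
#'
#' Writes community_incidence.csv, community_biomass.csv, traits.csv and
#' environment.csv (readable by [load_tables()]) plus truth.json.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(incidence = file.path(dir, "community_incidence.csv"),
             biomass = file.path(dir, "community_biomass.csv"),
             traits = file.path(dir, "traits.csv"),
             env = file.path(dir, "environment.csv"),
             truth = file.path(dir, "truth.json"))
  write_id_csv(format_num_df(as_cm_values(sim$incidence)), paths["incidence"],
               "sample_id")
  write_id_csv(format_num_df(as_cm_values(sim$biomass)), paths["biomass"],
               "sample_id")
  write_id_csv(sim$traits, paths["traits"], "species_id")
  env <- sim$env[, c("TP", "pond", "month"), drop = FALSE]
  write_id_csv(format_num_df(env), paths["env"], "sample_id")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
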