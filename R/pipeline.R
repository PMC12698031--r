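#' Pipeline configuration
#'
#' Either point the pipeline at CSV inputs (`community_incidence`,
#' `community_biomass`, `traits`, `env` paths; any one community basis may
#' be omitted) or let it simulate inputs by supplying `synthetic` (a
#' [synthetic_config()]).
#'
#' @param community_incidence,community_biomass,traits,env CSV paths.
#' @param synthetic a [synthetic_config()] used when no input paths are
#'   given.
#' @param metrics FD metrics to run through the null models.
#' @param include_cwm build null ensembles for CWM categories (biomass
#'   basis).
#' @param n_iter null-model iterations (>= 100; 1000 in the reference
#'   design).
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @param m_axes trait-space axes for hull metrics (default:
#'   [default_m_axes()]).
#' @param correction PCoA correction.
#' @param rao_convention RaoQ convention (see [rao_quadratic_entropy()]).
#' @param grouping `"entire"`, `"trophic_state"` or both.
#' @param out_dir output directory.
#' @param strict require a seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(community_incidence = NULL, community_biomass = NULL,
                            traits = NULL, env = NULL, synthetic = NULL,
                            metrics = c("FRic", "FEve", "FDiv", "FDis",
                                        "RaoQ", "FRed", "FD"),
                            include_cwm = TRUE, n_iter = 1000, seed = NULL,
                            m_axes = NULL, correction = "sqrt",
                            rao_convention = "gower",
                            grouping = c("entire", "trophic_state"),
                            out_dir = "pondfd_out", strict = FALSE) {
  if (n_iter < 100) stop_fmt("n_iter must be at least 100 (got %d)", n_iter)
  if (strict && is.null(seed)) stop_fmt("seed required in strict mode")
  grouping <- match.arg(grouping, several.ok = TRUE)
  have_paths <- !is.null(community_incidence) || !is.null(community_biomass)
  if (have_paths && (is.null(traits) || is.null(env)))
    stop_fmt("trait and environment paths are required with community input")
  if (!have_paths && is.null(synthetic))
    synthetic <- synthetic_config(seed = seed)
  structure(list(community_incidence = community_incidence,
                 community_biomass = community_biomass,
                 traits = traits, env = env, synthetic = synthetic,
                 metrics = metrics, include_cwm = include_cwm,
                 n_iter = n_iter, seed = seed, m_axes = m_axes,
                 correction = correction, rao_convention = rao_convention,
                 grouping = grouping, out_dir = out_dir, strict = strict),
            class = "pipeline_config")
}

#' Run the full assembly-rule pipeline
#'
#' Sequences: load or simulate inputs, Gower dissimilarity, PCoA trait
#' space, per-sample FD metrics and CWMs, null ensembles, standardized
#' effect sizes, per-group SES tests with assembly classification, and
#' SES-vs-TP trends. Writes fd_metrics.csv, cwm.csv, ses.csv,
#' assembly_calls.csv, trends.csv and run_manifest.json into
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all intermediate tables and the output
#'   directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ----
  if (!is.null(config$synthetic) && is.null(config$community_incidence) &&
      is.null(config$community_biomass)) {
    scfg <- config$synthetic
    if (is.null(scfg$seed)) scfg$seed <- config$seed
    log_stage("simulate", "regime = ", scfg$regime, ", seed = ",
              scfg$seed %||% "none")
    sim <- simulate_dataset(scfg)
    write_synthetic(sim, file.path(config$out_dir, "inputs"))
    incidence <- sim$incidence
    biomass <- sim$biomass
    traits <- sim$traits
    env <- sim$env
  } else {
    log_stage("load", "reading CSV inputs")
    incidence <- biomass <- NULL
    if (!is.null(config$community_incidence)) {
      b <- load_tables(config$community_incidence, config$traits, config$env,
                       mode = "incidence")
      incidence <- b$community; traits <- b$traits; env <- b$env
    }
    if (!is.null(config$community_biomass)) {
      b <- load_tables(config$community_biomass, config$traits, config$env,
                       mode = "biomass")
      biomass <- b$community
      if (is.null(incidence)) { traits <- b$traits; env <- b$env }
      else traits <- merge_traits(traits, b$traits)
    }
  }
  if (!is.null(incidence)) incidence <- drop_empty_samples(incidence)
  if (!is.null(biomass)) biomass <- drop_empty_samples(biomass)
  tick("inputs")

  # ---- trait space (fixed over the pooled species) ----
  log_stage("trait_space", "Gower dissimilarity and PCoA embedding")
  dmat <- gower_dissimilarity(traits)
  space <- pcoa_embed(dmat, correction = config$correction)
  rich <- c(if (!is.null(incidence)) species_richness(incidence),
            if (!is.null(biomass)) species_richness(biomass))
  m_axes <- config$m_axes %||% default_m_axes(space, rich)
  log_stage("trait_space", "m_axes = ", m_axes, ", quality = ",
            format_num(space$quality))
  tick("trait_space")

  # ---- observed metrics ----
  log_stage("metrics", "FD indices and CWMs")
  prof <- fd_profile(incidence = incidence, biomass = biomass, traits = traits,
                     m_axes = m_axes, correction = config$correction,
                     rao_convention = config$rao_convention)
  tick("metrics")

  # ---- null ensembles and SES ----
  ens <- NULL
  seed_off <- 10L
  for (cm in Filter(Negate(is.null), list(incidence, biomass))) {
    bs <- cm_basis(cm)
    log_stage("null", bs, " basis: ", config$n_iter, " iterations")
    e <- build_null_ensemble(
      cm, traits, metrics = config$metrics,
      include_cwm = config$include_cwm && bs == "biomass",
      n_iter = config$n_iter,
      seed = if (!is.null(config$seed)) config$seed + seed_off,
      m_axes = m_axes, correction = config$correction,
      rao_convention = config$rao_convention,
      space = space, dissimilarity = dmat, strict = config$strict)
    ens <- rbind(ens, e)
    seed_off <- seed_off + 1L
  }
  observed <- fd_long(prof$fd)
  if (config$include_cwm && !is.null(biomass))
    observed <- rbind(observed,
                      cwm_long(prof$cwm[prof$cwm$basis == "biomass", ]))
  observed <- observed[observed$metric %in% unique(ens$metric), ]
  ses <- standardized_effect_size(observed, ens)
  ses$group <- as.character(env[ses$sample_id, "trophic_state"])
  tick("null_models")

  # ---- group tests, classification, trends ----
  log_stage("classify", "per-group SES tests")
  env_for_groups <- if ("trophic_state" %in% config$grouping) env else NULL
  calls <- assembly_calls(ses, env_for_groups)
  trends <- ses_trends_table(ses, env)
  tick("classify")

  # ---- outputs ----
  fdm <- fd_metrics_long(prof$fd)
  outputs <- list(fd_metrics = fdm, cwm = prof$cwm, ses = ses_out_cols(ses),
                  assembly_calls = calls, trends = trends)
  for (nm in names(outputs)) {
    write_long_csv(outputs[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("pondFD")),
    config = config_echo(config),
    m_axes = m_axes,
    space_quality = space$quality,
    weights = as.list(attr(prof$fd, "weights")),
    row_counts = vapply(outputs, nrow, 0L),
    timings_s = as.list(timings))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "outputs in ", config$out_dir)
  invisible(list(fd = prof$fd, cwm = prof$cwm, ensemble = ens,
                 ses = ses, assembly_calls = calls, trends = trends,
                 space = space, dissimilarity = dmat, env = env,
                 traits = traits, m_axes = m_axes, out_dir = config$out_dir))
}

merge_traits <- function(a, b) {
  extra <- setdiff(rownames(b), rownames(a))
  if (length(extra)) a <- rbind(a, b[extra, , drop = FALSE])
  a
}

config_echo <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

ses_out_cols <- function(ses) {
  ses[, c("sample_id", "group", "basis", "metric", "observed",
          "null_mean", "null_sd", "ses")]
}

fd_metrics_long <- function(fd) {
  long <- fd_long(fd)
  names(long)[names(long) == "observed"] <- "value"
  rs <- attr(fd, "reasons")
  long$reason_code <- ""
  if (!is.null(rs) && nrow(rs)) {
    for (k in seq_len(nrow(rs))) {
      hit <- long$sample_id == rs$sample_id[k] & long$basis == rs$basis[k] &
        (long$metric == rs$metric[k] | rs$metric[k] == "all")
      long$reason_code[hit & is.na(long$value)] <- rs$reason_code[k]
    }
  }
  long
}

ses_trends_table <- function(ses, env) {
  rows <- list()
  for (key in unique(paste(ses$basis, ses$metric, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- ses[ses$basis == parts[1] & ses$metric == parts[2], ]
    tp <- env[sub$sample_id, "TP"]
    tr <- tryCatch(ses_trend(sub$ses, tp), error = function(e) NULL)
    if (is.null(tr)) next
    rows[[length(rows) + 1L]] <- data.frame(
      basis = parts[1], metric = parts[2], spearman_rho = tr$rho,
      p_value = tr$p_value, n = tr$n, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(basis = character(0), metric = character(0),
                      spearman_rho = numeric(0), p_value = numeric(0),
                      n = integer(0)))
  do.call(rbind, rows)
}

write_long_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
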