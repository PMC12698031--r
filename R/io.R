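#' Load and cross-validate the community, trait and environment tables
#'
#' Reads three CSV files (header row; first column is the row identifier):
#' a sample x species community table, a species x trait table, and a
#' sample-level environment table with columns `TP`, `pond` and `month`.
#' Species sets are reconciled: a species present (nonzero column total) in
#' the community but absent from the trait table is an error; trait-table
#' species absent from the community are dropped with a log message. Every
#' community sample must have an environment row; extra environment rows are
#' dropped with a log message.
#'
#' @param community_path,trait_path,env_path CSV file paths.
#' @param mode `"incidence"` or `"biomass"`.
#' @param codebook a [trait_codebook()].
#' @param transpose set TRUE if the community CSV is species x samples.
#' @return list with elements `community` ([community_matrix()]), `traits`
#'   (data.frame) and `env` (data.frame with derived `trophic_state`).
#' @export
load_tables <- function(community_path, trait_path, env_path,
                        mode = c("incidence", "biomass"),
                        codebook = default_codebook(), transpose = FALSE) {
  mode <- match.arg(mode)
  comm <- read_id_csv(community_path)
  if (transpose) comm <- as.data.frame(t(as.matrix(comm)))
  x <- as.matrix(comm)
  storage.mode(x) <- "double"
  community <- community_matrix(x, basis = mode)

  traits <- read_id_csv(trait_path)
  traits <- validate_traits(traits, codebook)

  present <- colnames(community)[colSums(as_cm_values(community)) > 0]
  missing_traits <- setdiff(present, rownames(traits))
  if (length(missing_traits))
    stop_fmt("species present in the community but absent from the trait table: %s",
             paste(missing_traits, collapse = ", "))
  extra <- setdiff(rownames(traits), colnames(community))
  if (length(extra)) {
    log_stage("load", "dropping trait rows for species not in the community: ",
              paste(extra, collapse = ", "))
    traits <- traits[setdiff(rownames(traits), extra), , drop = FALSE]
  }

  env <- read_id_csv(env_path)
  need <- c("TP", "pond", "month")
  miss <- setdiff(need, names(env))
  if (length(miss))
    stop_fmt("environment table is missing column(s): %s",
             paste(miss, collapse = ", "))
  no_env <- setdiff(rownames(community), rownames(env))
  if (length(no_env))
    stop_fmt("samples without an environment row: %s",
             paste(no_env, collapse = ", "))
  extra_env <- setdiff(rownames(env), rownames(community))
  if (length(extra_env)) {
    log_stage("load", "dropping environment rows for unknown samples: ",
              paste(extra_env, collapse = ", "))
  }
  env <- env[rownames(community), , drop = FALSE]
  env$TP <- as.numeric(env$TP)
  env$trophic_state <- classify_trophic_state(env$TP)

  list(community = community, traits = traits, env = env)
}

read_id_csv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("%s: expected an id column plus data columns", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_fmt("%s: duplicate ids: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

write_id_csv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a loaded bundle back to CSV files
#'
#' Inverse of [load_tables()]; round-trips through `load_tables()`.
#'
#' @param bundle list with `community`, `traits`, `env` (as from
#'   [load_tables()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(community = file.path(dir, "community.csv"),
             traits = file.path(dir, "traits.csv"),
             env = file.path(dir, "environment.csv"))
  write_id_csv(format_num_df(as_cm_values(bundle$community)),
               paths["community"], "sample_id")
  write_id_csv(bundle$traits, paths["traits"], "species_id")
  env <- bundle$env[, c("TP", "pond", "month"), drop = FALSE]
  write_id_csv(format_num_df(env), paths["env"], "sample_id")
  invisible(paths)
}

format_num_df <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format_num(df[[j]])
  rownames(df) <- rownames(x)
  df
}

# locale-independent, 10 significant digits, no trailing-zero noise
format_num <- function(v) {
  out <- formatC(v, digits = 10, format = "g", mode = "double")
  gsub(" ", "", out)
}
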