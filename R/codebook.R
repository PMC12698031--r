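#' Trait codebook
#'
#' A codebook fixes the closed vocabulary of trait categories: every trait
#' is either ordinal (categories carry a rank order, e.g. body size classes)
#' or categorical. Trait tables are validated against a codebook and the
#' Gower dissimilarity uses the codebook to decide how each trait enters
#' the distance.
#'
#' @param x data.frame with columns `trait_name`, `category`, `trait_kind`
#'   (`"ordinal"` or `"categorical"`) and `rank` (integer order for ordinal
#'   traits, `NA` for categorical ones).
#' @return A validated `trait_codebook` (a data.frame).
#' @export
trait_codebook <- function(x) {
  req <- c("trait_name", "category", "trait_kind", "rank")
  if (!all(req %in% names(x)))
    stop_fmt("codebook must have columns: %s", paste(req, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$trait_name <- as.character(x$trait_name)
  x$category <- as.character(x$category)
  x$trait_kind <- as.character(x$trait_kind)
  x$rank <- suppressWarnings(as.integer(x$rank))
  if (!all(x$trait_kind %in% c("ordinal", "categorical")))
    stop_fmt("trait_kind must be 'ordinal' or 'categorical'")
  for (tr in unique(x$trait_name)) {
    sub <- x[x$trait_name == tr, ]
    if (anyDuplicated(sub$category))
      stop_fmt("duplicate category in trait '%s'", tr)
    if (length(unique(sub$trait_kind)) != 1L)
      stop_fmt("trait '%s' mixes ordinal and categorical rows", tr)
    if (sub$trait_kind[1] == "ordinal") {
      if (anyNA(sub$rank) || anyDuplicated(sub$rank))
        stop_fmt("ordinal trait '%s' needs unique non-missing ranks", tr)
    }
  }
  class(x) <- c("trait_codebook", "data.frame")
  x
}

#' Default zooplankton trait codebook
#'
#' Four traits with 17 categories in total: an ordinal body-size class
#' (<200, 200-600, >600 um), eight feeding types (microphagous and raptorial
#' rotifers; stationary-suspension calanoids; tactile-raptorial cyclopoids,
#' harpacticoids and Leptodoridae; and the D-, B-, C- and S-filtration
#' cladoceran guilds), four trophic groups and two habitat affinities.
#'
#' @return A `trait_codebook`.
#' @export
default_codebook <- function() {
  path <- system.file("extdata", "trait_codebook.csv", package = "pondFD")
  if (path == "") path <- file.path("inst", "extdata", "trait_codebook.csv")
  trait_codebook(read.csv(path, stringsAsFactors = FALSE))
}

codebook_traits <- function(codebook) unique(codebook$trait_name)

codebook_categories <- function(codebook, trait) {
  codebook$category[codebook$trait_name == trait]
}

codebook_kind <- function(codebook, trait) {
  codebook$trait_kind[codebook$trait_name == trait][1]
}

codebook_ranks <- function(codebook, trait) {
  sub <- codebook[codebook$trait_name == trait, ]
  setNames(sub$rank, sub$category)
}

#' Validate a species trait table against a codebook
#'
#' @param traits data.frame of species trait values; row names are species
#'   ids and there is one column per codebook trait.
#' @param codebook a [trait_codebook()].
#' @return `traits`, invisibly coerced to character columns, after checks.
#' @export
validate_traits <- function(traits, codebook = default_codebook()) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  if (is.null(rownames(traits)) || anyDuplicated(rownames(traits)))
    stop_fmt("trait table needs unique species ids as row names")
  trs <- codebook_traits(codebook)
  miss <- setdiff(trs, names(traits))
  if (length(miss))
    stop_fmt("trait table is missing trait column(s): %s",
             paste(miss, collapse = ", "))
  for (tr in trs) {
    v <- as.character(traits[[tr]])
    if (anyNA(v) || any(!nzchar(v)))
      stop_fmt("missing values in trait '%s' (species: %s)", tr,
               paste(rownames(traits)[is.na(v) | !nzchar(v)], collapse = ", "))
    bad <- !(v %in% codebook_categories(codebook, tr))
    if (any(bad))
      stop_fmt("trait '%s' has value(s) outside the codebook for species %s: %s",
               tr, paste(rownames(traits)[bad], collapse = ", "),
               paste(unique(v[bad]), collapse = ", "))
    traits[[tr]] <- v
  }
  traits[, trs, drop = FALSE]
}
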