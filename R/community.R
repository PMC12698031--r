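#' Community matrix constructor
#'
#' A community matrix holds samples as rows and species as columns, with
#' values that are either presence/absence (`basis = "incidence"`) or
#' biomass in ug/L (`basis = "biomass"`).
#'
#' @param x numeric matrix with sample ids as row names and species ids as
#'   column names.
#' @param basis `"incidence"` or `"biomass"`.
#' @param transformed `"none"` or `"hellinger"` (set by
#'   [hellinger_transform()]).
#' @return a `community_matrix`.
#' @export
community_matrix <- function(x, basis = c("incidence", "biomass"),
                             transformed = "none") {
  basis <- match.arg(basis)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_fmt("community matrix needs sample row names and species column names")
  if (anyDuplicated(rownames(x)))
    stop_fmt("duplicate sample ids: %s",
             paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_fmt("duplicate species ids: %s",
             paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop_fmt("community matrix contains missing values")
  if (any(x < 0)) stop_fmt("community matrix contains negative values")
  if (basis == "incidence" && !all(x %in% c(0, 1)))
    stop_fmt("incidence matrix may only contain 0 and 1")
  if (!transformed %in% c("none", "hellinger"))
    stop_fmt("transformed must be 'none' or 'hellinger'")
  structure(x, basis = basis, transformed = transformed,
            class = c("community_matrix", class(x)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d species [%s, %s]\n",
              nrow(x), ncol(x), cm_basis(x), attr(x, "transformed")))
  invisible(x)
}

#' Basis (incidence or biomass) of a community matrix
#' @param m a [community_matrix()]
#' @return `"incidence"` or `"biomass"`
#' @export
cm_basis <- function(m) attr(m, "basis") %||% "biomass"

as_cm_values <- function(m) {
  # plain numeric matrix view
  y <- unclass(m)
  attr(y, "basis") <- NULL
  attr(y, "transformed") <- NULL
  y
}

#' Hellinger transformation
#'
#' Replaces each biomass value by the square root of its within-sample
#' relative abundance, y'_ij = sqrt(y_ij / sum_j y_ij), so that each row has
#' unit sum of squares. Recommended before distance-based analyses of
#' composition data.
#'
#' @param m a biomass [community_matrix()], untransformed.
#' @return a `community_matrix` with `transformed = "hellinger"`.
#' @export
hellinger_transform <- function(m) {
  if (cm_basis(m) != "biomass")
    stop_fmt("hellinger_transform expects a biomass matrix")
  if (attr(m, "transformed") != "none")
    stop_fmt("matrix is already transformed")
  x <- as_cm_values(m)
  tot <- rowSums(x)
  if (any(tot <= 0))
    stop_fmt("sample(s) with zero total biomass: %s (drop them explicitly with drop_empty_samples())",
             paste(rownames(x)[tot <= 0], collapse = ", "))
  y <- sqrt(sweep(x, 1, tot, "/"))
  community_matrix(y, basis = "biomass", transformed = "hellinger")
}

#' Relative abundance weights for one sample
#'
#' For a biomass matrix these are relative biomasses; for an incidence
#' matrix every present species gets weight 1/S.
#'
#' @param m a [community_matrix()]
#' @param sample_id a row name of `m`
#' @return named numeric vector over all species, summing to 1.
#' @export
relative_abundance <- function(m, sample_id) {
  if (!sample_id %in% rownames(m)) stop_fmt("unknown sample id '%s'", sample_id)
  v <- as_cm_values(m)[sample_id, ]
  tot <- sum(v)
  if (tot <= 0) stop_fmt("sample '%s' is empty", sample_id)
  if (cm_basis(m) == "incidence") {
    p <- (v > 0) / sum(v > 0)
  } else {
    p <- v / tot
  }
  setNames(as.numeric(p), colnames(m))
}

#' Drop all-zero samples, with a log message
#'
#' Metrics never silently skip empty rows; empty samples must be removed
#' explicitly by this filter.
#'
#' @param m a [community_matrix()]
#' @return the filtered `community_matrix`.
#' @export
drop_empty_samples <- function(m) {
  tot <- rowSums(as_cm_values(m))
  if (any(tot == 0)) {
    log_stage("filter", "dropping empty sample(s): ",
              paste(rownames(m)[tot == 0], collapse = ", "))
    m <- community_matrix(as_cm_values(m)[tot > 0, , drop = FALSE],
                          basis = cm_basis(m),
                          transformed = attr(m, "transformed"))
  }
  m
}

#' Species richness per sample
#'
#' Count of species with a nonzero entry in each row.
#'
#' @param m a [community_matrix()] or plain matrix / numeric row.
#' @return integer vector of counts.
#' @export
species_richness <- function(m) {
  if (is.null(dim(m))) return(sum(m > 0))
  rowSums(unclass(m) > 0)
}
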