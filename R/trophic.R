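#' Classify trophic state from total phosphorus
#'
#' Maps TP (ug/L) to the trophic states used to split the eutrophication
#' gradient: eutrophic [40, 100), hypereutrophic [100, 300) and highly
#' hypereutrophic [300, Inf). Intervals are half-open and lower-inclusive.
#' TP below 40 ug/L is below the gradient studied here and is labelled
#' eutrophic with a warning.
#'
#' @param tp numeric vector of total phosphorus, ug/L; must be positive.
#' @return ordered factor with levels eutrophic < hypereutrophic <
#'   highly_hypereutrophic.
#' @export
classify_trophic_state <- function(tp) {
  if (!is.numeric(tp) || anyNA(tp)) stop_fmt("TP must be numeric, no NAs")
  if (any(tp <= 0)) stop_fmt("TP must be positive (got %s)",
                             paste(tp[tp <= 0], collapse = ", "))
  if (any(tp < 40))
    warning(sprintf("%d TP value(s) below 40 ug/L: below the eutrophic range, labelled eutrophic",
                    sum(tp < 40)), call. = FALSE)
  lv <- c("eutrophic", "hypereutrophic", "highly_hypereutrophic")
  out <- ifelse(tp >= 300, lv[3], ifelse(tp >= 100, lv[2], lv[1]))
  factor(out, levels = lv, ordered = TRUE)
}
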