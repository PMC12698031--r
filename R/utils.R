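`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fmt("'%s' must be a single finite number", name)
}
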