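# Internal validation helpers shared across modules.

abort <- function(..., class = "lncprofiler_error") {
  stop(errorCondition(paste0(...), class = c(class, "lncprofiler_error")))
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x))
    abort(what, " contains ", length(bad), " non-finite value(s); first at index ",
          bad[1], class = "lncprofiler_nonfinite")
  }
  invisible(x)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so every stochastic operation in
#' the package draws from its own reproducible stream without disturbing the
#' caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
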