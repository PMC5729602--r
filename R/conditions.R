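# Classed conditions so callers can distinguish bad inputs from method failures.

lvtrab_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lvtrab_error", "error")))
}

abort_validation <- function(msg) lvtrab_abort(msg, "lvtrab_validation_error")
abort_input <- function(msg) lvtrab_abort(msg, "lvtrab_input_error")
abort_segmentation <- function(msg) lvtrab_abort(msg, "lvtrab_segmentation_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are pure
#' functions of their arguments and never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
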