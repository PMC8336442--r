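# Classed error conditions used across the package so callers can
# discriminate failure modes programmatically.

sl_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "slkgnn_error"), call = call))
}

abort_format    <- function(msg) sl_abort(msg, "slkgnn_format_error")
abort_integrity <- function(msg) sl_abort(msg, "slkgnn_integrity_error")
abort_empty     <- function(msg) sl_abort(msg, "slkgnn_empty_error")
abort_type      <- function(msg) sl_abort(msg, "slkgnn_type_error")
abort_capacity  <- function(msg) sl_abort(msg, "slkgnn_capacity_error")
abort_config    <- function(msg) sl_abort(msg, "slkgnn_config_error")
abort_shape     <- function(msg) sl_abort(msg, "slkgnn_shape_error")
abort_numeric   <- function(msg) sl_abort(msg, "slkgnn_numeric_error")
abort_invariant <- function(msg) sl_abort(msg, "slkgnn_invariant_error")
abort_metric    <- function(msg) sl_abort(msg, "slkgnn_metric_error")

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
# seed = NULL leaves the current stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
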