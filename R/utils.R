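# Internal helpers: classed conditions and small numeric utilities.

stim_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "stim_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_schema      <- function(msg) stim_abort(msg, "stim_schema_error")
abort_referential <- function(msg) stim_abort(msg, "stim_referential_error")
abort_validation  <- function(msg) stim_abort(msg, "stim_validation_error")
abort_input       <- function(msg) stim_abort(msg, "stim_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (divide-by-n) standard deviation; the standardisation used
# throughout the package so that z-scoring a sample against its own stats
# gives exactly unit spread.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Snap a value to the nearest multiple of `step`, exact halves rounded down.
snap_to_step <- function(x, step) {
  k <- x / step
  lo <- floor(k)
  frac <- k - lo
  step * ifelse(frac > 0.5, lo + 1, lo)
}

is_count <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
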