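# internal helpers shared across modules

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed dating tables in this field
#' conventionally round half up. Used for ka-scale TMRCA output only.
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a consistent error class so callers/tests can distinguish
# validation failures from programming errors
ychron_stop <- function(msg, class = "ychron_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

# deterministic seed derivation for simulation sub-stages; keeps results
# inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
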