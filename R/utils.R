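# Internal helpers shared across modules.

# Round half away from zero (deterministic "round-half-up" for nonnegative x).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_physioscreen <- function(code, msg) {
  cond <- structure(
    class = c(code, "physioscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Test-type prefix of a test label: leading letters before the first digit
# or separator, e.g. "C1" -> "C", "N-S" -> "N", "E" -> "E".
test_type_prefix <- function(labels) {
  sub("^([A-Za-z]+).*$", "\\1", labels)
}

# Truncated-normal draws (lower truncation only), via inverse CDF.
rnorm_trunc <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}
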