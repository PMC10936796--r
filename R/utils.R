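# Internal helpers: classed conditions, truncated-normal draws, seed handling.

# All package errors carry class "tn_error" plus a specific subclass so
# callers (and tests) can condition on the failure mode rather than the
# message text.
tn_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tn_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

tn_assert <- function(cond, msg, class) {
  if (!isTRUE(cond)) tn_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

# Inverse-CDF sampler for a Normal truncated to [lo, hi]; exact and
# deterministic under set.seed().
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Per-operation seed sequence: one user-facing seed drives each generator
# stage through a distinct offset, so stages can be regenerated independently
# and any derived seed stays inside 32-bit integer range.
tn_seed <- function(seed, offset) {
  tn_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number", "tn_config_error")
  as.integer((abs(seed) + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
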