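#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Derive a 32-bit sub-seed from a master seed and an integer tag, so that
# per-patient / per-stage random substreams are reproducible and independent
# of iteration order. Arithmetic in double precision, reduced mod 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  x <- (abs(seed) %% m) + 1
  # two rounds of a multiplicative congruential mix
  x <- (x * 48271) %% m
  x <- (x + (abs(tag) %% m) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

# Scalar checks with informative errors.
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) check_scalar(x, name, 0, 1)

# Largest grid point <= t for a grid anchored at 0 with the given step.
floor_grid <- function(t, step) floor(t / step) * step

# Smallest grid point >= t.
ceiling_grid <- function(t, step) ceiling(t / step) * step
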