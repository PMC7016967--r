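stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Sample-count rounding used throughout for non-integer `duration * rate`
#' (e.g. 51.2 Hz times 2 s = 102.4 samples rounds to 102). Unlike [round()],
#' which rounds half to even, halves move away from zero so the rule is
#' reproducible across languages.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' round_half_away(c(102.4, 102.5, -2.5))
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers never perturb the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed fan-out: one global seed plus small integer counters
# (subject, trial, modality ...) give a stable per-unit seed below 2^31.
sub_seed <- function(seed, ...) {
  ks <- c(...)
  primes <- c(1000003L, 10007L, 797L, 101L, 31L)
  acc <- as.double(seed) %% 2147483647
  for (i in seq_along(ks)) {
    acc <- (acc * 48271 + as.double(ks[i]) * primes[((i - 1L) %% 5L) + 1L]) %% 2147483647
  }
  as.integer(acc %% 2147483562) + 1L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
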