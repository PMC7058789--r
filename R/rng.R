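#' Counter-based seed splitting
#'
#' All randomness in the package flows from one master seed. Sub-streams
#' (per case, per perturbation variant, per mask slice, per pipeline stage)
#' are derived by hashing the master seed together with integer keys through
#' a Lehmer multiplicative congruential generator, so results do not depend
#' on the order in which sub-streams are consumed. All arithmetic stays
#' below 2^53 and outputs stay below 2^31, making the scheme exact in
#' doubles and safe for [set.seed()].
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the sub-stream.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' sub_seed(1, 3, 7)
#' @export
sub_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  a <- 48271
  keys <- c(vapply(list(...), as.numeric, numeric(1)))
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  step <- function(s) (a * s) %% m
  s <- step(s)
  for (k in keys) {
    s <- (s + (abs(k) %% (m - 1))) %% m
    if (s == 0) s <- 1
    s <- step(step(s))
  }
  as.integer(s)
}

# Uniform draws from a keyed counter stream, without touching .Random.seed.
counter_runif <- function(n, seed, ...) {
  m <- 2147483647
  a <- 48271
  s <- sub_seed(seed, ...)
  u <- numeric(n)
  for (i in seq_len(n)) {
    s <- (a * as.numeric(s)) %% m
    u[i] <- s / m
  }
  u
}
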