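#' @keywords internal
#' @importFrom stats fft rpois rnorm dnorm lm coef median sd cor cor.test
#'   wilcox.test approx complete.cases
#' @importFrom graphics lines abline
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Speed of light in vacuum, cm/ns
.C_VACUUM <- 29.9792458

#' Derive a stream seed from a session seed
#'
#' All randomness in the simulators flows from a single session seed.
#' Sub-streams (per repetition, per channel) use a fixed affine splitting
#' scheme modulo the Mersenne prime 2^31 - 1 so that fixtures are
#' bit-reproducible and streams do not collide for small indices.
#'
#' @param seed integer session seed.
#' @param k integer stream index (>= 0).
#' @return an integer seed suitable for [set.seed()].
#' @export
split_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + k * 9973 + 1) %% m)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

# midpoints of a bin-edge vector
bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
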