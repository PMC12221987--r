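#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rlnorm rpois runif rbinom sd median cor quantile
#' @importFrom stats uniroot optim lm AIC t.test pt coef var setNames cor.test
NULL

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stream of child seeds from one master seed
#'
#' All stochastic stages (kill-curve generator, cytometry generator, lineage
#' simulator, replicate loops) draw their seeds from a single master seed
#' through this splitter, so an entire pipeline run is reproducible from one
#' integer. Child seeds stay below 2^31 - 1.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds.
#' @param stream Optional stream label (integer offset) separating stages that
#'   share a master seed.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n = 1L, stream = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  base <- (as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483629
  (as.integer(base) + 7919L * seq_len(n)) %% 2147483629L
}

# Sarle's bimodality coefficient on a numeric vector: (skew^2 + 1) / kurtosis,
# with kurtosis the (non-excess) standardized fourth moment. Values above the
# uniform-distribution reference 5/9 indicate bi- or multimodality.
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  (skew^2 + 1) / kurt
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))
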