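# Internal helpers shared across modules.

#' @importFrom stats qlogis plogis qnorm qt qchisq qf optimize optim optimHess
#'   rbinom rnorm rlnorm dbinom dnorm pchisq setNames qbeta var sd
#'   complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never disturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  force(expr)
}

# Derive a per-stage seed from one global seed, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 11L, spillover = 23L, diagnosis = 37L, pipeline = 51L,
    coverage = 67L, recovery = 83L
  )
  off <- offsets[[stage]]
  if (is.null(off)) off <- sum(utf8ToInt(stage)) %% 97L
  as.integer((as.double(seed) * 101 + off) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
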