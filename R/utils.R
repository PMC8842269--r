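#' @keywords internal
"_PACKAGE"

## Wald multiplier for a 95% interval, fixed to the conventional value used
## when reporting OR [95% CI] tables.
Z95 <- 1.959964

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Solve a 2x2 probability table with fixed margins and odds ratio
#'
#' Given marginal probabilities `p = P(A=1)` and `q = P(B=1)` and a target
#' odds ratio `or`, returns the unique joint probability `p11 = P(A=1,B=1)`
#' such that the 2x2 table has the requested margins and odds ratio
#' (the Plackett construction). Used by the cohort generator to couple
#' binary covariates without disturbing their marginals.
#'
#' @param p,q marginal probabilities in \[0,1\].
#' @param or target odds ratio (> 0).
#' @return `P(A=1, B=1)`.
#' @examples
#' p11 <- solve_2x2_or(0.526, 0.238, 3)
#' @export
solve_2x2_or <- function(p, q, or) {
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1, or > 0)
  if (abs(or - 1) < 1e-12) return(p * q)
  s <- 1 + (p + q) * (or - 1)
  disc <- s^2 - 4 * or * (or - 1) * p * q
  p11 <- (s - sqrt(disc)) / (2 * (or - 1))
  ## numerical guard: p11 must lie within the Frechet bounds
  min(max(p11, max(0, p + q - 1)), min(p, q))
}

## round half away from zero (base round() uses banker's rounding, which
## would turn e.g. 6.5 into 6; clinical NNT/NNG tables round half up)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
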