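# Noncentral chi-square power analysis for likelihood-ratio (delta G^2)
# tests, in the style of G*Power's "Chi^2: Goodness-of-fit" procedures.
# The noncentrality parameter is lambda = w^2 * N, where N counts
# observations (participants x decisions per participant), not
# participants.

#' Achieved power of a chi-square test
#'
#' Upper-tail mass of the noncentral chi-square(df, `lambda = w^2 * n_obs`)
#' beyond the central chi-square critical value at `alpha`. At `w = 0` this
#' equals `alpha` exactly.
#'
#' @param w Cohen's effect size (>= 0).
#' @param n_obs Number of observations entering the statistic
#'   (participants x decisions per participant).
#' @param df Degrees of freedom of the test.
#' @param alpha Significance level.
#' @return Achieved power in (0, 1).
#' @export
#' @examples
#' chi2_power(w = 0.06, n_obs = 203 * 20, df = 1, alpha = 0.05)
chi2_power <- function(w, n_obs, df, alpha = 0.05) {
  stopifnot(w >= 0, n_obs >= 1, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = w^2 * n_obs, lower.tail = FALSE)
}

#' Sensitivity analysis: minimal detectable effect size
#'
#' Solves `chi2_power(w, n_obs, df, alpha) = target_power` for `w` by
#' bisection on [0, 1] to absolute tolerance 1e-8.
#'
#' @param target_power Target power, in (alpha, 1).
#' @param n_obs,df,alpha As in [chi2_power()].
#' @return Minimal detectable `w`.
#' @export
#' @examples
#' sensitivity_w(0.95, n_obs = 203 * 20, df = 1)  # about 0.057 -> "0.06"
sensitivity_w <- function(target_power, n_obs, df, alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  f <- function(w) chi2_power(w, n_obs, df, alpha) - target_power
  lo <- 0; hi <- 1
  if (f(hi) < 0)
    stop("no effect size in [0, 1] reaches the target power at this n_obs",
         call. = FALSE)
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' A-priori sample size for a chi-square test
#'
#' Smallest participant count `n` such that
#' `chi2_power(w, n * decisions_per_participant, df, alpha) >=
#' target_power`. The bracket is found by doubling, then the exact minimum
#' by scanning near the bracket.
#'
#' @param w Effect size to detect (> 0).
#' @param target_power Target power in (alpha, 1).
#' @param decisions_per_participant Observations contributed per
#'   participant (20 in the standard design: 20 test-phase punishment
#'   decisions).
#' @param df,alpha As in [chi2_power()].
#' @return Minimal integer participant count.
#' @export
#' @examples
#' a_priori_n(w = 0.02, target_power = 0.95, decisions_per_participant = 20,
#'            df = 1)  # 1625
a_priori_n <- function(w, target_power, decisions_per_participant = 20,
                       df = 1, alpha = 0.05) {
  stopifnot(w > 0, target_power > alpha, target_power < 1,
            decisions_per_participant >= 1)
  pow <- function(n) chi2_power(w, n * decisions_per_participant, df, alpha)
  hi <- 1L
  while (pow(hi) < target_power) {
    hi <- hi * 2L
    if (hi > .Machine$integer.max / 2)
      stop("required sample size exceeds integer range", call. = FALSE)
  }
  lo <- max(1L, hi %/% 2L)
  # binary search down to a window, then linear scan for the exact minimum
  while (hi - lo > 32L) {
    mid <- (lo + hi) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
  }
  for (n in seq.int(lo, hi)) if (pow(n) >= target_power) return(n)
  hi
}
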