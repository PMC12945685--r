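# Binary-outcome MR statistical power and minimal detectable effect.
#
# Power follows the standard non-centrality-parameter calculation for a
# 1-df test of the MR estimate: NCP = b_MR^2 / var(b_MR), where b_MR is
# the expected per-unit change in case probability implied by a true
# odds ratio at prevalence K, and var(b_MR) reflects the outcome sample
# size N and the exposure variance R^2 explained by the instruments.

#' Parameters for binary-outcome MR power
#'
#' @param K outcome prevalence in (0, 1)
#' @param N outcome sample size
#' @param R2 proportion of exposure variance explained by the IVs, [0, 1)
#' @param alpha test size (default 0.05)
#' @param target_power power defining the MDE (default 0.8)
#' @return list of class `power_params`
#' @export
power_params <- function(K, N, R2, alpha = 0.05, target_power = 0.8) {
  stop_if_not_scalar_prob(K, "K", open_right = TRUE)
  stopifnot(N > 0, R2 >= 0, R2 < 1, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  structure(list(K = K, N = N, R2 = R2, alpha = alpha,
                 target_power = target_power), class = "power_params")
}

#' Variance in exposure explained by a set of instruments
#'
#' R^2 = sum_i 2 MAF_i (1 - MAF_i) b_i^2 with b_i the per-allele effects
#' on the standardized exposure. The per-instrument effect enters
#' squared; see the methods vignette for why the unsquared variant is
#' not a variance. Capped below 1 with a warning when exceeded.
#'
#' @param mafs minor allele frequencies
#' @param betas standardized-exposure per-allele effects
#' @param squared set FALSE to reproduce the unsquared summand form
#'   (documentation only; can go negative)
#' @return R^2 in [0, 1) (unless `squared = FALSE`)
#' @export
iv_r2 <- function(mafs, betas, squared = TRUE) {
  if (length(mafs) != length(betas))
    stop("mafs and betas must have equal length")
  if (!length(mafs)) return(0)
  terms <- 2 * mafs * (1 - mafs) * (if (squared) betas^2 else betas)
  r2 <- sum(terms)
  if (squared && r2 >= 1) {
    warning("summed R2 >= 1; capped just below 1")
    r2 <- 1 - 1e-12
  }
  r2
}

#' Expected change in case probability for a true odds ratio
#'
#' b_MR = K (OR / (1 + K (OR - 1)) - 1): the difference in outcome
#' probability per unit exposure implied by OR at prevalence K.
#'
#' @param K prevalence
#' @param OR true odds ratio of the exposure on the outcome
#' @return b_MR (vectorized over OR)
#' @export
b_mr <- function(K, OR) {
  stopifnot(all(OR > 0))
  K * (OR / (1 + K * (OR - 1)) - 1)
}

ncp_binary <- function(params, OR, var_form = c("difference", "product")) {
  var_form <- match.arg(var_form)
  b <- b_mr(params$K, OR)
  v <- switch(var_form,
    difference = (params$K * (1 - params$K) - b^2) / (params$N * params$R2),
    # the product form makes NCP independent of OR (kept for reference)
    product = (params$K * (1 - params$K) * b^2) / (params$N * params$R2))
  b^2 / v
}

#' Statistical power of a binary-outcome MR test
#'
#' Power is the upper-tail probability of a noncentral chi-square (1 df,
#' NCP) beyond the central chi-square (1 - alpha) quantile, with
#' NCP = b_MR^2 / var(b_MR) and
#' var(b_MR) = (K (1 - K) - b_MR^2) / (N R^2).
#'
#' @param params [power_params()]
#' @param OR true odds ratio (vectorized)
#' @param var_form "difference" (default) or "product"; see the methods
#'   vignette for why the product form cannot define an MDE
#' @return power in [0, 1]
#' @export
power_binary <- function(params, OR, var_form = "difference") {
  stopifnot(inherits(params, "power_params"))
  if (params$R2 == 0) {
    warning("R2 = 0: instruments carry no information; power equals alpha")
    return(rep(params$alpha, length(OR)))
  }
  ncp <- ncp_binary(params, OR, var_form)
  # var(b_MR) <= 0 (|b_MR| at its prevalence bound): the test rejects
  # with certainty
  ncp[!is.finite(ncp) | ncp < 0] <- Inf
  crit <- stats::qchisq(1 - params$alpha, df = 1)
  out <- stats::pchisq(crit, df = 1, ncp = pmin(ncp, 1e6),
                       lower.tail = FALSE)
  out[ncp == Inf] <- 1
  out
}

#' Minimal detectable odds ratio at target power
#'
#' Bisection on OR > 1 (and symmetrically on OR < 1 for the protective
#' side) until the power curve crosses `target_power`, to a tolerance of
#' 1e-6 in OR. Also records a power curve over an OR grid.
#'
#' @param params [power_params()] with R2 > 0
#' @param or_max search ceiling (default 100)
#' @param grid_n points of the recorded power curve
#' @return object of class `power_result` with `mde` (risk side, >= 1),
#'   `mde_protective` (<= 1), `ncp_at_mde`, `b_mr_at_mde`, `or_grid`,
#'   `power`; [not_applicable()] when target power is unreachable below
#'   `or_max`
#' @export
mde <- function(params, or_max = 100, grid_n = 200L) {
  stopifnot(inherits(params, "power_params"), params$R2 > 0)
  target <- params$target_power
  pw <- function(or) power_binary(params, or)
  if (pw(or_max) < target)
    return(not_applicable(sprintf(
      "power %.3f at OR = %g never reaches target %.2f",
      pw(or_max), or_max, target)))
  bisect <- function(lo, hi) {
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (pw(mid) >= target) hi <- mid else lo <- mid
    }
    hi
  }
  m_risk <- bisect(1, or_max)
  # protective side searched directly on OR < 1
  lo <- 1 / or_max; hi <- 1
  if (pw(lo) >= target) {
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (pw(mid) >= target) lo <- mid else hi <- mid
    }
    m_prot <- lo
  } else m_prot <- NA_real_
  or_grid <- exp(seq(log(1 / or_max), log(or_max), length.out = grid_n))
  structure(list(mde = m_risk, mde_protective = m_prot,
                 ncp_at_mde = ncp_binary(params, m_risk),
                 b_mr_at_mde = b_mr(params$K, m_risk),
                 or_grid = or_grid, power = pw(or_grid), params = params),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("<power_result> MDE OR = %.4f (protective %.4f) at ",
                     "power %.0f%%, K=%.2g, N=%g, R2=%.3g\n"),
              x$mde, x$mde_protective, 100 * x$params$target_power,
              x$params$K, x$params$N, x$params$R2))
  invisible(x)
}
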