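# Pleiotropy and directionality sensitivity analyses: MR-PRESSO (global,
# per-variant outlier and distortion tests), Steiger filtering on the
# liability scale for binary outcomes, and assembly of the sensitivity
# suite consumed by the causal-call cascade.

# leave-one-out IVW estimates for every instrument, from running sums
loo_ivw <- function(bx, by, w) {
  sxy <- sum(bx * by * w); sxx <- sum(bx^2 * w)
  (sxy - bx * by * w) / (sxx - bx^2 * w)
}

#' MR-PRESSO pleiotropy residual sum of squares test
#'
#' Global test: the observed weighted residual sum of squares of each
#' outcome effect around its leave-one-out IVW prediction is compared
#' against `n_sim` parametric simulations under the fitted model
#' (exposure and outcome effects redrawn from their sampling
#' distributions around the leave-one-out fit). Per-variant outlier
#' p-values are Bonferroni-corrected at 0.05 to define outliers; the
#' outlier-corrected estimate is IVW on the remaining instruments. The
#' distortion test compares the observed raw-vs-corrected estimate shift
#' with shifts induced by removing random instrument subsets of the same
#' size.
#'
#' @param insts `instrument_set` with at least 4 instruments
#' @param n_sim number of parametric simulations (default 1000)
#' @param seed integer seed
#' @param outlier_alpha familywise outlier significance level (default 0.05)
#' @param distortion_alpha distortion-test level governing which estimate
#'   is chosen (default 0.05)
#' @return object of class `presso_result` with `global_p`, `outliers`
#'   (data frame id/p), `distortion_p`, `raw`, `corrected`, `chosen`;
#'   [not_applicable()] when n_iv < 4
#' @export
mr_presso <- function(insts, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05,
                      distortion_alpha = 0.05) {
  d <- iv_frame(insts)
  k <- nrow(d)
  if (k < 4) return(not_applicable("MR-PRESSO requires >= 4 instruments"))
  w <- 1 / d$se_y^2
  bx <- d$beta_x; by <- d$beta_y
  b_loo <- loo_ivw(bx, by, w)
  res_obs <- (by - b_loo * bx)^2 * w
  rss_obs <- sum(res_obs)

  sim <- with_seed(child_seed(seed, "presso_global"), {
    BX <- matrix(stats::rnorm(n_sim * k, rep(bx, each = n_sim),
                              rep(d$se_x, each = n_sim)), n_sim, k)
    BY <- matrix(stats::rnorm(n_sim * k, rep(b_loo * bx, each = n_sim),
                              rep(d$se_y, each = n_sim)), n_sim, k)
    W <- matrix(w, n_sim, k, byrow = TRUE)
    SXY <- rowSums(BX * BY * W); SXX <- rowSums(BX^2 * W)
    BL <- (SXY - BX * BY * W) / (SXX - BX^2 * W)   # LOO per sim/variant
    RES <- (BY - BL * BX)^2 * W
    list(rss = rowSums(RES), res = RES)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  out_p <- colMeans(sweep(sim$res, 2, res_obs, ">="))
  out_p_bonf <- pmin(out_p * k, 1)
  is_out <- out_p_bonf < outlier_alpha
  outliers <- data.frame(id = d$id[is_out], p = out_p_bonf[is_out],
                         stringsAsFactors = FALSE)
  raw <- mr_ivw(d)
  raw$method <- "presso_raw"
  corrected <- not_applicable("no outliers detected")
  distortion_p <- not_applicable("no outliers detected")
  chosen <- raw
  if (any(is_out) && sum(!is_out) >= 1) {
    corrected <- mr_ivw(d[!is_out, , drop = FALSE])
    corrected$method <- "presso_corrected"
    n_out <- sum(is_out)
    if (n_out < k) {
      obs_shift <- corrected$estimate - raw$estimate
      shifts <- with_seed(child_seed(seed, "presso_distortion"), {
        vapply(seq_len(n_sim), function(b) {
          drop_idx <- sample.int(k, n_out)
          mr_ivw(d[-drop_idx, , drop = FALSE])$estimate - raw$estimate
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(shifts) >= abs(obs_shift))) / (1 + n_sim)
      if (distortion_p < distortion_alpha) chosen <- corrected
    }
  }
  structure(list(global_p = global_p, outliers = outliers,
                 distortion_p = distortion_p, raw = raw,
                 corrected = corrected, chosen = chosen,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global_p=%.3g, %d outlier(s), chosen=%s\n",
              x$global_p, nrow(x$outliers), x$chosen$method))
  invisible(x)
}

#' Liability-scale variance explained for a binary outcome association
#'
#' Converts a per-allele logistic log-OR into the proportion of liability
#' variance explained. The log-OR is first mapped to the observed (0/1)
#' scale using the study case fraction P, then to the liability scale via
#' the standard prevalence transformation
#' r2_liab = r2_obs * K^2 (1-K)^2 / (P (1-P) z^2) with z the standard
#' normal density at the (1-K) quantile.
#'
#' @param logor per-allele log odds ratio (vectorized)
#' @param eaf effect-allele frequency
#' @param n_case,n_ctrl study case/control counts
#' @param K population prevalence
#' @return liability-scale r^2 per variant
#' @export
r2_liability <- function(logor, eaf, n_case, n_ctrl, K) {
  stop_if_not_scalar_prob(K, "K", open_right = TRUE)
  P <- n_case / (n_case + n_ctrl)
  vg <- 2 * eaf * (1 - eaf)
  # observed-scale linear coefficient approximating the logistic slope
  b_obs <- logor * P * (1 - P)
  r2_obs <- b_obs^2 * vg / (P * (1 - P))
  z <- stats::dnorm(stats::qnorm(1 - K))
  r2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Steiger directionality filtering on the liability scale
#'
#' Per instrument, the exposure variance explained is
#' 2 maf (1-maf) beta_x^2 on the standardized-exposure scale (falling
#' back to F/(F + n - 2) when the allele frequency is missing); the
#' outcome variance explained is [r2_liability()] at prevalence `K`. An
#' instrument is kept when it explains more variance in the exposure than
#' in the outcome liability; the Steiger-filtered IVW is computed on the
#' kept set.
#'
#' @param insts `instrument_set` whose outcome records carry n_case/n_ctrl
#' @param K outcome prevalence (default 0.10)
#' @return object of class `steiger_result` with `kept` (instrument data
#'   frame), `removed` ids, per-variant `r2_exposure` /
#'   `r2_outcome_liability`, and `steiger_ivw`
#' @export
steiger_filter <- function(insts, K = 0.10) {
  d <- iv_frame(insts)
  if (!nrow(d)) stop("empty instrument set")
  if (any(is.na(d$n_case)) || any(is.na(d$n_ctrl)))
    stop("Steiger filtering requires outcome n_case and n_ctrl")
  maf <- pmin(d$eaf_x, 1 - d$eaf_x)
  r2x <- ifelse(is.na(maf),
                d$f_stat / (d$f_stat + d$n_x - 2),
                2 * maf * (1 - maf) * d$beta_x^2)
  r2y <- r2_liability(d$beta_y, ifelse(is.na(d$eaf_y), d$eaf_x, d$eaf_y),
                      d$n_case, d$n_ctrl, K)
  keep <- r2x > r2y
  kept <- d[keep, , drop = FALSE]
  ivw <- if (nrow(kept) >= 1) {
    r <- mr_ivw(kept); r$method <- "steiger_ivw"; r
  } else not_applicable("all instruments removed by Steiger filtering")
  structure(list(kept = kept, removed = d$id[!keep],
                 r2_exposure = r2x, r2_outcome_liability = r2y, K = K,
                 steiger_ivw = ivw),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> kept %d / %d instrument(s) at K=%.2g\n",
              nrow(x$kept), nrow(x$kept) + length(x$removed), x$K))
  invisible(x)
}

#' Run the full sensitivity suite for one instrument set
#'
#' Populates IVW (Wald ratio for a single instrument), weighted median,
#' MR-Egger, MR-PRESSO (chosen estimate per its distortion rule) and
#' Steiger-filtered IVW, respecting each method's minimum instrument
#' count; components that cannot run are [not_applicable()]. The
#' concordance flag records whether every applicable sensitivity estimate
#' agrees in sign with the IVW estimate (configurable to CI overlap).
#'
#' @param insts `instrument_set`
#' @param K outcome prevalence for Steiger filtering
#' @param n_boot weighted-median bootstrap replicates
#' @param presso_n_sim MR-PRESSO simulation count
#' @param seed integer seed
#' @param concordance "sign" (default) or "ci": CI overlap with the IVW
#'   point estimate
#' @return object of class `sensitivity_suite`
#' @export
run_sensitivity_suite <- function(insts, K = 0.10, n_boot = 1000L,
                                  presso_n_sim = 1000L, seed = 1L,
                                  concordance = c("sign", "ci")) {
  concordance <- match.arg(concordance)
  d <- iv_frame(insts)
  if (!nrow(d)) stop("empty instrument set")
  ivw <- mr_ivw(d)
  wm <- mr_weighted_median(insts, n_boot = n_boot,
                           seed = child_seed(seed, "wm"))
  egger <- mr_egger(insts)
  presso <- mr_presso(insts, n_sim = presso_n_sim,
                      seed = child_seed(seed, "presso"))
  steiger <- if (nrow(d) < 2) {
    # single-instrument traits cannot be verified by sensitivity analyses
    not_applicable("sensitivity analyses require >= 2 instruments")
  } else {
    tryCatch(steiger_filter(insts, K = K), error = function(e)
      not_applicable(conditionMessage(e)))
  }
  presso_chosen <- if (is_na_result(presso)) presso else presso$chosen
  steiger_ivw <- if (is_na_result(steiger)) steiger else steiger$steiger_ivw
  het <- cochran(insts, estimate = ivw$estimate)
  egger_intercept_p <- if (is_na_result(egger)) egger else
    egger$extra$intercept_p

  comps <- list(wm = wm, egger = egger, presso_chosen = presso_chosen,
                steiger_ivw = steiger_ivw)
  applicable <- Filter(Negate(is_na_result), comps)
  concordant <- if (!length(applicable)) {
    not_applicable("no sensitivity method applicable (single instrument)")
  } else if (concordance == "sign") {
    all(vapply(applicable, function(m)
      sign(m$estimate) == sign(ivw$estimate), logical(1)))
  } else {
    all(vapply(applicable, function(m) {
      ci <- confint.mr_result(m)
      ivw$estimate >= ci[1] && ivw$estimate <= ci[2]
    }, logical(1)))
  }
  structure(list(ivw = ivw, wm = wm, egger = egger,
                 presso = presso, presso_chosen = presso_chosen,
                 steiger = steiger, steiger_ivw = steiger_ivw,
                 het = het, egger_intercept_p = egger_intercept_p,
                 concordant = concordant),
            class = "sensitivity_suite")
}

#' @export
print.sensitivity_suite <- function(x, ...) {
  fmt <- function(m) if (is_na_result(m)) "NA" else sprintf("%.4g", m$estimate)
  cat(sprintf(paste0("<sensitivity_suite> ivw=%.4g, wm=%s, egger=%s, ",
                     "presso=%s, steiger=%s, concordant=%s\n"),
              x$ivw$estimate, fmt(x$wm), fmt(x$egger), fmt(x$presso_chosen),
              fmt(x$steiger_ivw),
              if (is_na_result(x$concordant)) "NA" else x$concordant))
  invisible(x)
}
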