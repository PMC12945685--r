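# Point estimators and heterogeneity statistics for two-sample MR on a
# harmonized instrument set. Estimates are log-ORs per 1-SD change in the
# genetically predicted exposure.

mr_result <- function(method, estimate, se, p = NULL, n_iv, extra = list()) {
  if (is.null(p)) p <- z_pvalue(estimate, se)
  structure(list(method = method, estimate = estimate, se = se, p = p,
                 n_iv = as.integer(n_iv), extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result:%s> estimate=%.4g (OR %.4g), se=%.4g, p=%.3g, n_iv=%d\n",
              x$method, x$estimate, exp(x$estimate), x$se, x$p, x$n_iv))
  invisible(x)
}

#' Confidence interval for an MR estimate
#' @param object `mr_result`
#' @param parm ignored
#' @param level confidence level
#' @param ... ignored
#' @return two-column matrix on the log-OR scale
#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$estimate - z * object$se,
           object$estimate + z * object$se), 1, 2,
         dimnames = list(object$method, c("lower", "upper")))
}

het_stats <- function(Q, df) {
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(Q = Q, df = as.integer(df),
                 p = stats::pchisq(Q, df, lower.tail = FALSE), I2 = I2),
            class = "het_stats")
}

#' @export
print.het_stats <- function(x, ...) {
  cat(sprintf("<het_stats> Q=%.4g (df=%d, p=%.3g), I2=%.1f%%\n",
              x$Q, x$df, x$p, x$I2))
  invisible(x)
}

#' Wald ratio estimator for a single instrument
#'
#' estimate = beta_y / beta_x with first-order delta-method standard
#' error se_y / |beta_x| and a two-sided normal p-value.
#'
#' @param beta_x,se_x exposure association and SE
#' @param beta_y,se_y outcome association and SE
#' @return `mr_result`
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x = 0: variant cannot instrument the exposure")
  mr_result("wald", estimate = beta_y / beta_x, se = se_y / abs(beta_x),
            n_iv = 1L)
}

iv_frame <- function(insts) {
  if (inherits(insts, "instrument_set")) insts$instruments else insts
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect weighted regression of the outcome effects on the
#' exposure effects through the origin with weights 1/se_y^2. With a
#' single instrument this is exactly the Wald ratio. Optional
#' multiplicative random-effects scaling inflates the SE by the square
#' root of Q/(n-1) floored at 1.
#'
#' @param insts `instrument_set` (or its instrument data frame)
#' @param scale_se apply multiplicative random-effects SE scaling
#'   (default FALSE, plain fixed-effect IVW)
#' @return `mr_result`; heterogeneity statistics are attached as
#'   `$extra$het` when n_iv >= 2
#' @export
mr_ivw <- function(insts, scale_se = FALSE) {
  d <- iv_frame(insts)
  k <- nrow(d)
  if (k == 0) stop("empty instrument set")
  if (k == 1) return(wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y))
  w <- 1 / d$se_y^2
  sxx <- sum(d$beta_x^2 * w)
  est <- sum(d$beta_x * d$beta_y * w) / sxx
  se <- 1 / sqrt(sxx)
  Q <- sum((d$beta_y - est * d$beta_x)^2 * w)
  if (scale_se) se <- se * max(1, sqrt(Q / (k - 1)))
  res <- mr_result("ivw", est, se, n_iv = k)
  res$extra$het <- het_stats(Q, k - 1)
  res
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept (weights 1/se_y^2) after orienting all exposure effects
#' positive. The slope is the causal estimate; the intercept tests
#' directional pleiotropy. Standard errors use multiplicative
#' overdispersion with the scale floored at 1; p-values are t-based with
#' n_iv - 2 degrees of freedom.
#'
#' @param insts `instrument_set`
#' @return `mr_result` with `extra$intercept`, `extra$intercept_se`,
#'   `extra$intercept_p`; [not_applicable()] when n_iv < 3
#' @export
mr_egger <- function(insts) {
  d <- iv_frame(insts)
  k <- nrow(d)
  if (k < 3) return(not_applicable("MR-Egger requires >= 3 instruments"))
  sgn <- sign(d$beta_x); sgn[sgn == 0] <- 1
  bx <- d$beta_x * sgn; by <- d$beta_y * sgn
  w <- 1 / d$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, X * w)
  cf <- solve(XtWX, crossprod(X, by * w))
  resid <- by - X %*% cf
  sigma2 <- sum(w * resid^2) / (k - 2)
  scale <- max(1, sigma2)
  V <- solve(XtWX) * scale
  est <- cf[2]; se <- sqrt(V[2, 2])
  int <- cf[1]; int_se <- sqrt(V[1, 1])
  p <- 2 * stats::pt(-abs(est / se), df = k - 2)
  mr_result("egger", est, se, p = p, n_iv = k,
            extra = list(intercept = int, intercept_se = int_se,
                         intercept_p = 2 * stats::pt(-abs(int / int_se),
                                                     df = k - 2)))
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Weighted median of the per-instrument Wald ratios with inverse-variance
#' weights on the delta-method ratio SEs, interpolating at cumulative
#' standardized weight 0.5. The SE comes from a seeded parametric
#' bootstrap resampling the exposure and outcome effects from their
#' sampling distributions.
#'
#' @param insts `instrument_set`
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return `mr_result`; [not_applicable()] when n_iv < 3
#' @export
mr_weighted_median <- function(insts, n_boot = 1000L, seed = 1L) {
  d <- iv_frame(insts)
  k <- nrow(d)
  if (k < 3) return(not_applicable("weighted median requires >= 3 instruments"))
  ratio <- d$beta_y / d$beta_x
  se_r <- d$se_y / abs(d$beta_x)
  w <- 1 / se_r^2
  est <- weighted_median_point(ratio, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, d$beta_x, d$se_x)
      by <- stats::rnorm(k, d$beta_y, d$se_y)
      bx[bx == 0] <- .Machine$double.eps
      rb <- by / bx
      weighted_median_point(rb, 1 / (d$se_y / abs(bx))^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se, n_iv = k)
}

#' Cochran's Q heterogeneity across instruments
#'
#' Q = sum w_j (ratio_j - estimate)^2 with w_j = (beta_x_j / se_y_j)^2,
#' df = n_iv - 1; I^2 = max(0, (Q - df)/Q) * 100.
#'
#' @param insts `instrument_set`
#' @param estimate reference causal estimate (defaults to the IVW estimate)
#' @return `het_stats`; [not_applicable()] when n_iv < 2
#' @export
cochran <- function(insts, estimate = NULL) {
  d <- iv_frame(insts)
  k <- nrow(d)
  if (k < 2) return(not_applicable("heterogeneity requires >= 2 instruments"))
  if (is.null(estimate)) estimate <- mr_ivw(d)$estimate
  w <- (d$beta_x / d$se_y)^2
  Q <- sum(w * (d$beta_y / d$beta_x - estimate)^2)
  het_stats(Q, k - 1)
}
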