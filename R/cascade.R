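# The causal-call cascade: multiple-testing correction within each
# analysis stratum, the four-criterion causal decision, replication
# evaluation with its five-criterion ladder, and cross-ancestry
# random-effects meta-analysis.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values, order-preserving with the input.
#'
#' @param pvals numeric vector of p-values in (0, 1]
#' @return q-values in input order (empty in, empty out)
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

# conjunction over criteria where NA (not-applicable) entries are skipped
.skip_na_all <- function(flags) {
  flags <- flags[!is.na(flags)]
  if (!length(flags)) return(NA)
  all(flags)
}

#' Four-criterion causal call for one trait
#'
#' Criteria: (1) FDR-corrected IVW/Wald q-value below `q_threshold`;
#' (2) sign-concordant sensitivity estimates; (3) no significant
#' heterogeneity (I^2 below `i2_threshold`) and no significant
#' directional pleiotropy (Egger intercept p at or above
#' `egger_alpha`); (4) colocalization max PPH4 above `pph4_threshold`.
#' Criteria 2-3 are recorded not-applicable (and skipped in the
#' conjunction) when too few instruments exist to evaluate them;
#' criteria 1 and 4 are always required.
#'
#' @param mr headline `mr_result` (IVW, or Wald ratio for one instrument)
#' @param q FDR-adjusted p-value for this trait within its stratum
#' @param suite `sensitivity_suite` (or NULL for single-instrument traits)
#' @param coloc `coloc_result` or [not_applicable()]
#' @param trait_id,ancestry,tissue labels
#' @param q_threshold,i2_threshold,pph4_threshold,egger_alpha strict
#'   comparator thresholds (defaults 0.05, 50, 0.8, 0.05)
#' @return one-row data frame of class `causal_decision`
#' @export
call_causal <- function(mr, q, suite = NULL, coloc = NULL,
                        trait_id = "trait", ancestry = "NA", tissue = NA,
                        q_threshold = 0.05, i2_threshold = 50,
                        pph4_threshold = 0.8, egger_alpha = 0.05) {
  crit_q <- q < q_threshold
  crit_sensitivity <- NA
  crit_het_pleio <- NA
  if (!is.null(suite) && !is_na_result(suite)) {
    if (!is_na_result(suite$concordant))
      crit_sensitivity <- isTRUE(suite$concordant)
    parts <- logical(0)
    if (!is_na_result(suite$het))
      parts <- c(parts, suite$het$I2 < i2_threshold)
    if (!is_na_result(suite$egger_intercept_p))
      parts <- c(parts, suite$egger_intercept_p >= egger_alpha)
    if (length(parts)) crit_het_pleio <- all(parts)
  }
  crit_coloc <- if (is.null(coloc) || is_na_result(coloc)) NA else
    coloc$max_pph4 > pph4_threshold
  sens_ok <- .skip_na_all(c(crit_sensitivity, crit_het_pleio))
  causal <- isTRUE(crit_q) && isTRUE(crit_coloc) && !isFALSE(sens_ok)
  out <- data.frame(trait_id = trait_id, ancestry = ancestry,
                    tissue = if (is.null(tissue)) NA else tissue,
                    estimate = mr$estimate, se = mr$se, p = mr$p, q = q,
                    n_iv = mr$n_iv, crit_q = crit_q,
                    crit_sensitivity = crit_sensitivity,
                    crit_het_pleio = crit_het_pleio,
                    crit_coloc = crit_coloc, causal = causal,
                    stringsAsFactors = FALSE)
  class(out) <- c("causal_decision", class(out))
  out
}

#' Evaluate replication of discovery-causal traits
#'
#' BH-FDR is applied over exactly the discovery-causal traits present in
#' the replication data; a trait replicates when its replication q-value
#' is below `q_threshold` and its direction agrees with the discovery
#' IVW estimate. Discovery-causal traits absent from the replication set
#' are excluded from both the FDR correction and the replication-rate
#' denominator.
#'
#' @param discovery data frame with trait_id, causal, estimate
#' @param replication data frame with trait_id, estimate, p
#' @param q_threshold replication significance threshold (default 0.05)
#' @return data frame trait_id, estimate_discovery, estimate_replication,
#'   q_replication, direction_concordant, replicated
#' @export
evaluate_replication <- function(discovery, replication,
                                 q_threshold = 0.05) {
  disc <- discovery[discovery$causal %in% TRUE, , drop = FALSE]
  tested <- disc[disc$trait_id %in% replication$trait_id, , drop = FALSE]
  if (!nrow(tested))
    return(data.frame(trait_id = character(), estimate_discovery = numeric(),
                      estimate_replication = numeric(),
                      q_replication = numeric(),
                      direction_concordant = logical(),
                      replicated = logical()))
  rep_sub <- replication[match(tested$trait_id, replication$trait_id), ]
  q_rep <- bh_fdr(rep_sub$p)
  conc <- sign(rep_sub$estimate) == sign(tested$estimate)
  data.frame(trait_id = tested$trait_id,
             estimate_discovery = tested$estimate,
             estimate_replication = rep_sub$estimate,
             q_replication = q_rep,
             direction_concordant = conc,
             replicated = q_rep < q_threshold & conc,
             stringsAsFactors = FALSE)
}

#' Replication rate under a ladder of nested discovery criteria
#'
#' Rebuilds the discovery "significant" set under five nested criteria -
#' (1) all tested traits, (2) nominal p < 0.05, (3) q < 0.05, (4) plus
#' concordant sensitivity analyses with no heterogeneity or pleiotropy,
#' (5) plus colocalization evidence - and, for each, recomputes the
#' replication FDR over the significant traits present in the
#' replication data. The rate is the proportion of tested traits with
#' replication q below 0.05. The final criterion is additionally split
#' by single- versus multi-instrument traits. Not-applicable sensitivity
#' criteria (single-instrument traits) are skipped, not failed.
#'
#' @param discovery decision table: trait_id, p, q, n_iv,
#'   crit_sensitivity, crit_het_pleio, crit_coloc
#' @param replication data frame trait_id, estimate, p
#' @return data frame criterion, n_significant, n_tested, n_replicated,
#'   rate (NA when nothing can be tested)
#' @export
replication_ladder <- function(discovery, replication) {
  ok_na <- function(x) is.na(x) | x
  sel <- list(
    all_tested = rep(TRUE, nrow(discovery)),
    nominal_p = discovery$p < 0.05,
    fdr_q = discovery$q < 0.05,
    sensitivity = discovery$q < 0.05 & ok_na(discovery$crit_sensitivity) &
      ok_na(discovery$crit_het_pleio),
    full_criteria = discovery$q < 0.05 & ok_na(discovery$crit_sensitivity) &
      ok_na(discovery$crit_het_pleio) & (discovery$crit_coloc %in% TRUE))
  sel$full_criteria_single_iv <- sel$full_criteria & discovery$n_iv == 1
  sel$full_criteria_multi_iv <- sel$full_criteria & discovery$n_iv > 1
  rows <- lapply(names(sel), function(nm) {
    keep <- sel[[nm]] & !is.na(sel[[nm]])
    ids <- discovery$trait_id[keep]
    tested <- intersect(ids, replication$trait_id)
    if (length(tested)) {
      rp <- replication[match(tested, replication$trait_id), ]
      q_rep <- bh_fdr(rp$p)
      n_repl <- sum(q_rep < 0.05)
      rate <- n_repl / length(tested)
    } else {
      n_repl <- NA_integer_; rate <- NA_real_
    }
    data.frame(criterion = nm, n_significant = length(ids),
               n_tested = length(tested), n_replicated = n_repl,
               rate = rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-ancestry random-effects meta-analysis of MR estimates
#'
#' Pools log-OR estimates across ancestries with an additive
#' between-ancestry variance component. The default DerSimonian-Laird
#' estimator is closed-form: tau^2 = max(0, (Q - (k-1)) /
#' (sum w - sum w^2 / sum w)) with fixed-effect weights w = 1/se^2;
#' pooled weights are 1/(se^2 + tau^2). REML estimation is available via
#' the metafor package when installed.
#'
#' @param estimates numeric vector of per-ancestry log-OR estimates
#' @param ses their standard errors
#' @param method "DL" (default) or "REML"
#' @return object of class `meta_result`: estimate, se, p, k, tau2,
#'   Q_ancestry, Q_p
#' @export
meta_analyze <- function(estimates, ses, method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(estimates)
  stopifnot(length(ses) == k)
  if (k < 2)
    stop("meta-analysis requires estimates from at least two ancestries")
  w <- 1 / ses^2
  fe <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - fe)^2)
  if (method == "DL") {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  } else {
    if (!requireNamespace("metafor", quietly = TRUE))
      stop("REML estimation requires the metafor package")
    fit <- metafor::rma(yi = estimates, sei = ses, method = "REML")
    tau2 <- fit$tau2
  }
  ws <- 1 / (ses^2 + tau2)
  est <- sum(ws * estimates) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  structure(list(estimate = est, se = se, p = z_pvalue(est, se),
                 k = as.integer(k), tau2 = tau2, Q_ancestry = Q,
                 Q_p = stats::pchisq(Q, k - 1, lower.tail = FALSE),
                 method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(paste0("<meta_result:%s> estimate=%.4g (OR %.4g), se=%.4g, ",
                     "p=%.3g, k=%d, tau2=%.3g, Q=%.3g (p=%.3g)\n"),
              x$method, x$estimate, exp(x$estimate), x$se, x$p, x$k,
              x$tau2, x$Q_ancestry, x$Q_p))
  invisible(x)
}

#' Meta-analysis significance call
#'
#' A trait is meta-significant when its meta-analysis q-value is below
#' `q_threshold` and at least one contributing cohort shows compelling
#' evidence: a nominally significant p-value together with that same
#' cohort's sensitivity and colocalization criteria met (not-applicable
#' sensitivity criteria are skipped).
#'
#' @param meta_q FDR-adjusted meta-analysis p-value
#' @param per_cohort decision table of the contributing cohorts: p,
#'   crit_sensitivity, crit_het_pleio, crit_coloc
#' @param q_threshold,p_nominal thresholds (defaults 0.05, 0.05)
#' @return logical flag
#' @export
call_meta_significant <- function(meta_q, per_cohort, q_threshold = 0.05,
                                  p_nominal = 0.05) {
  if (!(meta_q < q_threshold)) return(FALSE)
  ok_na <- function(x) is.na(x) | x
  compelling <- per_cohort$p < p_nominal &
    ok_na(per_cohort$crit_sensitivity) &
    ok_na(per_cohort$crit_het_pleio) &
    (per_cohort$crit_coloc %in% TRUE)
  any(compelling)
}
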