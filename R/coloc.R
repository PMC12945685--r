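# Approximate-Bayes-factor colocalization under a single-causal-variant
# assumption per trait, extended to multi-signal loci by pairwise
# conditional analysis: secondary associations are identified by stepwise
# approximate conditional selection from marginal statistics plus
# reference LD, and every pair of conditioned (and marginal) datasets is
# re-colocalized, keeping the configuration with the highest posterior
# probability of a shared causal variant.

#' Colocalization priors
#'
#' @param p1,p2 prior probability that a variant is causal for trait 1 / 2
#' @param p12 prior probability that a variant is causal for both
#' @return list of class `coloc_priors`
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), max(p1, p2) < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

coloc_slice <- function(stats) {
  d <- if (inherits(stats, "sumstats")) stats$records else stats
  stopifnot(all(c("id", "beta", "se") %in% names(d)))
  d
}

#' Per-variant Wakefield log approximate Bayes factor
#'
#' log ABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W)) with V = se^2 and W the
#' squared prior effect SD.
#'
#' @param beta,se association estimate and SE
#' @param sd_prior prior effect SD (0.20 for quantitative traits, 0.15 on
#'   the log-OR scale for case-control traits)
#' @return vector of log ABFs
#' @export
wakefield_labf <- function(beta, se, sd_prior) {
  V <- se^2
  W <- sd_prior^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + (beta / se)^2 * r)
}

# log sum over ordered pairs (i, j), i != j, of exp(l1_i + l2_j),
# computed by direct pairwise summation: the algebraic shortcut
# exp(s1 + s2) - exp(s12) cancels catastrophically when the diagonal
# (shared-signal) term dominates
log_pair_sum <- function(l1, l2) {
  M <- outer(l1, l2, "+")
  diag(M) <- -Inf
  logsumexp(as.numeric(M))
}

#' Approximate-Bayes-factor colocalization of two traits at a locus
#'
#' Computes posterior probabilities of the five single-causal-variant
#' hypotheses (H0 no association, H1/H2 trait-specific, H3 distinct
#' causal variants, H4 shared causal variant) from per-variant Wakefield
#' ABFs on the variants shared between the two datasets.
#'
#' @param stats1,stats2 `sumstats` objects or data frames with id, beta, se
#' @param priors [coloc_priors()]
#' @param trait_types length-2 character, each "quantitative" or
#'   "case_control"; sets the prior effect SD per trait (0.20 / 0.15)
#' @return object of class `coloc_result` with `pph` (named H0..H4),
#'   `n_variants`, `max_pph4`, `pairs_tested`, `conditioned_on`;
#'   [not_applicable()] with fewer than 2 shared variants
#' @export
abf_coloc <- function(stats1, stats2, priors = coloc_priors(),
                      trait_types = c("quantitative", "case_control")) {
  sd0 <- ifelse(trait_types == "case_control", 0.15, 0.20)
  d1 <- coloc_slice(stats1); d2 <- coloc_slice(stats2)
  shared <- intersect(d1$id, d2$id)
  if (length(shared) < 2)
    return(not_applicable("fewer than 2 shared variants"))
  d1 <- d1[match(shared, d1$id), ]; d2 <- d2[match(shared, d2$id), ]
  ok <- is.finite(d1$beta) & is.finite(d1$se) & d1$se > 0 &
    is.finite(d2$beta) & is.finite(d2$se) & d2$se > 0
  d1 <- d1[ok, ]; d2 <- d2[ok, ]
  if (nrow(d1) < 2) return(not_applicable("fewer than 2 shared variants"))
  l1 <- wakefield_labf(d1$beta, d1$se, sd0[1])
  l2 <- wakefield_labf(d2$beta, d2$se, sd0[2])
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(priors$p1) + s1,
          H2 = log(priors$p2) + s2,
          H3 = log(priors$p1) + log(priors$p2) + log_pair_sum(l1, l2),
          H4 = log(priors$p12) + s12)
  pph <- exp(lh - logsumexp(lh))
  pph <- pph / sum(pph)
  structure(list(pph = pph, n_variants = nrow(d1),
                 conditioned_on = list(character(), character()),
                 max_pph4 = unname(pph["H4"]), pairs_tested = 1L,
                 labf = list(l1, l2), ids = d1$id),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0("<coloc_result> %d variants, %d pair(s) tested; PPH0..4 = ",
                     "%s; max PPH4 = %.3f\n"),
              x$n_variants, x$pairs_tested,
              paste(sprintf("%.3f", x$pph), collapse = " "), x$max_pph4))
  invisible(x)
}

#' Approximate conditional association analysis from marginal statistics
#'
#' Conditions each variant's marginal estimate on a set of lead variants
#' using reference-panel LD, on the standardized genotype/phenotype
#' scale: the conditioning set is fitted jointly, and each remaining
#' variant is residualized against it. With an empty conditioning set the
#' input is returned unchanged; conditioning a variant on itself yields a
#' zero effect.
#'
#' @param stats `sumstats` or data frame with id, beta, se, n
#' @param panel `ref_panel` covering all variants
#' @param conditioning character vector of lead variant ids
#' @return data frame id, beta, se, p of conditional estimates
#' @export
cojo_condition <- function(stats, panel, conditioning = character()) {
  d <- coloc_slice(stats)
  out <- data.frame(id = d$id, beta = d$beta, se = d$se,
                    p = z_pvalue(d$beta, d$se), stringsAsFactors = FALSE)
  if (!length(conditioning)) return(out)
  pid <- panel$variants$id
  if (!all(conditioning %in% pid) || !all(conditioning %in% d$id))
    stop("conditioning variants must be present in both panel and stats")
  n <- stats::median(d$n %||% rep(1e4, nrow(d)), na.rm = TRUE)
  if (!is.finite(n)) n <- 1e4
  idx_all <- match(d$id, pid)
  idx_S <- match(conditioning, pid)
  R_S <- panel$ld[idx_S, idx_S, drop = FALSE]
  if (kappa(R_S) > 1e8)
    stop("singular LD submatrix for conditioning set")
  z <- d$beta / d$se
  b_std <- z / sqrt(n)                      # standardized marginal effects
  conv <- d$beta / b_std                    # per-variant scale factor
  conv[!is.finite(conv)] <- stats::median(conv[is.finite(conv)])
  b_S <- b_std[match(conditioning, d$id)]
  RinvB <- solve(R_S, b_S)
  sigma2 <- max(1 - sum(b_S * RinvB), 0.05) # residual phenotypic variance
  r_kS <- panel$ld[idx_all, idx_S, drop = FALSE]
  num <- b_std - as.numeric(r_kS %*% RinvB)
  den <- 1 - rowSums((r_kS %*% solve(R_S)) * r_kS)
  self <- d$id %in% conditioning | den < 1e-10
  den[self] <- 1
  b_cond <- num / den
  se_cond <- sqrt(sigma2 / (n * den))
  out$beta <- b_cond * conv
  out$se <- se_cond * conv
  out$beta[self] <- 0
  out$se[self] <- Inf
  out$p <- ifelse(self, 1, z_pvalue(out$beta, out$se))
  out
}

#' Stepwise selection of independent association signals at a locus
#'
#' Seeds with the minimum-p variant if below `p_threshold`, then
#' iteratively adds the variant with the smallest conditional p-value
#' below the threshold whose r^2 with every selected lead is below
#' `collinearity_r2`, stopping at `max_signals`. Each returned signal
#' carries the locus statistics conditioned on the other leads.
#'
#' @param stats `sumstats` or data frame (id, beta, se, n)
#' @param panel `ref_panel`
#' @param p_threshold signal significance threshold
#' @param collinearity_r2 maximum r^2 between selected leads (default 0.9)
#' @param max_signals maximum number of signals (default 10)
#' @return list of signals, each `list(lead =, conditional_stats =)`;
#'   empty list when no variant passes
#' @export
select_signals <- function(stats, panel, p_threshold = 1e-5,
                           collinearity_r2 = 0.9, max_signals = 10L) {
  d <- coloc_slice(stats)
  d <- d[d$id %in% panel$variants$id, , drop = FALSE]
  if (!nrow(d)) return(list())
  leads <- character()
  repeat {
    cond <- tryCatch(cojo_condition(d, panel, leads),
                     error = function(e) NULL)
    if (is.null(cond)) break
    pid <- match(d$id, panel$variants$id)
    elig <- !(d$id %in% leads)
    if (length(leads)) {
      r2max <- apply(panel$ld[pid, match(leads, panel$variants$id),
                              drop = FALSE]^2, 1, max)
      elig <- elig & r2max < collinearity_r2
    }
    if (!any(elig)) break
    cand <- cond[elig, , drop = FALSE]
    best <- which.min(cand$p)
    if (!length(best) || cand$p[best] >= p_threshold) break
    leads <- c(leads, cand$id[best])
    if (length(leads) >= max_signals) break
  }
  lapply(leads, function(lead) {
    others <- setdiff(leads, lead)
    list(lead = lead,
         conditional_stats = tryCatch(cojo_condition(d, panel, others),
                                      error = function(e) NULL))
  })
}

#' Pairwise conditional colocalization
#'
#' Runs marginal [abf_coloc()] first; if its PPH4 is at or above
#' `pph4_threshold` it is returned unchanged. Otherwise independent
#' signals are selected on each side and colocalization is re-run on
#' every pair of conditioned datasets, and on each conditioned dataset
#' against the other trait's marginal statistics; the result with the
#' maximal PPH4 is returned together with the number of pairs tested.
#'
#' @param stats1,stats2 locus `sumstats` (trait 1 = molecular exposure,
#'   trait 2 = disease outcome by default)
#' @param panel `ref_panel` for the shared ancestry
#' @param priors [coloc_priors()]
#' @param trait_types per-trait type as in [abf_coloc()]
#' @param p_threshold_1,p_threshold_2 stepwise signal thresholds for each
#'   trait (defaults 1e-5 QTL side, 5e-8 GWAS side)
#' @param collinearity_r2,max_signals stepwise selection controls
#' @param pph4_threshold conditional analysis is attempted only below
#'   this marginal PPH4 (default 0.8)
#' @return `coloc_result` with `max_pph4` over all tested pairs, the
#'   winning pair's `pph` and `conditioned_on`, `pairs_tested`, and the
#'   full `pair_table`
#' @export
pwcoco <- function(stats1, stats2, panel, priors = coloc_priors(),
                   trait_types = c("quantitative", "case_control"),
                   p_threshold_1 = 1e-5, p_threshold_2 = 5e-8,
                   collinearity_r2 = 0.9, max_signals = 10L,
                   pph4_threshold = 0.8) {
  marg <- abf_coloc(stats1, stats2, priors, trait_types)
  if (is_na_result(marg)) return(marg)
  if (marg$max_pph4 >= pph4_threshold) return(marg)

  sig1 <- select_signals(stats1, panel, p_threshold_1, collinearity_r2,
                         max_signals)
  sig2 <- select_signals(stats2, panel, p_threshold_2, collinearity_r2,
                         max_signals)
  sets1 <- c(list(list(lead = NA_character_,
                       conditional_stats = coloc_slice(stats1),
                       cond_on = character())),
             lapply(sig1, function(s)
               list(lead = s$lead, conditional_stats = s$conditional_stats,
                    cond_on = setdiff(vapply(sig1, `[[`, "", "lead"),
                                      s$lead))))
  sets2 <- c(list(list(lead = NA_character_,
                       conditional_stats = coloc_slice(stats2),
                       cond_on = character())),
             lapply(sig2, function(s)
               list(lead = s$lead, conditional_stats = s$conditional_stats,
                    cond_on = setdiff(vapply(sig2, `[[`, "", "lead"),
                                      s$lead))))
  best <- marg
  best$conditioned_on <- list(character(), character())
  pair_rows <- list(data.frame(lead1 = NA, lead2 = NA,
                               pph4 = marg$pph["H4"]))
  pairs_tested <- 1L
  for (i in seq_along(sets1)) for (j in seq_along(sets2)) {
    if (i == 1 && j == 1) next   # marginal-marginal already done
    s1 <- sets1[[i]]; s2 <- sets2[[j]]
    if (is.null(s1$conditional_stats) || is.null(s2$conditional_stats)) next
    res <- abf_coloc(s1$conditional_stats, s2$conditional_stats, priors,
                     trait_types)
    if (is_na_result(res)) next
    pairs_tested <- pairs_tested + 1L
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(lead1 = s1$lead, lead2 = s2$lead, pph4 = res$pph["H4"])
    if (res$pph["H4"] > best$pph["H4"]) {
      best <- res
      best$conditioned_on <- list(s1$cond_on, s2$cond_on)
    }
  }
  best$pairs_tested <- pairs_tested
  best$max_pph4 <- max(vapply(pair_rows, function(r) r$pph4, numeric(1)))
  best$pair_table <- do.call(rbind, pair_rows)
  best
}
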