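# End-to-end driver: instrument selection, MR, sensitivity suite and
# colocalization per (gene, ancestry, tissue), FDR within each analysis
# stratum, causal calls, and the cross-ancestry meta-analysis layer.

#' Run the full MR cascade over a simulated or assembled study bundle
#'
#' For every exposure table in the bundle: selects instruments against
#' the matching ancestry outcome, computes the headline IVW (Wald ratio
#' for single instruments), runs the sensitivity suite and pairwise
#' conditional colocalization on the cis locus, applies BH-FDR within
#' each (ancestry x tissue) stratum, and issues the four-criterion
#' causal call per trait.
#'
#' @param bundle `study_bundle` from [simulate_study()] (or an equivalent
#'   list with `exposures`, `outcomes`, `outcome_loci`, `panels`,
#'   `annotation`)
#' @param cfg [iv_config()]
#' @param priors [coloc_priors()]
#' @param K outcome prevalence for Steiger filtering
#' @param n_boot,presso_n_sim sensitivity-suite simulation sizes
#' @param run_coloc set FALSE to skip colocalization (criterion 4 then
#'   not-applicable; no trait can be called causal)
#' @param seed integer seed for the seeded sensitivity components
#' @return list with `decisions` (decision table, one row per tested
#'   trait x ancestry x tissue) and `details` (per-key list of
#'   instrument sets, suites and coloc results)
#' @export
run_mr_cascade <- function(bundle, cfg = iv_config(), priors = coloc_priors(),
                           K = 0.10, n_boot = 200L, presso_n_sim = 200L,
                           run_coloc = TRUE, seed = 1L) {
  details <- list()
  rows <- list()
  for (key in names(bundle$exposures)) {
    expo <- bundle$exposures[[key]]
    anc <- expo$ancestry
    g <- expo$trait_id
    panel <- bundle$panels[[anc]][[g]]
    gene <- bundle$annotation[bundle$annotation$gene_id == g, ]
    outcome <- if (!is.null(bundle$outcome_loci))
      bundle$outcome_loci[[anc]][[g]] else bundle$outcomes[[anc]]
    insts <- select_instruments(expo, outcome, panel, gene, cfg)
    if (n_iv(insts) == 0) {
      details[[key]] <- list(instruments = insts)
      next
    }
    mr <- mr_ivw(insts)
    suite <- run_sensitivity_suite(insts, K = K, n_boot = n_boot,
                                   presso_n_sim = presso_n_sim,
                                   seed = child_seed(seed, key))
    coloc <- if (run_coloc) {
      locus_ok <- expo$records$chrom == as.character(gene$chrom) &
        abs(expo$records$pos - gene$tss) <= cfg$cis_flank_bp
      eslice <- expo$records[locus_ok, c("id", "beta", "se", "n")]
      orec <- outcome$records
      oslice <- orec[orec$id %in% eslice$id, c("id", "beta", "se", "n")]
      pwcoco(eslice, oslice, panel, priors,
             trait_types = c("quantitative", "case_control"))
    } else not_applicable("colocalization disabled")
    details[[key]] <- list(instruments = insts, mr = mr, suite = suite,
                           coloc = coloc)
    rows[[key]] <- data.frame(key = key, trait_id = g, ancestry = anc,
                              tissue = expo$tissue %||% NA_character_,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(decisions = NULL, details = details))
  idx <- do.call(rbind, rows)
  # FDR within each (ancestry x tissue) analysis stratum
  strat <- paste(idx$ancestry, idx$tissue, sep = "\r")
  p_head <- vapply(idx$key, function(k) details[[k]]$mr$p, numeric(1))
  q <- numeric(length(p_head))
  for (s in unique(strat)) {
    sel <- strat == s
    q[sel] <- bh_fdr(p_head[sel])
  }
  decisions <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    k <- idx$key[i]
    call_causal(details[[k]]$mr, q[i], details[[k]]$suite,
                details[[k]]$coloc, trait_id = idx$trait_id[i],
                ancestry = idx$ancestry[i], tissue = idx$tissue[i])
  }))
  rownames(decisions) <- NULL
  list(decisions = decisions, details = details)
}

#' Cross-ancestry meta-analysis layer over a decision table
#'
#' Pools each (trait, tissue) tested in at least two ancestries with the
#' random-effects model, applies BH-FDR across the pooled traits within
#' each tissue, and issues the meta-significance call using the
#' contributing cohorts' criteria.
#'
#' @param decisions decision table from [run_mr_cascade()]
#' @param method "DL" or "REML"
#' @return data frame trait_id, tissue, k, estimate, se, p, q, tau2,
#'   Q_ancestry, Q_p, significant (traits with k >= 2 only)
#' @export
meta_across_ancestries <- function(decisions, method = "DL") {
  keyf <- paste(decisions$trait_id, decisions$tissue, sep = "\r")
  rows <- list()
  for (k in unique(keyf)) {
    sub <- decisions[keyf == k, , drop = FALSE]
    if (nrow(sub) < 2) next
    m <- meta_analyze(sub$estimate, sub$se, method = method)
    rows[[k]] <- data.frame(trait_id = sub$trait_id[1],
                            tissue = sub$tissue[1], k = m$k,
                            estimate = m$estimate, se = m$se, p = m$p,
                            tau2 = m$tau2, Q_ancestry = m$Q_ancestry,
                            Q_p = m$Q_p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (tis in unique(out$tissue)) {
    sel <- out$tissue %in% tis
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  out$significant <- vapply(seq_len(nrow(out)), function(i) {
    sub <- decisions[decisions$trait_id == out$trait_id[i] &
                     decisions$tissue %in% out$tissue[i], , drop = FALSE]
    call_meta_significant(out$q[i], sub)
  }, logical(1))
  out
}
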