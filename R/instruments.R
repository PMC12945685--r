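# Instrument selection: cis-window restriction, QTL significance filter,
# greedy LD clumping, proxy substitution for variants missing from the
# outcome, F-statistic filter, and harmonization against the outcome.

#' Instrument-selection configuration
#'
#' Thresholds follow strict comparators: instruments require F > f_min,
#' proxies require r^2 > proxy_r2, clumping keeps pairs at r^2 <= clump_r2.
#' The clumping and proxy-search window is interpreted as
#' `+/- clump_window_bp / 2` around the index variant.
#'
#' @param cis_flank_bp flank around the TSS defining the cis window
#'   (default 1 Mb each side; set per exposure study when the study
#'   defines its own window)
#' @param qtl_sig_threshold exposure significance threshold (study-defined)
#' @param clump_r2 LD pruning threshold (default 0.001)
#' @param clump_window_bp clumping window in bp (default 10 Mb total)
#' @param proxy_r2 minimum LD for proxy substitution (default 0.8, strict >)
#' @param f_min minimum F-statistic (default 10, strict >)
#' @param palindrome_eaf_limit passed to [harmonize()]
#' @return list of class `iv_config`
#' @export
iv_config <- function(cis_flank_bp = 1e6, qtl_sig_threshold = 5e-8,
                      clump_r2 = 0.001, clump_window_bp = 1e7,
                      proxy_r2 = 0.8, f_min = 10,
                      palindrome_eaf_limit = 0.42) {
  stopifnot(clump_r2 < proxy_r2, clump_r2 > 0, clump_r2 <= 1,
            proxy_r2 > 0, proxy_r2 <= 1, qtl_sig_threshold > 0,
            qtl_sig_threshold <= 1, f_min > 0)
  structure(list(cis_flank_bp = cis_flank_bp,
                 qtl_sig_threshold = qtl_sig_threshold,
                 clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
                 proxy_r2 = proxy_r2, f_min = f_min,
                 palindrome_eaf_limit = palindrome_eaf_limit),
            class = "iv_config")
}

#' Instrument-strength F-statistic
#'
#' F = beta^2 / se^2, the squared z of the variant-exposure association.
#'
#' @param beta exposure effect estimate
#' @param se its standard error (> 0)
#' @return nonnegative F value (vectorized)
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  beta^2 / se^2
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value
#' (ties broken by position, then id, ascending) and removes all variants
#' with r^2 > `clump_r2` within `+/- clump_window_bp / 2` of it. Variants
#' absent from the panel are dropped with a log entry.
#'
#' @param stats `sumstats` restricted to the locus of interest
#' @param panel `ref_panel` supplying pairwise LD
#' @param cfg [iv_config()]
#' @return character vector of retained variant ids in selection order;
#'   attribute `"log"` carries a data frame of per-variant fates
#' @export
ld_clump <- function(stats, panel, cfg = iv_config()) {
  rec <- stats$records
  log <- data.frame(variant = character(), stage = character(),
                    action = character(), reason = character(),
                    stringsAsFactors = FALSE)
  in_panel <- rec$id %in% panel$variants$id
  if (any(!in_panel)) {
    log <- rbind(log, data.frame(variant = rec$id[!in_panel],
                                 stage = "clump", action = "drop",
                                 reason = "absent_from_panel"))
    rec <- rec[in_panel, , drop = FALSE]
  }
  keep <- character()
  ord <- order(rec$p, rec$pos, rec$id)
  rec <- rec[ord, , drop = FALSE]
  pidx <- match(rec$id, panel$variants$id)
  half_win <- cfg$clump_window_bp / 2
  alive <- rep(TRUE, nrow(rec))
  while (any(alive)) {
    i <- which(alive)[1]
    keep <- c(keep, rec$id[i])
    alive[i] <- FALSE
    cand <- which(alive & abs(rec$pos - rec$pos[i]) <= half_win)
    if (length(cand)) {
      r2 <- panel$ld[pidx[i], pidx[cand]]^2
      kill <- cand[r2 > cfg$clump_r2]
      if (length(kill)) {
        log <- rbind(log, data.frame(variant = rec$id[kill],
                                     stage = "clump", action = "drop",
                                     reason = paste0("r2_with_", rec$id[i])))
        alive[kill] <- FALSE
      }
    }
  }
  structure(keep, log = log)
}

#' Find an LD proxy for an instrument missing from the outcome data
#'
#' Among panel variants present in both the outcome and the exposure
#' tables with r^2 > `proxy_r2` to the index variant (within the clumping
#' window), returns the id with maximal r^2; ties broken by distance to
#' the index variant, then lexicographic id.
#'
#' @param iv_id index variant id
#' @param exposure,outcome `sumstats` objects
#' @param panel `ref_panel`
#' @param cfg [iv_config()]
#' @return list(id, r2) or NULL when no candidate qualifies
#' @export
find_proxy <- function(iv_id, exposure, outcome, panel, cfg = iv_config()) {
  i <- match(iv_id, panel$variants$id)
  if (is.na(i)) return(NULL)
  cand <- which(panel$variants$id %in% outcome$records$id &
                panel$variants$id %in% exposure$records$id &
                panel$variants$id != iv_id &
                abs(panel$variants$pos - panel$variants$pos[i]) <=
                  cfg$clump_window_bp / 2)
  if (!length(cand)) return(NULL)
  r2 <- panel$ld[i, cand]^2
  ok <- r2 > cfg$proxy_r2
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r2 <- r2[ok]
  dist <- abs(panel$variants$pos[cand] - panel$variants$pos[i])
  ord <- order(-r2, dist, panel$variants$id[cand])
  list(id = panel$variants$id[cand[ord[1]]], r2 = r2[ord[1]])
}

#' Select instruments for one molecular trait
#'
#' Pipeline: cis-window restriction (TSS +/- `cis_flank_bp`), exposure
#' significance filter, greedy LD clumping, proxy substitution for
#' instruments absent from the outcome, F-statistic filter (F > f_min),
#' and allele harmonization against the outcome. An empty set is a valid
#' outcome (the trait is simply not tested).
#'
#' @param exposure,outcome `sumstats` objects
#' @param panel `ref_panel` for the matching ancestry
#' @param gene list/row with `gene_id`, `chrom`, `tss` (1-based)
#' @param cfg [iv_config()]
#' @return object of class `instrument_set`: data frame `instruments`
#'   (harmonized pairs with f_stat, is_proxy, proxy_source,
#'   r2_with_source), `selection_log`, trait metadata
#' @export
select_instruments <- function(exposure, outcome, panel, gene,
                               cfg = iv_config()) {
  log <- data.frame(variant = character(), stage = character(),
                    action = character(), reason = character(),
                    stringsAsFactors = FALSE)
  note <- function(ids, stage, action, reason) {
    if (length(ids))
      log <<- rbind(log, data.frame(variant = ids, stage = stage,
                                    action = action, reason = reason))
  }
  empty <- function() {
    structure(list(trait_id = exposure$trait_id, ancestry = exposure$ancestry,
                   tissue = exposure$tissue,
                   instruments = data.frame(), selection_log = log,
                   cfg = cfg),
              class = "instrument_set")
  }
  rec <- exposure$records
  cis <- rec$chrom == as.character(gene$chrom) &
    abs(rec$pos - gene$tss) <= cfg$cis_flank_bp
  note(rec$id[!cis], "cis_window", "drop", "outside_cis_window")
  rec <- rec[cis, , drop = FALSE]
  sig <- rec$p < cfg$qtl_sig_threshold
  note(rec$id[!sig], "significance", "drop", "above_qtl_sig_threshold")
  rec <- rec[sig, , drop = FALSE]
  if (!nrow(rec)) return(empty())

  cis_expo <- exposure; cis_expo$records <- rec
  kept <- ld_clump(cis_expo, panel, cfg)
  log <- rbind(log, attr(kept, "log"))
  note(kept, "clump", "keep", "index_variant")

  rows <- list()
  for (id in kept) {
    erec <- rec[rec$id == id, ]
    proxy <- FALSE; proxy_src <- NA_character_; r2src <- NA_real_
    if (!(id %in% outcome$records$id)) {
      px <- find_proxy(id, exposure, outcome, panel, cfg)
      if (is.null(px)) {
        note(id, "proxy", "drop", "absent_from_outcome_no_proxy")
        next
      }
      note(id, "proxy", "replace", paste0("proxy_", px$id))
      proxy <- TRUE; proxy_src <- id; r2src <- px$r2
      # re-anchor to the proxy's exposure record
      erec <- exposure$records[exposure$records$id == px$id, ]
      id <- px$id
    }
    f <- f_statistic(erec$beta, erec$se)
    if (!(f > cfg$f_min)) {
      note(id, "f_filter", "drop", sprintf("F=%.3g_not_greater_than_%g",
                                           f, cfg$f_min))
      next
    }
    orec <- outcome$records[outcome$records$id == id, ]
    h <- harmonize(as.list(erec), as.list(orec), cfg$palindrome_eaf_limit)
    if (!h$status %in% c("kept", "flipped", "palindromic_inferred")) {
      note(id, "harmonize", "drop", h$status)
      next
    }
    note(id, "harmonize", "keep", h$status)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, chrom = erec$chrom, pos = erec$pos,
      effect_allele = erec$effect_allele, other_allele = erec$other_allele,
      beta_x = h$beta_x, se_x = h$se_x, eaf_x = h$eaf_x,
      beta_y = h$beta_y, se_y = h$se_y, eaf_y = h$eaf_y,
      p_x = erec$p, f_stat = f, status = h$status,
      is_proxy = proxy, proxy_source = proxy_src, r2_with_source = r2src,
      n_x = erec$n, n_y = orec$n, n_case = orec$n_case,
      n_ctrl = orec$n_ctrl, stringsAsFactors = FALSE)
  }
  out <- empty()
  if (length(rows)) out$instruments <- do.call(rbind, rows)
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s (%s%s): %d instrument(s)\n",
              x$trait_id, x$ancestry,
              if (!is.null(x$tissue)) paste0(", ", x$tissue) else "",
              nrow(x$instruments)))
  invisible(x)
}

#' Number of instruments in a set
#' @param insts `instrument_set`
#' @return integer count
#' @export
n_iv <- function(insts) nrow(insts$instruments)
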