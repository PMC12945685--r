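# Contextualization layers: tissue-expression filtering, gene-set and
# tissue-cluster enrichment, tissue overlap / heterogeneity summaries,
# and locus-overlap grouping against curated effector-gene lists.

#' Tissues in which each gene is expressed
#'
#' A gene counts as expressed in a tissue when its median TPM is strictly
#' greater than `threshold` (default 0.1).
#'
#' @param expr numeric matrix or data frame, genes x tissues, of median
#'   TPM values (rownames = gene ids)
#' @param threshold strict expression cutoff
#' @return named list mapping gene id to a character vector of tissues
#' @export
expression_filter <- function(expr, threshold = 0.1) {
  m <- as.matrix(expr)
  if (any(m < 0, na.rm = TRUE)) stop("TPM values must be nonnegative")
  out <- apply(m, 1, function(row)
    colnames(m)[!is.na(row) & row > threshold], simplify = FALSE)
  names(out) <- rownames(m)
  out
}

#' Fisher's exact enrichment of causal calls in a gene set
#'
#' Builds the 2x2 table (in set / not in set) x (causal / not causal)
#' over the tested genes and reports the two-sided exact p-value, the
#' sample odds ratio, and the fold enrichment of the percentage of
#' causal genes inside versus outside the set.
#'
#' @param causal character vector of causal gene ids (subset of tested)
#' @param tested character vector of all tested gene ids
#' @param gene_set character vector of annotation gene ids
#' @return object of class `enrichment_result` with `table`,
#'   `odds_ratio` (sample OR; Inf sentinel for empty off-cells), `p`,
#'   `fold`
#' @export
fisher_enrichment <- function(causal, tested, gene_set) {
  tested <- unique(tested)
  causal <- unique(causal)
  if (!length(tested)) stop("empty tested set")
  if (!all(causal %in% tested)) stop("causal genes must be a subset of tested")
  in_set <- tested %in% gene_set
  is_causal <- tested %in% causal
  tab <- matrix(c(sum(in_set & is_causal), sum(in_set & !is_causal),
                  sum(!in_set & is_causal), sum(!in_set & !is_causal)),
                2, 2, byrow = TRUE,
                dimnames = list(c("in_set", "not_in_set"),
                                c("causal", "not_causal")))
  if (sum(tab["in_set", ]) == 0 || sum(tab[, "causal"]) == 0) {
    p <- 1; or <- NA_real_; fold <- NA_real_
  } else {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value
    a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
    or <- if (b == 0 || c2 == 0) Inf else (a * d) / (b * c2)
    pct_in <- a / (a + b)
    pct_out <- c2 / (c2 + d)
    fold <- if (pct_out == 0) Inf else pct_in / pct_out
  }
  structure(list(table = tab, odds_ratio = or, p = p, fold = fold),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> OR=%.3g, fold=%.3g, p=%.3g\n",
              x$odds_ratio, x$fold, x$p))
  print(x$table)
  invisible(x)
}

#' Per tissue-cluster enrichment of causal effects with FDR
#'
#' One Fisher's exact test per (tissue, cluster) pair with at least one
#' gene both in the cluster and causal in the tissue, contrasting
#' cluster membership with causal evidence over the tested gene
#' universe; BH-FDR across the retained pairs.
#'
#' @param clusters named list: cluster name -> gene ids
#' @param calls data frame with gene_id, tissue, causal (logical) over
#'   the tested genes
#' @return data frame tissue, cluster, odds_ratio, fold, p, q, n_overlap
#' @export
cluster_tissue_enrichment <- function(clusters, calls) {
  rows <- list()
  for (tis in unique(calls$tissue)) {
    sub <- calls[calls$tissue == tis, , drop = FALSE]
    tested <- unique(sub$gene_id)
    causal <- unique(sub$gene_id[sub$causal %in% TRUE])
    for (cl in names(clusters)) {
      overlap <- sum(causal %in% clusters[[cl]])
      if (overlap < 1) next
      er <- fisher_enrichment(causal, tested, clusters[[cl]])
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tis, cluster = cl, odds_ratio = er$odds_ratio,
        fold = er$fold, p = er$p, n_overlap = overlap,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tissue = character(), cluster = character(),
                      odds_ratio = numeric(), fold = numeric(),
                      p = numeric(), n_overlap = integer(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Pairwise tissue overlap of causal calls
#'
#' @param calls data frame gene_id, tissue, causal (logical), estimate
#' @return list with `matrix` (symmetric pairwise counts of genes causal
#'   in both tissues; diagonal = per-tissue totals), `n_multi` (genes
#'   causal in >= 2 tissues) and `n_concordant` (of those, genes whose
#'   causal estimates share one sign across all their causal tissues)
#' @export
tissue_overlap <- function(calls) {
  cc <- calls[calls$causal %in% TRUE, , drop = FALSE]
  tissues <- sort(unique(calls$tissue))
  mat <- matrix(0L, length(tissues), length(tissues),
                dimnames = list(tissues, tissues))
  by_gene <- split(cc, cc$gene_id)
  for (g in by_gene) {
    ts <- unique(g$tissue)
    for (t1 in ts) mat[t1, t1] <- mat[t1, t1] + 1L
    if (length(ts) >= 2) {
      prs <- utils::combn(sort(ts), 2)
      for (k in seq_len(ncol(prs))) {
        mat[prs[1, k], prs[2, k]] <- mat[prs[1, k], prs[2, k]] + 1L
        mat[prs[2, k], prs[1, k]] <- mat[prs[2, k], prs[1, k]] + 1L
      }
    }
  }
  multi <- Filter(function(g) length(unique(g$tissue)) >= 2, by_gene)
  n_conc <- sum(vapply(multi, function(g) {
    s <- sign(g$estimate)
    all(s == s[1])
  }, logical(1)))
  list(matrix = mat, n_multi = length(multi), n_concordant = n_conc)
}

#' Cross-tissue heterogeneity of causal estimates per gene
#'
#' Cochran's Q and I^2 of each gene's tissue-level MR estimates around
#' their fixed-effect pooled value, for genes tested in at least two
#' tissues.
#'
#' @param estimates data frame gene_id, tissue, estimate, se
#' @return list with `per_gene` (gene_id, k, Q, df, p, I2),
#'   `n_excluded` (genes with a single tissue) and `frac_significant`
#'   (fraction of included genes with Q p < 0.05)
#' @export
tissue_heterogeneity <- function(estimates) {
  by_gene <- split(estimates, estimates$gene_id)
  keep <- Filter(function(g) nrow(g) >= 2, by_gene)
  rows <- lapply(keep, function(g) {
    w <- 1 / g$se^2
    fe <- sum(w * g$estimate) / sum(w)
    Q <- sum(w * (g$estimate - fe)^2)
    h <- het_stats(Q, nrow(g) - 1)
    data.frame(gene_id = g$gene_id[1], k = nrow(g), Q = h$Q, df = h$df,
               p = h$p, I2 = h$I2, stringsAsFactors = FALSE)
  })
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), k = integer(), Q = numeric(),
               df = integer(), p = numeric(), I2 = numeric())
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       n_excluded = length(by_gene) - length(keep),
       frac_significant = if (nrow(per_gene)) mean(per_gene$p < 0.05)
       else NA_real_)
}

#' Locus-overlap grouping of causal genes against a reference gene list
#'
#' Each causal gene is grouped by its relationship to the reference
#' (effector) genes within a window centred on the gene midpoint:
#' group 2 when the gene itself is a reference gene (precedence),
#' group 3 when a different reference gene lies within the window,
#' group 1 when no reference gene does. Genes with missing coordinates
#' are reported ungrouped (group NA).
#'
#' @param causal data frame gene_id, chrom, start, end
#' @param reference data frame gene_id, chrom, start, end of the curated
#'   reference genes
#' @param window_bp full window width centred on the gene midpoint
#'   (default 1 Mb)
#' @return data frame gene_id, group (1, 2, 3 or NA), nearest_reference
#' @export
locus_overlap <- function(causal, reference, window_bp = 1e6) {
  half <- window_bp / 2
  res <- data.frame(gene_id = causal$gene_id, group = NA_integer_,
                    nearest_reference = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(causal))) {
    g <- causal[i, ]
    if (g$gene_id %in% reference$gene_id) {
      res$group[i] <- 2L
      res$nearest_reference[i] <- g$gene_id
      next
    }
    if (is.na(g$start) || is.na(g$end) || is.na(g$chrom)) next
    mid <- (g$start + g$end) / 2
    cand <- reference[reference$chrom == g$chrom &
                      reference$gene_id != g$gene_id, , drop = FALSE]
    if (nrow(cand)) {
      # distance from the window centre to the nearest point of each gene
      d <- pmax(cand$start - mid, mid - cand$end, 0)
      hit <- d <= half
      if (any(hit)) {
        res$group[i] <- 3L
        res$nearest_reference[i] <- cand$gene_id[which.min(d)]
        next
      }
    }
    res$group[i] <- 1L
  }
  res
}
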