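# Summary-statistics container, delimited-text I/O and allele harmonization.
#
# A `sumstats` object holds per-variant association records for one trait
# (exposure or outcome) in one ancestry / tissue: a data frame keyed by
# variant id with columns id, chrom, pos, effect_allele, other_allele,
# beta, se, eaf, p, n, n_case, n_ctrl.  Variants are restricted to
# biallelic SNVs; coordinates are 1-based.

#' Default column dialect (GWAS-SSF style names)
#'
#' Maps internal field names to the column names expected in input files.
#' Supply a modified copy to [read_sumstats()] for other layouts.
#'
#' @return named character vector
#' @export
gwas_ssf_dialect <- function() {
  c(id = "rsid", chrom = "chromosome", pos = "base_pair_location",
    effect_allele = "effect_allele", other_allele = "other_allele",
    beta = "beta", se = "standard_error", eaf = "effect_allele_frequency",
    p = "p_value", n = "n", n_case = "n_case", n_ctrl = "n_ctrl")
}

REQUIRED_FIELDS <- c("chrom", "pos", "effect_allele", "other_allele",
                     "beta", "se", "p")

#' Construct a summary-statistics object
#'
#' Validates per-variant records, dropping rows that violate invariants
#' (non-SNV or identical alleles, se <= 0, p outside (0,1], pos < 1,
#' duplicated variant id) and recording counts per reason in a load report.
#' Missing p-values are recomputed from beta/se by a two-sided normal
#' approximation.
#'
#' @param records data frame with columns id, chrom, pos, effect_allele,
#'   other_allele, beta, se and optionally eaf, p, n, n_case, n_ctrl
#' @param trait_id trait label
#' @param trait_role "exposure" or "outcome"
#' @param ancestry ancestry label
#' @param tissue tissue label or NULL
#' @return object of class `sumstats`
#' @export
sumstats <- function(records, trait_id, trait_role = c("exposure", "outcome"),
                     ancestry = "NA", tissue = NULL) {
  trait_role <- match.arg(trait_role)
  for (col in c("eaf", "p", "n", "n_case", "n_ctrl"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  if (is.null(records$id) || all(is.na(records$id))) {
    records$id <- paste0(records$chrom, ":", records$pos, ":",
                         records$other_allele, ":", records$effect_allele)
  }
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "beta", "se", "eaf", "p", "n", "n_case", "n_ctrl"))
    records[[col]] <- as.numeric(records[[col]])

  report <- c(input = nrow(records))
  drop <- function(bad, reason) {
    bad[is.na(bad)] <- TRUE
    report[reason] <<- sum(bad)
    records <<- records[!bad, , drop = FALSE]
  }
  nt <- c("A", "C", "G", "T")
  drop(!(records$effect_allele %in% nt & records$other_allele %in% nt),
       "non_snv_allele")
  drop(records$effect_allele == records$other_allele, "identical_alleles")
  drop(records$pos < 1, "bad_position")
  drop(!is.finite(records$beta) | !is.finite(records$se) | records$se <= 0,
       "bad_beta_se")
  miss_p <- is.na(records$p)
  if (any(miss_p)) {
    records$p[miss_p] <- z_pvalue(records$beta[miss_p], records$se[miss_p])
    report["p_recomputed"] <- sum(miss_p)
  }
  drop(records$p <= 0 | records$p > 1, "bad_p")
  bad_eaf <- !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1)
  if (any(bad_eaf)) {
    report["eaf_set_missing"] <- sum(bad_eaf)
    records$eaf[bad_eaf] <- NA_real_
  }
  dup <- duplicated(records$id)
  if (any(dup)) {
    warning(sum(dup), " duplicated variant id(s) dropped (first kept)")
    drop(dup, "duplicate_id")
  }
  # n = n_case + n_ctrl when both sides are present
  has_cc <- !is.na(records$n_case) & !is.na(records$n_ctrl)
  records$n[has_cc] <- records$n_case[has_cc] + records$n_ctrl[has_cc]
  report["kept"] <- nrow(records)

  rownames(records) <- NULL
  structure(list(trait_id = trait_id, trait_role = trait_role,
                 ancestry = ancestry, tissue = tissue,
                 records = records, load_report = report),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s [%s] ancestry=%s%s: %d variants\n",
              x$trait_id, x$trait_role, x$ancestry,
              if (!is.null(x$tissue)) paste0(" tissue=", x$tissue) else "",
              nrow(x$records)))
  invisible(x)
}

#' Read a summary-statistics table
#'
#' Reads a delimited text file with header, resolves columns through a
#' dialect mapping, validates rows and returns a [sumstats()] object.
#' Rows failing invariants are dropped and counted in `$load_report`.
#'
#' @param path file path (tab-separated by default)
#' @param trait_id,trait_role,ancestry,tissue trait metadata
#' @param dialect named vector mapping internal fields to column names,
#'   see [gwas_ssf_dialect()]
#' @param sep field separator
#' @return `sumstats` object
#' @export
read_sumstats <- function(path, trait_id, trait_role = "exposure",
                          ancestry = "NA", tissue = NULL,
                          dialect = gwas_ssf_dialect(), sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = NA, check.names = FALSE)
  missing_cols <- setdiff(dialect[REQUIRED_FIELDS], names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  rec <- data.frame(row.names = seq_len(nrow(tab)))
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (col %in% names(tab)) rec[[field]] <- tab[[col]]
  }
  s <- sumstats(rec, trait_id = trait_id, trait_role = trait_role,
                ancestry = ancestry, tissue = tissue)
  if (nrow(s$records) == 0L)
    stop("no valid rows in ", path)
  s
}

#' Write a summary-statistics table
#'
#' Writes tab-separated text with GWAS-SSF-style column names; numeric
#' fields carry 17 significant digits so that a read of the written file
#' reproduces the records exactly. Missing values are written as NA.
#'
#' @param s `sumstats` object
#' @param path output path
#' @return invisibly, the path
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  d <- gwas_ssf_dialect()
  rec <- s$records
  out <- data.frame(row.names = seq_len(max(nrow(rec), 0L)))
  for (field in names(d)) {
    v <- rec[[field]]
    out[[d[[field]]]] <- if (is.numeric(v)) {
      ifelse(is.na(v), NA, format(v, digits = 17, scientific = TRUE,
                                  trim = TRUE))
    } else v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize one exposure/outcome record pair onto the exposure effect allele
#'
#' Orients the outcome association to the exposure's effect allele. When the
#' outcome effect allele equals the exposure other allele (directly or on the
#' complementary strand) the outcome beta is negated and its allele frequency
#' reflected. Palindromic variants (A/T, C/G) cannot be strand-resolved from
#' alleles alone and are inferred from allele-frequency concordance; they are
#' dropped when the minor-allele frequency exceeds `palindrome_eaf_limit` on
#' either side or when a frequency is missing. Irreconcilable allele sets
#' give status `dropped_mismatch`.
#'
#' @param exposure,outcome single-row record lists/data frames with fields
#'   chrom, pos, effect_allele, other_allele, beta, se, eaf
#' @param palindrome_eaf_limit drop palindromic variants whose minor-allele
#'   frequency exceeds this on either side (default 0.42)
#' @return list with fields variant, beta_x, se_x, beta_y, se_y, eaf_x,
#'   eaf_y, status
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  if (exposure$chrom != outcome$chrom || exposure$pos != outcome$pos)
    stop("harmonize() called on records at different positions")
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele;  oa_y <- outcome$other_allele
  out <- list(variant = list(id = exposure$id, chrom = exposure$chrom,
                             pos = exposure$pos, effect_allele = ea_x,
                             other_allele = oa_x),
              beta_x = exposure$beta, se_x = exposure$se,
              eaf_x = exposure$eaf %||% NA_real_,
              beta_y = outcome$beta, se_y = outcome$se,
              eaf_y = outcome$eaf %||% NA_real_,
              status = "dropped_mismatch")
  pal <- is_palindromic(ea_x, oa_x)

  # nominal orientation from allele labels (trying the reported strand,
  # then the complementary strand)
  orient <- NA  # TRUE = aligned, FALSE = needs flip
  if (ea_y == ea_x && oa_y == oa_x) orient <- TRUE
  else if (ea_y == oa_x && oa_y == ea_x) orient <- FALSE
  else {
    cea <- unname(.complement[ea_y]); coa <- unname(.complement[oa_y])
    if (identical(cea, ea_x) && identical(coa, oa_x)) orient <- TRUE
    else if (identical(cea, oa_x) && identical(coa, ea_x)) orient <- FALSE
  }
  if (is.na(orient)) return(out)  # dropped_mismatch

  flip <- function() {
    out$beta_y <<- -out$beta_y
    if (!is.na(out$eaf_y)) out$eaf_y <<- 1 - out$eaf_y
  }
  if (!pal) {
    if (!orient) flip()
    out$status <- if (orient) "kept" else "flipped"
    return(out)
  }
  # palindromic: allele labels cannot resolve strand; use EAF concordance
  if (is.na(out$eaf_x) || is.na(out$eaf_y)) {
    out$status <- "dropped_palindromic"; return(out)
  }
  if (!orient) flip()
  maf_x <- min(out$eaf_x, 1 - out$eaf_x)
  maf_y <- min(out$eaf_y, 1 - out$eaf_y)
  if (maf_x > palindrome_eaf_limit || maf_y > palindrome_eaf_limit) {
    out$status <- "dropped_palindromic"
    return(out)
  }
  if ((out$eaf_x < 0.5) != (out$eaf_y < 0.5)) flip()
  out$status <- "palindromic_inferred"
  out
}

#' Harmonize two summary-statistics tables on their shared variants
#'
#' Joins exposure and outcome records on variant id (requiring matching
#' chromosome and position) and applies [harmonize()] pairwise.
#'
#' @param exposure,outcome `sumstats` objects
#' @inheritParams harmonize
#' @return data frame with one row per shared variant: id, chrom, pos,
#'   effect_allele, other_allele, beta_x, se_x, eaf_x, beta_y, se_y, eaf_y,
#'   status, plus outcome n/n_case/n_ctrl carried through
#' @export
harmonize_sumstats <- function(exposure, outcome,
                               palindrome_eaf_limit = 0.42) {
  ex <- exposure$records
  oy <- outcome$records
  shared <- intersect(ex$id, oy$id)
  ex <- ex[match(shared, ex$id), , drop = FALSE]
  oy <- oy[match(shared, oy$id), , drop = FALSE]
  same_locus <- ex$chrom == oy$chrom & ex$pos == oy$pos
  ex <- ex[same_locus, , drop = FALSE]
  oy <- oy[same_locus, , drop = FALSE]
  n <- nrow(ex)
  res <- data.frame(id = ex$id, chrom = ex$chrom, pos = ex$pos,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_x = NA_real_, se_x = ex$se, eaf_x = ex$eaf,
                    beta_y = NA_real_, se_y = oy$se, eaf_y = NA_real_,
                    status = NA_character_,
                    n_x = ex$n, n_y = oy$n,
                    n_case = oy$n_case, n_ctrl = oy$n_ctrl,
                    p_x = ex$p,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    h <- harmonize(as.list(ex[i, ]), as.list(oy[i, ]), palindrome_eaf_limit)
    res$beta_x[i] <- h$beta_x
    res$beta_y[i] <- h$beta_y
    res$eaf_y[i] <- h$eaf_y
    res$status[i] <- h$status
  }
  res
}
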