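# Programmatic fixtures shared across test files.

# a harmonized instrument frame as produced by select_instruments()
make_iv_frame <- function(beta_x, beta_y, se_x = 0.02, se_y = 0.02,
                          eaf_x = 0.3, n_x = 1e4, n_case = 2e4,
                          n_ctrl = 2e4) {
  k <- length(beta_x)
  rep_k <- function(v) rep_len(v, k)
  data.frame(id = sprintf("rs%03d", seq_len(k)), chrom = "1",
             pos = seq_len(k) * 1000, effect_allele = "A",
             other_allele = "G", beta_x = beta_x, se_x = rep_k(se_x),
             eaf_x = rep_k(eaf_x), beta_y = beta_y, se_y = rep_k(se_y),
             eaf_y = rep_k(eaf_x), p_x = 1e-10,
             f_stat = beta_x^2 / rep_k(se_x)^2, status = "kept",
             is_proxy = FALSE, proxy_source = NA, r2_with_source = NA,
             n_x = rep_k(n_x), n_y = rep_k(n_case) + rep_k(n_ctrl),
             n_case = rep_k(n_case), n_ctrl = rep_k(n_ctrl),
             stringsAsFactors = FALSE)
}

make_instrument_set <- function(...) {
  structure(list(trait_id = "trait", ancestry = "TST", tissue = NULL,
                 instruments = make_iv_frame(...),
                 selection_log = data.frame()),
            class = "instrument_set")
}

# a records data frame accepted by sumstats()
make_records <- function(n = 3, chrom = "1", pos = NULL, beta = NULL,
                         se = NULL, eaf = NULL, p = NULL,
                         ea = "A", oa = "G") {
  data.frame(id = sprintf("rs%d", seq_len(n)), chrom = chrom,
             pos = pos %||% (1e6 + seq_len(n) * 1000),
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             beta = beta %||% rep(0.1, n), se = se %||% rep(0.02, n),
             eaf = eaf %||% rep(0.3, n), p = p %||% rep(1e-8, n),
             n = 1e4, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small reference panel reused by LD-dependent tests
test_panel <- function(m = 20, n_ref = 500, rho = 0.5, seed = 11,
                       maf_range = c(0.1, 0.5), ancestry = "TST") {
  simulate_reference_panel(panel_config(
    ancestry = ancestry, m_variants = m, n_ref = n_ref,
    maf_range = maf_range, ld_rho = rho, seed = seed))
}

# hand-built cascade inputs with chosen criterion values
fake_suite <- function(concordant = TRUE, I2 = 10, int_p = 0.5,
                       na_all = FALSE) {
  if (na_all)
    return(structure(list(concordant = not_applicable(""),
                          het = not_applicable(""),
                          egger_intercept_p = not_applicable("")),
                     class = "sensitivity_suite"))
  structure(list(concordant = concordant,
                 het = structure(list(Q = 1, df = 1, p = 0.3, I2 = I2),
                                 class = "het_stats"),
                 egger_intercept_p = int_p),
            class = "sensitivity_suite")
}
fake_coloc <- function(pph4) structure(list(max_pph4 = pph4,
                                            pph = c(H4 = pph4)),
                                       class = "coloc_result")
fake_mr <- function(est = 0.2, se = 0.05, n = 3)
  structure(list(method = "ivw", estimate = est, se = se,
                 p = 2 * pnorm(-abs(est / se)), n_iv = n),
            class = "mr_result")
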