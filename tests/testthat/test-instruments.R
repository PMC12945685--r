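# Instrument selection: F filter, clumping, proxies, full pipeline.

test_that("the F-statistic is beta^2/se^2 with a strict F > 10 filter downstream", {
  expect_equal(f_statistic(0.5, 0.05), 100)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_false(f_statistic(-0.3, 0.1) > 10)   # boundary excluded
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("clumping keeps independent variants and prunes by LD dominance", {
  panel <- test_panel(m = 2, n_ref = 500, rho = 0, seed = 1)
  panel$ld <- diag(2)
  s <- sumstats(data.frame(id = panel$variants$id, chrom = "1",
                           pos = panel$variants$pos, effect_allele = "A",
                           other_allele = "G", beta = 0.1, se = 0.02,
                           eaf = 0.3, p = c(1e-10, 1e-4), n = 1e4), "g")
  kept <- ld_clump(s, panel, iv_config())
  expect_setequal(as.character(kept), panel$variants$id)

  panel$ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  kept2 <- ld_clump(s, panel, iv_config())
  expect_equal(as.character(kept2), panel$variants$id[1])
})

test_that("clumping matches an exhaustive greedy oracle across random panels", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- 50
    panel <- test_panel(m = m, n_ref = 150, rho = runif(1, 0, 0.9),
                        seed = seed)
    s <- sumstats(data.frame(id = panel$variants$id, chrom = "1",
                             pos = panel$variants$pos,
                             effect_allele = "A", other_allele = "G",
                             beta = 0.1, se = 0.02, eaf = 0.3,
                             p = runif(m), n = 1e4), "g")
    cfg <- iv_config(clump_r2 = sample(c(0.001, 0.05, 0.3), 1),
                     clump_window_bp = sample(c(2e4, 1e7), 1))
    got <- as.character(ld_clump(s, panel, cfg))
    want <- oracle_clump(panel$variants$id, panel$variants$pos,
                         s$records$p, panel$ld^2, cfg$clump_r2,
                         cfg$clump_window_bp)
    expect_identical(got, want)
  }
})

test_that("clump selection is invariant to input row order", {
  panel <- test_panel(m = 30, n_ref = 200, rho = 0.6, seed = 4)
  set.seed(4)
  s <- sumstats(data.frame(id = panel$variants$id, chrom = "1",
                           pos = panel$variants$pos, effect_allele = "A",
                           other_allele = "G", beta = 0.1, se = 0.02,
                           eaf = 0.3, p = runif(30), n = 1e4), "g")
  s_shuf <- s
  s_shuf$records <- s$records[sample.int(30), ]
  expect_identical(as.character(ld_clump(s, panel, iv_config(clump_r2 = 0.1))),
                   as.character(ld_clump(s_shuf, panel,
                                         iv_config(clump_r2 = 0.1))))
})

make_panel_stats <- function(panel, p = NULL, beta = 0.5, se = 0.05) {
  m <- nrow(panel$variants)
  sumstats(cbind(panel$variants,
                 data.frame(beta = rep_len(beta, m), se = rep_len(se, m),
                            eaf = panel$eaf, p = p %||% rep(1e-12, m),
                            n = 1e4, n_case = 5e3, n_ctrl = 5e3)), "g",
           ancestry = panel$ancestry)
}

test_that("proxy search honors the strict r2 threshold and distance tie-break", {
  panel <- test_panel(m = 5, n_ref = 200, rho = 0, seed = 6)
  ld <- diag(5)
  ld[1, 2] <- ld[2, 1] <- sqrt(0.9)
  ld[1, 4] <- ld[4, 1] <- sqrt(0.9)   # same r2, further away
  ld[1, 3] <- ld[3, 1] <- sqrt(0.79)
  panel$ld <- ld
  ex <- make_panel_stats(panel)
  ids <- panel$variants$id
  oy <- make_panel_stats(panel)
  oy$records <- oy$records[oy$records$id != ids[1], ]

  px <- find_proxy(ids[1], ex, oy, panel, iv_config())
  expect_equal(px$id, ids[2])          # nearest of the two r2=0.9 proxies
  expect_equal(px$r2, 0.9)

  # best below the strict threshold: no proxy
  ld2 <- diag(5); ld2[1, 3] <- ld2[3, 1] <- sqrt(0.79)
  panel$ld <- ld2
  expect_null(find_proxy(ids[1], ex, oy, panel, iv_config()))
  # exactly at the threshold is excluded (strict >)
  ld3 <- diag(5); ld3[1, 3] <- ld3[3, 1] <- sqrt(0.8)
  panel$ld <- ld3
  expect_null(find_proxy(ids[1], ex, oy, panel, iv_config()))
})

test_that("select_instruments runs the pipeline stages in order", {
  panel <- test_panel(m = 5, n_ref = 300, rho = 0, seed = 8)
  panel$ld <- diag(5)
  gene <- list(gene_id = "g", chrom = "1",
               tss = panel$variants$pos[3])
  p_vec <- c(1e-12, rep(0.5, 4))

  ex <- make_panel_stats(panel, p = p_vec)
  oy <- make_panel_stats(panel, beta = 0.05)
  cfg <- iv_config(qtl_sig_threshold = 5e-8)
  iv <- select_instruments(ex, oy, panel, gene, cfg)
  expect_equal(n_iv(iv), 1)
  expect_equal(iv$instruments$f_stat, 100)

  # weak instrument: F = 9 is excluded
  ex_w <- make_panel_stats(panel, p = p_vec, beta = 0.15, se = 0.05)
  iv_w <- select_instruments(ex_w, oy, panel, gene, cfg)
  expect_equal(n_iv(iv_w), 0)
  expect_true(any(grepl("F=9", iv_w$selection_log$reason)))

  # instrument missing from outcome, strong proxy available
  panel2 <- panel
  ld <- diag(5); ld[1, 2] <- ld[2, 1] <- sqrt(0.95)
  panel2$ld <- ld
  oy_missing <- oy
  oy_missing$records <- oy$records[-1, ]
  iv_p <- select_instruments(ex, oy_missing, panel2, gene, cfg)
  expect_equal(n_iv(iv_p), 1)
  expect_true(iv_p$instruments$is_proxy)
  expect_equal(iv_p$instruments$id, panel$variants$id[2])
  expect_gt(iv_p$instruments$r2_with_source, 0.8)
})

test_that("selection shrinks monotonically with stricter thresholds", {
  panel <- test_panel(m = 40, n_ref = 400, rho = 0.5, seed = 10)
  gene <- list(gene_id = "g", chrom = "1",
               tss = panel$variants$pos[20])
  set.seed(10)
  ex <- make_panel_stats(panel, p = 10^runif(40, -14, 0),
                         beta = rnorm(40, 0, 0.3), se = 0.05)
  oy <- make_panel_stats(panel, beta = 0.05)
  base <- iv_config(qtl_sig_threshold = 1e-3, f_min = 10, clump_r2 = 0.3)
  n_base <- n_iv(select_instruments(ex, oy, panel, gene, base))
  stricter_f <- iv_config(qtl_sig_threshold = 1e-3, f_min = 50,
                          clump_r2 = 0.3)
  stricter_p <- iv_config(qtl_sig_threshold = 1e-8, f_min = 10,
                          clump_r2 = 0.3)
  expect_lte(n_iv(select_instruments(ex, oy, panel, gene, stricter_f)),
             n_base)
  expect_lte(n_iv(select_instruments(ex, oy, panel, gene, stricter_p)),
             n_base)
})

test_that("retained instruments never exceed the clump r2 in the panel", {
  panel <- test_panel(m = 40, n_ref = 400, rho = 0.7, seed = 12)
  gene <- list(gene_id = "g", chrom = "1", tss = panel$variants$pos[20])
  set.seed(12)
  ex <- make_panel_stats(panel, p = 10^runif(40, -14, -4),
                         beta = rnorm(40, 0.5, 0.1), se = 0.05)
  oy <- make_panel_stats(panel, beta = 0.05)
  cfg <- iv_config(qtl_sig_threshold = 1e-3, clump_r2 = 0.05)
  iv <- select_instruments(ex, oy, panel, gene, cfg)
  ids <- iv$instruments$id
  if (length(ids) >= 2) {
    idx <- match(ids, panel$variants$id)
    r2 <- panel$ld[idx, idx]^2
    diag(r2) <- 0
    expect_lte(max(r2), cfg$clump_r2)
  }
  expect_gte(length(ids), 1)
})
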