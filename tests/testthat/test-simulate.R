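# Synthetic-data generator: seed determinism, LD and MAF calibration,
# null distributions and signal strength of generated summary statistics.

test_that("reference panels are deterministic given the seed", {
  cfg <- panel_config(m_variants = 15, n_ref = 200, seed = 5)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$ld, p2$ld)
  p3 <- simulate_reference_panel(panel_config(m_variants = 15, n_ref = 200,
                                              seed = 6))
  expect_false(identical(p1$dosages, p3$dosages))
})

test_that("panel invariants hold: unit diagonal, PSD LD, maf in (0, 0.5]", {
  p <- test_panel(m = 30, n_ref = 300, rho = 0.7, seed = 3)
  expect_equal(diag(p$ld), rep(1, 30))
  expect_true(min(eigen(p$ld, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-8)
  expect_true(all(p$maf > 0 & p$maf <= 0.5))
})

test_that("uncorrelated panels show only sampling-level LD", {
  p <- test_panel(m = 40, n_ref = 5000, rho = 0, seed = 9)
  off <- abs(p$ld[upper.tri(p$ld)])
  expect_lt(mean(off), 0.05)  # ~1/sqrt(n_ref) scale
})

test_that("empirical MAF matches the binomial sampling bound at a point target", {
  p <- simulate_reference_panel(panel_config(
    m_variants = 25, n_ref = 5000, maf_range = c(0.3, 0.3), ld_rho = 0,
    seed = 2))
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * 5000))
  expect_true(all(abs(p$maf - 0.3) <= tol))
})

test_that("empirical LD tracks the target AR(1) profile", {
  p <- test_panel(m = 30, n_ref = 5000, rho = 0.6, seed = 21)
  # target profile: the population dosage correlation implied by the
  # copula, approximated by a very large independent draw
  set.seed(22)
  G_big <- mrcascade::draw_genotypes(2e5, p$gen$f, p$gen$rho)
  target <- cor(G_big)
  expect_lt(mean(abs(p$ld - target)[upper.tri(target)]), 0.05)
  lag1 <- p$ld[cbind(1:29, 2:30)]
  lag2 <- p$ld[cbind(1:28, 3:30)]
  expect_lt(mean(lag2), mean(lag1))   # monotone decay with distance
})

test_that("null expression scans give uniform p-values; causal variants carry the expected F", {
  p <- simulate_reference_panel(panel_config(
    m_variants = 1000, n_ref = 100, maf_range = c(0.1, 0.5), ld_rho = 0,
    seed = 7))
  s0 <- simulate_expression_sumstats(p, gamma = rep(0, 1000), h2_expr = 0,
                                     n_exp = 500, seed = 13)
  ks <- suppressWarnings(ks.test(s0$records$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  p1 <- simulate_reference_panel(panel_config(
    m_variants = 5, n_ref = 400, maf_range = c(0.2, 0.5), ld_rho = 0,
    seed = 8))
  gamma <- c(1, 0, 0, 0, 0)
  s1 <- simulate_expression_sumstats(p1, gamma, h2_expr = 0.1,
                                     n_exp = 10000, seed = 14)
  f_obs <- f_statistic(s1$records$beta[1], s1$records$se[1])
  f_exp <- 10000 * 0.1 / 0.9
  expect_lt(abs(f_obs - f_exp) / f_exp, 0.25)

  s1b <- simulate_expression_sumstats(p1, gamma, h2_expr = 0.1,
                                      n_exp = 10000, seed = 14)
  expect_identical(s1$records, s1b$records)
  expect_error(simulate_expression_sumstats(p1, rep(0, 5), 0.1, 100, 1),
               "nonzero gamma")
})

test_that("null outcome scans give uniform p-values and record case counts", {
  p <- simulate_reference_panel(panel_config(
    m_variants = 1000, n_ref = 100, maf_range = c(0.1, 0.5), ld_rho = 0,
    seed = 17))
  tt <- truth_table(gamma = rep(0, 1000), theta = 0, h2_expr = 0,
                    K = 0.1, n_case = 800, n_ctrl = 800)
  s <- simulate_outcome_sumstats(p, tt, seed = 19)
  ks <- suppressWarnings(ks.test(s$records$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_true(all(s$records$n_case == 800 & s$records$n_ctrl == 800))
  s2 <- simulate_outcome_sumstats(p, tt, seed = 19)
  expect_identical(s$records, s2$records)
})

test_that("downstream IVW recovers the generating causal log-OR", {
  # strong single instrument, large samples: the Wald ratio should sit
  # within 3 SE of the true effect in nearly all replicates
  theta <- log(1.5)
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    p <- simulate_reference_panel(panel_config(
      m_variants = 3, n_ref = 300, maf_range = c(0.2, 0.5), ld_rho = 0,
      seed = 100 + r))
    gamma <- c(1, 0, 0)
    ex <- simulate_expression_sumstats(p, gamma, 0.1, 8000,
                                       seed = 200 + r)
    tt <- truth_table(gamma, theta = theta, h2_expr = 0.1, K = 0.1,
                      n_case = 4000, n_ctrl = 4000)
    oy <- simulate_outcome_sumstats(p, tt, seed = 300 + r)
    est <- oy$records$beta[1] / ex$records$beta[1]
    se <- oy$records$se[1] / abs(ex$records$beta[1])
    if (abs(est - theta) < 3 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("study bundles have the expected shape and sign-flipped tissue effects", {
  study <- list(
    ancestries = list(
      A1 = list(panel = list(m_variants = 12, n_ref = 150, ld_rho = 0.3),
                n_exp = 3000, n_case = 600, n_ctrl = 600),
      A2 = list(panel = list(m_variants = 12, n_ref = 150, ld_rho = 0.3),
                n_exp = 3000, n_case = 600, n_ctrl = 600)),
    genes = data.frame(gene_id = paste0("G", 1:10),
                       theta = c(rep(log(1.6), 5), rep(0, 5))),
    tissues = c("t1", "t2"), tissue_sharing = "sign_flipped", K = 0.1)
  b <- simulate_study(study, seed = 31)
  expect_length(b$exposures, 2 * 2 * 10)
  expect_length(b$outcomes, 2)
  expect_length(b$truth, 10)
  b2 <- simulate_study(study, seed = 31)
  expect_identical(b$exposures[[1]]$records, b2$exposures[[1]]$records)

  # in causal genes, Wald ratios from the two tissues have opposite signs
  flips <- 0L; total <- 0L
  for (g in paste0("G", 1:5)) {
    for (anc in c("A1", "A2")) {
      tt <- b$truth[[g]]
      j <- which.max(abs(tt$gamma))
      e1 <- b$exposures[[paste(g, anc, "t1", sep = "|")]]$records
      e2 <- b$exposures[[paste(g, anc, "t2", sep = "|")]]$records
      oy <- b$outcome_loci[[anc]][[g]]$records
      r1 <- oy$beta[j] / e1$beta[j]
      r2 <- oy$beta[j] / e2$beta[j]
      total <- total + 1L
      if (sign(r1) != sign(r2)) flips <- flips + 1L
    }
  }
  expect_gte(flips / total, 0.9)
})

test_that("the z-score generator reproduces marginal expectations under LD", {
  panel <- test_panel(m = 60, n_ref = 2000, rho = 0.6, seed = 23)
  bj <- numeric(60); bj[30] <- 0.3
  zs <- vapply(1:60, function(r) {
    s <- simulate_zscore_sumstats(panel, bj, n = 20000, seed = 7000 + r)
    s$records$beta[30] / s$records$se[30]
  }, numeric(1))
  se30 <- 1 / sqrt(2 * panel$eaf[30] * (1 - panel$eaf[30]) * 20000)
  expect_lt(abs(mean(zs) - 0.3 / se30) / (0.3 / se30), 0.1)
})
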