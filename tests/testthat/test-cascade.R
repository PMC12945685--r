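# FDR, causal calls, replication, the replication ladder and
# cross-ancestry meta-analysis.

test_that("BH q-values match the step-up oracle, including edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(81)
  for (r in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("the four-criterion causal call applies strict comparators", {
  d <- call_causal(fake_mr(), q = 0.01, fake_suite(), fake_coloc(0.95))
  expect_true(d$causal)

  # PPH4 exactly 0.8 or below fails the strict > 0.8 rule
  expect_false(call_causal(fake_mr(), 0.01, fake_suite(),
                           fake_coloc(0.80))$causal)
  expect_false(call_causal(fake_mr(), 0.01, fake_suite(),
                           fake_coloc(0.79))$causal)
  # q at the threshold fails
  expect_false(call_causal(fake_mr(), 0.05, fake_suite(),
                           fake_coloc(0.95))$causal)
  # I2 at 50 fails the strict < 50 rule
  expect_false(call_causal(fake_mr(), 0.01, fake_suite(I2 = 50),
                           fake_coloc(0.95))$causal)
  # significant Egger intercept fails
  expect_false(call_causal(fake_mr(), 0.01, fake_suite(int_p = 0.01),
                           fake_coloc(0.95))$causal)
  # discordant sensitivity fails
  expect_false(call_causal(fake_mr(), 0.01, fake_suite(concordant = FALSE),
                           fake_coloc(0.95))$causal)
})

test_that("single-instrument traits skip criteria 2-3 but still need q and coloc", {
  d <- call_causal(fake_mr(n = 1), q = 0.001, fake_suite(na_all = TRUE),
                   fake_coloc(0.9))
  expect_true(d$causal)
  expect_true(is.na(d$crit_sensitivity))
  expect_true(is.na(d$crit_het_pleio))
  # but colocalization remains mandatory
  d2 <- call_causal(fake_mr(n = 1), 0.001, fake_suite(na_all = TRUE),
                    not_applicable("no shared variants"))
  expect_false(d2$causal)
})

test_that("replication requires FDR significance and a concordant direction", {
  disc <- data.frame(trait_id = c("g1", "g2", "g3", "g4"),
                     causal = c(TRUE, TRUE, TRUE, FALSE),
                     estimate = c(0.3, -0.2, 0.25, 0.1))
  repl <- data.frame(trait_id = c("g1", "g2", "x"),
                     estimate = c(0.28, 0.3, 0),
                     p = c(0.001, 0.002, 0.5))
  out <- evaluate_replication(disc, repl)
  # g3 untestable: excluded from the FDR set and the denominator
  expect_equal(nrow(out), 2)
  expect_equal(out$q_replication, bh_fdr(c(0.001, 0.002)))
  expect_true(out$replicated[out$trait_id == "g1"])
  # significant but direction-discordant
  expect_false(out$replicated[out$trait_id == "g2"])

  repl2 <- data.frame(trait_id = "g1", estimate = 0.2, p = 0.04)
  out2 <- evaluate_replication(disc[1, ], repl2)
  expect_true(out2$replicated)   # q = p with one test, same sign
})

test_that("the replication ladder is nested and handles empty overlap", {
  disc <- data.frame(trait_id = paste0("g", 1:8),
                     p = c(0.001, 0.002, 0.2, 0.01, 0.03, 0.5, 1e-5, 0.04),
                     q = c(0.004, 0.008, 0.4, 0.02, 0.06, 0.7, 8e-5, 0.06),
                     n_iv = c(1, 3, 1, 4, 1, 2, 5, 1),
                     crit_sensitivity = c(NA, TRUE, NA, FALSE, NA, TRUE,
                                          TRUE, NA),
                     crit_het_pleio = c(NA, TRUE, NA, TRUE, NA, TRUE, TRUE,
                                        NA),
                     crit_coloc = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                                    FALSE, TRUE))
  repl <- data.frame(trait_id = paste0("g", c(1, 2, 4, 7)),
                     estimate = c(0.2, 0.3, 0.1, 0.2),
                     p = c(0.001, 0.01, 0.3, 0.002))
  lad <- replication_ladder(disc, repl)
  expect_equal(lad$criterion[1:5],
               c("all_tested", "nominal_p", "fdr_q", "sensitivity",
                 "full_criteria"))
  expect_true(all(diff(lad$n_significant[1:5]) <= 0))

  lad0 <- replication_ladder(disc, repl[0, ])
  expect_true(all(is.na(lad0$rate)))
})

test_that("DL meta-analysis matches a closed-form oracle and degenerates correctly", {
  m0 <- meta_analyze(c(0.2, 0.2), c(0.05, 0.05))
  expect_equal(m0$estimate, 0.2)
  expect_equal(m0$tau2, 0)

  m <- meta_analyze(c(0.2, 0.4), c(0.05, 0.05))
  want <- oracle_dl(c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(m$estimate, want$estimate, tolerance = 1e-10)
  expect_equal(m$se, want$se, tolerance = 1e-10)
  expect_equal(m$tau2, want$tau2, tolerance = 1e-10)
  expect_equal(m$Q_ancestry, want$Q, tolerance = 1e-10)

  expect_error(meta_analyze(0.2, 0.05), "at least two")

  set.seed(82)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    est <- rnorm(k, 0.2, 0.2); se <- runif(k, 0.02, 0.2)
    got <- meta_analyze(est, se)
    want <- oracle_dl(est, se)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-10)
    # when tau2 = 0, DL reduces to fixed-effect pooling exactly
    if (want$tau2 == 0) {
      w <- 1 / se^2
      expect_equal(got$estimate, sum(w * est) / sum(w), tolerance = 1e-12)
      expect_equal(got$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
    }
  }
})

test_that("DL pooling agrees with metafor's implementation", {
  skip_if_not_installed("metafor")
  set.seed(83)
  est <- rnorm(4, 0.3, 0.2); se <- runif(4, 0.05, 0.2)
  got <- meta_analyze(est, se, method = "DL")
  fit <- metafor::rma(yi = est, sei = se, method = "DL")
  expect_equal(got$estimate, as.numeric(fit$beta), tolerance = 1e-8)
  expect_equal(got$se, fit$se, tolerance = 1e-8)
  expect_equal(got$tau2, fit$tau2, tolerance = 1e-8)
})

test_that("meta-significance needs meta FDR plus one compelling cohort", {
  cohorts <- data.frame(p = c(0.03, 0.2),
                        crit_sensitivity = c(TRUE, TRUE),
                        crit_het_pleio = c(TRUE, TRUE),
                        crit_coloc = c(TRUE, FALSE))
  expect_true(call_meta_significant(0.01, cohorts))
  # no cohort passes colocalization
  cohorts2 <- cohorts; cohorts2$crit_coloc <- FALSE
  expect_false(call_meta_significant(0.01, cohorts2))
  # meta q above threshold fails regardless
  expect_false(call_meta_significant(0.06, cohorts))
  # nominal p in the colocalizing cohort required
  cohorts3 <- cohorts; cohorts3$p <- c(0.2, 0.01)
  expect_false(call_meta_significant(0.01, cohorts3))
})
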