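# Multi-ancestry synthetic-data generator with known causal architecture.
#
# Individual-level simulation keeps marginal statistics, LD and
# case-control ascertainment mutually consistent: genotypes arise from a
# latent Gaussian copula with AR(1) adjacent-variant correlation under
# Hardy-Weinberg equilibrium; expression follows an additive cis model
# with fixed heritability; the binary outcome follows a liability
# threshold model at prevalence K with case-control sampling.  A fast
# multivariate-normal z-score generator is provided for coloc-scale tests.

#' Reference-panel configuration
#'
#' @param ancestry ancestry label
#' @param m_variants number of biallelic SNVs (>= 2)
#' @param n_ref number of reference individuals
#' @param maf_range interval within (0, 0.5] for target allele frequencies
#' @param ld_rho AR(1) adjacent-variant latent correlation in [0, 1)
#' @param seed integer seed
#' @param chrom chromosome label
#' @param start_bp position of the first variant (1-based)
#' @param spacing_bp base pairs between adjacent variants
#' @return list of class `panel_config`
#' @export
panel_config <- function(ancestry = "POP", m_variants = 50, n_ref = 1000,
                         maf_range = c(0.05, 0.5), ld_rho = 0.5, seed = 1,
                         chrom = "1", start_bp = 1e6, spacing_bp = 2000) {
  stopifnot(m_variants >= 2, n_ref >= 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1)
  structure(list(ancestry = ancestry, m_variants = as.integer(m_variants),
                 n_ref = as.integer(n_ref), maf_range = maf_range,
                 ld_rho = ld_rho, seed = as.integer(seed), chrom = chrom,
                 start_bp = start_bp, spacing_bp = spacing_bp),
            class = "panel_config")
}

# Non-palindromic ordered allele pairs; the generator emits
# strand-unambiguous SNVs (A/T and C/G ambiguity is exercised in the
# harmonization unit tests, not in generated studies).
.allele_pairs <- local({
  nt <- c("A", "C", "G", "T")
  p <- expand.grid(ea = nt, oa = nt, stringsAsFactors = FALSE)
  p <- p[p$ea != p$oa, ]
  p[!(unname(c(A = "T", C = "G", G = "C", T = "A")[p$ea]) == p$oa), ]
})

#' Draw unphased genotype dosages from a latent AR(1) Gaussian copula
#'
#' Each haplotype's allele indicators come from thresholding an AR(1)
#' latent normal at the allele-frequency quantile; dosage is the sum of
#' two independent haplotypes (Hardy-Weinberg).
#'
#' @param n individuals
#' @param f per-variant effect-allele frequencies
#' @param rho AR(1) latent correlation
#' @return n x length(f) integer dosage matrix in 0..2
#' @export
draw_genotypes <- function(n, f, rho) {
  m <- length(f)
  if (rho == 0) {
    # independent variants: binomial dosages directly
    return(matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), n, m))
  }
  thr <- stats::qnorm(f)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    sc <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sc * z[, j]
    sweep(z, 2, thr, "<") + 0
  }
  hap() + hap()
}

#' Simulate an LD reference panel
#'
#' Deterministic given the seed in `cfg`. Allele frequencies are drawn
#' uniformly in `maf_range`; dosages for `n_ref` individuals are drawn via
#' [draw_genotypes()]; the LD matrix is the empirical dosage correlation.
#'
#' @param cfg [panel_config()]
#' @return object of class `ref_panel` with elements `ancestry`,
#'   `variants` (id, chrom, pos, effect_allele, other_allele), `eaf`
#'   (empirical effect-allele frequency), `maf`, `ld`, `dosages`, and the
#'   generative parameters in `gen` (used to draw study cohorts from the
#'   same population)
#' @export
simulate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    m <- cfg$m_variants
    f <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    # code a random half of variants by their major allele so effect-allele
    # frequencies span (0,1)
    swap <- stats::runif(m) < 0.5
    f[swap] <- 1 - f[swap]
    G <- draw_genotypes(cfg$n_ref, f, cfg$ld_rho)
    # guarantee polymorphism in the panel
    mono <- which(apply(G, 2, function(g) length(unique(g)) == 1L))
    for (j in mono) G[sample.int(nrow(G), 1), j] <- 1L
    pair_idx <- sample.int(nrow(.allele_pairs), m, replace = TRUE)
    pos <- cfg$start_bp + (seq_len(m) - 1L) * cfg$spacing_bp
    variants <- data.frame(
      id = sprintf("%s_%s:%d", cfg$ancestry, cfg$chrom, pos),
      chrom = cfg$chrom, pos = pos,
      effect_allele = .allele_pairs$ea[pair_idx],
      other_allele = .allele_pairs$oa[pair_idx],
      stringsAsFactors = FALSE)
    eaf <- colMeans(G) / 2
    ld <- suppressWarnings(stats::cor(G))
    ld[!is.finite(ld)] <- 0
    diag(ld) <- 1
    structure(list(ancestry = cfg$ancestry, variants = variants, eaf = eaf,
                   maf = pmin(eaf, 1 - eaf), ld = ld, dosages = G,
                   gen = list(f = f, rho = cfg$ld_rho)),
              class = "ref_panel")
  })
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %s: %d variants, %d reference individuals\n",
              x$ancestry, nrow(x$variants), nrow(x$dosages)))
  invisible(x)
}

#' Draw a fresh genotyped cohort from a panel's source population
#' @noRd
draw_cohort <- function(panel, n) {
  draw_genotypes(n, panel$gen$f, panel$gen$rho)
}

# shared marginal-OLS engine: per-variant regression of y on each dosage
marginal_ols <- function(G, y) {
  n <- nrow(G)
  gbar <- colMeans(G)
  Sxx <- colSums(G^2) - n * gbar^2
  Sxy <- as.numeric(crossprod(G, y)) - n * gbar * mean(y)
  Syy <- sum((y - mean(y))^2)
  beta <- Sxy / Sxx
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(beta = beta, se = se, p = pmin(pmax(p, .Machine$double.xmin), 1),
       eaf = gbar / 2)
}

#' Simulate cis-eQTL / pQTL exposure summary statistics
#'
#' Expression for `n_exp` fresh individuals from the panel's population is
#' `y = (G gamma) s + e`, with `s` chosen so the genetic variance equals
#' `h2_expr` and the total variance 1. Returns per-variant marginal
#' regression statistics.
#'
#' @param panel `ref_panel`
#' @param gamma per-variant causal effects on expression (length m)
#' @param h2_expr cis heritability in [0, 1)
#' @param n_exp exposure sample size
#' @param seed integer seed
#' @param trait_id,tissue metadata labels
#' @return `sumstats` object (exposure role)
#' @export
simulate_expression_sumstats <- function(panel, gamma, h2_expr, n_exp, seed,
                                         trait_id = "gene", tissue = NULL) {
  stopifnot(length(gamma) == nrow(panel$variants), h2_expr >= 0, h2_expr < 1)
  if (all(gamma == 0) && h2_expr > 0)
    stop("h2_expr > 0 requires at least one nonzero gamma")
  with_seed(seed, {
    G <- draw_cohort(panel, n_exp)
    g <- as.numeric(G %*% gamma)
    vg <- stats::var(g)
    s <- if (h2_expr > 0 && vg > 0) sqrt(h2_expr / vg) else 0
    y <- g * s + stats::rnorm(n_exp, 0, sqrt(1 - h2_expr))
    mo <- marginal_ols(G, y)
    rec <- cbind(panel$variants,
                 data.frame(beta = mo$beta, se = mo$se, eaf = mo$eaf,
                            p = mo$p, n = n_exp))
    sumstats(rec, trait_id = trait_id, trait_role = "exposure",
             ancestry = panel$ancestry, tissue = tissue)
  })
}

#' Truth table for one simulated gene
#'
#' @param gamma per-variant causal effects on expression
#' @param theta causal log-OR of a 1-SD increase in expression on the
#'   outcome (the quantity the MR pipeline should recover)
#' @param delta per-variant direct (pleiotropic) liability effects
#' @param h2_expr expression cis heritability
#' @param K outcome prevalence
#' @param n_exp,n_case,n_ctrl sample sizes
#' @return list of class `truth_table`
#' @export
truth_table <- function(gamma, theta = 0, delta = NULL, h2_expr = 0.1,
                        K = 0.1, n_exp = 5000, n_case = 5000,
                        n_ctrl = 5000) {
  stopifnot(h2_expr >= 0, h2_expr < 1, K > 0, K < 1)
  if (is.null(delta)) delta <- rep(0, length(gamma))
  stopifnot(length(delta) == length(gamma))
  structure(list(gamma = gamma, theta = theta, delta = delta,
                 h2_expr = h2_expr, K = K, n_exp = n_exp,
                 n_case = n_case, n_ctrl = n_ctrl),
            class = "truth_table")
}

# liability slope corresponding to a marginal log-OR near the null
logor_to_liability <- function(theta, K) {
  theta * K * (1 - K) / stats::dnorm(stats::qnorm(1 - K))
}

#' Simulate case-control outcome summary statistics under a liability model
#'
#' Liability is `b_l * x + G delta + e` where `x` is the (variance-1)
#' expression phenotype from the same architecture as the exposure study
#' and `b_l` is the liability slope matching a marginal log-OR of `theta`
#' per SD of expression. An individual is a case when liability exceeds
#' the (1-K) standard-normal quantile; cases and controls are accumulated
#' by rejection sampling. Per-variant log-ORs and SEs come from a one-step
#' (score) approximation to logistic regression.
#'
#' @param panel `ref_panel`
#' @param truth [truth_table()]
#' @param seed integer seed
#' @param trait_id metadata label
#' @param max_batches rejection-sampling iteration cap
#' @return `sumstats` object (outcome role) with n_case / n_ctrl recorded
#' @export
simulate_outcome_sumstats <- function(panel, truth, seed,
                                      trait_id = "disease",
                                      max_batches = 2000L) {
  stopifnot(inherits(truth, "truth_table"),
            length(truth$gamma) == nrow(panel$variants))
  with_seed(seed, {
    m <- nrow(panel$variants)
    K <- truth$K
    thr <- stats::qnorm(1 - K)
    # scale gamma to the standardized-expression scale using the panel LD
    Sigma <- stats::cov(panel$dosages)
    vg <- as.numeric(truth$gamma %*% Sigma %*% truth$gamma)
    s <- if (truth$h2_expr > 0 && vg > 0) sqrt(truth$h2_expr / vg) else 0
    b_l <- logor_to_liability(truth$theta, K)
    a <- b_l * truth$gamma * s + truth$delta      # per-dosage liability effect
    var_gen <- as.numeric(a %*% Sigma %*% a)
    var_envx <- b_l^2 * (1 - truth$h2_expr)       # expression noise carried in
    sd_e <- sqrt(max(1 - var_gen - var_envx, 1e-6))
    mu_gen <- sum(2 * panel$gen$f * a)  # centre liability so prevalence is K

    need_case <- truth$n_case; need_ctrl <- truth$n_ctrl
    batch <- max(2000L, ceiling(need_case / max(K, 0.01)),
                 ceiling(need_ctrl / max(1 - K, 0.01)))
    Gc <- vector("list", 0L); Gt <- vector("list", 0L)
    got_case <- 0L; got_ctrl <- 0L; it <- 0L
    while ((got_case < need_case || got_ctrl < need_ctrl)) {
      it <- it + 1L
      if (it > max_batches)
        stop("rejection sampling exceeded ", max_batches,
             " batches; prevalence K = ", K,
             " is too extreme for the requested case count - reduce ",
             "n_case or use a less extreme K")
      G <- draw_cohort(panel, batch)
      l <- as.numeric(G %*% a) - mu_gen + b_l *
        stats::rnorm(batch, 0, sqrt(1 - truth$h2_expr)) +
        stats::rnorm(batch, 0, sd_e)
      case <- l > thr
      if (got_case < need_case && any(case)) {
        take <- utils::head(which(case), need_case - got_case)
        Gc[[length(Gc) + 1L]] <- G[take, , drop = FALSE]
        got_case <- got_case + length(take)
      }
      if (got_ctrl < need_ctrl && any(!case)) {
        take <- utils::head(which(!case), need_ctrl - got_ctrl)
        Gt[[length(Gt) + 1L]] <- G[take, , drop = FALSE]
        got_ctrl <- got_ctrl + length(take)
      }
    }
    G <- rbind(do.call(rbind, Gc), do.call(rbind, Gt))
    y <- rep(c(1, 0), c(need_case, need_ctrl))
    pbar <- need_case / (need_case + need_ctrl)
    gbar <- colMeans(G)
    U <- as.numeric(crossprod(G, y - pbar))
    I <- pbar * (1 - pbar) * (colSums(G^2) - nrow(G) * gbar^2)
    beta <- U / I
    se <- 1 / sqrt(I)
    p <- pmin(pmax(z_pvalue(beta, se), .Machine$double.xmin), 1)
    rec <- cbind(panel$variants,
                 data.frame(beta = beta, se = se, eaf = gbar / 2, p = p,
                            n = need_case + need_ctrl,
                            n_case = need_case, n_ctrl = need_ctrl))
    sumstats(rec, trait_id = trait_id, trait_role = "outcome",
             ancestry = panel$ancestry)
  })
}

#' Fast multivariate-normal z-score generator for a locus
#'
#' Draws marginal z-scores directly as `z ~ MVN(R z_joint, R)` where
#' `z_joint` is the joint (conditional) z implied by per-allele causal
#' effects `beta_joint`, bypassing individual-level simulation. Suited to
#' colocalization-scale experiments; sample sizes enter only through the
#' per-variant standard errors.
#'
#' @param panel `ref_panel`
#' @param beta_joint per-allele joint causal effects (length m, mostly 0)
#' @param n total sample size
#' @param trait_type "quantitative" or "case_control"
#' @param n_case,n_ctrl case-control split (required for "case_control")
#' @param seed integer seed
#' @param trait_id,trait_role,tissue metadata
#' @return `sumstats` object
#' @export
simulate_zscore_sumstats <- function(panel, beta_joint, n,
                                     trait_type = c("quantitative",
                                                    "case_control"),
                                     n_case = NULL, n_ctrl = NULL, seed = 1,
                                     trait_id = "trait",
                                     trait_role = "exposure", tissue = NULL) {
  trait_type <- match.arg(trait_type)
  m <- nrow(panel$variants)
  stopifnot(length(beta_joint) == m)
  f <- panel$eaf
  vg <- 2 * f * (1 - f)
  se <- if (trait_type == "quantitative") {
    1 / sqrt(vg * n)
  } else {
    stopifnot(!is.null(n_case), !is.null(n_ctrl))
    phi <- n_case / (n_case + n_ctrl)
    1 / sqrt(vg * (n_case + n_ctrl) * phi * (1 - phi))
  }
  R <- panel$ld
  L <- chol(R + diag(1e-6, m))
  with_seed(seed, {
    z <- as.numeric(R %*% (beta_joint / se) + crossprod(L, stats::rnorm(m)))
    rec <- cbind(panel$variants,
                 data.frame(beta = z * se, se = se, eaf = f,
                            p = pmin(pmax(z_pvalue(z, 1),
                                          .Machine$double.xmin), 1),
                            n = n))
    if (trait_type == "case_control") {
      rec$n_case <- n_case; rec$n_ctrl <- n_ctrl
    }
    sumstats(rec, trait_id = trait_id, trait_role = trait_role,
             ancestry = panel$ancestry, tissue = tissue)
  })
}

#' Simulate a complete multi-ancestry, multi-tissue study bundle
#'
#' Each gene gets its own cis locus (panels per ancestry share causal
#' architecture but have ancestry-specific allele frequencies and LD
#' draws). Tissues share, redraw or sign-flip the causal eQTL effects
#' according to `tissue_sharing`. One outcome table per ancestry
#' concatenates the per-locus case-control statistics.
#'
#' @param study list with components:
#'   * `ancestries`: named list; each element has `panel` (arguments for
#'     [panel_config()] except ancestry/seed/chrom/start), `n_exp`,
#'     `n_case`, `n_ctrl`
#'   * `genes`: data frame with `gene_id`, `theta`, and optionally
#'     `n_causal` (default 1) and `h2_expr` (default 0.1)
#'   * `tissues`: character vector of tissue labels (default "blood")
#'   * `tissue_sharing`: "shared", "independent" or "sign_flipped"
#'   * `K`: outcome prevalence (default 0.1)
#'   * `delta_sd`: SD of per-variant pleiotropic liability effects
#'     assigned to causal variants (default 0, none)
#' @param seed integer master seed; all per-gene / per-ancestry draws use
#'   reproducible child seeds
#' @param arch_seed seed governing the causal architecture and the
#'   reference panels (defaults to `seed`); supplying the discovery
#'   study's value with a fresh `seed` yields an independent replication
#'   cohort of the same population and architecture
#' @return object of class `study_bundle` with `panels[[ancestry]][[gene]]`,
#'   `exposures[[gene|ancestry|tissue]]`, `outcomes[[ancestry]]` (plus
#'   per-locus slices in `outcome_loci`), `truth[[gene]]`, and a gene
#'   `annotation` data frame
#' @export
simulate_study <- function(study, seed = 1, arch_seed = seed) {
  stopifnot(is.list(study$ancestries), length(study$ancestries) >= 1)
  genes <- study$genes
  stopifnot(is.data.frame(genes), all(c("gene_id", "theta") %in% names(genes)))
  if (is.null(genes$n_causal)) genes$n_causal <- 1L
  if (is.null(genes$h2_expr)) genes$h2_expr <- 0.1
  tissues <- study$tissues %||% "blood"
  sharing <- study$tissue_sharing %||% "shared"
  stopifnot(sharing %in% c("shared", "independent", "sign_flipped"))
  K <- study$K %||% 0.1
  delta_sd <- study$delta_sd %||% 0

  panels <- list(); exposures <- list(); outcome_loci <- list()
  truth <- list()
  anc_names <- names(study$ancestries)
  locus_gap <- 1e7   # loci far apart: independent draws are faithful
  annotation <- data.frame(gene_id = genes$gene_id, chrom = "1",
                           start = NA_real_, end = NA_real_,
                           tss = NA_real_, stringsAsFactors = FALSE)

  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene_id[gi]
    start_bp <- 1e6 + (gi - 1) * locus_gap
    # causal architecture shared across ancestries
    gene_arch_seed <- child_seed(arch_seed, "arch", g)
    first_panel <- study$ancestries[[1]]$panel
    m <- first_panel$m_variants %||% 50
    gam_by_tissue <- with_seed(gene_arch_seed, {
      idx <- sample.int(m, min(genes$n_causal[gi], m))
      base <- numeric(m)
      base[idx] <- stats::rnorm(length(idx), mean = 1, sd = 0.25) *
        sample(c(-1, 1), length(idx), replace = TRUE)
      out <- list()
      for (ti in seq_along(tissues)) {
        out[[tissues[ti]]] <- switch(sharing,
          shared = base,
          sign_flipped = if (ti == 1) base else -base,
          independent = {
            idx2 <- sample.int(m, min(genes$n_causal[gi], m))
            b2 <- numeric(m)
            b2[idx2] <- stats::rnorm(length(idx2), 1, 0.25) *
              sample(c(-1, 1), length(idx2), replace = TRUE)
            b2
          })
      }
      out
    })
    delta <- if (delta_sd > 0) {
      with_seed(child_seed(arch_seed, "delta", g),
                ifelse(gam_by_tissue[[1]] != 0,
                       stats::rnorm(m, 0, delta_sd), 0))
    } else numeric(m)

    tss <- start_bp + floor(m / 2) * (first_panel$spacing_bp %||% 2000)
    annotation$start[gi] <- start_bp
    annotation$end[gi] <- start_bp + (m - 1) * (first_panel$spacing_bp %||% 2000)
    annotation$tss[gi] <- tss

    for (anc in anc_names) {
      acfg <- study$ancestries[[anc]]
      pc_args <- acfg$panel %||% list()
      pc <- do.call(panel_config, utils::modifyList(
        list(ancestry = anc, seed = child_seed(arch_seed, "panel", g, anc),
             chrom = "1", start_bp = start_bp),
        pc_args))
      stopifnot(pc$m_variants == m)
      panel <- simulate_reference_panel(pc)
      panels[[anc]][[g]] <- panel
      for (tis in tissues) {
        key <- paste(g, anc, tis, sep = "|")
        exposures[[key]] <- simulate_expression_sumstats(
          panel, gam_by_tissue[[tis]], genes$h2_expr[gi],
          acfg$n_exp %||% 5000,
          seed = child_seed(seed, "expr", g, anc, tis),
          trait_id = g, tissue = tis)
      }
      tt <- truth_table(gamma = gam_by_tissue[[1]], theta = genes$theta[gi],
                        delta = delta, h2_expr = genes$h2_expr[gi], K = K,
                        n_exp = acfg$n_exp %||% 5000,
                        n_case = acfg$n_case %||% 5000,
                        n_ctrl = acfg$n_ctrl %||% 5000)
      outcome_loci[[anc]][[g]] <- simulate_outcome_sumstats(
        panel, tt, seed = child_seed(seed, "outcome", g, anc))
      if (anc == anc_names[1]) truth[[g]] <- tt
    }
  }
  outcomes <- lapply(anc_names, function(anc) {
    rec <- do.call(rbind, lapply(outcome_loci[[anc]],
                                 function(s) s$records))
    sumstats(rec, trait_id = "disease", trait_role = "outcome",
             ancestry = anc)
  })
  names(outcomes) <- anc_names
  structure(list(panels = panels, exposures = exposures,
                 outcomes = outcomes, outcome_loci = outcome_loci,
                 truth = truth, annotation = annotation,
                 tissues = tissues, ancestries = anc_names),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0("<study_bundle> %d genes x %d ancestries x %d",
                     " tissues (%d exposure tables)\n"),
              length(x$truth), length(x$ancestries), length(x$tissues),
              length(x$exposures)))
  invisible(x)
}
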