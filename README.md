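# mrcascade

Ancestry- and tissue-aware two-sample Mendelian randomization (MR) for
molecular exposures — gene expression and protein abundance instrumented
by *cis*-QTLs — against a binary disease outcome, with the full evidence
cascade a modern *cis*-MR study runs: instrument selection, sensitivity
analyses, colocalization, replication, cross-ancestry meta-analysis, and
power calculations. It is written for statistical geneticists and
epidemiologists who work from GWAS/QTL summary statistics and want every
stage of that cascade as a tested, reusable R function rather than a
one-off script.

## What it computes

For each molecular trait, instruments are *cis* variants passing the
study significance threshold, LD-clumped (greedy by p-value, r² ≤ 0.001
within a 10 Mb window), proxied into the outcome data when absent
(r² > 0.8), and required to have F = β²/se² > 10. After allele
harmonization, the headline causal estimate is the Wald ratio
β_Y/β_X for a single instrument or inverse-variance-weighted (IVW)
regression through the origin otherwise:

    β_IVW = Σ β_X β_Y / se_Y²  /  Σ β_X² / se_Y² .

A trait is called **causal** when all applicable criteria hold:

1. FDR-corrected IVW/Wald q < 0.05 (BH within each cohort stratum);
2. sign-concordant estimates across weighted median, MR-Egger,
   MR-PRESSO (outlier-corrected when its distortion test has P < 0.05)
   and Steiger-filtered IVW (liability scale, prevalence K = 0.10);
3. Cochran's I² < 50% and no significant Egger intercept;
4. colocalization PPH4 > 0.8, via approximate-Bayes-factor coloc
   extended with pairwise conditional analysis (conditioning out
   secondary signals identified by stepwise approximate conditional
   selection from reference LD) whenever the marginal PPH4 < 0.8.

Criteria 2–3 are skipped (not failed) for single-instrument traits.
Traits tested in ≥ 2 ancestries are pooled with DerSimonian–Laird
random-effects IVW; binary-outcome power and the minimal detectable OR
follow the standard non-centrality-parameter calculation
NCP = b_MR²/var(b_MR) with b_MR = K(OR/(1+K(OR−1)) − 1). Post-analysis
helpers cover tissue-expression filtering (median TPM > 0.1), Fisher
gene-set and tissue-cluster enrichment, tissue overlap/heterogeneity
summaries, and locus-overlap grouping.

Because real QTL and GWAS resources cannot ship with a package, a
first-class synthetic-data module generates multi-ancestry reference
panels (latent AR(1) Gaussian-copula genotypes), *cis*-eQTL exposure
statistics with known heritability, and liability-threshold case-control
outcome statistics with a known causal log-OR — so every stage is
testable against ground truth.

## Worked example

Simulate a two-ancestry blood study of four genes — true ORs per 1 SD of
expression of 1.4, 0.75, 1, 1 — then run the cascade and meta-analysis:

```r
library(mrcascade)

study <- list(
  ancestries = list(
    EUR = list(panel = list(m_variants = 20, n_ref = 400,
                            maf_range = c(0.1, 0.5), ld_rho = 0.4),
               n_exp = 8000, n_case = 6000, n_ctrl = 6000),
    AFR = list(panel = list(m_variants = 20, n_ref = 400,
                            maf_range = c(0.05, 0.5), ld_rho = 0.4),
               n_exp = 5000, n_case = 4000, n_ctrl = 4000)),
  genes = data.frame(gene_id = c("GENE1", "GENE2", "GENE3", "GENE4"),
                     theta = c(log(1.4), log(0.75), 0, 0),
                     n_causal = 2, h2_expr = 0.15),
  K = 0.1)
bundle <- simulate_study(study, seed = 42)
res <- run_mr_cascade(bundle, cfg = iv_config(qtl_sig_threshold = 5e-8),
                      seed = 1)
res$decisions[, c("trait_id", "ancestry", "n_iv", "estimate", "q",
                  "crit_het_pleio", "crit_coloc", "causal")]
```

```
  trait_id ancestry n_iv estimate        q crit_het_pleio crit_coloc causal
1    GENE1      EUR    1  0.37206 1.76e-13             NA       TRUE   TRUE
2    GENE1      AFR    2  0.29795 1.44e-05          FALSE       TRUE  FALSE
3    GENE2      EUR    2 -0.32044 5.85e-12          FALSE       TRUE  FALSE
4    GENE2      AFR    2 -0.21700 4.60e-04          FALSE       TRUE  FALSE
5    GENE3      EUR    1 -0.00485 9.63e-01             NA      FALSE  FALSE
6    GENE3      AFR    2  0.00224 9.69e-01           TRUE      FALSE  FALSE
7    GENE4      EUR    2  0.00218 9.63e-01           TRUE      FALSE  FALSE
8    GENE4      AFR    2 -0.05194 6.38e-01           TRUE      FALSE  FALSE
```

GENE1 in EUR is called causal: its single instrument gives
OR = exp(0.372) ≈ 1.45 (truth 1.4), q ≈ 2 × 10⁻¹³, and the locus
colocalizes (PPH4 = 1.00). The null genes colocalize nowhere and are
never called. GENE2 illustrates the cascade's conservatism: both
ancestries are FDR-significant with the right sign, but with only two
instruments the between-ratio I² lands above 50% and criterion 3 fails —
a decision the decision table makes auditable rather than silent.
Pooling ancestries:

```r
meta_across_ancestries(res$decisions)
```

```
  trait_id k estimate     se        q   Q_p significant
1    GENE1 2  0.34464 0.0391 5.03e-18 0.360        TRUE
2    GENE2 2 -0.27531 0.0513 1.60e-07 0.166       FALSE
3    GENE3 2 -0.00117 0.0413 9.77e-01 0.932       FALSE
4    GENE4 2 -0.01364 0.0397 9.74e-01 0.535       FALSE
```

The pooled GENE1 effect (OR ≈ 1.41) is meta-significant — q < 0.05 with
compelling single-cohort evidence — and shows no ancestry heterogeneity
(Cochran's Q_p = 0.36). Finally, the smallest OR detectable at 80% power
for a trait whose two instruments explain R² ≈ 0.055 of expression in an
outcome study of N = 12,000 at prevalence 10%:

```r
mde(power_params(K = 0.1, N = 12000, R2 = iv_r2(c(0.3, 0.2), c(0.25, 0.3))))
#> <power_result> MDE OR = 1.3747 (protective 0.6514) at power 80%,
#>                K=0.1, N=12000, R2=0.0551
```

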