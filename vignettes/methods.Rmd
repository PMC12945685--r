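---
title: "Methods: the cis-QTL MR evidence cascade in mrcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cis-QTL MR evidence cascade in mrcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind every stage of the
package, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate,
and the design decisions that were genuinely open.

## The causal model and its assumptions

Two-sample MR treats genetic variants as instruments for a molecular
exposure (gene expression or protein abundance, standardized to unit
variance) and asks whether genetically predicted exposure shifts the
risk of a binary disease outcome. Validity rests on the three classical
instrumental-variable assumptions: relevance (the variant predicts the
exposure — testable, enforced here as F = β²/se² strictly greater than
10), independence (no confounding of the variant–outcome relation) and
exclusion restriction (no effect on the outcome except through the
exposure). The last two are untestable; the package therefore surrounds
the point estimate with a sensitivity suite (weighted median, MR-Egger,
MR-PRESSO, Steiger filtering) and requires colocalization of the
exposure and outcome association signals, which guards against the
common failure mode where the instrument tags a nearby causal variant
acting through another pathway.

Estimates are log-ORs per 1 SD of genetically predicted exposure. The
Wald ratio uses the first-order delta-method SE (se_Y/|β_X|); with
F > 10 the neglected second-order term is below ~10% of the variance,
the standard trade-off in summary-data MR. IVW is the fixed-effect
weighted regression through the origin; a multiplicative
random-effects SE inflation is available (`scale_se = TRUE`) but off by
default, because the headline significance criterion refers to plain
IVW. MR-Egger orients all β_X positive (a convention the estimators
need but the literature rarely states), uses weights 1/se_Y², reports
t-based p-values on n−2 degrees of freedom, and floors its
multiplicative overdispersion scale at 1 so that under-dispersed sets
are not anti-conservative.

## Instrument selection

Defaults in `iv_config()`: cis window ±1 Mb of the TSS (overridable per
study, since QTL studies define their own windows), exposure
significance 5 × 10⁻⁸, clumping r² ≤ 0.001 in a 10 Mb window, proxy
r² > 0.8, F > 10, palindromic-variant frequency limit 0.42. Clumping is
greedy by ascending p with ties broken by position then id, so
selection is invariant to input row order. The clumping window is
interpreted as ±5 Mb around the index variant; the alternative (±10 Mb)
is configurable, as tool conventions differ. Proxy search is confined
to the same window and re-anchors the exposure effect to the proxy's
own exposure record, so the harmonized pair stays internally
consistent.

Harmonization flips the outcome effect and frequency when the outcome
effect allele matches the exposure other allele, on either the reported
or the complementary strand. Palindromic (A/T, C/G) variants cannot be
strand-resolved from labels; strand is inferred from allele-frequency
concordance and the variant is dropped when either minor-allele
frequency exceeds 0.42 or a frequency is missing. The 0.42 limit is a
declared stand-in for upstream tools' "default parameters", not a claim
about any particular study's run, and is configurable.

## Sensitivity cascade

MR-PRESSO simulates the weighted residual sum of squares around
leave-one-out IVW predictions (default 1,000 parametric simulations,
seeded); outliers are variants whose Bonferroni-corrected simulation
p-value falls below 0.05; the outlier-corrected IVW replaces the raw
estimate only when the distortion test — observed shift versus shifts
from removing random subsets of the same size — has P < 0.05. Steiger
filtering drops variants explaining more variance in the outcome
liability than in the exposure; the outcome side converts the logistic
log-OR to the liability scale via the observed-scale slope
β·P(1−P) and the prevalence transformation K²(1−K)²/(P(1−P)z²) at
K = 0.10 (the package-wide default prevalence), validated in the test
suite against a brute-force latent-variable simulation. Raising K
toward 0.5 weakly raises the liability-scale r², making the filter
monotone in prevalence.

"Concordant sensitivity analyses" is implemented as sign agreement of
every applicable sensitivity estimate with IVW — the weakest defensible
reading of concordance — with a CI-overlap alternative available.
Likewise, the heterogeneity/pleiotropy criterion requires I² < 50 *and*
an Egger intercept p ≥ 0.05; the grammar of the usual prose
("no significant heterogeneity and pleiotropy") is ambiguous, so the
comparator is explicit and configurable. Single-instrument traits
cannot be probed by any of these methods; the cascade records their
criteria as not-applicable and excludes them from the conjunction
rather than failing them, since most *cis* traits are instrumented by
exactly one QTL and would otherwise be untestable by construction.

## Colocalization

`abf_coloc()` computes per-variant Wakefield log approximate Bayes
factors with prior effect SDs 0.20 (quantitative) and 0.15 (log-OR
scale), priors p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵ — the field's standard
defaults, recorded in output because they are genuinely assumptions.
The H3 (distinct causal variants) term is summed directly over all
ordered variant pairs in log space: the algebraically equivalent
shortcut exp(s1+s2) − exp(s12) cancels catastrophically when a shared
signal dominates, and the direct sum keeps log-posteriors accurate to
better than 10⁻⁸ (verified against an independent enumeration oracle).

Multi-signal loci are handled by pairwise conditional analysis:
stepwise selection of independent signals from marginal statistics plus
reference LD (thresholds 10⁻⁵ on the QTL side and 5 × 10⁻⁸ on the GWAS
side, collinearity r² < 0.9, at most 10 signals), conditioning each
side on its other leads, and re-running coloc on every conditioned and
conditioned-versus-marginal combination. Conditioning works on the
standardized scale (marginal z/√n), fits the conditioning set jointly,
and residualizes the remaining variants; it refuses conditioning sets
whose LD submatrix has condition number above 10⁸. The conditional step
runs only when the marginal PPH4 is below 0.8, and the reported
`max_pph4` is the maximum over all tested pairs, so it can never fall
below the marginal value. The reference panel is an explicit
per-ancestry argument precisely because LD mismatch between QTL and
GWAS populations is a known cause of spurious non-colocalization.

## Cascade, replication, meta-analysis

FDR correction is BH within each (cohort × tissue) stratum. All
comparators are strict: q < 0.05, I² < 50, PPH4 > 0.8, TPM > 0.1,
F > 10, proxy r² > 0.8. Replication applies BH over exactly the
discovery-causal traits testable in the replication data and requires
direction concordance. The five-criterion ladder (all tested → nominal
p → q < 0.05 → + sensitivity/heterogeneity → + colocalization) treats
not-applicable criteria as skipped, and splits its last row by single-
versus multi-instrument traits.

Cross-ancestry pooling uses random-effects IVW with the closed-form
DerSimonian–Laird τ² by default (exactly testable against hand
computation); REML via `metafor` is available since reference
implementations default to it. One property worth knowing: with k = 2
cohorts, Q follows a χ²₁ under homogeneity, τ̂² > 0 whenever Q > 1, and
the pooled SE exceeds the smaller input SE whenever (for equal inputs)
Q > 2 — about 16% of homogeneous replicates. A random-effects pooled
interval is therefore *not* uniformly narrower than the best single
cohort; this is intrinsic to estimating a between-study variance from
two points, not an implementation artifact, and the test suite
documents it.

## Power and the minimal detectable effect

Power uses NCP = b_MR²/var(b_MR) with b_MR = K(OR/(1+K(OR−1)) − 1) and
a 1-df noncentral chi-square test at α = 0.05 (the test size is not
standardized in the literature for such calculations; 0.05 is the
declared default). Two printed-formula variants circulating for this
calculation do not survive dimensional analysis and are implemented
only behind flags, never silently:

* var(b_MR) as the *product* K(1−K)·b_MR²/(N·R²) makes the NCP
  independent of OR — b_MR² cancels — so no MDE exists;
  `var_form = "difference"` (the default) uses
  (K(1−K) − b_MR²)/(N·R²), which matches a Monte-Carlo Wald-test oracle
  within 0.03 across the tested grid.
* R² as Σ2·MAF(1−MAF)·b without the square can be negative;
  `squared = FALSE` reproduces it for reference only.

The MDE is found by bisection to 10⁻⁶ in OR on both the risk
(OR > 1) and protective (OR < 1) sides. Because var(b_MR) shrinks to
zero as |b_MR| approaches its prevalence bound √(K(1−K)), the power
curve always reaches 1 at a finite OR; an unreachable target can only
arise from a restricted search ceiling, and is reported as
not-applicable rather than extrapolated.

## The synthetic-data generator

The generator is individual-level so that marginal statistics, LD and
case-control ascertainment stay mutually consistent. Genotypes are
unphased dosages from two latent AR(1) Gaussian-copula haplotypes under
Hardy–Weinberg equilibrium; allele frequencies are drawn uniformly from
a configurable range per ancestry (different ranges emulate
ancestry-restricted instruments). Expression is y = (Gγ)s + ε with s
set so the cis-genetic variance equals h² (default 0.1, a typical
strong cis signal) and total variance 1. The outcome is a liability
threshold model at prevalence K = 0.10: liability combines the full
expression phenotype (genetic and environmental parts) scaled by the
liability slope matching a marginal log-OR of θ per SD of expression,
optional per-variant direct (pleiotropic) effects, and residual noise
normalized to unit total variance; the genetic contribution is centred
so the realized prevalence equals K — without centring, the threshold
shifts and the recovered log-OR attenuates by several percent. Cases
and controls are accumulated by rejection sampling (with an iteration
cap), and per-variant log-ORs use a one-step score approximation to
logistic regression, which the tests show is indistinguishable from the
full fit at these effect sizes. A fast z-score generator
(z ~ MVN(R·λ, R)) serves colocalization-scale experiments where
individual-level realism is unnecessary.

What the generator does *not* emulate: realistic human LD maps
(AR(1) is a caricature with tunable decay), imputation error,
relatedness, admixture, genotyping batch effects, winner's-curse
selection of instruments from the same data, or sample overlap between
exposure and outcome studies. Generated studies also produce
strand-unambiguous variants only; palindromic handling is exercised by
direct unit tests instead. Passing tests on synthetic data therefore
establish internal statistical correctness — estimator calibration,
type-I control, recovery of known effects — not robustness to every
artefact of real cohort data.

Simulated loci are placed 10 Mb apart and outcome statistics are drawn
per locus from independent cohort draws; for the small per-locus
effects simulated here this matches a single shared cohort to first
order while keeping generation fast. All randomness flows from one
integer master seed through deterministic child seeds per gene,
ancestry, tissue and stage; no global RNG state leaks between stages.

## Problem sizes in the test suite

The simulation-backed tests use study sizes chosen to give each check
high power while keeping the whole suite comfortably re-runnable on a
laptop: null type-I control over 200 genes × 2 ancestries; parameter
recovery over 200 replicates of 10 instruments with 20,000 cases and
controls; 50-replicate colocalization scenarios at 60-variant loci; and
oracle-equivalence sweeps of 100–1,000 random inputs. These sizes are
the package's own validation design, and the tolerances in the tests
(binomial bounds, KS distances, 10⁻⁸–10⁻¹² numeric agreement) are
stated alongside each check.

## Known limitations

Beyond the generator's simplifications above: multivariable MR,
mode-based and robust IVW estimators, SuSiE-style colocalization,
trans-QTL instruments and genome-build liftover are out of scope;
conditional estimates inherit the usual fragility of summary-based
conditioning when panel LD mismatches the study cohort; and the
liability-to-log-OR mapping is first-order, so generated marginal
log-ORs deviate from θ by O(θ²) terms — negligible at the OR ≤ 1.5
range the package targets but visible for very large effects.
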