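---
title: "Testing pleiotropy vs. separate QTL: model, algorithms and design choices"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing pleiotropy vs. separate QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

# The question and the model

Two traits measured on the same multiparental population both map to one
genomic region.  Is a single locus responsible for both (pleiotropy), or are
there two distinct, linked loci?  `pleioscan` answers this with a likelihood
ratio test between

* H0: the two trait-specific QTL positions coincide, λ1 = λ2, and
* HA: they differ, λ1 ≠ λ2,

within a user-chosen interval.  Restricting attention to an interval keeps the
two-dimensional search tractable and matches how the question arises in
practice: the interval is chosen where univariate scans of both traits already
show peaks.

## Data structures

Four aligned objects enter the analysis:

* an n × k × m array of **founder-allele probabilities** for the chromosome
  under test (`alleleprob`): for each subject and marker, the probability of
  carrying each of the k founder alleles.  Rows sum to one.  These are the
  standard output of hidden-Markov-model genotype reconstruction in
  multiparental populations; this package consumes them precomputed (or
  synthesizes them — see below) and deliberately does not implement the HMM;
* an n × 2 **trait pair** (`trait_pair`);
* an optional n × c **covariate matrix**;
* an n × n **kinship matrix**, by preference leave-one-chromosome-out (LOCO):
  computed from all chromosomes except the one being scanned, so the polygenic
  term does not absorb the very signal under test.

`align_inputs()` restricts everything to the common subjects
(complete cases only, no imputation; the genotype object's order wins), and
`calc_kinship_loco()` computes kinship as the average over markers of the
founder-probability inner product Σₐ p(i,a,j)·p(i′,a,j).  The kinship
estimator is not uniquely pinned down by the methodology this package
implements; the allele-probability cross-product is the convention used
throughout this ecosystem.  Note the scale of the estimated genetic covariance
Vg depends on this choice; a `normalize` switch (off by default) rescales to
unit mean diagonal.

## The bivariate mixed model

With Y the n × 2 phenotype matrix,

$$\mathrm{vec}(Y) = X\,\mathrm{vec}(B) + \mathrm{vec}(G) + \mathrm{vec}(E),
\qquad G \sim MN(0, K, V_g),\quad E \sim MN(0, I_n, V_e),$$

so the stacked trait vector is Gaussian with covariance
$\Sigma = V_g \otimes K + V_e \otimes I_n$ (column-major stacking: the first
n entries are trait 1).  X is block diagonal with one block per trait.  In a
two-QTL fit the trait-t block is `[allele probabilities at the trait-t QTL |
covariates]`; in the no-QTL null it is `[1 | covariates]`.

**Intercept rule.**  Because the k allele dosages sum to one, an intercept
column alongside them is exactly collinear.  Each trait block therefore drops
the intercept whenever allele columns are present and keeps it in the null
design.  This preserves full column rank without dropping an allele column,
keeps allele effects interpretable as founder means, and makes the null model
strictly nested in every scanned model.

## Parameter inference

Joint maximization over (B, Vg, Ve, λ1, λ2) would be prohibitively expensive,
so the variance components are estimated **once**, by REML under the no-QTL
null, and held fixed throughout the scan.  Estimation uses an
expectation-maximization algorithm on the restricted likelihood, run in the
eigenbasis of K: with K = U D Uᵀ and all data rotated by Uᵀ, Σ becomes block
diagonal with per-subject 2 × 2 blocks dᵢVg + Ve, and each EM iteration costs
O(n).  The E-step needs only the per-subject diagonal blocks of the REML
projection P = Σ⁻¹ − Σ⁻¹X(XᵀΣ⁻¹X)⁻¹XᵀΣ⁻¹, and the M-step is

$$V_g \leftarrow V_g + V_g\Big[\tfrac1n\textstyle\sum_i d_i(t_it_i^\top - P_{ii})\Big]V_g,
\qquad t = Py,$$

and analogously for Ve without the dᵢ weight.  This is a genuine EM, so the
restricted log-likelihood never decreases — a property the test suite asserts
on every fit it runs.

Numerical choices, all configurable:

* **Initialization**: Vg = Ve = half the residual covariance of an ordinary
  covariates-only regression — symmetric and on the right scale.
* **Convergence**: relative change in restricted log-likelihood below 1e-6,
  cap of 10,000 iterations; non-convergence returns the last iterate with a
  warning flag rather than an error.
* **PSD floor**: after every M-step the eigenvalues of Vg and Ve are clamped
  at 1e-8, so iterates remain symmetric positive semidefinite even when the
  truth sits on the boundary (e.g. no genetic covariance).
* **Degenerate kinship**: if all eigenvalues of K are equal (K ∝ I), Vg and
  Ve enter the likelihood only through dᵢVg + Ve and are not separately
  identifiable; the fit warns.
* **Likelihoods are stored in log10** (LOD units); natural logs are used
  internally and converted once.

Two ambiguities had to be resolved by decision.  First, the scan evaluates
the **ordinary (ML) Gaussian likelihood** of vec(Y) at the GLS estimate
B̂ with Σ̂ fixed — not the restricted likelihood — since the statistic
compares fits with different fixed-effect designs, for which REML likelihoods
are not comparable.  Second, phenotypes are analyzed **as given**: no
standardization is applied by default (a per-trait z-scaling flag exists),
because the test statistic is invariant to separate linear rescalings of the
traits under both hypotheses.

## The scan, the statistic and the traces

`scan_pvl()` fits, for every ordered pair (λ1, λ2) of markers in the interval,
the two-QTL model by GLS at the fixed Σ̂ and records the log10 likelihood
ll10(λ1, λ2).  The scan grid consists of the observed markers only — no
pseudomarker insertion (interval endpoints inclusive); argmax ties break to
the first index in map order.  The test statistic is

$$\mathrm{LOD} = \max_{\lambda_1,\lambda_2} \mathrm{ll10}(\lambda_1,\lambda_2)
 - \max_{\lambda} \mathrm{ll10}(\lambda,\lambda) \ \ge 0 .$$

For visualization, `profile_traces()` reports
profile1(λ1) = maxλ2 ll10(λ1, λ2) − maxdiag, the analogous profile2, and the
pleiotropy trace ll10(λ, λ) − maxdiag.  By construction the two profile
traces share the LOD as their common maximum and the pleiotropy trace peaks at
exactly zero; the tests assert these identities on random grids and on full
scans.

Computationally, the rotation reduces each grid cell to a weighted GLS with
per-subject 2 × 2 weights; all m² cells share three weighted cross-product
matrices over the full marker set, so a 7-marker scan at n = 150 takes well
under a millisecond.  The compiled path is verified against a dense
2n × 2n brute-force implementation (explicit Σ, explicit GLS, explicit
Gaussian density) to 1e-6 in log10-likelihood and 1e-8 relative in B̂ on
dozens of random instances.

## Parametric bootstrap

The null distribution of the LOD is not chi-square: the statistic involves a
two-dimensional search over positions.  `boot_pvl()` therefore:

1. estimates Σ̂ under the no-QTL null;
2. scans and records the observed LOD;
3. finds the pleiotropic peak λ̂ (the diagonal argmax) and refits the full
   effect matrix B̂ (alleles and covariates) there;
4. simulates b trait pairs Y* = X vec(B̂) + G* + E* from the fitted
   pleiotropic model, and for each re-estimates the variance components and
   rescans;
5. reports p = #{LOD*ᵢ ≥ LOD} / b — the plain proportion, which can be 0,
   exactly matching the estimator's definition (no (1+#)/(1+b) correction).

Per-replicate variance-component **re-estimation is the default** (each
bootstrap data set undergoes the same analysis as the original); a
`reuse_varcomp` switch reuses the original Σ̂ for speed.  Replicate EM fits
are warm-started at the observed-data estimates, which changes only the
iteration count, never the optimum.  The full fitted B̂ at λ̂ — covariate
effects included — is reused when simulating, since the bootstrap should
mimic the fitted null completely.  A master seed spawns one child seed per
replicate, so parallel and serial execution produce identical results, and a
failed replicate aborts the run rather than being silently dropped.

## Synthetic genomes

`generate_genome()` produces the founder-haplotype mosaics the rest of the
package consumes: per subject and chromosome, founder labels follow a Markov
process with exponentially distributed segment lengths of mean
100/(crossover_rate × mosaic_generations) cM, a new founder drawn uniformly
from the other k − 1 at each breakpoint.  Allele probabilities place
`certainty` on the true founder and spread the rest uniformly.  Defaults:
8 founders, crossover_rate 1 per Morgan per meiosis-equivalent,
23 meiosis-equivalents (mean segment ≈ 4.3 cM, typical of a mature outbred
mouse population), certainty 0.95 (high-confidence HMM reconstructions),
2 chromosomes of 60 cM × 61 markers.  Mosaics are haploid-equivalent — one
founder label per position rather than a diplotype pair — because the test
consumes n × k allele dosages; diploid bookkeeping would add nothing to the
statistics being exercised.

What the generator does **not** emulate: real pedigree structure (so kinship
is closer to exchangeable than in a true breeding design), linkage
disequilibrium between founders, genotyping-error patterns, non-uniform
founder frequencies, and X-chromosome inheritance.  Passing tests on these
genomes therefore demonstrates the statistical machinery is correct and
calibrated under the stated model, not that real-data error rates will match
any particular published figure — reproducing those exactly would require the
original mouse genotypes.

## Simulation studies

Two factorial experiments mirror the standard calibration analyses for this
test, at desk scale (defaults n = 150 subjects, 100 simulations per cell,
b = 100 bootstrap replicates; the original studies used 400/400 on 479 mice,
available via the same knobs):

* **Type-I error** (`run_type1_study()`): a 2³ design over allele-effect
  difference (6, 12), allele partition (ABCD:EFGH even split vs. a private
  allele in founder F) and genetic correlation (0, 0.6).  Traits are simulated
  pleiotropically at the central marker of the interval with unit marginal
  genetic variances and Ve = I; each pair goes through the full
  scan-plus-bootstrap test; the rejection proportion at nominal 0.05 is
  reported with its binomial standard error.
* **Power** (`run_power_study()`): a 2 × 2 × 5 design over effect difference
  (1, 2), partition, and interlocus distance (0, 0.5, 1, 2, 3 cM), with
  Vg = Ve = I.  For positive distances the b × n_sim bootstrap statistics of
  a cell follow approximately one distribution, so they are pooled into a
  single empirical null and every simulated LOD is compared to its upper 5%
  tail; at distance 0 (where "power" is a type-I error rate) scoring is
  per-replicate, exactly as in the type-I study.

The study genome uses 2 chromosomes of 20 cM with 0.5 cM marker spacing — the
smallest structure that supports LOCO kinship, a 7–9-marker scan interval and
the 0–3 cM distance grid.  Scan intervals default to 3 cM (type I, QTL at the
central marker) and 4 cM (power, trait-1 QTL at the first interval marker).
Cell-level seeds are derived deterministically from the master seed and the
cell's factor levels, so results are invariant to which cells are run and in
what order.  Expected qualitative behavior, asserted by the acceptance tests:
rejection at or below nominal under pleiotropy; power nondecreasing in
distance; even allele partition dominating the private-allele partition.

The package's acceptance script (`scripts/acceptance.R`) re-runs one type-I
cell (difference 6, even partition, zero genetic correlation) from scratch and
reports the empirical rejection rate; the heavier two-cell and full power
checks live in the test suite.  At these replicate counts the binomial SE of
a 5% rate is about 2.2 percentage points, which is why all comparisons carry
two-SE slack.

## Known limitations

* Two traits only; partially pleiotropic topologies with more than two QTL
  and model selection among them are out of scope.
* Additive allele effects; dominance design matrices are not built.
* Marker-grid scans only (no pseudomarkers), cM coordinates only.
* The LOD's null distribution is estimated per data set by bootstrap;
  there is deliberately no asymptotic (chi-square) p-value.
* EM-REML convergence is linear, and near boundary optima (a genetic
  covariance at or near zero) the restricted likelihood is almost flat while
  the iterates still move, so the default likelihood-change stopping rule can
  leave Vg a little above its converged value; tighten `tol` (e.g. 1e-8) when
  the variance-component estimates themselves are the quantity of interest.
  Pathological cases return the last iterate with a warning rather than
  iterating indefinitely.

## A complete run

```{r example, eval = FALSE}
g <- generate_genome(genome_spec(n_subjects = 150,
        chromosomes = chrom_table(c("1", "2"), c(20, 20), c(41, 41))),
        seed = 42)
probs <- g$probs[["1"]]; kin <- g$kinship[["1"]]

eff <- make_effects(2, "ABCD:EFGH")
yy <- sim_trait_pair(probs, marker1 = 18, marker2 = 22, effects = eff,
                     varcomp = var_comp(diag(2), diag(2)), kin = kin, seed = 42)

sc <- scan_pvl(probs, yy, kin = kin, interval = c(8, 12))
summary(sc)
plot(sc)
boot_pvl(probs, yy, kin = kin, interval = c(8, 12), b = 100, seed = 42)
```
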