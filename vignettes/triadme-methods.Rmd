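---
title: "Methods: gene-methylation and parent-of-origin-methylation interactions in case-parent triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-methylation and parent-of-origin-methylation interactions in case-parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadme)
library(dplyr)
```

## The problem

A standard family-based association analysis estimates the relative risk
(RR) that a child's copy of a SNP's variant allele confers for a
dichotomous, early-onset outcome, using case-parent triads (affected
child plus both parents) or parent-child dyads. DNA methylation near the
SNP can plausibly modify that risk — for example when methylation of a
promoter changes the expression of the gene the SNP sits in. `triadme`
tests for two kinds of such modification:

* **G×Me** — the child-allele relative risk changes across strata of
  nearby region-averaged methylation;
* **PoO×Me** — the *parent-of-origin* effect, quantified as the
  relative-risk ratio RRR = RR~M~/RR~F~ between a maternally and a
  paternally inherited variant allele, changes across methylation strata.
  An RRR ≠ 1 is the classic statistical signature of imprinting-like
  behaviour.

## Penetrance model

Write $C_{ij} = A_iA_j$ for the ordered child genotype, with allele
$A_i$ inherited from the mother and $A_j$ from the father, and let
$Me = m$ index the methylation stratum of the child (tertiles by
default). The penetrance is modelled multiplicatively:

$$P(D \mid C_{ij}, Me = m) = B^{(m)} \cdot RR_{M,i}^{(m)} \cdot RR_{F,j}^{(m)},$$

with the reference allele fixed at $RR_{M,1}^{(m)} = RR_{F,1}^{(m)} = 1$.
Under the **gene-dose** model the maternal and paternal RRs are equal, so
the risk factor depends only on the variant-allele dose, with the
double-dose RR equal to the square of the single-dose RR
(a free double-dose parameter is available via `dose = "free"`). Under
the **poo** model, $RR_M$ and $RR_F$ are free and the contrast
$\log RRR = \log RR_M - \log RR_F$ is the parameter of interest.

The baseline $B^{(m)}$ absorbs the disease prevalence and is not
identifiable from case-only data; it cancels from every likelihood the
package fits and is never reported.

## Likelihoods

**Complete triads.** Among case triads, the joint cell probability
factorises into the population mating-type distribution $P(M,F)$, the
Mendelian transmission $P(C \mid M, F)$ and the penetrance. Conditioning
on the parental mating type removes $P(M,F)$ and $B^{(m)}$ entirely, so
`fit_stratum()` maximises the multinomial likelihood of the unordered
child genotype within each mating type. This makes the RR estimates
robust to arbitrary population structure in the parental genotypes — a
property exercised in the test suite with a deliberately non-Hardy-
Weinberg, correlated mating distribution. The heterozygous child of two
heterozygous parents cannot be oriented; it is kept as a single
ambiguous cell whose probability is the sum of its two ordered
constituents (weights from Mendelian transmission), never split.

**Dyads.** When one parent is missing, the mating type cannot be
conditioned on. `fit_dyads_em()` maximises the observed-data likelihood
under Hardy-Weinberg equilibrium and random mating, with the variant
allele frequency estimated jointly. The E-step distributes each family
over the ordered (mother, father, child) cells compatible with its
observed genotypes; the M-step is a weighted multinomial fit by
quasi-Newton on the log parameters plus the logit allele frequency. The
observed log-likelihood is checked to be non-decreasing at every
iteration (tolerance `1e-8`, at most 500 iterations); any decrease is
flagged `em_failure` rather than ignored. The covariance matrix comes
from the numerical Hessian of the observed-data log-likelihood, so dyad
standard errors correctly reflect the information lost with the missing
parent.

**Numerical choices.** Fits run on the log-RR scale, starting from 0
(RR = 1), with BFGS followed by Newton polishing until the gradient
infinity-norm is below 1e-6 where the curvature allows it; `converged`
is reported honestly otherwise. Estimates with $|\log RR| \ge 10$ are
flagged as boundary cases (essentially monomorphic data). No continuity
corrections are applied; instead, any fit with an informative expected
cell count below 5 is flagged `"unstable"` and the flag is propagated
into the interaction result.

## From raw methylation to strata

The region pipeline follows the summarise-then-stratify design:

1. `beta_from_intensities()` computes $\beta = I_M / (I_M + I_U + 100)$,
   the standard array methylation fraction with the +100 guard against
   empty probes.
2. `select_cpgs_near_snp()` keeps CpGs within 50 kb of the SNP
   (inclusive boundary — the convention is fixed here for
   reproducibility; coordinates are 1-based throughout, with strict BED
   input converted at the boundary by `read_regions()`).
3. `classify_cpgs()` assigns each CpG to every region category
   (promoter, enhancer, gene body) whose closed interval contains it; a
   CpG can legitimately serve several categories, and each populated
   category becomes one analysis unit (`plan_analyses()`, at most three
   units — hence at most six analyses, G×Me and PoO×Me — per SNP).
4. `summarize_region()` averages the non-missing $\beta$ values per
   sample; `assign_strata()` ranks samples and cuts them into
   `n_strata` equally sized groups (default 3), larger groups at lower
   strata when $n$ is not divisible, ties broken by stable ascending
   sample id. Strata are computed within each analysis dataset
   separately (cases on their own distribution, controls on theirs);
   `region_strata(boundaries = )` lets one dataset's cut points be
   imported into another when a shared scale is wanted.

Averaging across a region deliberately trades per-CpG detail for
stability: two samples with opposite per-CpG profiles but the same mean
land in the same stratum. That is a property of the summary, not a bug,
and the worked example in the test suite pins it down.

## Interaction tests

`stratified_fit()` fits each stratum independently (the strata partition
the families, so the fits are independent samples) plus one pooled
"all" fit that ignores strata entirely — a refit, not an average.
`wald_interaction_test()` stacks the selected per-stratum log
parameters, takes successive differences between adjacent strata, and
forms $W = d^\top (CVC^\top)^{-1} d$ with block-diagonal $V$;
$W \sim \chi^2_{(S-1)k}$ under the null of no interaction, and the
statistic does not depend on which stratum is the baseline. For PoO×Me
the tested parameter is $\log RRR$. `trend_test()` regresses the scalar
log parameter on centred stratum scores (default 1, 2, 3) by
inverse-variance weighted least squares; it gains power against
monotone alternatives and coincides with the Wald test at $S = 2$. All
tests are two-sided and operate on the multiplicative (log) scale.

## Identifying assumptions and the control-triad diagnostics

G×Me inference from case families alone needs methylation to be
independent of the child genotype conditional on the parental
genotypes. A SNP that directly drives nearby methylation (an meQTL)
violates this and produces spurious "interactions". Two safeguards are
implemented:

* `control_comparison()` repeats the analysis in control families; a
  significant interaction in *both* datasets is flagged
  `suspected_false_positive` — a background SNP-methylation correlation
  rather than a disease effect.
* `estimate_control_methylation()` uses control triads (valid under the
  rare-disease approximation) to estimate $P(Me \mid M, F, C)$ and to
  test the *origin-symmetry* condition
  $P(Me \mid M, F, C_{ij}) = P(Me \mid M, F, C_{ji})$ with a chi-square
  contrast between heterozygous children whose variant allele is
  maternally vs paternally derived (restricted to families where the
  origin is determined).

The PoO×Me analysis needs only the weaker symmetry condition: if
methylation depends on the unordered child genotype but not on the
allele's origin, the per-stratum $RR_M$ and $RR_F$ estimates are both
biased by the same multiplicative factor, and their ratio — the RRR —
remains unbiased. This is the method's key robustness property and is
verified empirically by the acceptance suite under a generator scenario
built to violate independence while preserving symmetry.

## What the simulator emulates

`sim_config()` + `simulate_families()` generate the study conditions the
statistical claims are tested under: Hardy-Weinberg parents, Mendelian
transmission with recorded parental origin, a methylation stratum drawn
with configurable genotype dependence, penetrance per the model above
(validated to stay ≤ 1 before any sampling), and ascertainment by
rejection sampling on the disease outcome. Defaults: variant frequency
0.3, baseline risk 0.01 (small enough that simulated controls satisfy
the rare-disease approximation), three strata.

The four `me_dependence` scenarios map directly onto the assumptions:

| scenario | depends on | independence | origin symmetry |
|---|---|---|---|
| `independent` | nothing | holds | holds |
| `parental` | parental dose sum $m + f$ | holds (conditional) | holds |
| `child_symmetric` | unordered child dose | violated | holds |
| `child_asymmetric` | maternal-origin variant indicator | violated | violated |

`n_case` accepts per-stratum quotas, mirroring the fact that analysis
strata are tertiles and therefore exactly balanced in real runs;
controls are ascertained without quotas so their methylation
distribution stays informative.

`simulate_beta_block()` generates raw logit-normal CpG values whose
region means rank-agree with the assigned strata by construction
(disjoint latent intervals per stratum), with per-CpG offsets scaled by
$\sqrt{1-\rho}$ (so $\rho = 1$ gives identical columns) and correlated
logit-scale noise. At zero noise the full region pipeline reproduces the
generator's strata exactly. What the generator does *not* emulate:
realistic 450K array noise, probe artefacts, batch effects or cell-type
mixtures — so passing tests demonstrate the statistical machinery, not
robustness to array-specific measurement pathology.

## Simulation sizes used in the checks

The test and acceptance runs use problem sizes chosen to make the
Monte-Carlo error small relative to the tolerances while keeping a
single-CPU run practical: 200 replicates at 1000 case triads per
stratum for recovery/coverage, 1000 null replicates for the type-I
error of the interaction tests, 200 replicates at 2000 per stratum for
the RRR robustness claim, 100 replicates for the dyad-EM comparison,
and 40-60 replicates for the control-screening flag rates. The
acceptance script reports the same quantities at moderately reduced
replicate counts.

## Known limitations

* Single biallelic autosomal SNPs only: no haplotypes, no multi-allelic
  markers, no X-chromosome dosage handling.
* Case-only G×Me inference stands or falls with the
  methylation-independence condition; the control-based diagnostics
  detect, but cannot correct, violations (no hybrid case+control joint
  likelihood is fitted).
* Maternal-genotype main effects and covariate adjustment are out of
  scope.
* The EM dyad likelihood assumes Hardy-Weinberg and random mating for
  the missing parent; strong population structure would bias dyad (but
  not complete-triad conditional) fits.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_case = c(600, 600, 600), rr = c(1, 1.5, 2.2), var_freq = 0.3,
  cpg_block = list(n_cpgs = 5, rho = 0.6, noise_sd = 0.02)
)
sim <- simulate_families(cfg, seed = 1)

plan <- plan_analyses(as.list(sim$snp[1, ]), sim$manifest, sim$regions)
strata <- region_strata(sim$beta, plan$cpg_ids[[1]])
fam <- sim$families |>
  select(-stratum) |>
  inner_join(strata |> select(sample_id, stratum),
             by = c(child_sample_id = "sample_id"))

res <- run_gxme(fam, snp_id = sim$snp$snp_id,
                category = plan$category[1])
glance(res)
tidy(res)
autoplot(res)
```
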