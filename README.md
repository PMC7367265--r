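# triadme

Family-based tests for **gene–methylation (G×Me)** and
**parent-of-origin–methylation (PoO×Me)** interactions from case-parent
triads and parent–child dyads.

`triadme` is for epidemiologists and statistical geneticists who have
family genotypes for a dichotomous, early-onset outcome plus genome-wide
DNA-methylation data on the children, and who want to know whether the
methylation level of a region near a SNP *modifies* the SNP's relative
risk — or modifies the dependence of that risk on which parent the
allele came from.

## The model

For an ordered child genotype $C_{ij} = A_iA_j$ ($A_i$ maternal, $A_j$
paternal) and methylation stratum $Me = m$ (tertiles of the
region-averaged beta value), disease risk follows the multiplicative
penetrance

$$P(D \mid C_{ij}, Me = m) = B^{(m)} \cdot RR_{M,i}^{(m)} \cdot RR_{F,j}^{(m)},
\qquad RR_{M,1}^{(m)} = RR_{F,1}^{(m)} = 1 .$$

* **G×Me** sets $RR_{M,i}^{(m)} = RR_{F,i}^{(m)} = RR_i^{(m)}$ (gene-dose
  model) and asks whether $RR^{(m)}$ changes across strata.
* **PoO×Me** leaves the parental risks free and asks whether the
  relative-risk ratio $RRR^{(m)} = RR_M^{(m)} / RR_F^{(m)}$ — the
  parent-of-origin effect — changes across strata.

Per-stratum maximum-likelihood fits condition on the parental mating
type for complete triads (so the parental genotype distribution and the
baseline risk cancel), and use an EM algorithm under Hardy–Weinberg for
dyads with a missing parent. Interactions are tested with a Wald
chi-square over successive stratum contrasts and an inverse-variance
trend test on ordered stratum scores; control families provide
false-positive screening (`control_comparison()`) and a diagnostic of
the methylation-independence assumptions
(`estimate_control_methylation()`).

## Worked example

Simulate triads whose true RR rises across methylation strata, push the
raw CpG values through the region pipeline, and test for interaction:

```r
library(triadme)
library(dplyr)

cfg <- sim_config(
  n_case = c(600, 600, 600), rr = c(1, 1.5, 2.2), var_freq = 0.3,
  cpg_block = list(n_cpgs = 5, rho = 0.6, noise_sd = 0.02)
)
sim <- simulate_families(cfg, seed = 1)

plan   <- plan_analyses(as.list(sim$snp[1, ]), sim$manifest, sim$regions)
strata <- region_strata(sim$beta, plan$cpg_ids[[1]])
fam <- sim$families |>
  select(-stratum) |>
  inner_join(strata |> select(sample_id, stratum),
             by = c(child_sample_id = "sample_id"))

res <- run_gxme(fam, snp_id = sim$snp$snp_id, category = plan$category[1])
glance(res)
#> # A tibble: 1 × 12
#>   snp_id category analysis model     dose           wald_chi2 wald_df   wald_p
#>   <chr>  <chr>    <chr>    <chr>     <chr>              <dbl>   <dbl>    <dbl>
#> 1 snp1   promoter gxme     gene_dose multiplicative      53.1       2 2.96e-12
#>   trend_z  trend_p control_wald_p flag
#>     <dbl>    <dbl>          <dbl> <chr>
#> 1    7.17 7.32e-13             NA ok
tidy(res)
#> # A tibble: 4 × 11
#>   snp_id category analysis stratum term   n_families var_freq_child estimate
#> 1 snp1   promoter gxme     1       log_rr        600          0.312  -0.0148
#> 2 snp1   promoter gxme     2       log_rr        600          0.382   0.293
#> 3 snp1   promoter gxme     3       log_rr        600          0.498   0.870
#> 4 snp1   promoter gxme     all     log_rr       1800          0.397   0.390
#>      rr conf.low conf.high
#> 1 0.985    0.832      1.17
#> 2 1.34     1.13       1.59
#> 3 2.39     2.01       2.84
#> 4 1.48     1.34       1.63
```

Reading the output: the per-stratum RR climbs from 0.99 (low
methylation) through 1.34 to 2.39 (high), close to the simulated
1 / 1.5 / 2.2; the unstratified "all" fit (1.48) would have averaged the
effect away. The Wald interaction test (chi-square 53.1 on 2 df,
p ≈ 3e-12) and the trend test (z = 7.17) both detect the change across
strata. `autoplot(res)` draws the per-stratum forest plot, and
`run_pooxme()` runs the parent-of-origin analogue on the same input.

A thin command-line wrapper over the same functions is installed at
`inst/cli/triadme` (subcommands `simulate`, `gxme`, `pooxme`, `scan`,
`qq`).

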