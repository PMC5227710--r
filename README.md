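# fullgem

Full genetic-model GWAS for quantitative traits in multi-ethnic cohorts.

Most genome-wide association analyses fit one SNP at a time with an
additive dosage, which leaves dominance, epistasis and ancestry-specific
genetic effects on the table. `fullgem` implements the opposite end of the
spectrum for people studying complex traits in structured cohorts: a
multi-locus mixed model in which selected loci carry additive ($a$) and
dominance ($d$) effects, selected pairs carry digenic epistasis
($aa, ad, da, dd$), and ethnicity enters as a random effect together with
locus-by-ethnicity interaction classes ($ae$, $de$, and the
epistasis-by-ethnicity classes):

$$
y = \mu + \text{sex} + \textstyle\sum_i (x^A_i a_i + x^D_i d_i)
  + \sum_{i<j} \sum_{w \in \{aa,ad,da,dd\}} x^w_{ij} w_{ij}
  + e_h + \sum_i (x^A_i\, ae_{ih} + x^D_i\, de_{ih}) + \cdots + \varepsilon
$$

with the classical codings $x^A = 1/0/{-1}$ for QQ/Qq/qq (Q = major
allele) and $x^D = 1$ for heterozygotes. Variance components come from
Henderson method III, each model term is tested with an F statistic
calibrated against a permutation null of the maximum F (experiment-wise
$P$ values, including a generalized-Pareto tail for values beyond the
permutation resolution), and effects are estimated by Gibbs sampling.
Heritability is partitioned into additive, dominance, epistasis and the
three ethnicity-interaction classes, summing exactly to the total.

The package also ships the two comparison arms — the reduced multi-locus
*additive* model and a single-locus regression baseline with
principal-component stratification control, genomic control
($\lambda_{GC}$), LD pruning and Bonferroni thresholds — plus a synthetic
cohort generator (Balding–Nichols population structure, LD blocks,
repeated phenotype measures) and an evaluation harness that scores power,
false-discovery rate (raw and LD-adjusted) and estimation bias over
repeated simulations. Genotypes are read from PLINK text (`.ped`/`.map`)
or binary (`.bed`/`.bim`/`.fam`) files; phenotypes from a TSV with columns
`iid`, `sex`, `ethnicity`, `exam`, `value`.

## Worked example

Simulate a small cohort with one additive and one dominance locus among
null SNPs, then run the pipeline: QC, screening, stepwise model building,
and the full-model fit.

```r
library(fullgem)

truth <- tibble::tibble(snp1 = c("rs1", "rs2"), snp2 = NA,
                        effect = c("a", "d"), level = NA, value = c(3, -2.5))
pop  <- population_model(maf = 0.3, fst = 0.05)
geno <- gen_genotypes(pop, 1500, 6, seed = 7,
                      snp_ids = c("rs1","rs2","rs3","rs4","rs5","rs6"))
scen <- sim_scenario("demo", truth = truth, sigma_e = 8, n = 1500)
ph   <- simulate_phenotypes(scen, geno, seed = 8)

geno <- qc_filter(geno)
scr  <- screen_candidates(geno, ph, p1d = 1e-4, max_candidates = 10, top_m = 4)
spec <- stepwise_build(scr, geno, ph, alpha_ew = 0.05, n_perm = 500, seed = 9)
fit  <- fit_full_model(spec, geno, ph,
                       engine_settings(n_perm = 500, gibbs_iterations = 4000,
                                       burn_in = 1000, seed = 10))
fit
#> <qts_fit> 20 tested terms, 2 experiment-wise significant (alpha=0.05)
#>   total h2 = 7.25%
dplyr::select(tidy(fit, significant_only = TRUE),
              term, effect, estimate, se, F, neglog10_p_ew, h2)
#> # A tibble: 2 x 7
#>   term  effect estimate    se     F neglog10_p_ew    h2
#>   <chr> <chr>     <dbl> <dbl> <dbl>         <dbl> <dbl>
#> 1 a_rs1 a          2.84 0.250 155.          31.7   5.38
#> 2 d_rs2 d         -2.47 0.487  40.5          7.67  1.83
```

Both planted loci — and only they — are declared experiment-wise
significant. The additive estimate 2.84 ± 0.25 recovers the planted
$a = 3$ (half the QQ−qq difference), the dominance estimate −2.47 ± 0.49
the planted $d = -2.5$ (heterozygote deviation); `neglog10_p_ew` is the
experiment-wise $-\log_{10} P$ against the 500-permutation max-F null
(values above ~2.7 are tail extrapolations), and `h2` the percent of
phenotypic variance each locus explains. `glance(fit)` returns the
heritability class totals and the permutation critical F;
`autoplot(fit)` draws the effect forest plot; `write_qts_table(fit, path)`
exports the association table as TSV.

`fit_additive_model()` runs the same machinery under the additive
reduction, `single_locus_scan()` + `lambda_gc()` + `ld_prune()` +
`bonferroni_threshold()` form the single-locus arm, and
`run_replicates()` / `score_replicates()` drive the power–FDR–bias
comparison between the approaches. A thin command-line front end is
installed at `exec/fullgem` (subcommands `simulate`, `qc`, `screen`,
`fit-full`, `fit-additive`, `scan-single`, `evaluate`, `all`) with a YAML
configuration; see `?run_config`.

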