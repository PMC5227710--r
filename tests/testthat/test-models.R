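# full and additive model fits end to end on small simulated cohorts

test_that("full-model fit recovers a planted additive effect", {
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                          level = NA, value = 2)
  geno <- gen_genotypes(population_model(), 500, 3, seed = 2)
  scen <- sim_scenario("mini", truth = truth, sigma_e = 2, n = 500)
  ph <- simulate_phenotypes(scen, geno, seed = 3)
  sp <- spec_from_truth(truth)
  fit <- fit_full_model(sp, geno, ph,
                        engine_settings(n_perm = 200, gibbs_iterations = 2000,
                                        burn_in = 400, seed = 4))
  td <- tidy(fit)
  row <- td[td$term == "a_snp1", ]
  expect_true(row$significant)
  expect_equal(row$estimate, 2, tolerance = 0.15)
  expect_gt(row$neglog10_p_ew, 2)
  expect_gt(row$h2, 0)
  g <- glance(fit)
  expect_equal(g$n_significant, sum(td$significant))
  expect_gt(g$h2_total, 0)
})

test_that("additive and full fits agree on additive-only truth, dominance centers on zero", {
  truth <- tibble::tibble(snp1 = c("snp1", "snp2"), snp2 = NA, effect = "a",
                          level = NA, value = c(1.5, -1))
  geno <- gen_genotypes(population_model(), 600, 2, seed = 5)
  scen <- sim_scenario("mini", truth = truth, sigma_e = 2, n = 600)
  ph <- simulate_phenotypes(scen, geno, seed = 6)
  sp_full <- model_spec(
    tibble::tibble(snp = c("snp1", "snp2"),
                   terms = list(c("a", "d"), c("a", "d"))),
    random_classes = c("e", "ae", "de"))
  st <- engine_settings(n_perm = 200, gibbs_iterations = 2000,
                        burn_in = 400, seed = 7)
  fit_f <- fit_full_model(sp_full, geno, ph, st)
  fit_a <- fit_additive_model(sp_full, geno, ph, st)
  tf <- tidy(fit_f); ta <- tidy(fit_a)
  for (s in c("snp1", "snp2")) {
    ef <- tf$estimate[tf$term == paste0("a_", s)]
    ea <- ta$estimate[ta$term == paste0("a_", s)]
    se <- tf$se[tf$term == paste0("a_", s)]
    expect_lt(abs(ef - ea), 3 * se)       # paired agreement within MC error
    # dominance estimates center on zero under additive truth
    ed <- tf$estimate[tf$term == paste0("d_", s)]
    sed <- tf$se[tf$term == paste0("d_", s)]
    expect_lt(abs(ed), 3 * sed)
  }
  # the additive fit has no dominance or interaction-with-d terms
  expect_false(any(grepl("^d_|^de_", ta$term)))
})

test_that("empty additive spec yields an intercept/sex fit with zero heritability", {
  cohort <- make_cohort(n = 120, m = 1, seed = 8)
  sp <- model_spec(tibble::tibble(snp = "s1", terms = list("d")),
                   random_classes = c("e", "de"))
  red <- reduce_to_additive(sp)
  expect_equal(nrow(red$loci), 0L)
  # fitting an empty spec errors cleanly at design level (no genetic terms,
  # nothing to permute): callers check for the empty spec instead
  expect_equal(length(spec_snps(red)), 0L)
})

test_that("experiment-wise type-I control holds on a zero-effect trait", {
  # one pure-noise trait, full machinery: the chance of any significant term
  # is alpha_EW; check over a handful of traits that false declarations are
  # rare (binomial(5, 0.05): P(>=3 hits) ~ 1e-3)
  geno <- gen_genotypes(population_model(), 300, 4, seed = 9)
  sp <- model_spec(tibble::tibble(snp = paste0("snp", 1:4),
                                  terms = replicate(4, c("a", "d"),
                                                    simplify = FALSE)),
                   random_classes = c("e", "ae", "de"))
  groups <- attr(geno, "groups")
  hits <- vapply(1:5, function(i) {
    truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                            level = NA, value = 0)
    scen <- sim_scenario("null", truth = truth, sigma_e = 1, n = 300)
    ph <- simulate_phenotypes(scen, geno, groups, seed = 100 + i)
    fit <- fit_full_model(sp, geno, ph,
                          engine_settings(n_perm = 300, gibbs_iterations = 0,
                                          seed = 100 + i))
    sum(fit$records$significant, na.rm = TRUE) > 0
  }, logical(1))
  expect_lt(sum(hits), 3)
})
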