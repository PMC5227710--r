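# genotype and phenotype simulation: Balding-Nichols structure, LD blocks,
# linearity, replicates, residual calibration

test_that("FST = 0 keeps every group at the ancestral frequency", {
  pop <- population_model(maf = 0.25, fst = 0)
  geno <- gen_genotypes(pop, 8000, 5, seed = 2)
  groups <- attr(geno, "groups")
  for (h in 1:4) {
    rows <- groups == h
    q_hat <- colMeans(2 - geno$calls[rows, ]) / 2
    expect_lt(max(abs(q_hat - 0.25)), 0.04)
  }
})

test_that("within-group genotype frequencies match their Balding-Nichols draws", {
  pop <- population_model(maf = 0.3, fst = 0.05)
  geno <- gen_genotypes(pop, 10000, 4, seed = 3)
  groups <- attr(geno, "groups")
  q <- attr(geno, "group_freqs")
  # chi-square goodness of fit of genotype classes to HWE at the drawn
  # frequency, per group x SNP; no rejection at alpha = 1e-3 in the bulk
  pvals <- c()
  for (h in 1:4) for (j in 1:4) {
    rows <- which(groups == h)
    counts <- table(factor(geno$calls[rows, j], levels = 0:2))
    qq <- q[h, j]
    probs <- c(qq^2, 2 * qq * (1 - qq), (1 - qq)^2)  # calls count majors
    pvals <- c(pvals, suppressWarnings(chisq.test(counts, p = probs)$p.value))
  }
  expect_lt(mean(pvals < 1e-3), 0.2)
})

test_that("LD blocks produce high genotype r-squared within block", {
  pop <- population_model(maf = 0.3, fst = 0, ld_block_len = 2, ld_rho = 0.95)
  geno <- gen_genotypes(pop, 5000, 4, seed = 4)
  r2_block <- cor(geno$calls[, 1], geno$calls[, 2])^2
  r2_cross <- cor(geno$calls[, 2], geno$calls[, 3])^2
  expect_gt(r2_block, 0.75)
  expect_lt(r2_cross, 0.05)
})

test_that("generation is reproducible by seed", {
  pop <- population_model()
  g1 <- gen_genotypes(pop, 100, 6, seed = 5)
  g2 <- gen_genotypes(pop, 100, 6, seed = 5)
  expect_identical(g1$calls, g2$calls)
  g3 <- gen_genotypes(pop, 100, 6, seed = 6)
  expect_false(identical(g1$calls, g3$calls))
})

test_that("null phenotypes center on mu with residual variance sigma^2", {
  geno <- gen_genotypes(population_model(), 3000, 1, seed = 6)
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                          level = NA, value = 0)
  scen <- sim_scenario("custom", truth = truth, sigma_e = 3, mu = 200,
                       sex_effect = 0, n = 3000)
  ph <- simulate_phenotypes(scen, geno, seed = 7)
  expect_equal(mean(ph$value), 200, tolerance = 0.25)
  expect_equal(var(ph$value), 9, tolerance = 0.6)
})

test_that("noise-free phenotypes are exactly linear in the effects", {
  geno <- gen_genotypes(population_model(), 200, 2, seed = 8)
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                          level = NA, value = 2)
  scen <- sim_scenario("custom", truth = truth, sigma_e = 1e-12, mu = 0,
                       sex_effect = 0, n = 200)
  ph <- simulate_phenotypes(scen, geno, seed = 9)
  xa <- code_additive(geno$calls[match(ph$iid, geno$samples), "snp1"])
  expect_equal(ph$value, 2 * xa, tolerance = 1e-6)
  # doubling all effects doubles the genetic contribution exactly
  truth2 <- truth; truth2$value <- 4
  ph2 <- simulate_phenotypes(sim_scenario("custom", truth = truth2,
                                          sigma_e = 1e-12, mu = 0,
                                          sex_effect = 0, n = 200),
                             geno, seed = 9)
  expect_equal(ph2$value, 2 * ph$value, tolerance = 1e-6)
  # QQ vs qq difference is exactly 2a = 4
  expect_equal(max(ph$value) - min(ph$value), 4, tolerance = 1e-6)
})

test_that("replicate records share the genetic value and differ only in noise", {
  geno <- gen_genotypes(population_model(), 150, 1, seed = 10)
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                          level = NA, value = 3)
  scen <- sim_scenario("custom", truth = truth, sigma_e = 0.5, mu = 100,
                       replications = 2, n = 150)
  ph <- simulate_phenotypes(scen, geno, seed = 11)
  wide <- tidyr::pivot_wider(ph, id_cols = "iid", names_from = "exam",
                             values_from = "value")
  diffs <- wide$`1` - wide$`2`
  # the between-replicate difference is pure noise: variance 2 sigma^2
  expect_equal(var(diffs), 2 * 0.25, tolerance = 0.1)
  # while the genetic signal is common: replicates correlate strongly
  expect_gt(cor(wide$`1`, wide$`2`), 0.7)
})

test_that("interaction effects activate only in their ethnic group", {
  geno <- gen_genotypes(population_model(), 400, 1, seed = 12)
  groups <- attr(geno, "groups")
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "ae",
                          level = 3L, value = 5)
  scen <- sim_scenario("custom", truth = truth, sigma_e = 1e-12, mu = 0,
                       sex_effect = 0, replications = 1, n = 400)
  ph <- simulate_phenotypes(scen, geno, seed = 13)
  xa <- code_additive(geno$calls[match(ph$iid, geno$samples), 1])
  expect_equal(ph$value[ph$ethnicity == 3], 5 * xa[ph$ethnicity == 3],
               tolerance = 1e-6)
  expect_equal(ph$value[ph$ethnicity != 3], rep(0, sum(ph$ethnicity != 3)),
               tolerance = 1e-6)
})

test_that("residual calibration hits the target variance shares", {
  pop <- population_model(maf = 0.3, fst = 0.05)
  truth <- scenario_truth("I")
  geno <- gen_genotypes(pop, 5000, length(scenario_loci("I")), seed = 14,
                        snp_ids = scenario_loci("I"))
  groups <- attr(geno, "groups")
  # anchor calibration: the anchor's additive share equals its target
  sig <- calibrate_residual(truth, geno, groups,
                            target = list(anchor = "rs629301", effect = "a",
                                          h2 = 1.46))
  anchor <- truth[truth$snp1 == "rs629301" & truth$effect == "a" &
                    is.na(truth$level), ]
  xa <- code_additive(geno$calls[, "rs629301"])
  share <- var(anchor$value * xa) / attr(sig, "v_p")
  expect_equal(100 * share, 1.46, tolerance = 0.01)
  # total-heritability calibration: realized share within 1 point of target
  sig2 <- calibrate_residual(truth, geno, groups,
                             target = list(total_h2 = 33.64))
  expect_equal(100 * attr(sig2, "v_genetic") / attr(sig2, "v_p"), 33.64,
               tolerance = 1)
  # degenerate targets error
  expect_error(calibrate_residual(truth, geno, groups,
                                  target = list(total_h2 = 0)), "positive")
})

test_that("scenario truth sets have the expected structure", {
  t1 <- scenario_truth("I")
  expect_equal(nrow(t1), 52L)
  expect_equal(sum(!is.na(t1$snp2)), 8L)     # 8 epistasis effects on 4 pairs
  expect_equal(t1$value[t1$snp1 == "rs629301" & t1$effect == "a"], 4.94)
  t2 <- scenario_truth("II")
  expect_equal(nrow(t2), 13L)
  expect_true(all(t2$effect == "a"))
  t2ae <- scenario_truth("II", ae_effects = tibble::tibble(
    snp1 = "rs629301", level = 4, value = 1.5))
  expect_equal(nrow(t2ae), 14L)
  expect_error(sim_scenario("II", truth = scenario_truth("I")), "scenario II")
})
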