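# replicate scoring: power, raw and LD-adjusted FDR, bias flags

# build a sim_replicates object by hand around a small genotype panel
fake_reps <- function(det, truth, geno, n_sims) {
  structure(list(detections = det, truth = truth, genotypes = geno,
                 groups = attr(geno, "groups"),
                 scenario = NULL, seeds = seq_len(n_sims)),
            class = "sim_replicates")
}

test_that("perfect detections give power 100 and FDR 0", {
  geno <- gen_genotypes(population_model(), 100, 3, seed = 2,
                        snp_ids = c("t1", "t2", "x1"))
  truth <- tibble::tibble(snp1 = c("t1", "t2"), snp2 = NA,
                          effect = "a", level = NA, value = c(2, -1))
  det <- tidyr::expand_grid(sim = 1:4, snp1 = c("t1", "t2"))
  det <- dplyr::mutate(det, method = "full", term = paste0("a_", snp1),
                       effect = "a", snp2 = NA_character_,
                       level = NA_integer_, F = 50,
                       estimate = rep(c(2.1, -0.9), 4), se = 0.2,
                       significant = TRUE)
  rep <- score_replicates(fake_reps(det, truth, geno, 4))
  expect_true(all(rep$per_locus$power == 100))
  expect_true(all(rep$per_effect$power == 100))
  expect_equal(rep$summary$fdr, 0)
  expect_equal(rep$summary$fdr_adjusted, 0)
})

test_that("an LD neighbor counts false raw but true adjusted", {
  base <- gen_genotypes(population_model(), 400, 2, seed = 3,
                        snp_ids = c("t1", "x1"))
  # neighbor constructed as a noisy copy: r^2 > 0.85 with t1
  calls <- cbind(base$calls, nb = base$calls[, "t1"])
  set.seed(4)
  i <- sample(400, 12); calls[i, 3] <- sample(0:2, 12, TRUE)
  geno <- geno_matrix(calls, tibble::tibble(
    chr = "1", snp = c("t1", "x1", "nb"), pos = c(1L, 2L, 3L) * 1000L,
    major = "A", minor = "B"))
  attr(geno, "groups") <- attr(base, "groups")
  expect_gt(cor(2 - calls[, "t1"], 2 - calls[, "nb"])^2, 0.85)
  truth <- tibble::tibble(snp1 = "t1", snp2 = NA, effect = "a",
                          level = NA, value = 2)
  det <- tibble::tibble(sim = 1L, method = "full", term = "a_nb",
                        effect = "a", snp1 = "nb", snp2 = NA_character_,
                        level = NA_integer_, F = 30, estimate = 2, se = 0.3,
                        significant = TRUE)
  rep <- score_replicates(fake_reps(det, truth, geno, 1), r2_match = 0.85)
  expect_equal(rep$summary$fdr, 100)          # nb is not a truth locus
  expect_equal(rep$summary$fdr_adjusted, 0)   # but tags one at r^2 > 0.85
  expect_lte(rep$summary$fdr_adjusted, rep$summary$fdr)
})

test_that("zero detections give NA FDR and zero power", {
  geno <- gen_genotypes(population_model(), 50, 1, seed = 5, snp_ids = "t1")
  truth <- tibble::tibble(snp1 = "t1", snp2 = NA, effect = "a",
                          level = NA, value = 1)
  det <- tibble::tibble(sim = 1L, method = "full", term = "a_t1",
                        effect = "a", snp1 = "t1", snp2 = NA_character_,
                        level = NA_integer_, F = 0.5, estimate = 0.1,
                        se = 0.2, significant = FALSE)
  rep <- score_replicates(fake_reps(det, truth, geno, 1))
  expect_true(is.na(rep$summary$fdr))
  expect_equal(rep$per_locus$power, 0)
})

test_that("bias flags follow the empirical interval", {
  geno <- gen_genotypes(population_model(), 50, 1, seed = 6, snp_ids = "t1")
  truth <- tibble::tibble(snp1 = "t1", snp2 = NA, effect = "a",
                          level = NA, value = 0)
  mk <- function(ests) {
    tibble::tibble(sim = seq_along(ests), method = "full", term = "a_t1",
                   effect = "a", snp1 = "t1", snp2 = NA_character_,
                   level = NA_integer_, F = 10, estimate = ests, se = 0.1,
                   significant = TRUE)
  }
  set.seed(7)
  # estimates all well above truth 0: overestimation
  r_over <- score_replicates(fake_reps(mk(rnorm(40, 3, 0.3)), truth, geno, 40))
  expect_equal(r_over$per_effect$bias, "over")
  # estimates centered on truth: unbiased
  r_ok <- score_replicates(fake_reps(mk(rnorm(40, 0, 0.3)), truth, geno, 40))
  expect_equal(r_ok$per_effect$bias, "unbiased")
  # estimates all below: underestimation
  r_und <- score_replicates(fake_reps(mk(rnorm(40, -3, 0.3)), truth, geno, 40))
  expect_equal(r_und$per_effect$bias, "under")
})

test_that("run_replicates is deterministic and respects n_sims", {
  truth <- tibble::tibble(snp1 = "snp1", snp2 = NA, effect = "a",
                          level = NA, value = 1.5)
  scen <- sim_scenario("mini", truth = truth, sigma_e = 2, n = 120,
                       replications = 2)
  st <- engine_settings(n_perm = 100, gibbs_iterations = 0, seed = 1)
  r1 <- run_replicates(scen, methods = "full", n_sims = 2, base_seed = 5,
                       settings = st)
  r2 <- run_replicates(scen, methods = "full", n_sims = 2, base_seed = 5,
                       settings = st)
  expect_equal(r1$detections, r2$detections)
  expect_equal(sort(unique(r1$detections$sim)), 1:2)
  r3 <- run_replicates(scen, methods = "single", n_sims = 1, base_seed = 5,
                       settings = st)
  expect_equal(unique(r3$detections$method), "single")
})
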