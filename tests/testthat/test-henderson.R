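# Henderson method III against closed-form ANOVA oracles

test_that("balanced one-way random design reproduces the ANOVA moment estimator", {
  # groups {1.0, 1.2} and {2.0, 2.2}: MSB = 1.0, MSW = 0.02,
  # sigma2_group = (MSB - MSW)/2 = 0.49, sigma2_e = 0.02
  d <- one_way_design(c(1.0, 1.2, 2.0, 2.2), k_groups = 2, reps = 2)
  vc <- henderson3_components(d)
  expect_equal(vc$variance[vc$component == "grp"], 0.49)
  expect_equal(vc$variance[vc$component == "residual"], 0.02)
  expect_false(any(vc$truncated))
})

test_that("balanced one-way designs match the ANOVA closed form in general", {
  set.seed(11)
  for (case in list(c(k = 5, r = 4), c(k = 8, r = 3))) {
    k <- case[["k"]]; r <- case[["r"]]
    y <- rnorm(k * r, rep(rnorm(k, sd = 2), each = r), 0.7)
    d <- one_way_design(y, k, r)
    vc <- henderson3_components(d)
    grp <- gl(k, r)
    msw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / (k * (r - 1))
    msb <- r * sum((tapply(y, grp, mean) - mean(y))^2) / (k - 1)
    expect_equal(vc$variance[vc$component == "residual"], msw, tolerance = 1e-10)
    expect_equal(vc$variance[vc$component == "grp"],
                 max((msb - msw) / r, 0), tolerance = 1e-10)
  }
})

test_that("no random classes returns the OLS residual mean square", {
  cohort <- make_cohort(n = 50, m = 2, seed = 7)
  sp <- model_spec(tibble::tibble(snp = "s1", terms = list("a")),
                   random_classes = character(0))
  d <- build_design(cohort$geno, cohort$ph, sp)
  vc <- henderson3_components(d)
  ols <- lm(cohort$ph$value ~ cohort$ph$sex +
              code_additive(cohort$geno$calls[, "s1"]))
  expect_equal(vc$variance, sum(ols$residuals^2) / ols$df.residual,
               tolerance = 1e-10)
})

test_that("a zero-variance random class truncates to zero on average", {
  # simulate many small balanced datasets with sigma2_group = 0: the
  # truncated estimator must average near zero (it cannot, by construction,
  # be negative)
  set.seed(21)
  ests <- replicate(200, {
    y <- rnorm(12)
    vc <- henderson3_components(one_way_design(y, 4, 3))
    vc$variance[vc$component == "grp"]
  })
  expect_true(all(ests >= 0))
  # distribution-theory oracle: MSB ~ chi2(3)/3, MSW ~ chi2(8)/8 under the
  # null, estimator = max((MSB - MSW)/3, 0)
  set.seed(22)
  oracle <- mean(pmax((rchisq(20000, 3) / 3 - rchisq(20000, 8) / 8) / 3, 0))
  expect_equal(mean(ests), oracle, tolerance = 0.35)
})

test_that("two-way crossed random design matches the balanced ANOVA solution", {
  # y_ijk = a_i + b_j + e_ijk, balanced; Henderson III on balanced data
  # equals the classical moment estimators
  set.seed(31)
  I <- 6; J <- 5; s_a <- 1.5; s_b <- 0.8; s_e <- 0.5
  a <- rnorm(I, 0, s_a); b <- rnorm(J, 0, s_b)
  df <- expand.grid(i = 1:I, j = 1:J)
  y <- a[df$i] + b[df$j] + rnorm(I * J, 0, s_e)
  A <- outer(df$i, 1:I, `==`) * 1; colnames(A) <- paste0("a", 1:I)
  B <- outer(df$j, 1:J, `==`) * 1; colnames(B) <- paste0("b", 1:J)
  d <- structure(list(
    fixed = matrix(1, I * J, 1, dimnames = list(NULL, "mu")),
    random = list(fa = A, fb = B),
    column_map = tibble::tibble(column = c("mu", colnames(A), colnames(B)),
                                block = c("fixed", rep("fa", I), rep("fb", J)),
                                snp1 = NA, snp2 = NA,
                                effect = c("mu", rep("fa", I), rep("fb", J)),
                                level = NA_integer_),
    y = y, records = NULL, ind = as.character(seq_len(I * J)), dropped = 0L),
    class = "design_matrices")
  vc <- henderson3_components(d)
  av <- anova(lm(y ~ factor(df$i) + factor(df$j)))
  mse <- av["Residuals", "Mean Sq"]
  msa <- av[1, "Mean Sq"]; msb <- av[2, "Mean Sq"]
  expect_equal(vc$variance[vc$component == "residual"], mse, tolerance = 1e-8)
  expect_equal(vc$variance[vc$component == "fa"], max((msa - mse) / J, 0),
               tolerance = 1e-8)
  expect_equal(vc$variance[vc$component == "fb"], max((msb - mse) / I, 0),
               tolerance = 1e-8)
})
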