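# design-matrix construction: column layout, interaction blocks, row drops

test_that("fixed columns follow the spec: intercept, sex, requested terms", {
  cohort <- make_cohort(n = 30, m = 2, seed = 2)
  sp <- model_spec(tibble::tibble(snp = "s1", terms = list("a")),
                   random_classes = character(0))
  d <- build_design(cohort$geno, cohort$ph, sp)
  expect_equal(colnames(d$fixed), c("mu", "sex", "a_s1"))
  expect_true(all(d$fixed[, "mu"] == 1))
  expect_equal(length(d$y), nrow(cohort$ph))
})

test_that("an ae class with two additive loci yields an 8-column random block", {
  cohort <- make_cohort(n = 40, m = 3, seed = 3)
  sp <- model_spec(tibble::tibble(snp = c("s1", "s2"),
                                  terms = list("a", "a")),
                   random_classes = c("e", "ae"))
  d <- build_design(cohort$geno, cohort$ph, sp)
  expect_equal(ncol(d$random$ae), 8L)
  expect_equal(ncol(d$random$e), 4L)
})

test_that("interaction rows carry the coefficient in the individual's group column", {
  cohort <- make_cohort(n = 60, m = 2, seed = 4)
  sp <- model_spec(tibble::tibble(snp = "s1", terms = list("a")),
                   random_classes = c("e", "ae"))
  d <- build_design(cohort$geno, cohort$ph, sp)
  xa <- d$fixed[, "a_s1"]
  for (h in 1:4) {
    col <- d$random$ae[, paste0("ae_s1_", h)]
    in_h <- d$records$ethnicity == h
    expect_equal(col[in_h], xa[in_h])
    expect_true(all(col[!in_h] == 0))
  }
  # row sums over the 4 group columns reproduce the main coefficient
  expect_equal(rowSums(d$random$ae), xa)
})

test_that("records with missing genotypes at model loci are dropped and counted", {
  cohort <- make_cohort(n = 25, m = 2, seed = 5, exams = 2)
  g <- cohort$geno
  g$calls[3, "s1"] <- NA_integer_      # individual 3 missing at model locus
  sp <- model_spec(tibble::tibble(snp = "s1", terms = list(c("a", "d"))),
                   random_classes = "e")
  d <- build_design(g, cohort$ph, sp)
  expect_equal(d$dropped, 2L)          # both replicate records
  expect_equal(length(d$y), nrow(cohort$ph) - 2L)
  expect_false(g$samples[3] %in% d$ind)
})

test_that("unknown SNPs and fully-dropped records raise errors", {
  cohort <- make_cohort(n = 10, m = 1, seed = 6)
  sp <- model_spec(tibble::tibble(snp = "nope", terms = list("a")))
  expect_error(build_design(cohort$geno, cohort$ph, sp), "absent")
  g <- cohort$geno
  g$calls[, 1] <- NA_integer_
  sp2 <- model_spec(tibble::tibble(snp = "s1", terms = list("a")))
  expect_error(build_design(g, cohort$ph, sp2), "no phenotype records")
})

test_that("reduced additive spec drops non-additive terms and random classes", {
  sp <- model_spec(
    tibble::tibble(snp = c("s1", "s2"), terms = list(c("a", "d"), "d")),
    pairs = tibble::tibble(snp1 = "s1", snp2 = "s2", terms = list("aa")),
    random_classes = c("e", "ae", "de", "aae"))
  red <- reduce_to_additive(sp)
  expect_true(red$reduced_additive)
  expect_equal(red$loci$snp, "s1")
  expect_equal(red$loci$terms[[1]], "a")
  expect_equal(nrow(red$pairs), 0L)
  expect_equal(sort(red$random_classes), c("ae", "e"))
})

test_that("epistasis pair members must be distinct", {
  expect_error(
    model_spec(tibble::tibble(snp = "s1", terms = list("a")),
               pairs = tibble::tibble(snp1 = "s1", snp2 = "s1",
                                      terms = list("aa"))),
    "distinct")
})
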