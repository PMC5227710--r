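# shared fixture builders: everything is generated in code at test time

# small unstructured cohort with independent SNPs and a null or single-locus
# trait; returns genotypes, groups and a one-exam phenotype tibble
make_cohort <- function(n = 200, m = 4, seed = 1, fst = 0,
                        effect_snp = NULL, effect = 0, sigma = 1,
                        exams = 1) {
  geno <- gen_genotypes(population_model(fst = fst), n, m, seed = seed,
                        snp_ids = paste0("s", seq_len(m)))
  groups <- attr(geno, "groups")
  set.seed(seed + 1000)
  sex <- rbinom(n, 1, 0.5)
  g <- if (is.null(effect_snp)) rep(0, n) else
    effect * code_additive(geno$calls[, effect_snp])
  ph <- tidyr::expand_grid(i = seq_len(n), exam = seq_len(exams))
  ph <- tibble::tibble(iid = geno$samples[ph$i], sex = sex[ph$i],
                       ethnicity = groups[ph$i], exam = ph$exam,
                       value = g[ph$i] + rnorm(nrow(ph), 0, sigma))
  list(geno = geno, groups = groups, ph = ph)
}

# hand-built design with one random grouping factor (balanced one-way)
one_way_design <- function(y, k_groups, reps) {
  n <- k_groups * reps
  stopifnot(length(y) == n)
  G <- matrix(0, n, k_groups)
  for (g in seq_len(k_groups)) G[(g - 1) * reps + seq_len(reps), g] <- 1
  colnames(G) <- paste0("g", seq_len(k_groups))
  structure(list(
    fixed = matrix(1, n, 1, dimnames = list(NULL, "mu")),
    random = list(grp = G),
    column_map = tibble::tibble(
      column = c("mu", colnames(G)),
      block = c("fixed", rep("grp", k_groups)),
      snp1 = NA, snp2 = NA,
      effect = c("mu", rep("grp", k_groups)),
      level = NA_integer_),
    y = y, records = NULL, ind = as.character(seq_len(n)), dropped = 0L),
    class = "design_matrices")
}
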