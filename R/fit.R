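#' Engine settings for model fitting
#'
#' Bundles the knobs of the mixed-model machinery. Defaults mirror the study
#' protocol: 2000 permutations, experiment-wise alpha 0.05, 20000 Gibbs
#' iterations with 2000 burn-in.
#'
#' @param n_perm permutations for the experiment-wise null.
#' @param alpha_ew experiment-wise significance level.
#' @param gibbs_iterations,burn_in,thinning Gibbs chain settings; set
#'   `gibbs_iterations = 0` to skip effect estimation (F tests and variance
#'   components only).
#' @param seed integer seed driving both the permutation null and the chain.
#' @return A list of class `engine_settings`.
#' @export
engine_settings <- function(n_perm = 2000, alpha_ew = 0.05,
                            gibbs_iterations = 20000, burn_in = 2000,
                            thinning = 1, seed = 1L) {
  structure(list(n_perm = n_perm, alpha_ew = alpha_ew,
                 gibbs_iterations = gibbs_iterations, burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed)),
            class = "engine_settings")
}

#' Fit the full genetic model
#'
#' Runs the complete association machinery for a selected model: builds the
#' design, computes term-wise Henderson-III F statistics, calibrates them
#' against the permutation null of the maximum F, estimates variance
#' components (Henderson III), estimates every fixed effect and every
#' ethnic-interaction level by Gibbs sampling, and partitions heritability
#' into effect classes.
#'
#' @param spec a [model_spec()].
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a phenotype tibble.
#' @param settings an [engine_settings()] list.
#' @return An object of class `qts_fit`: list with `records` (tibble of
#'   per-term results: estimate, SE, F, -log10 experiment-wise P, h2),
#'   `heritability` (class partition tibble), `varcomp`, `null`
#'   (the permutation null), `design`, `settings`.
#' @export
fit_full_model <- function(spec, genotypes, phenotypes,
                           settings = engine_settings()) {
  design <- build_design(genotypes, phenotypes, spec)
  engine <- fg_engine(design)
  ft <- term_F(design, engine = engine)
  null <- permutation_threshold(design, n_perm = settings$n_perm,
                                alpha_ew = settings$alpha_ew,
                                seed = settings$seed, engine = engine)
  p_ew <- experimentwise_p(ft$F, null)
  vc <- henderson3_components(design)
  est <- NULL
  if (settings$gibbs_iterations > 0) {
    est <- gibbs_estimate(design, iterations = settings$gibbs_iterations,
                          burn_in = settings$burn_in,
                          thinning = settings$thinning, seed = settings$seed)
  }
  records <- ft
  records$p_ew <- as.numeric(p_ew)
  records$neglog10_p_ew <- -log10(records$p_ew)
  records$significant <- !is.na(records$F) & records$F > null$critical_F
  herit <- NULL
  if (!is.null(est)) {
    records <- dplyr::left_join(
      records,
      est$estimates[, c("column", "estimate", "se")],
      by = c(term = "column"))
    herit <- heritability_partition(est, design)
    records <- dplyr::left_join(records, attr(herit, "per_term"),
                                by = c(term = "column"))
  }
  structure(list(records = records, heritability = herit, varcomp = vc,
                 null = null, design = design, settings = settings,
                 estimates = est, spec = spec),
            class = "qts_fit")
}

#' Fit the reduced multi-locus additive model
#'
#' Identical machinery to [fit_full_model()] with the specification reduced
#' to additive main effects and ethnicity / additive-by-ethnicity random
#' classes. Loci whose only effects are dominance or epistasis drop out of
#' the reduced model entirely.
#'
#' @inheritParams fit_full_model
#' @return A `qts_fit`, see [fit_full_model()].
#' @export
fit_additive_model <- function(spec, genotypes, phenotypes,
                               settings = engine_settings()) {
  fit_full_model(reduce_to_additive(spec), genotypes, phenotypes, settings)
}

#' @export
print.qts_fit <- function(x, ...) {
  cat(sprintf("<qts_fit>%s %d tested terms, %d experiment-wise significant (alpha=%g)\n",
              if (isTRUE(x$spec$reduced_additive)) " [additive]" else "",
              nrow(x$records), sum(x$records$significant, na.rm = TRUE),
              x$settings$alpha_ew))
  if (!is.null(x$heritability)) {
    cat(sprintf("  total h2 = %.2f%%\n", sum(x$heritability$h2)))
  }
  invisible(x)
}

#' Heritability partition from realized effect variances
#'
#' Each term's contribution to phenotypic variance is the sample variance
#' across records of its predicted component (coefficient column times the
#' estimated effect); interaction terms of one locus/pair are first summed
#' over their four group levels, giving one pooled contribution per
#' locus-class. Contributions are divided by the phenotypic variance of the
#' response and summed into the six effect classes: additive, dominance,
#' epistasis (aa+ad+da+dd), additive-by-ethnicity, dominance-by-ethnicity
#' and epistasis-by-ethnicity. Total heritability is the exact sum of the
#' class shares.
#'
#' @param estimates an [gibbs_estimate()] result (or any object with an
#'   `estimates` tibble of columns `column`, `estimate`).
#' @param design the [build_design()] result the estimates refer to.
#' @param y response vector (defaults to the design's trait values).
#' @return A `heritability_partition` tibble with columns `class`, `h2`
#'   (percent); attribute `per_term` holds per-column h2 with pooled
#'   locus-class values, attribute `total` the summed total.
#' @export
heritability_partition <- function(estimates, design, y = design$y) {
  vp <- var(y)
  if (vp == 0) abort("phenotypic variance is zero")
  est <- estimates$estimates
  X <- design_full_matrix(design)
  cm <- design$column_map
  cm <- cm[cm$column %in% colnames(X), ]
  est <- est[match(colnames(X), est$column), ]

  class_of <- c(a = "a", d = "d", aa = "epistasis", ad = "epistasis",
                da = "epistasis", dd = "epistasis",
                ae = "ae", de = "de",
                aae = "epistasis_e", ade = "epistasis_e",
                dae = "epistasis_e", dde = "epistasis_e")
  # group columns: one group per fixed genetic term, one per
  # (locus/pair, interaction class); mu/sex/e excluded from heritability
  genetic <- !(cm$effect %in% c("mu", "sex", "e"))
  cmg <- cm[genetic, ]
  key <- ifelse(cmg$block == "fixed", cmg$column,
                paste(cmg$block, cmg$snp1, ifelse(is.na(cmg$snp2), "", cmg$snp2),
                      sep = "|"))
  groups <- split(cmg$column, key)
  per_group <- purrr::map_dfr(groups, function(cols) {
    comp <- X[, cols, drop = FALSE] %*% est$estimate[match(cols, est$column)]
    tibble::tibble(columns = list(cols),
                   effect = cm$effect[match(cols[1], cm$column)],
                   h2 = 100 * var(drop(comp)) / vp)
  })
  # assign pooled group h2 to the first column of the group, NA to the rest
  per_term <- purrr::map_dfr(seq_len(nrow(per_group)), function(i) {
    cols <- per_group$columns[[i]]
    tibble::tibble(column = cols,
                   h2 = c(per_group$h2[i], rep(NA_real_, length(cols) - 1)))
  })
  per_group$class <- unname(class_of[per_group$effect])
  out <- per_group |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(h2 = sum(.data$h2), .groups = "drop")
  all_classes <- c("a", "d", "epistasis", "ae", "de", "epistasis_e")
  out <- dplyr::left_join(tibble::tibble(class = all_classes), out, by = "class")
  out$h2[is.na(out$h2)] <- 0
  attr(out, "per_term") <- per_term
  attr(out, "total") <- sum(out$h2)
  class(out) <- c("heritability_partition", class(out))
  out
}

#' Sum heritability class components into totals
#'
#' The additivity identity of the partition: total heritability is the exact
#' sum of the class components (for the additive model, of the additive and
#' additive-by-ethnicity components).
#'
#' @param components tibble with columns `class` and `h2` (percent).
#' @return A tibble with one row: `h2_total` plus the input classes spread
#'   into columns.
#' @export
aggregate_heritability <- function(components) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("class", "h2") %in% names(components)))
  wide <- tidyr::pivot_wider(components, names_from = "class",
                             values_from = "h2", names_prefix = "h2_")
  wide$h2_total <- sum(components$h2)
  wide
}

#' Remove phenotypic outliers by standardized residuals
#'
#' Records whose standardized residual exceeds `z_threshold` in absolute
#' value are removed; the caller is expected to refit once on the cleaned
#' table.
#'
#' @param phenotypes the phenotype tibble the residuals refer to (row order
#'   must match).
#' @param residuals residual vector from a model fit.
#' @param z_threshold absolute standardized-residual cut-off (default 3).
#' @return The filtered phenotype tibble with attribute `removed` (count).
#' @export
remove_outliers <- function(phenotypes, residuals, z_threshold = 3) {
  ph <- tibble::as_tibble(phenotypes)
  if (nrow(ph) != length(residuals)) {
    abort("`residuals` must have one value per phenotype record")
  }
  z <- (residuals - mean(residuals)) / sd(residuals)
  keep <- abs(z) <= z_threshold
  out <- ph[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}
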