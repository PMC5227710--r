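#' Repeated-simulation study of the model approaches
#'
#' Runs `n_sims` seeded simulations of a scenario and, for each requested
#' method, records which loci and effects are declared significant and the
#' estimated effects. The model approaches ("full", "additive") fit the
#' scenario's architecture with the mixed-model machinery and declare a term
#' significant when its F exceeds the simulation's permutation critical F at
#' `alpha_ew`; the "single" approach runs the per-SNP additive scan on one
#' exam with PC covariates against the Bonferroni threshold.
#'
#' Genotypes are generated once and reused across simulations (each
#' simulation redraws phenotypes with seed `base_seed + i`), matching a
#' repeated-trait design on a fixed cohort. When `extra_null_snps > 0` the
#' panel is augmented with null SNPs and each simulation re-screens the
#' panel (screen + stepwise), so false detections are possible and FDR is
#' measurable; with no extra SNPs the truth model is fitted directly and
#' only power/bias are measured.
#'
#' @param scenario a [sim_scenario()]; `sigma_e = NULL` is calibrated on the
#'   generated panel with the default anchor.
#' @param methods subset of `c("full", "additive", "single")`.
#' @param n_sims number of simulations (study default 100).
#' @param base_seed integer seed; simulation i uses `base_seed + i`.
#' @param pop a [population_model()] for the genotype panel.
#' @param settings an [engine_settings()]; Gibbs iterations apply per
#'   simulation (set 0 to skip estimates).
#' @param extra_null_snps null SNPs added to the panel (default 0).
#' @param screen_thresholds list(p1d, p2d, max_candidates, top_m) for the
#'   re-screening runs.
#' @param n_pcs PCs for the single-locus arm.
#' @return An object of class `sim_replicates`: list with `detections`
#'   (tibble: sim, method, term-level results), `truth`, `genotypes`,
#'   `seeds`.
#' @export
run_replicates <- function(scenario, methods = c("full", "additive"),
                           n_sims = 100, base_seed = 1L,
                           pop = population_model(),
                           settings = engine_settings(n_perm = 500,
                                                      gibbs_iterations = 0),
                           extra_null_snps = 0,
                           screen_thresholds = list(p1d = 1e-4, p2d = 1e-4,
                                                    max_candidates = 30,
                                                    top_m = 15),
                           n_pcs = 5) {
  methods <- match.arg(methods, c("full", "additive", "single"),
                       several.ok = TRUE)
  truth <- scenario$truth
  loci <- unique(c(truth$snp1, truth$snp2))
  loci <- loci[!is.na(loci)]
  m_truth <- length(loci)
  m_total <- m_truth + extra_null_snps
  geno <- gen_genotypes(pop, scenario$n, m_total, seed = base_seed,
                        snp_ids = c(loci, if (extra_null_snps > 0)
                          paste0("null", seq_len(extra_null_snps))))
  groups <- attr(geno, "groups")
  if (is.null(scenario$sigma_e)) {
    anchor <- truth$snp1[which.max(abs(truth$value) *
                                     (truth$effect == "a" & is.na(truth$level)))]
    scenario$sigma_e <- as.numeric(
      calibrate_residual(truth, geno, groups,
                         target = list(anchor = anchor, effect = "a", h2 = 1.46)))
  }

  rescreen <- extra_null_snps > 0
  spec_full <- spec_from_truth(truth)
  spec_add <- reduce_to_additive(spec_full)
  # fixed-panel fast path: prebuild engines once, responses vary per sim
  sexes <- NULL

  detections <- vector("list", n_sims * length(methods))
  k <- 0L
  for (i in seq_len(n_sims)) {
    seed_i <- base_seed + i
    ph <- simulate_phenotypes(scenario, geno, groups, seed = seed_i)
    for (method in methods) {
      k <- k + 1L
      if (method %in% c("full", "additive")) {
        if (rescreen) {
          scr <- screen_candidates(geno, ph,
                                   p1d = screen_thresholds$p1d,
                                   p2d = screen_thresholds$p2d,
                                   max_candidates = screen_thresholds$max_candidates,
                                   top_m = screen_thresholds$top_m)
          sp <- stepwise_build(scr, geno, ph, alpha_ew = settings$alpha_ew,
                               n_perm = settings$n_perm, seed = seed_i,
                               reduced_additive = method == "additive")
          if (nrow(sp$loci) == 0) {
            detections[[k]] <- tibble::tibble(sim = i, method = method)
            next
          }
        } else {
          sp <- if (method == "full") spec_full else spec_add
        }
        st <- settings
        st$seed <- seed_i
        fit <- fit_full_model(sp, geno, ph, st)
        rec <- fit$records[fit$records$significant, , drop = FALSE]
        est_cols <- intersect(c("estimate", "se"), names(fit$records))
        out <- fit$records[, c("term", "effect", "snp1", "snp2", "level",
                               "F", "significant", est_cols)]
        out$sim <- i
        out$method <- method
        detections[[k]] <- out
      } else {
        ph1 <- ph[ph$exam == 1, ]
        kpc <- min(n_pcs, ncol(geno$calls) - 1, length(geno$samples) - 2)
        pcs <- if (kpc >= 1) pca_covariates(geno, kpc) else NULL
        sc <- single_locus_scan(geno, ph1, covariates = pcs)
        thr <- bonferroni_threshold(sum(sc$flag == "ok"), settings$alpha_ew)
        out <- tibble::tibble(term = paste0("a_", sc$snp), effect = "a",
                              snp1 = sc$snp, snp2 = NA_character_,
                              level = NA_integer_,
                              F = NA_real_, estimate = sc$beta, se = sc$se,
                              significant = !is.na(sc$p) &
                                -log10(sc$p) > thr)
        out$sim <- i
        out$method <- method
        detections[[k]] <- out
      }
    }
  }
  structure(list(detections = dplyr::bind_rows(detections),
                 truth = truth, genotypes = geno, groups = groups,
                 scenario = scenario,
                 seeds = base_seed + seq_len(n_sims)),
            class = "sim_replicates")
}

#' Score simulation replicates: power, FDR, bias
#'
#' Per-locus power is the percent of simulations in which any term of a
#' truth locus is significant; per-effect power the percent in which the
#' specific effect (for interactions, the specific ethnic level) is
#' significant. FDR is the ratio of falsely detected loci to all detected
#' loci, averaged over simulations; the LD-adjusted FDR re-classifies a
#' detected non-truth locus as true when its genotype r-squared with a truth
#' locus exceeds `r2_match`. Bias flags compare each truth value with the
#' empirical 95% interval of its estimates across simulations: `over` when
#' the truth lies below the interval, `under` when above, else `unbiased`.
#'
#' @param reps a [run_replicates()] result.
#' @param r2_match LD threshold for the adjusted FDR (default 0.85).
#' @return An object of class `evaluation_report`: list of tibbles
#'   `per_effect`, `per_locus`, `summary`.
#' @export
score_replicates <- function(reps, r2_match = 0.85) {
  stopifnot(inherits(reps, "sim_replicates"))
  det <- reps$detections
  truth <- reps$truth
  n_sims <- length(reps$seeds)
  truth_loci <- unique(c(truth$snp1, truth$snp2))
  truth_loci <- truth_loci[!is.na(truth_loci)]

  dos <- 2 - reps$genotypes$calls
  ld_true <- function(snp) {
    if (snp %in% truth_loci) return(TRUE)
    r2 <- suppressWarnings(
      stats::cor(dos[, snp], dos[, truth_loci, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    any(r2 > r2_match, na.rm = TRUE)
  }

  truth_key <- paste(truth$snp1, truth$snp2, truth$effect, truth$level)
  per_effect <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    per_method <- purrr::map_dfr(unique(det$method), function(mth) {
      d <- det[det$method == mth & !is.na(det$effect), ]
      hit <- d$snp1 %in% r$snp1 &
        (is.na(r$snp2) & is.na(d$snp2) |
           !is.na(r$snp2) & !is.na(d$snp2) & d$snp2 %in% r$snp2) &
        d$effect == r$effect &
        (is.na(r$level) & is.na(d$level) |
           !is.na(r$level) & !is.na(d$level) & d$level %in% r$level)
      sig_sims <- unique(d$sim[hit & d$significant])
      ests <- d$estimate[hit]
      ests <- ests[!is.na(ests)]
      ci <- if (length(ests) >= 10) {
        stats::quantile(ests, c(0.025, 0.975), names = FALSE)
      } else c(NA_real_, NA_real_)
      bias <- if (anyNA(ci)) NA_character_
        else if (r$value < ci[1]) "over"
        else if (r$value > ci[2]) "under"
        else "unbiased"
      tibble::tibble(method = mth, snp1 = r$snp1, snp2 = r$snp2,
                     effect = r$effect, level = r$level, value = r$value,
                     power = 100 * length(sig_sims) / n_sims,
                     mean_estimate = if (length(ests)) mean(ests) else NA_real_,
                     ci_lo = ci[1], ci_hi = ci[2], bias = bias)
    })
    per_method
  })

  per_locus <- purrr::map_dfr(unique(det$method), function(mth) {
    d <- det[det$method == mth & !is.na(det$effect) & d_sig(det, mth), ]
    purrr::map_dfr(truth_loci, function(s) {
      hit_sims <- unique(d$sim[(d$snp1 %in% s |
                                  (!is.na(d$snp2) & d$snp2 %in% s))])
      tibble::tibble(method = mth, locus = s,
                     power = 100 * length(hit_sims) / n_sims)
    })
  })

  summary <- purrr::map_dfr(unique(det$method), function(mth) {
    d <- det[det$method == mth & !is.na(det$effect) & d_sig(det, mth), ]
    fdr_by_sim <- purrr::map_dbl(seq_len(n_sims), function(i) {
      di <- d[d$sim == i, ]
      loci_det <- unique(c(di$snp1, di$snp2[!is.na(di$snp2)]))
      if (!length(loci_det)) return(NA_real_)
      100 * sum(!(loci_det %in% truth_loci)) / length(loci_det)
    })
    fdr_adj_by_sim <- purrr::map_dbl(seq_len(n_sims), function(i) {
      di <- d[d$sim == i, ]
      loci_det <- unique(c(di$snp1, di$snp2[!is.na(di$snp2)]))
      if (!length(loci_det)) return(NA_real_)
      100 * sum(!vapply(loci_det, ld_true, logical(1))) / length(loci_det)
    })
    tibble::tibble(
      method = mth,
      mean_per_locus_power = mean(per_locus$power[per_locus$method == mth]),
      mean_per_effect_power = mean(per_effect$power[per_effect$method == mth]),
      fdr = if (all(is.na(fdr_by_sim))) NA_real_ else mean(fdr_by_sim, na.rm = TRUE),
      fdr_adjusted = if (all(is.na(fdr_adj_by_sim))) NA_real_
        else mean(fdr_adj_by_sim, na.rm = TRUE),
      mean_detections = mean(purrr::map_dbl(seq_len(n_sims), function(i) {
        di <- d[d$sim == i, ]
        length(unique(c(di$snp1, di$snp2[!is.na(di$snp2)])))
      }))
    )
  })

  structure(list(per_effect = per_effect, per_locus = per_locus,
                 summary = summary, n_sims = n_sims, r2_match = r2_match,
                 seeds = reps$seeds),
            class = "evaluation_report")
}

d_sig <- function(det, mth) {
  det$method == mth & !is.na(det$significant) & det$significant
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d simulations\n", x$n_sims))
  print(x$summary)
  invisible(x)
}

#' Scenario power study on a fixed simulated cohort
#'
#' The scaled reproduction of the simulation protocol for per-effect power:
#' synthetic genotypes for the scenario panel are generated once
#' (Balding-Nichols, MAF 0.30, FST 0.05, four groups at the cohort's
#' recruitment shares), the residual SD is calibrated so the anchor locus's
#' additive term explains its target share of phenotypic variance, and
#' `n_sims` seeded traits (two replicate records per individual) are
#' analyzed with the truth-architecture model. Per-effect power is the
#' percent of simulations in which the effect's F exceeds that simulation's
#' permutation critical F at `alpha_ew`. Because the design is fixed across
#' simulations and permutations, the engine is decomposed once, which keeps
#' the 500-permutation null affordable.
#'
#' @param scenario_tag `"I"` or `"II"`.
#' @param n individuals (default 5277).
#' @param n_sims simulations (default 50).
#' @param n_perm permutations per simulation (default 500).
#' @param alpha_ew experiment-wise level (default 0.05).
#' @param anchor_h2 target percent of variance for the anchor additive
#'   effect (default 1.46).
#' @param anchor anchor locus id (default "rs629301").
#' @param seed integer base seed.
#' @param pop population model (default MAF 0.30, FST 0.05).
#' @param batch permutations per matrix batch.
#' @return A tibble of per-effect power (%) with one row per truth effect,
#'   plus attributes `sigma_e`, `critical_F` (per-sim vector).
#' @export
scenario_power_study <- function(scenario_tag = "I", n = 5277, n_sims = 50,
                                 n_perm = 500, alpha_ew = 0.05,
                                 anchor_h2 = 1.46, anchor = "rs629301",
                                 seed = 1L, pop = population_model(),
                                 batch = 250L) {
  truth <- scenario_truth(scenario_tag)
  loci <- scenario_loci(scenario_tag)
  geno <- gen_genotypes(pop, n, length(loci), seed = seed, snp_ids = loci,
                        chr = unname(.fg_truth_chr[loci]))
  groups <- attr(geno, "groups")
  sigma_e <- as.numeric(
    calibrate_residual(truth, geno, groups,
                       target = list(anchor = anchor, effect = "a",
                                     h2 = anchor_h2)))
  scen <- sim_scenario(scenario_tag, truth = truth, sigma_e = sigma_e, n = n)
  spec <- spec_from_truth(truth)

  # one design/engine for all simulations: the genotype panel is fixed and
  # only the response changes
  ph0 <- simulate_phenotypes(scen, geno, groups, seed = seed)
  design <- build_design(geno, ph0, spec)
  engine <- fg_engine(design)
  sex0 <- design$records$sex[!duplicated(design$records$iid)]

  tn <- names(engine$terms)
  sig_count <- setNames(numeric(length(tn)), tn)
  crit <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    seed_i <- seed + i
    ph <- simulate_phenotypes(scen, geno, groups, sex = sex0, seed = seed_i)
    y <- ph$value
    ft <- engine_F(engine, y)
    null <- permutation_threshold(design, y = y, n_perm = n_perm,
                                  alpha_ew = alpha_ew, seed = seed_i,
                                  engine = engine, batch = batch)
    crit[i] <- null$critical_F
    hit <- !is.na(ft$F[, 1]) & ft$F[, 1] > null$critical_F
    sig_count[hit] <- sig_count[hit] + 1
  }

  meta <- purrr::map_dfr(engine$terms, function(t) {
    tibble::tibble(term = t$term, effect = t$effect,
                   snp1 = as.character(t$snp1 %||% NA),
                   snp2 = as.character(t$snp2 %||% NA),
                   level = as.integer(t$level %||% NA))
  })
  out <- meta
  out$power <- 100 * sig_count[out$term] / n_sims
  attr(out, "sigma_e") <- sigma_e
  attr(out, "critical_F") <- crit
  attr(out, "n_sims") <- n_sims
  out
}
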