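#' Population model for genotype simulation
#'
#' Describes a structured population of four ethnic groups with
#' group-differentiated allele frequencies under the Balding-Nichols model:
#' each group's minor-allele frequency is drawn from a Beta distribution
#' around the ancestral frequency, parameterized by FST. Optional LD blocks
#' are induced by a Gaussian copula on the latent haplotype draws.
#'
#' Defaults emulate the multi-ethnic cohort the analysis targets: group
#' shares 38/12/28/22 percent (E-A, C-A, A-A, H-A), ancestral MAF 0.30 at
#' model loci, FST 0.05.
#'
#' @param props group proportions in model order (E-A, C-A, A-A, H-A).
#' @param maf ancestral minor-allele frequency, scalar or per-SNP (in
#'   (0, 0.5]).
#' @param fst differentiation among groups (in [0, 1)).
#' @param ld_block_len consecutive SNPs per LD block (1 = independent SNPs).
#' @param ld_rho latent within-block correlation (in [0, 1)).
#' @param missing_rate fraction of calls set missing at random.
#' @return A list of class `population_model`.
#' @export
population_model <- function(props = .fg_group_props, maf = 0.30, fst = 0.05,
                             ld_block_len = 1, ld_rho = 0, missing_rate = 0) {
  if (length(props) != 4 || any(props <= 0)) abort("`props` must be 4 positive shares")
  props <- props / sum(props)
  if (any(maf <= 0 | maf > 0.5)) abort("`maf` must be in (0, 0.5]")
  .fg_assert_scalar_num(fst, "fst", 0, 1 - 1e-12)
  .fg_assert_scalar_num(ld_rho, "ld_rho", 0, 1 - 1e-12)
  .fg_assert_scalar_num(missing_rate, "missing_rate", 0, 1)
  structure(list(props = props, maf = maf, fst = fst,
                 ld_block_len = as.integer(ld_block_len), ld_rho = ld_rho,
                 missing_rate = missing_rate),
            class = "population_model")
}

#' Assign individuals to ethnic groups
#'
#' Deterministic block assignment by the model's group shares (rounded so
#' the sizes sum to `n`).
#'
#' @param model a [population_model()].
#' @param n number of individuals.
#' @return Integer vector of group codes (1-4) of length `n`.
#' @export
assign_groups <- function(model, n) {
  sizes <- floor(model$props * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- model$props * n - sizes
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  rep(1:4, times = sizes)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Group-specific minor-allele frequencies are drawn once per SNP from
#' Beta(p(1-FST)/FST, (1-p)(1-FST)/FST) around the ancestral frequency p
#' (with FST = 0 every group keeps p exactly). Genotypes are in
#' Hardy-Weinberg proportions within group. If the model requests LD blocks,
#' the two latent haplotype draws of each individual are correlated within a
#' block through a compound-symmetric Gaussian copula, giving genotype LD
#' controlled by `ld_rho`.
#'
#' @param model a [population_model()].
#' @param n number of individuals.
#' @param m_snps number of SNPs.
#' @param groups optional pre-assigned group codes (default
#'   [assign_groups()]).
#' @param seed integer seed; output is reproducible given the seed.
#' @param snp_ids,chr,pos optional SNP metadata (defaults: snp1..m on
#'   chromosome "1" at 10 kb spacing).
#' @return A [geno_matrix()]. Group codes are stored in the `groups`
#'   attribute.
#' @export
gen_genotypes <- function(model, n, m_snps, groups = NULL, seed = 1L,
                          snp_ids = NULL, chr = NULL, pos = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (n < 1 || m_snps < 1) abort("`n` and `m_snps` must be at least 1")
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(groups)) groups <- assign_groups(model, n)
  maf <- rep(model$maf, length.out = m_snps)
  fst <- model$fst
  blocks <- split(seq_len(m_snps),
                  ceiling(seq_len(m_snps) / max(1L, model$ld_block_len)))

  # per-group minor allele frequencies; SNPs of one LD block share their
  # Balding-Nichols drift draw (tight LD means shared genealogy, and
  # independent drift would dilute the within-block genotype correlation)
  q <- matrix(0, 4, m_snps)
  for (h in 1:4) {
    if (fst == 0) {
      q[h, ] <- maf
    } else {
      for (b in blocks) {
        # one drift rank per block, mapped through each SNP's Beta marginal
        u <- stats::runif(1)
        draw <- stats::qbeta(u, maf[b] * (1 - fst) / fst,
                             (1 - maf[b]) * (1 - fst) / fst)
        # keep frequencies away from fixation so loci stay polymorphic
        q[h, b] <- pmin(pmax(draw, 1e-4), 1 - 1e-4)
      }
    }
  }
  minor_count <- matrix(0L, n, m_snps)
  for (b in blocks) {
    L <- length(b)
    for (h in 1:4) {
      rows <- which(groups == h)
      if (!length(rows)) next
      qh <- q[h, b]
      r_lat <- if (L > 1 && model$ld_rho > 0) {
        .fg_latent_rho(model$ld_rho, mean(qh))
      } else 0
      for (hap in 1:2) {
        if (L > 1 && model$ld_rho > 0) {
          zc <- stats::rnorm(length(rows))
          Z <- sqrt(r_lat) * zc +
            sqrt(1 - r_lat) * matrix(stats::rnorm(length(rows) * L),
                                     length(rows), L)
        } else {
          Z <- matrix(stats::rnorm(length(rows) * L), length(rows), L)
        }
        alle <- sweep(Z, 2, stats::qnorm(qh), `<`) * 1L
        minor_count[rows, b] <- minor_count[rows, b] + alle
      }
    }
  }
  calls <- 2L - minor_count
  if (model$missing_rate > 0) {
    calls[stats::runif(length(calls)) < model$missing_rate] <- NA_integer_
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m_snps))
  if (is.null(chr)) chr <- rep("1", m_snps)
  if (is.null(pos)) pos <- 10000L * seq_len(m_snps)
  out <- geno_matrix(calls,
                     tibble::tibble(chr = chr, snp = snp_ids, pos = pos,
                                    major = "A", minor = "B"),
                     paste0("ind", seq_len(n)))
  attr(out, "groups") <- groups
  attr(out, "group_freqs") <- q
  out
}

#' Simulation scenario description
#'
#' Bundles a truth set with the generator parameters of the simulated trait:
#' population mean, sex effect, residual SD, replicate records per
#' individual, sample size.
#'
#' @param scenario `"I"` or `"II"` (selects the default truth set), or any
#'   tag when `truth` is supplied.
#' @param truth truth tibble (default [scenario_truth()] of the tag).
#' @param sigma_e residual SD in trait units; `NULL` means calibrate with
#'   [calibrate_residual()] before simulating.
#' @param mu population mean (default 200, a total-cholesterol scale).
#' @param sex_effect fixed male-female difference in trait units (default 5).
#' @param replications records per individual (default 2).
#' @param n individuals (default 5277).
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(scenario = "I", truth = NULL, sigma_e = NULL,
                         mu = 200, sex_effect = 5, replications = 2,
                         n = 5277) {
  if (is.null(truth)) truth <- scenario_truth(scenario)
  truth <- tibble::as_tibble(truth)
  if (scenario == "II" &&
      !all(truth$effect %in% c("a", "ae"))) {
    abort("scenario II truth may contain only additive (a) and ae effects")
  }
  structure(list(scenario = scenario, truth = truth, sigma_e = sigma_e,
                 mu = mu, sex_effect = sex_effect,
                 replications = as.integer(replications), n = as.integer(n)),
            class = "sim_scenario")
}

# latent Gaussian correlation reproducing a target allele-level (phi)
# correlation for threshold-dichotomized normals at frequency q: solves the
# tetrachoric relation numerically so `ld_rho` is on the interpretable
# allele-correlation scale (genotype r^2 ~ ld_rho^2)
.fg_latent_rho <- function(phi, q) {
  t <- stats::qnorm(q)
  p11_target <- q^2 + phi * q * (1 - q)
  biv <- function(r) {
    if (r >= 1) return(q)
    f <- function(z) stats::dnorm(z) * stats::pnorm((t - r * z) / sqrt(1 - r^2))
    stats::integrate(f, -Inf, t, rel.tol = 1e-9)$value
  }
  if (phi <= 0) return(0)
  stats::uniroot(function(r) biv(r) - p11_target, c(1e-6, 1 - 1e-9),
                 tol = 1e-7)$root
}

# per-individual genetic value implied by a truth set
.fg_genetic_value <- function(truth, genotypes, groups) {
  snps <- unique(c(truth$snp1, truth$snp2))
  snps <- snps[!is.na(snps)]
  missing_loci <- setdiff(snps, genotypes$snps$snp)
  if (length(missing_loci)) {
    abort(paste0("truth loci absent from genotypes: ",
                 paste(missing_loci, collapse = ", ")))
  }
  xa <- apply(genotypes$calls[, snps, drop = FALSE], 2, code_additive)
  xd <- apply(genotypes$calls[, snps, drop = FALSE], 2, code_dominance)
  if (length(snps) == 1L) {
    xa <- matrix(xa, ncol = 1, dimnames = list(NULL, snps))
    xd <- matrix(xd, ncol = 1, dimnames = list(NULL, snps))
  }
  g <- numeric(nrow(genotypes$calls))
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    coef <- switch(sub("e$", "", r$effect),
      a = xa[, r$snp1],
      d = xd[, r$snp1],
      aa = xa[, r$snp1] * xa[, r$snp2],
      ad = xa[, r$snp1] * xd[, r$snp2],
      da = xd[, r$snp1] * xa[, r$snp2],
      dd = xd[, r$snp1] * xd[, r$snp2],
      abort(paste0("unknown effect kind '", r$effect, "'")))
    if (!is.na(r$level)) coef <- coef * (groups == r$level)
    g <- g + r$value * coef
  }
  g
}

#' Simulate phenotypes from a truth set
#'
#' Builds each individual's genetic value from the truth effects and the
#' coded genotype coefficients (interaction effects activated by group
#' membership), then draws `replications` records per individual:
#' y = mu + sex effect + genetic value + independent N(0, sigma_e^2) noise
#' per record. Replicate records of an individual share the genetic value
#' and differ only in noise. Individuals with a missing genotype at a truth
#' locus are dropped and counted in the `dropped` attribute.
#'
#' @param scenario a [sim_scenario()] with `sigma_e` set.
#' @param genotypes a [geno_matrix()] containing the truth loci.
#' @param groups integer group codes per individual (default: the `groups`
#'   attribute of `genotypes`).
#' @param sex 0/1 vector per individual (default: random balanced draw).
#' @param seed integer seed.
#' @return A phenotype tibble (iid, sex, ethnicity, exam, value) with
#'   attribute `dropped`.
#' @export
simulate_phenotypes <- function(scenario, genotypes, groups = NULL,
                                sex = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(scenario$sigma_e) || scenario$sigma_e <= 0) {
    abort("`sigma_e` must be a positive number; calibrate it first")
  }
  if (is.null(groups)) groups <- attr(genotypes, "groups")
  if (is.null(groups)) abort("no group assignment available")
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(genotypes$calls)
  if (is.null(sex)) sex <- rbinom(n, 1, 0.5)

  snps <- unique(c(scenario$truth$snp1, scenario$truth$snp2))
  snps <- snps[!is.na(snps)]
  obs <- rowSums(is.na(genotypes$calls[, snps, drop = FALSE])) == 0
  dropped_ind <- sum(!obs)
  gsub <- geno_subset(genotypes, samples = genotypes$samples[obs])
  g <- .fg_genetic_value(scenario$truth, gsub, groups[obs])

  reps <- scenario$replications
  ph <- tidyr::expand_grid(idx = seq_len(sum(obs)), exam = seq_len(reps))
  ph <- tibble::tibble(
    iid = gsub$samples[ph$idx],
    sex = sex[obs][ph$idx],
    ethnicity = groups[obs][ph$idx],
    exam = ph$exam,
    value = scenario$mu + scenario$sex_effect * sex[obs][ph$idx] +
      g[ph$idx] + stats::rnorm(nrow(ph), 0, scenario$sigma_e)
  )
  attr(ph, "dropped") <- dropped_ind * reps
  ph
}

#' Calibrate the residual SD to a heritability target
#'
#' Chooses sigma_e so that either the total genetic variance share or the
#' share of one anchor effect matches a target heritability, given the
#' realized coefficient variances on the simulated genotype panel.
#'
#' @param truth truth tibble.
#' @param genotypes a [geno_matrix()].
#' @param groups group codes per individual.
#' @param target either `list(total_h2 = x)` or
#'   `list(anchor = snp_id, effect = "a", h2 = x)`, h2 in percent.
#' @return The calibrated residual SD (scalar). Attributes `v_genetic` and
#'   `v_p` carry the realized genetic variance and implied phenotypic
#'   variance.
#' @export
calibrate_residual <- function(truth, genotypes, groups,
                               target = list(anchor = "rs629301",
                                             effect = "a", h2 = 1.46)) {
  truth <- tibble::as_tibble(truth)
  g_all <- .fg_genetic_value(truth, genotypes, groups)
  v_gen <- var(g_all)
  if (!is.null(target$total_h2)) {
    h2 <- target$total_h2 / 100
    if (h2 <= 0) abort("target heritability must be positive")
    v_p <- v_gen / h2
  } else {
    h2 <- target$h2 / 100
    if (is.null(h2) || h2 <= 0) abort("target heritability must be positive")
    anchor_rows <- truth[truth$snp1 == target$anchor &
                           is.na(truth$snp2) &
                           truth$effect == (target$effect %||% "a") &
                           is.na(truth$level), ]
    if (!nrow(anchor_rows)) abort("anchor effect not found in truth set")
    g_anchor <- .fg_genetic_value(anchor_rows, genotypes, groups)
    v_p <- var(g_anchor) / h2
  }
  if (v_p <= v_gen) {
    abort("target heritability implies non-positive residual variance")
  }
  out <- sqrt(v_p - v_gen)
  attr(out, "v_genetic") <- v_gen
  attr(out, "v_p") <- v_p
  out
}
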