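#' Candidate screening by exhaustive F tests
#'
#' Two-pass filtering step that reduces the SNP panel to a candidate set for
#' model building. The 1D scan tests the additive and dominance coefficients
#' of each SNP jointly by a partial F test, adjusting for sex and ethnic
#' group means. The 2D scan takes the `top_m` SNPs by 1D score and tests the
#' four epistasis coefficients of every pair given the pair's main effects.
#' Candidates are the union of SNPs passing `p1d` and pair members passing
#' `p2d`, capped at `max_candidates` by score.
#'
#' @param genotypes a QC-passed [geno_matrix()].
#' @param phenotypes a phenotype tibble.
#' @param p1d nominal P threshold of the 1D joint a/d test (default 1e-4).
#' @param p2d nominal P threshold of the 2D epistasis test (default 1e-4).
#' @param max_candidates cap on the candidate count (>= 1).
#' @param top_m SNPs entering the pairwise scan (default 30).
#' @return An object of class `screen_result`: list with `snps` (tibble:
#'   snp, F, df1, p, score), `pairs` (tibble: snp1, snp2, F, p, score),
#'   `candidates` (character vector), `thresholds`.
#' @export
screen_candidates <- function(genotypes, phenotypes, p1d = 1e-4, p2d = 1e-4,
                              max_candidates = 50, top_m = 30) {
  if (max_candidates < 1) abort("`max_candidates` must be at least 1")
  ph <- validate_phenotypes(phenotypes)
  ungeno <- setdiff(unique(ph$iid), genotypes$samples)
  if (length(ungeno)) abort("phenotyped individuals lack genotypes")
  ridx <- match(ph$iid, genotypes$samples)
  y <- ph$value
  n <- length(y)

  # covariates: intercept, sex, ethnic-group means
  C <- cbind(1, ph$sex, outer(ph$ethnicity, 2:4, `==`) * 1)

  partial_F <- function(G, extra_adjust = NULL) {
    # F of the column group G given covariates (and optional extra columns),
    # on the records where everything is observed
    ok <- stats::complete.cases(cbind(G, extra_adjust))
    A <- cbind(C, extra_adjust)[ok, , drop = FALSE]
    qa <- qr(A)
    ys <- y[ok] - qr.fitted(qa, y[ok])
    Gr <- G[ok, , drop = FALSE] - qr.fitted(qa, G[ok, , drop = FALSE])
    qg <- qr(Gr)
    df1 <- qg$rank
    if (df1 == 0) return(list(F = NA_real_, df1 = 0L, p = 1))
    dss <- sum(qr.fitted(qg, ys)^2)
    df2 <- sum(ok) - qa$rank - df1
    Fv <- (dss / df1) / ((sum(ys^2) - dss) / df2)
    list(F = Fv, df1 = as.integer(df1),
         p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }

  snp_ids <- genotypes$snps$snp
  one_d <- purrr::map_dfr(snp_ids, function(s) {
    calls <- genotypes$calls[ridx, s]
    r <- partial_F(cbind(code_additive(calls, s), code_dominance(calls, s)))
    tibble::tibble(snp = s, F = r$F, df1 = r$df1, p = r$p)
  })
  one_d$score <- -log10(pmax(one_d$p, 1e-300))

  top <- one_d$snp[order(one_d$p)][seq_len(min(top_m, nrow(one_d)))]
  pair_grid <- if (length(top) >= 2) utils::combn(top, 2) else matrix(character(), 2, 0)
  two_d <- purrr::map_dfr(seq_len(ncol(pair_grid)), function(i) {
    s1 <- pair_grid[1, i]; s2 <- pair_grid[2, i]
    c1 <- genotypes$calls[ridx, s1]; c2 <- genotypes$calls[ridx, s2]
    xa1 <- code_additive(c1); xd1 <- code_dominance(c1)
    xa2 <- code_additive(c2); xd2 <- code_dominance(c2)
    E <- as.matrix(code_epistasis(xa1, xd1, xa2, xd2))
    M <- cbind(xa1, xd1, xa2, xd2)
    r <- partial_F(E, extra_adjust = M)
    tibble::tibble(snp1 = s1, snp2 = s2, F = r$F, p = r$p)
  })
  if (nrow(two_d)) two_d$score <- -log10(pmax(two_d$p, 1e-300))

  hit1 <- one_d[!is.na(one_d$p) & one_d$p < p1d, ]
  hitp <- if (nrow(two_d)) two_d[!is.na(two_d$p) & two_d$p < p2d, ] else two_d
  cand_scores <- c(setNames(hit1$score, hit1$snp),
                   setNames(hitp$score, hitp$snp1),
                   setNames(hitp$score, hitp$snp2))
  cand_scores <- sort(tapply(cand_scores, names(cand_scores), max), decreasing = TRUE)
  candidates <- names(cand_scores)[seq_len(min(max_candidates, length(cand_scores)))]

  structure(list(snps = one_d, pairs = two_d,
                 candidate_pairs = hitp[hitp$snp1 %in% candidates &
                                          hitp$snp2 %in% candidates, , drop = FALSE],
                 candidates = candidates,
                 thresholds = list(p1d = p1d, p2d = p2d,
                                   max_candidates = max_candidates, top_m = top_m)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d candidate SNPs, %d candidate pairs (p1d < %g, p2d < %g)\n",
              length(x$candidates), nrow(x$candidate_pairs),
              x$thresholds$p1d, x$thresholds$p2d))
  invisible(x)
}

#' Stepwise construction of the optimum model
#'
#' Forward selection over the screened candidates: each round the candidate
#' term group (a/d mains of a locus, or the epistasis terms of a candidate
#' pair) with the largest conditional F enters if its nominal P passes the
#' entry gate; aliased candidates (zero added rank, e.g. a duplicate SNP in
#' complete LD) never enter. After selection the assembled model is
#' calibrated against the permutation null and only experiment-wise
#' significant loci/pairs are kept (backward elimination at `alpha_ew`).
#' Ties in F are broken by genome order (chromosome, then position).
#'
#' @param candidates a [screen_candidates()] result.
#' @param genotypes,phenotypes data as in [fit_full_model()].
#' @param alpha_ew experiment-wise level for the final backward step.
#' @param n_perm permutations for the final calibration.
#' @param enter_p nominal P gate for forward entry (default 1e-3).
#' @param max_terms cap on forward rounds.
#' @param seed integer seed (permutation null).
#' @param reduced_additive select under the reduced additive model
#'   (candidate loci enter by their additive term only; no pairs).
#' @return A [model_spec()] containing the selected loci and pairs (possibly
#'   empty).
#' @export
stepwise_build <- function(candidates, genotypes, phenotypes,
                           alpha_ew = 0.05, n_perm = 500, enter_p = 1e-3,
                           max_terms = 20, seed = 1L,
                           reduced_additive = FALSE) {
  stopifnot(inherits(candidates, "screen_result"))
  if (length(candidates$candidates) == 0) {
    return(model_spec(tibble::tibble(snp = character(), terms = list())))
  }
  if (alpha_ew <= 0) {
    return(model_spec(tibble::tibble(snp = character(), terms = list())))
  }
  geno_order <- genotypes$snps
  ord_key <- function(s) {
    i <- match(s, geno_order$snp)
    as.numeric(geno_order$pos[i]) + 1e9 * as.numeric(factor(geno_order$chr[i]))
  }

  in_loci <- character()
  in_pairs <- candidates$candidate_pairs[0, c("snp1", "snp2")]
  pool_loci <- candidates$candidates
  pool_pairs <- candidates$candidate_pairs[, c("snp1", "snp2")]

  main_terms <- if (reduced_additive) "a" else c("a", "d")
  rand_cls <- if (reduced_additive) c("e", "ae") else c("e", "ae", "de")
  make_spec <- function(loci, pairs) {
    if (length(loci) == 0) return(NULL)
    pr <- NULL
    if (!reduced_additive && nrow(pairs)) {
      pr <- tibble::tibble(snp1 = pairs$snp1, snp2 = pairs$snp2,
                           terms = replicate(nrow(pairs),
                                             c("aa", "ad", "da", "dd"),
                                             simplify = FALSE))
    }
    model_spec(tibble::tibble(snp = loci,
                              terms = replicate(length(loci), main_terms,
                                                simplify = FALSE)),
               pr, random_classes = rand_cls,
               reduced_additive = reduced_additive)
  }

  current_F <- function(loci, pairs) {
    sp <- make_spec(loci, pairs)
    design <- build_design(genotypes, phenotypes, sp)
    term_F(design)
  }

  for (round in seq_len(max_terms)) {
    best <- NULL
    # candidate loci
    for (s in setdiff(pool_loci, in_loci)) {
      ft <- tryCatch(current_F(c(in_loci, s), in_pairs), error = function(e) NULL)
      if (is.null(ft)) next
      fr <- ft[!is.na(ft$snp1) & ft$snp1 == s & is.na(ft$snp2) &
                 ft$effect %in% c("a", "d"), ]
      if (!nrow(fr) || all(is.na(fr$F))) next   # aliased with current model
      fmax <- max(fr$F, na.rm = TRUE)
      df1 <- sum(fr$df[!is.na(fr$F)])
      key <- list(type = "locus", id = s, F = fmax, ord = ord_key(s))
      if (is.null(best) || fmax > best$F ||
          (fmax == best$F && key$ord < best$ord)) best <- key
    }
    # candidate pairs (both members must already be in the model)
    if (!reduced_additive && nrow(pool_pairs)) {
      for (i in seq_len(nrow(pool_pairs))) {
        s1 <- pool_pairs$snp1[i]; s2 <- pool_pairs$snp2[i]
        if (!(s1 %in% in_loci && s2 %in% in_loci)) next
        if (any(in_pairs$snp1 == s1 & in_pairs$snp2 == s2)) next
        ft <- tryCatch(current_F(in_loci, dplyr::bind_rows(in_pairs,
                                   tibble::tibble(snp1 = s1, snp2 = s2))),
                       error = function(e) NULL)
        if (is.null(ft)) next
        fr <- ft[!is.na(ft$snp2) & ft$snp1 == s1 & ft$snp2 == s2 &
                   ft$effect %in% c("aa", "ad", "da", "dd"), ]
        if (!nrow(fr) || all(is.na(fr$F))) next
        fmax <- max(fr$F, na.rm = TRUE)
        key <- list(type = "pair", id = c(s1, s2), F = fmax, ord = ord_key(s1))
        if (is.null(best) || fmax > best$F ||
            (fmax == best$F && key$ord < best$ord)) best <- key
      }
    }
    if (is.null(best)) break
    # entry gate on the nominal P of the best candidate's strongest term
    sp_try <- if (best$type == "locus") {
      make_spec(c(in_loci, best$id), in_pairs)
    } else {
      make_spec(in_loci, dplyr::bind_rows(in_pairs,
                  tibble::tibble(snp1 = best$id[1], snp2 = best$id[2])))
    }
    design <- build_design(genotypes, phenotypes, sp_try)
    engine <- fg_engine(design)
    ft <- term_F(design, engine = engine)
    p_nom <- stats::pf(best$F, 1, engine$df_res, lower.tail = FALSE)
    if (is.na(p_nom) || p_nom >= enter_p) break
    if (best$type == "locus") in_loci <- c(in_loci, best$id)
    else in_pairs <- dplyr::bind_rows(in_pairs,
                                      tibble::tibble(snp1 = best$id[1],
                                                     snp2 = best$id[2]))
  }

  if (length(in_loci) == 0) {
    return(model_spec(tibble::tibble(snp = character(), terms = list())))
  }

  # backward elimination: keep loci/pairs with at least one experiment-wise
  # significant term under the permutation null
  repeat {
    sp <- make_spec(in_loci, in_pairs)
    design <- build_design(genotypes, phenotypes, sp)
    engine <- fg_engine(design)
    ft <- term_F(design, engine = engine)
    null <- permutation_threshold(design, n_perm = n_perm, alpha_ew = alpha_ew,
                                  seed = seed, engine = engine)
    sig <- ft[!is.na(ft$F) & ft$F > null$critical_F, ]
    keep_pairs <- in_pairs[paste(in_pairs$snp1, in_pairs$snp2) %in%
                             paste(sig$snp1, sig$snp2)[!is.na(sig$snp2)], ,
                           drop = FALSE]
    keep_loci <- unique(c(sig$snp1[is.na(sig$snp2)],
                          keep_pairs$snp1, keep_pairs$snp2))
    keep_loci <- keep_loci[!is.na(keep_loci)]
    if (length(keep_loci) == length(in_loci) &&
        nrow(keep_pairs) == nrow(in_pairs)) break
    in_loci <- keep_loci
    in_pairs <- keep_pairs
    if (length(in_loci) == 0) {
      return(model_spec(tibble::tibble(snp = character(), terms = list())))
    }
  }
  make_spec(in_loci, in_pairs)
}
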