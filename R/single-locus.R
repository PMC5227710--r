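#' Principal-component covariates for stratification control
#'
#' Top principal components of the centered, standardized genotype matrix
#' (minor-allele dosage; missing calls mean-imputed per SNP). Deterministic
#' up to column sign.
#'
#' @param genotypes a [geno_matrix()].
#' @param k number of components (>= 1, <= rank of the matrix).
#' @return Matrix of per-individual scores (individuals x k), rownames =
#'   sample ids.
#' @export
pca_covariates <- function(genotypes, k = 10) {
  if (k < 1) abort("`k` must be at least 1")
  dos <- 2 - genotypes$calls            # minor-allele dosage
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]
  s <- apply(dos, 2, stats::sd)
  keep <- s > 0
  Z <- scale(dos[, keep, drop = FALSE])
  sv <- svd(Z, nu = min(nrow(Z), ncol(Z)), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) abort(sprintf("`k` = %d exceeds the matrix rank (%d)", k, rank))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- genotypes$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Single-locus additive association scan
#'
#' Per-SNP least-squares regression of the trait on the minor-allele dosage
#' (0/1/2) plus covariates, one phenotype record per individual (a single
#' examination; the single-locus baseline cannot use replicate records).
#' Note the dosage coding differs from the full model's \{1, 0, -1\}
#' major-allele coding: the sign convention of `beta` is per minor allele.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes phenotype tibble restricted to one exam (one record per
#'   individual).
#' @param covariates matrix of per-individual covariates (e.g.
#'   [pca_covariates()] scores), rownames = sample ids, or `NULL`.
#' @param include_sex add sex from the phenotype table as a covariate.
#' @return An object of class `scan_result`: tibble with columns `snp`,
#'   `chr`, `pos`, `beta`, `se`, `p`, `flag` and attributes `lambda_gc`,
#'   `covariate_set`.
#' @export
single_locus_scan <- function(genotypes, phenotypes, covariates = NULL,
                              include_sex = TRUE) {
  ph <- validate_phenotypes(phenotypes)
  if (anyDuplicated(ph$iid)) {
    abort("single-locus scan needs one record per individual; filter to one exam")
  }
  ridx <- match(ph$iid, genotypes$samples)
  if (anyNA(ridx)) abort("phenotyped individuals lack genotypes")
  y <- ph$value
  n <- length(y)
  C <- matrix(1, n, 1)
  cov_desc <- "intercept"
  if (include_sex) {
    C <- cbind(C, ph$sex)
    cov_desc <- c(cov_desc, "sex")
  }
  if (!is.null(covariates)) {
    C <- cbind(C, covariates[match(ph$iid, rownames(covariates)), , drop = FALSE])
    cov_desc <- c(cov_desc, colnames(covariates))
  }
  qc <- qr(C)
  ry <- y - qr.fitted(qc, y)
  dos <- 2 - genotypes$calls[ridx, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    ok <- !is.na(g)
    if (all(ok)) {
      rg <- g - qr.fitted(qc, g)
      yr <- ry
      df2 <- n - qc$rank - 1
    } else {
      qs <- qr(C[ok, , drop = FALSE])
      rg <- g[ok] - qr.fitted(qs, g[ok])
      yr <- y[ok] - qr.fitted(qs, y[ok])
      df2 <- sum(ok) - qs$rank - 1
    }
    sgg <- sum(rg^2)
    if (sgg < 1e-10 * max(1, sum(!is.na(g)))) {
      flag <- if (stats::var(g, na.rm = TRUE) == 0) "monomorphic" else "aliased"
      return(tibble::tibble(beta = NA_real_, se = NA_real_,
                            p = if (flag == "monomorphic") 1 else NA_real_,
                            flag = flag))
    }
    beta <- sum(rg * yr) / sgg
    rss <- sum(yr^2) - beta^2 * sgg
    se <- sqrt(rss / df2 / sgg)
    tstat <- beta / se
    tibble::tibble(beta = beta, se = se,
                   p = 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE),
                   flag = "ok")
  })
  out <- dplyr::bind_cols(genotypes$snps[, c("snp", "chr", "pos")], res)
  attr(out, "lambda_gc") <- lambda_gc(out$p[out$flag == "ok"])
  attr(out, "covariate_set") <- cov_desc
  class(out) <- c("scan_result", class(out))
  out
}

#' Genomic inflation factor
#'
#' Lambda_GC: the median of the chi-square(1) quantile transform of the scan
#' P values divided by the null median 0.4549364. Values near 1 indicate
#' controlled population stratification.
#'
#' @param pvalues numeric vector of P values in (0, 1].
#' @return The scalar inflation factor.
#' @export
lambda_gc <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) return(NA_real_)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Greedy sliding-window LD pruning
#'
#' Mimics PLINK's `--indep-pairwise`: within each window of `window_snps`
#' consecutive SNPs, while any retained pair has squared dosage correlation
#' above `r2_max`, the member with the lower minor-allele frequency is
#' dropped (ties: the later genome position); the window then advances by
#' `step` SNPs. Pruning the pruned panel again changes nothing.
#'
#' @param genotypes a [geno_matrix()].
#' @param window_snps window size in SNPs (default 50).
#' @param step window step in SNPs (default 5; must not exceed the window).
#' @param r2_max maximum pairwise r-squared retained (default 0.75).
#' @return Character vector of retained SNP ids, in genome order.
#' @export
ld_prune <- function(genotypes, window_snps = 50, step = 5, r2_max = 0.75) {
  if (window_snps < step) abort("`window_snps` must be >= `step`")
  m <- ncol(genotypes$calls)
  dos <- 2 - genotypes$calls
  maf <- geno_stats(genotypes)$maf
  pos <- genotypes$snps$pos
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window_snps - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1) {
      repeat {
        cc <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        cc[!is.finite(cc)] <- 0
        diag(cc) <- 0
        r2 <- cc^2
        mx <- max(r2)
        if (mx <= r2_max) break
        w <- which(r2 == mx, arr.ind = TRUE)[1, ]
        i1 <- idx[w[1]]; i2 <- idx[w[2]]
        drop <- if (maf[i1] < maf[i2]) i1
          else if (maf[i2] < maf[i1]) i2
          else if (pos[i1] >= pos[i2]) i1 else i2
        keep[drop] <- FALSE
        idx <- setdiff(idx, drop)
        if (length(idx) < 2) break
      }
    }
    if (end >= m) break
    start <- start + step
  }
  genotypes$snps$snp[keep]
}

#' Bonferroni genome-wide significance threshold
#'
#' `-log10(alpha / n_tests)`; displayed to two decimals.
#'
#' @param n_tests number of (approximately independent) tests.
#' @param alpha family-wise error level (default 0.05).
#' @return The threshold on the -log10 P scale (full precision; round to two
#'   decimals for display).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1 || alpha <= 0 || alpha > 1) abort("invalid arguments")
  -log10(alpha / n_tests)
}
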