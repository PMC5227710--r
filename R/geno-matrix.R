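#' Genotype matrix container
#'
#' Holds biallelic SNP calls for a set of individuals as counts of the
#' *major* allele (2 = major homozygote QQ, 1 = heterozygote Qq,
#' 0 = minor homozygote qq, `NA` = missing), together with per-SNP metadata.
#' The major/minor orientation is the reference frame for all effect codings:
#' the additive coefficient is +1 for the major homozygote.
#'
#' @param calls integer matrix, individuals in rows and SNPs in columns,
#'   values in \{0, 1, 2, NA\}.
#' @param snps tibble with columns `chr`, `snp`, `pos`, `major`, `minor`
#'   (one row per column of `calls`).
#' @param samples character vector of individual ids (one per row of `calls`).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, snps, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  samples <- as.character(samples)
  snps <- tibble::as_tibble(snps)
  need <- c("chr", "snp", "pos", "major", "minor")
  if (!all(need %in% names(snps))) {
    abort(paste0("`snps` must have columns ", paste(need, collapse = ", ")))
  }
  if (nrow(snps) != ncol(calls)) abort("`snps` rows must match `calls` columns")
  if (length(samples) != nrow(calls)) abort("`samples` must match `calls` rows")
  if (anyDuplicated(snps$snp)) abort("SNP ids must be unique")
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, 2]
    abort(sprintf("invalid genotype call at SNP '%s': calls must be 0/1/2/NA",
                  snps$snp[j]))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples, snps$snp)
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs (%.1f%% missing)\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$calls))))
  print(utils::head(x$snps, 5))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by SNP ids and/or sample ids
#'
#' @param x a [geno_matrix()].
#' @param snps character vector of SNP ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return A `geno_matrix` restricted to the requested SNPs/samples.
#' @export
geno_subset <- function(x, snps = NULL, samples = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  j <- if (is.null(snps)) seq_len(ncol(x$calls)) else {
    miss <- setdiff(snps, x$snps$snp)
    if (length(miss)) abort(paste0("unknown SNP id(s): ", paste(miss, collapse = ", ")))
    match(snps, x$snps$snp)
  }
  i <- if (is.null(samples)) seq_len(nrow(x$calls)) else {
    miss <- setdiff(samples, x$samples)
    if (length(miss)) abort(paste0("unknown sample id(s): ", paste(miss, collapse = ", ")))
    match(samples, x$samples)
  }
  geno_matrix(x$calls[i, j, drop = FALSE], x$snps[j, ], x$samples[i])
}

#' Per-SNP summary statistics
#'
#' Minor-allele frequency (folded: always the rarer allele in-sample) and
#' call rate per SNP.
#'
#' @param x a [geno_matrix()].
#' @return A tibble with columns `snp`, `maf`, `call_rate`, `freq_major`.
#' @export
geno_stats <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  n_obs <- colSums(!is.na(x$calls))
  freq_major <- colMeans(x$calls, na.rm = TRUE) / 2
  freq_major[n_obs == 0] <- NA_real_
  tibble::tibble(
    snp = x$snps$snp,
    freq_major = freq_major,
    maf = pmin(freq_major, 1 - freq_major),
    call_rate = n_obs / nrow(x$calls)
  )
}

#' Quality-control filter for SNPs
#'
#' Removes SNPs with minor-allele frequency below `maf_min` or call rate
#' below `call_rate_min`. Exclusion is strict (`<`), so SNPs exactly at a
#' threshold are retained. No Hardy-Weinberg filter is applied: in a
#' heterogeneous multi-ethnic sample HWE fails by construction.
#'
#' @param x a [geno_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param call_rate_min minimum call rate (default 0.90).
#' @return The filtered `geno_matrix`, with a `qc_report` attribute: a tibble
#'   counting SNPs removed per criterion.
#' @export
qc_filter <- function(x, maf_min = 0.05, call_rate_min = 0.90) {
  .fg_assert_scalar_num(maf_min, "maf_min", 0, 1)
  .fg_assert_scalar_num(call_rate_min, "call_rate_min", 0, 1)
  st <- geno_stats(x)
  fail_maf <- is.na(st$maf) | st$maf < maf_min
  fail_cr <- st$call_rate < call_rate_min
  keep <- !(fail_maf | fail_cr)
  if (!any(keep)) warn("qc_filter removed every SNP")
  report <- tibble::tibble(
    criterion = c("maf", "call_rate", "either", "retained"),
    n = c(sum(fail_maf), sum(fail_cr), sum(!keep), sum(keep))
  )
  out <- geno_matrix(x$calls[, keep, drop = FALSE], x$snps[keep, ], x$samples)
  attr(out, "qc_report") <- report
  out
}
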