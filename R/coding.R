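#' Additive effect coding
#'
#' Maps major-allele counts to the additive coefficient: 1 for the major
#' homozygote QQ, 0 for the heterozygote Qq, -1 for the minor homozygote qq.
#' Missing calls propagate.
#'
#' @param calls integer vector of major-allele counts in \{0, 1, 2, NA\}.
#' @param snp optional SNP id used in error messages.
#' @return Numeric vector of coefficients in \{1, 0, -1, NA\}.
#' @export
code_additive <- function(calls, snp = NULL) {
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) {
    abort(sprintf("invalid genotype value%s while coding additive effect",
                  if (is.null(snp)) "" else paste0(" at SNP '", snp, "'")))
  }
  as.numeric(calls) - 1
}

#' Dominance effect coding
#'
#' 1 for the heterozygote Qq, 0 for both homozygotes. Missing propagates.
#'
#' @inheritParams code_additive
#' @return Numeric vector of coefficients in \{1, 0, NA\}.
#' @export
code_dominance <- function(calls, snp = NULL) {
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) {
    abort(sprintf("invalid genotype value%s while coding dominance effect",
                  if (is.null(snp)) "" else paste0(" at SNP '", snp, "'")))
  }
  as.numeric(calls == 1L)
}

#' Digenic epistasis effect coding
#'
#' The four epistasis coefficients of a locus pair are the products of the
#' single-locus additive/dominance codings: aa = x_a^i x_a^j,
#' ad = x_a^i x_d^j, da = x_d^i x_a^j, dd = x_d^i x_d^j. So, for example,
#' aa is 1 for QQxQQ and qqxqq, -1 for QQxqq and qqxQQ, 0 otherwise, and dd
#' is 1 only for QqxQq. A missing genotype at either locus makes all four
#' coefficients missing.
#'
#' @param xa_i,xd_i additive and dominance codings at the first locus.
#' @param xa_j,xd_j additive and dominance codings at the second locus.
#' @return A tibble with columns `aa`, `ad`, `da`, `dd`.
#' @export
code_epistasis <- function(xa_i, xd_i, xa_j, xd_j) {
  n <- length(xa_i)
  stopifnot(length(xd_i) == n, length(xa_j) == n, length(xd_j) == n)
  miss <- is.na(xa_i) | is.na(xd_i) | is.na(xa_j) | is.na(xd_j)
  out <- tibble::tibble(
    aa = xa_i * xa_j,
    ad = xa_i * xd_j,
    da = xd_i * xa_j,
    dd = xd_i * xd_j
  )
  out[miss, ] <- NA_real_
  out
}
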