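#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted genetic model
#'
#' One row per tested term: the QTS-table view of the fit (effect kind,
#' estimate, SE, F, -log10 experiment-wise P, pooled locus-class h2).
#'
#' @param x a `qts_fit` from [fit_full_model()] or [fit_additive_model()].
#' @param significant_only keep only experiment-wise significant terms.
#' @param ... unused.
#' @return A tibble.
#' @method tidy qts_fit
#' @export
tidy.qts_fit <- function(x, significant_only = FALSE, ...) {
  out <- tibble::as_tibble(x$records)
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  out
}

#' One-line model summary
#'
#' Heritability class totals, residual variance, permutation critical F and
#' counts of significant terms.
#'
#' @param x a `qts_fit`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance qts_fit
#' @export
glance.qts_fit <- function(x, ...) {
  h <- x$heritability
  base <- tibble::tibble(
    n_records = length(x$design$y),
    n_terms = nrow(x$records),
    n_significant = sum(x$records$significant, na.rm = TRUE),
    critical_F = x$null$critical_F,
    alpha_ew = x$settings$alpha_ew,
    sigma2_residual = x$varcomp$variance[x$varcomp$component == "residual"]
  )
  if (!is.null(h)) {
    wide <- aggregate_heritability(h[, c("class", "h2")])
    base <- dplyr::bind_cols(base, wide)
  }
  base
}

#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) tibble::as_tibble(x)

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$per_effect

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) x$summary

#' Export a fit's significant terms as a QTS table TSV
#'
#' Columns follow the association-table layout: locus (or pair), effect,
#' estimate, SE, -log10 experiment-wise P, h2 (%).
#'
#' @param fit a `qts_fit`.
#' @param path output TSV path.
#' @param significant_only write only experiment-wise significant terms
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_qts_table <- function(fit, path, significant_only = TRUE) {
  td <- tidy(fit, significant_only = significant_only)
  cols <- intersect(c("term", "snp1", "snp2", "effect", "level", "estimate",
                      "se", "F", "neglog10_p_ew", "h2"), names(td))
  readr::write_tsv(td[, cols], path, progress = FALSE)
  invisible(path)
}
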