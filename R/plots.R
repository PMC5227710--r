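#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_errorbar
#'   geom_hline labs facet_wrap theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Forest plot of fitted genetic effects
#'
#' Estimates with +/- 2 SE bars for every (significant) term of a fit.
#'
#' @param object a `qts_fit`.
#' @param significant_only plot only experiment-wise significant terms.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot qts_fit
#' @export
autoplot.qts_fit <- function(object, significant_only = TRUE, ...) {
  td <- tidy(object, significant_only = significant_only)
  if (!"estimate" %in% names(td)) {
    abort("fit has no effect estimates (Gibbs iterations were 0)")
  }
  td <- td[!is.na(td$estimate), ]
  ggplot(td, aes(x = .data$estimate, y = .data$term)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$estimate - 2 * .data$se,
                      xmax = .data$estimate + 2 * .data$se), width = 0.2) +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "estimate (trait units)", y = NULL,
         title = "Estimated genetic effects (+/- 2 SE)") +
    theme_minimal()
}

#' Manhattan-style plot of a single-locus scan
#'
#' @param object a `scan_result` from [single_locus_scan()].
#' @param threshold optional -log10 P threshold line (e.g.
#'   [bonferroni_threshold()]).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$p), ]
  df$neglog10_p <- -log10(pmax(df$p, 1e-300))
  p <- ggplot(df, aes(x = .data$pos, y = .data$neglog10_p,
                      colour = .data$chr)) +
    geom_point(size = 0.8) +
    labs(x = "position (bp)", y = expression(-log[10](P)),
         title = "Single-locus additive scan") +
    theme_minimal()
  if (!is.null(threshold)) p <- p + geom_hline(yintercept = threshold,
                                               linetype = 2)
  p
}

#' Power comparison plot across methods
#'
#' Per-effect detection power by method from an evaluation report.
#'
#' @param object an `evaluation_report` from [score_replicates()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  pe <- object$per_effect
  pe$label <- paste0(pe$snp1,
                     ifelse(is.na(pe$snp2), "", paste0("x", pe$snp2)),
                     ":", pe$effect,
                     ifelse(is.na(pe$level), "", paste0("_", pe$level)))
  ggplot(pe, aes(x = .data$label, y = .data$power, fill = .data$method)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "detection power (%)",
         title = "Per-effect detection power") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
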