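#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats var sd quantile rnorm rgamma runif median qchisq pchisq qf pf
#' @importFrom stats complete.cases setNames qnorm pnorm rbinom prcomp cor
#' @importFrom utils head tail
NULL

# ethnic group labels, in model order 1..4
.fg_groups <- c("E-A", "C-A", "A-A", "H-A")

# recruitment shares of the four groups (E-A, C-A, A-A, H-A)
.fg_group_props <- c(0.38, 0.12, 0.28, 0.22)

.fg_assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# empirical upper quantile by order statistic: smallest x with
# F_hat(x) >= 1 - alpha; alpha = 1 returns the minimum
.fg_upper_quantile <- function(x, alpha) {
  s <- sort(x)
  k <- max(1L, ceiling((1 - alpha) * length(s)))
  s[k]
}
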