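#' Gibbs-sampling estimation of the mixed-model effects
#'
#' Standard Bayesian linear mixed-model sweep: fixed effects are drawn from
#' their conditional normal under a flat prior, each random-class level
#' vector from its conditional normal given its class variance, and every
#' variance (class variances and the residual) from its conditional
#' inverse-gamma with a diffuse IG(0.001, 0.001) prior. Posterior means and
#' standard deviations after burn-in and thinning are reported. All
#' conditionals are computed from precomputed cross-products, so iteration
#' cost does not grow with the number of records.
#'
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the design's trait values).
#' @param iterations total Gibbs iterations (study default 20000).
#' @param burn_in iterations discarded (default 2000).
#' @param thinning keep every `thinning`-th draw (default 1).
#' @param seed integer seed; chains are reproducible given the seed.
#' @param prior inverse-gamma shape/rate for all variances (default 0.001).
#' @return An object of class `effect_estimates`: list with `estimates`
#'   (tibble: column, block, effect, snp1, snp2, level, estimate, se),
#'   `varcomp` (a `variance_components` tibble, method `"gibbs"`), and
#'   `settings`.
#' @export
gibbs_estimate <- function(design, y = design$y, iterations = 20000,
                           burn_in = 2000, thinning = 1, seed = 1L,
                           prior = 0.001) {
  if (var(y) == 0) abort("response has zero variance: degenerate input")
  if (iterations <= burn_in) abort("`iterations` must exceed `burn_in`")

  W <- design$fixed
  qw <- qr(W)
  dropped_fixed <- character()
  if (qw$rank < ncol(W)) {
    keep <- qw$pivot[seq_len(qw$rank)]
    dropped_fixed <- colnames(W)[-keep]
    warn(paste0("dropping aliased fixed column(s): ",
                paste(dropped_fixed, collapse = ", ")))
    W <- W[, sort(keep), drop = FALSE]
  }
  blocks <- design$random
  X <- do.call(cbind, c(list(W), unname(blocks)))
  p <- ncol(X)
  n <- nrow(X)
  idx_fixed <- seq_len(ncol(W))
  idx_blocks <- list()
  off <- ncol(W)
  for (cls in names(blocks)) {
    idx_blocks[[cls]] <- off + seq_len(ncol(blocks[[cls]]))
    off <- off + ncol(blocks[[cls]])
  }

  C <- crossprod(X)
  cy <- drop(crossprod(X, y))
  yy <- sum(y^2)
  Rff <- chol(C[idx_fixed, idx_fixed, drop = FALSE] +
                diag(1e-10, length(idx_fixed)))

  set.seed(as.integer(seed %% .Machine$integer.max))
  theta <- numeric(p)
  g <- numeric(p)                      # g = C theta, kept incrementally
  s2e <- var(y) / 2
  s2v <- setNames(rep(var(y) / (2 * max(1, length(blocks))), length(blocks)),
                  names(blocks))
  a0 <- b0 <- prior

  upd <- function(idx, new) {
    delta <- new - theta[idx]
    g <<- g + drop(C[, idx, drop = FALSE] %*% delta)
    theta[idx] <<- new
  }

  n_keep <- floor((iterations - burn_in) / thinning)
  sum1 <- numeric(p); sum2 <- numeric(p)
  vs1 <- numeric(length(blocks) + 1); vs2 <- numeric(length(blocks) + 1)
  kept <- 0L

  for (it in seq_len(iterations)) {
    # fixed block
    rhs <- cy[idx_fixed] - (g[idx_fixed] - drop(C[idx_fixed, idx_fixed, drop = FALSE] %*% theta[idx_fixed]))
    m <- backsolve(Rff, backsolve(Rff, rhs, transpose = TRUE))
    bdraw <- m + sqrt(s2e) * backsolve(Rff, rnorm(length(idx_fixed)))
    upd(idx_fixed, bdraw)

    for (cls in names(blocks)) {
      idx <- idx_blocks[[cls]]
      Cvv <- C[idx, idx, drop = FALSE]
      A <- Cvv / s2e + diag(1 / s2v[[cls]], length(idx))
      Ra <- chol(A)
      rhs <- (cy[idx] - (g[idx] - drop(Cvv %*% theta[idx]))) / s2e
      m <- backsolve(Ra, backsolve(Ra, rhs, transpose = TRUE))
      u <- m + backsolve(Ra, rnorm(length(idx)))
      upd(idx, u)
      s2v[[cls]] <- 1 / rgamma(1, a0 + length(idx) / 2,
                               rate = b0 + sum(u^2) / 2)
    }

    rssq <- max(yy - 2 * sum(theta * cy) + sum(theta * g), 1e-12)
    s2e <- 1 / rgamma(1, a0 + n / 2, rate = b0 + rssq / 2)

    if (!all(is.finite(theta)) || !is.finite(s2e)) {
      abort(sprintf("divergent Gibbs chain at iteration %d", it))
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0) {
      kept <- kept + 1L
      sum1 <- sum1 + theta; sum2 <- sum2 + theta^2
      vv <- c(unlist(s2v), s2e)
      vs1 <- vs1 + vv; vs2 <- vs2 + vv^2
    }
  }

  post_mean <- sum1 / kept
  post_sd <- sqrt(pmax(sum2 / kept - post_mean^2, 0))
  cm <- design$column_map
  est <- tibble::tibble(column = colnames(X),
                        estimate = post_mean, se = post_sd)
  est <- dplyr::left_join(est, cm, by = "column")
  v_mean <- vs1 / kept
  v_sd <- sqrt(pmax(vs2 / kept - v_mean^2, 0))
  varcomp <- tibble::tibble(component = c(names(blocks), "residual"),
                            variance = v_mean, se = v_sd,
                            truncated = FALSE)
  attr(varcomp, "method") <- "gibbs"
  class(varcomp) <- c("variance_components", class(varcomp))
  structure(list(estimates = est, varcomp = varcomp,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thinning = thinning, seed = seed,
                                 n_kept = kept, dropped_fixed = dropped_fixed)),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("<effect_estimates> %d columns, %d kept draws (seed %s)\n",
              nrow(x$estimates), x$settings$n_kept, x$settings$seed))
  invisible(x)
}
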