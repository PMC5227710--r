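#' Permutation null of the maximum F statistic and experiment-wise threshold
#'
#' Builds the experiment-wise null by permuting the response against the
#' genetic design and recording, for each permutation, the maximum F over all
#' tested terms. The permutation unit is the individual: both replicate
#' records of an individual move together (individuals are permuted within
#' strata of equal record count). Non-genetic structure (intercept, sex,
#' ethnic means) is preserved Freedman-Lane style: residuals from the
#' non-genetic fit are permuted and the non-genetic fitted values added back,
#' so the design matrix is fixed across permutations and the null is computed
#' from a single decomposition.
#'
#' The critical F is the empirical (1 - alpha_ew) quantile of the max-F
#' samples. A generalized Pareto distribution fitted to the upper tail is
#' stored so that experiment-wise P values beyond the permutation resolution
#' can be extrapolated (see [experimentwise_p()]).
#'
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the design's trait values).
#' @param n_perm number of permutations (>= 100; the study default is 2000).
#' @param alpha_ew experiment-wise type-I error level (default 0.05).
#' @param seed integer seed; the null is reproducible given the seed.
#' @param engine optionally a prebuilt internal engine (reused across calls).
#' @param batch permutations per matrix batch (memory/speed trade-off).
#' @return An object of class `permutation_null`: list with `max_F`
#'   (n_perm samples), `critical_F`, `alpha_ew`, `n_perm`, `tail`
#'   (generalized Pareto fit), `seed`.
#' @export
permutation_threshold <- function(design, y = design$y, n_perm = 2000,
                                  alpha_ew = 0.05, seed = 1L,
                                  engine = NULL, batch = 250L) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  .fg_assert_scalar_num(alpha_ew, "alpha_ew", 0, 1)
  if (is.null(engine)) engine <- fg_engine(design)

  ind <- design$ind
  rows_by_ind <- split(seq_along(ind), ind)
  n_units <- length(rows_by_ind)
  if (lgamma(n_units + 1) < log(n_perm)) {
    abort(sprintf("only %d individuals: fewer than n_perm distinct permutations exist",
                  n_units))
  }
  counts <- lengths(rows_by_ind)
  strata <- split(seq_len(n_units), counts)

  # Freedman-Lane nuisance: intercept, sex, ethnic indicators
  cm <- design$column_map
  nuis_cols <- cm$column[cm$effect %in% c("mu", "sex", "e")]
  X <- design_full_matrix(design)
  Nz <- X[, intersect(nuis_cols, colnames(X)), drop = FALSE]
  qn <- qr(Nz)
  fitted <- qr.fitted(qn, y)
  resid <- y - fitted

  set.seed(as.integer(seed %% .Machine$integer.max))
  max_F <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    k <- min(batch, n_perm - done)
    Y <- matrix(0, length(y), k)
    for (b in seq_len(k)) {
      rp <- numeric(length(y))
      for (s in strata) {
        pi_s <- if (length(s) > 1) sample(s) else s
        src <- unlist(rows_by_ind[pi_s], use.names = FALSE)
        dst <- unlist(rows_by_ind[s], use.names = FALSE)
        rp[dst] <- resid[src]
      }
      Y[, b] <- fitted + rp
    }
    Fb <- engine_F(engine, Y)$F
    max_F[done + seq_len(k)] <- apply(Fb, 2, max, na.rm = TRUE)
    done <- done + k
  }

  structure(list(max_F = max_F,
                 critical_F = .fg_upper_quantile(max_F, alpha_ew),
                 alpha_ew = alpha_ew, n_perm = n_perm,
                 tail = .fg_gpd_tail_fit(max_F),
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d permutations, critical F(alpha=%g) = %.3f\n",
              x$n_perm, x$alpha_ew, x$critical_F))
  invisible(x)
}

# generalized Pareto fit (MLE) to exceedances over the empirical 90th
# percentile, for extrapolating P values beyond 1/(n_perm+1)
.fg_gpd_tail_fit <- function(x, frac = 0.10) {
  u <- quantile(x, 1 - frac, names = FALSE, type = 1)
  z <- x[x > u] - u
  p_exc <- length(z) / length(x)
  if (length(z) < 10 || var(z) == 0) {
    return(list(u = u, p_exc = p_exc, sigma = max(mean(z), 1e-8), xi = 0))
  }
  nll <- function(par) {
    s <- exp(par[1]); xi <- par[2]
    w <- 1 + xi * z / s
    if (any(w <= 0)) return(1e10)
    if (abs(xi) < 1e-8) length(z) * log(s) + sum(z / s)
    else length(z) * log(s) + (1 / xi + 1) * sum(log(w))
  }
  fit <- stats::optim(c(log(mean(z)), 0.1), nll, method = "Nelder-Mead")
  list(u = u, p_exc = p_exc, sigma = exp(fit$par[1]), xi = fit$par[2])
}

.fg_gpd_sf <- function(q, tail) {
  # survival function of exceedance beyond tail$u; a negative fitted shape
  # (bounded support) is an artifact of small tail samples for an F-like
  # null, so extrapolation falls back to the exponential tail
  z <- pmax(q - tail$u, 0)
  xi <- max(tail$xi, 0)
  if (xi < 1e-8) exp(-z / tail$sigma)
  else (1 + xi * z / tail$sigma)^(-1 / xi)
}

#' Experiment-wise P value from a permutation null
#'
#' For an observed F within the range of the permutation max-F samples the P
#' value is the add-one empirical tail probability
#' (1 + #\{max F >= F_obs\}) / (n_perm + 1). Beyond the permutation
#' resolution the stored generalized Pareto tail fit is used, so the P value
#' is an extrapolation (flagged in the `extrapolated` attribute). The result
#' is monotone non-increasing in `F_obs`.
#'
#' @param F_obs numeric vector of observed F statistics (>= 0).
#' @param null a [permutation_threshold()] result.
#' @return Numeric vector of experiment-wise P values in (0, 1], with a
#'   logical attribute `extrapolated`.
#' @export
experimentwise_p <- function(F_obs, null) {
  stopifnot(inherits(null, "permutation_null"))
  if (any(F_obs < 0, na.rm = TRUE)) abort("`F_obs` must be non-negative")
  np <- null$n_perm
  exceed <- vapply(F_obs, function(f) sum(null$max_F >= f), numeric(1))
  p_emp <- (1 + exceed) / (np + 1)
  top <- max(null$max_F)
  extrap <- !is.na(F_obs) & F_obs > top
  if (any(extrap)) {
    p_tail <- null$tail$p_exc * .fg_gpd_sf(F_obs[extrap], null$tail)
    # never above the empirical floor, never exactly zero
    p_emp[extrap] <- pmin(p_emp[extrap], pmax(p_tail, 1e-300))
  }
  attr(p_emp, "extrapolated") <- extrap
  p_emp
}
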