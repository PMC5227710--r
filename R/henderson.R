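#' Henderson method III variance-component estimation
#'
#' Method-of-moments estimation of the random-class variances from
#' differences of least-squares reductions. For each random class v the
#' observed reduction R(all) - R(all minus v) is equated to its expectation,
#' a linear combination of the class variances (trace terms) plus the added
#' degrees of freedom times the residual variance; together with the residual
#' sum-of-squares equation this gives a linear system in the variances, which
#' is solved directly. Fixed effects cancel from every class equation because
#' the reduced model always contains all fixed columns. Negative solutions
#' are truncated at zero and flagged.
#'
#' With no random classes in the design, the ordinary least-squares residual
#' mean square is returned as the residual variance.
#'
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the design's trait values).
#' @return An object of class `variance_components`: a tibble with columns
#'   `component`, `variance`, `truncated`, with attribute `method =
#'   "henderson3"`.
#' @export
henderson3_components <- function(design, y = design$y) {
  classes <- names(design$random)
  X <- design_full_matrix(design)
  n <- nrow(X)
  qx <- qr(X)
  r <- qx$rank
  if (n <= r) abort("no residual degrees of freedom")
  Q <- qr.Q(qx)[, seq_len(r), drop = FALSE]
  z <- crossprod(Q, y)
  rss <- max(sum(y^2) - sum(z^2), 0)

  if (length(classes) == 0L) {
    out <- tibble::tibble(component = "residual", variance = rss / (n - r),
                          truncated = FALSE)
    attr(out, "method") <- "henderson3"
    class(out) <- c("variance_components", class(out))
    return(out)
  }

  Xr <- crossprod(Q, X)
  colnames(Xr) <- colnames(X)
  all_cols <- colnames(X)
  class_cols <- lapply(design$random, colnames)

  nv <- length(classes)
  A <- matrix(0, nv + 1, nv + 1,
              dimnames = list(c(classes, "residual"), c(classes, "residual")))
  b <- numeric(nv + 1)
  for (i in seq_along(classes)) {
    v <- classes[i]
    cond <- setdiff(all_cols, class_cols[[v]])
    qc <- qr(Xr[, cond, drop = FALSE])
    rc <- qc$rank
    QC <- qr.Q(qc)[, seq_len(rc), drop = FALSE]
    B <- Xr[, class_cols[[v]], drop = FALSE] - QC %*% crossprod(QC, Xr[, class_cols[[v]], drop = FALSE])
    qg <- qr(B)
    dfv <- qg$rank
    if (dfv == 0) {
      abort(paste0("random class '", v, "' adds no rank to the design; ",
                   "remove the term or an aliased one"))
    }
    N <- qr.Q(qg)[, seq_len(dfv), drop = FALSE]
    # observed reduction
    b[i] <- sum((crossprod(N, z))^2)
    for (j in seq_along(classes)) {
      Uw <- Xr[, class_cols[[classes[j]]], drop = FALSE]
      A[i, j] <- sum((crossprod(N, Uw))^2)
    }
    A[i, nv + 1] <- dfv
  }
  # residual equation: E[RSS] = sum_w sigma2_w tr(Uw'(I-P)Uw) + (n-r) sigma2_e
  for (j in seq_along(classes)) {
    Uj <- X[, class_cols[[classes[j]]], drop = FALSE]
    A[nv + 1, j] <- max(sum(Uj^2) - sum(Xr[, class_cols[[classes[j]]], drop = FALSE]^2), 0)
  }
  A[nv + 1, nv + 1] <- n - r
  b[nv + 1] <- rss

  sol <- tryCatch(solve(A, b), error = function(e) {
    abort(paste0("Henderson III system is singular; consider removing a ",
                 "random class (", conditionMessage(e), ")"))
  })
  trunc <- sol < 0
  # keep residual variance strictly positive
  sol[seq_len(nv)][sol[seq_len(nv)] < 0] <- 0
  if (sol[nv + 1] <= 0) {
    sol[nv + 1] <- rss / (n - r)
    trunc[nv + 1] <- TRUE
  }
  out <- tibble::tibble(component = c(classes, "residual"),
                        variance = as.numeric(sol),
                        truncated = as.logical(trunc))
  attr(out, "method") <- "henderson3"
  class(out) <- c("variance_components", class(out))
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> (%s)\n", attr(x, "method") %||% "?"))
  NextMethod()
}
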