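# Least-squares projection engine.
#
# Henderson method III and the term-wise F statistics are built from
# differences of least-squares reductions R(.) computed with every effect
# treated as fixed. All candidate column sets live inside the column space of
# the full design, so reductions are computed in the r-dimensional coordinates
# of an orthonormal basis Q of that space: R(S) for a column subset S is
# ||P_{B_S} Q'y||^2 with B_S = Q'X_S. For a tested term g with conditioning
# set C the difference projector P_{C+g} - P_C has a small orthonormal basis
# N_g (r x df_g), precomputed once per design, so that
# deltaSS_g(y) = ||N_g' Q'y||^2. This makes permutation nulls cheap: the
# design is decomposed once and each permuted response costs one r x n
# product.

fg_engine <- function(design, per_level = TRUE, class_terms = FALSE) {
  X <- design_full_matrix(design)
  n <- nrow(X)
  qx <- qr(X)
  r <- qx$rank
  if (n <= r) abort("design has no residual degrees of freedom")
  Q <- qr.Q(qx)[, seq_len(r), drop = FALSE]
  Xr <- crossprod(Q, X)            # r x p coordinates of all columns
  colnames(Xr) <- colnames(X)

  orth_extra <- function(cond_cols, test_cols) {
    # orthonormal basis of span(cond + test) minus span(cond), in Q-coords
    B_test <- Xr[, test_cols, drop = FALSE]
    if (length(cond_cols)) {
      qc <- qr(Xr[, cond_cols, drop = FALSE])
      rc <- qc$rank
      if (rc > 0) {
        QC <- qr.Q(qc)[, seq_len(rc), drop = FALSE]
        B_test <- B_test - QC %*% crossprod(QC, B_test)
      }
    }
    qg <- qr(B_test)
    df <- qg$rank
    list(N = qr.Q(qg)[, seq_len(df), drop = FALSE], df = df)
  }

  all_cols <- colnames(X)
  tinfo <- design_terms(design, per_level = per_level, class_terms = class_terms)
  terms <- lapply(tinfo, function(tt) {
    cond <- setdiff(all_cols, c(tt$test, tt$exclude))
    ex <- orth_extra(cond, tt$test)
    c(tt, ex)
  })

  structure(list(Q = Q, Xr = Xr, n = n, rank = r, df_res = n - r,
                 terms = terms, col_names = all_cols,
                 col_norm2 = colSums(X^2)),
            class = "fg_engine")
}

# F statistics for every engine term, for one response vector or a matrix of
# responses (columns = responses). Returns list(F = terms x k matrix,
# delta_ss, df, ms_res, rss).
engine_F <- function(engine, Y) {
  Y <- as.matrix(Y)
  Z <- crossprod(engine$Q, Y)
  rss <- pmax(colSums(Y^2) - colSums(Z^2), 0)
  ms <- rss / engine$df_res
  k <- ncol(Y)
  tn <- names(engine$terms)
  Fm <- matrix(NA_real_, length(tn), k, dimnames = list(tn, NULL))
  Dm <- Fm
  df <- vapply(engine$terms, `[[`, numeric(1), "df")
  for (i in seq_along(engine$terms)) {
    tt <- engine$terms[[i]]
    if (tt$df == 0) next
    dss <- colSums((crossprod(tt$N, Z))^2)
    Dm[i, ] <- dss
    Fm[i, ] <- (dss / tt$df) / ms
  }
  list(F = Fm, delta_ss = Dm, df = df, ms_res = ms, rss = rss)
}

#' Term-wise F statistic by Henderson-III reduction
#'
#' Computes, for one model term, the reduction in residual sum of squares
#' from adding the term's column group to the model containing the other
#' selected columns (respecting marginality: a main effect's own
#' ethnicity-interaction levels are excluded from the conditioning set, since
#' the four group columns sum exactly to the main column), divided by its
#' added degrees of freedom and by the residual mean square of the
#' all-columns fit. With no random classes in the design this is exactly the
#' classical partial F of ordinary least squares.
#'
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the design's trait values).
#' @param term term label, a column name such as `"a_rs1"` or `"ae_rs1_3"`;
#'   `NULL` returns every tested term.
#' @param engine optionally a prebuilt internal engine (reused across calls).
#' @return A tibble with columns `term`, `effect`, `snp1`, `snp2`, `level`,
#'   `delta_ss`, `df`, `F`.
#' @export
term_F <- function(design, y = design$y, term = NULL, engine = NULL) {
  if (is.null(engine)) engine <- fg_engine(design)
  res <- engine_F(engine, y)
  out <- tibble::tibble(
    term = names(engine$terms),
    effect = vapply(engine$terms, `[[`, character(1), "effect"),
    snp1 = vapply(engine$terms, function(t) as.character(t$snp1 %||% NA), character(1)),
    snp2 = vapply(engine$terms, function(t) as.character(t$snp2 %||% NA), character(1)),
    level = vapply(engine$terms, function(t) as.integer(t$level %||% NA), integer(1)),
    delta_ss = unname(res$delta_ss[, 1]),
    df = unname(res$df),
    F = unname(res$F[, 1])
  )
  if (!is.null(term)) {
    if (!term %in% out$term) abort(paste0("unknown term '", term, "'"))
    out <- out[out$term == term, ]
    if (is.na(out$F)) abort(paste0("term '", term, "' is aliased (zero added rank)"))
  }
  out
}
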