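#' Build fixed and random design matrices for the genetic mixed model
#'
#' Expands a [model_spec()] into the record-level coefficient matrices of the
#' mixed model: one row per phenotype record (replicate examinations
#' stacked), fixed columns for the intercept, the sex block and every
#' requested additive/dominance/epistasis term, and one random block per
#' requested random class. Interaction blocks carry one column per
#' (locus or pair, ethnic group): the genetic coefficient multiplied by the
#' group indicator, so the four group columns of a term sum to the
#' main-term coefficient.
#'
#' Records of individuals with a missing genotype at any model locus are
#' dropped (listwise) and counted in the `dropped` field.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a phenotype tibble (see [validate_phenotypes()]).
#' @param spec a [model_spec()].
#' @return An object of class `design_matrices`: list with elements `fixed`
#'   (matrix), `random` (named list of matrices), `column_map` (tibble),
#'   `y`, `records`, `ind` (individual id per row), `dropped` (record count).
#' @export
build_design <- function(genotypes, phenotypes, spec) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(spec, "model_spec"))
  ph <- validate_phenotypes(phenotypes)
  snps <- spec_snps(spec)
  unknown <- setdiff(snps, genotypes$snps$snp)
  if (length(unknown)) {
    abort(paste0("model spec references SNP(s) absent from genotypes: ",
                 paste(unknown, collapse = ", ")))
  }
  ungeno <- setdiff(unique(ph$iid), genotypes$samples)
  if (length(ungeno)) {
    abort(paste0(length(ungeno), " phenotyped individual(s) lack genotypes"))
  }

  # per-individual codings for every SNP the spec touches
  calls <- genotypes$calls[, snps, drop = FALSE]
  xa <- apply(calls, 2, code_additive)
  xd <- apply(calls, 2, code_dominance)
  if (length(snps) == 1L) {
    xa <- matrix(xa, ncol = 1, dimnames = list(NULL, snps))
    xd <- matrix(xd, ncol = 1, dimnames = list(NULL, snps))
  }
  rownames(xa) <- rownames(xd) <- genotypes$samples

  ind_ok <- genotypes$samples[rowSums(is.na(xa)) == 0]
  keep <- ph$iid %in% ind_ok
  dropped <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]
  if (nrow(ph) == 0L) abort("no phenotype records remain after dropping missing genotypes")

  ridx <- match(ph$iid, genotypes$samples)
  n <- nrow(ph)

  cols <- list()
  map <- list()
  add_col <- function(name, values, block, snp1, snp2, effect, level) {
    cols[[name]] <<- values
    map[[name]] <<- tibble::tibble(column = name, block = block,
                                   snp1 = snp1, snp2 = snp2,
                                   effect = effect, level = level)
  }

  add_col("mu", rep(1, n), "fixed", NA, NA, "mu", NA_integer_)
  if (spec$include_sex) add_col("sex", as.numeric(ph$sex), "fixed", NA, NA, "sex", NA_integer_)

  for (i in seq_len(nrow(spec$loci))) {
    s <- spec$loci$snp[i]
    for (t in spec$loci$terms[[i]]) {
      v <- if (t == "a") xa[ridx, s] else xd[ridx, s]
      add_col(paste0(t, "_", s), v, "fixed", s, NA, t, NA_integer_)
    }
  }
  for (i in seq_len(nrow(spec$pairs))) {
    s1 <- spec$pairs$snp1[i]; s2 <- spec$pairs$snp2[i]
    epi <- code_epistasis(xa[ridx, s1], xd[ridx, s1], xa[ridx, s2], xd[ridx, s2])
    for (t in spec$pairs$terms[[i]]) {
      add_col(paste0(t, "_", s1, "_", s2), epi[[t]], "fixed", s1, s2, t, NA_integer_)
    }
  }
  fixed <- do.call(cbind, lapply(cols, unname))

  # random blocks: ethnicity indicators and coefficient x group-indicator
  # columns for each interaction class
  eth_ind <- outer(ph$ethnicity, 1:4, `==`) * 1
  random <- list()
  if ("e" %in% spec$random_classes) {
    block <- eth_ind
    colnames(block) <- paste0("e_", 1:4)
    for (h in 1:4) map[[paste0("e_", h)]] <-
        tibble::tibble(column = paste0("e_", h), block = "e",
                       snp1 = NA, snp2 = NA, effect = "e", level = h)
    random$e <- block
  }
  inter_main <- list(ae = "a", de = "d")
  for (cls in intersect(c("ae", "de"), spec$random_classes)) {
    mt <- inter_main[[cls]]
    loci_cls <- spec$loci$snp[vapply(spec$loci$terms, function(t) mt %in% t, logical(1))]
    if (!length(loci_cls)) next
    blocks <- lapply(loci_cls, function(s) {
      coef <- if (mt == "a") xa[ridx, s] else xd[ridx, s]
      b <- coef * eth_ind
      colnames(b) <- paste0(cls, "_", s, "_", 1:4)
      b
    })
    block <- do.call(cbind, blocks)
    for (nm in colnames(block)) {
      parts <- strsplit(nm, "_")[[1]]
      h <- as.integer(parts[length(parts)])
      s <- paste(parts[-c(1, length(parts))], collapse = "_")
      map[[nm]] <- tibble::tibble(column = nm, block = cls, snp1 = s, snp2 = NA,
                                  effect = cls, level = h)
    }
    random[[cls]] <- block
  }
  inter_epi <- c(aae = "aa", ade = "ad", dae = "da", dde = "dd")
  for (cls in intersect(names(inter_epi), spec$random_classes)) {
    et <- inter_epi[[cls]]
    sel <- which(vapply(spec$pairs$terms, function(t) et %in% t, logical(1)))
    if (!length(sel)) next
    blocks <- lapply(sel, function(i) {
      s1 <- spec$pairs$snp1[i]; s2 <- spec$pairs$snp2[i]
      coef <- cols[[paste0(et, "_", s1, "_", s2)]]
      b <- coef * eth_ind
      colnames(b) <- paste0(cls, "_", s1, "_", s2, "_", 1:4)
      for (h in 1:4) map[[paste0(cls, "_", s1, "_", s2, "_", h)]] <<-
          tibble::tibble(column = paste0(cls, "_", s1, "_", s2, "_", h),
                         block = cls, snp1 = s1, snp2 = s2, effect = cls, level = h)
      b
    })
    random[[cls]] <- do.call(cbind, blocks)
  }

  column_map <- dplyr::bind_rows(map[c(colnames(fixed),
                                       unlist(lapply(random, colnames)))])
  structure(list(fixed = fixed, random = random, column_map = column_map,
                 y = ph$value,
                 records = ph[, c("iid", "sex", "ethnicity", "exam")],
                 ind = ph$iid, dropped = dropped),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("<design_matrices> %d records, %d fixed columns, %d random blocks (%s), %d records dropped\n",
              length(x$y), ncol(x$fixed), length(x$random),
              paste(names(x$random), collapse = ", "), x$dropped))
  invisible(x)
}

# full treat-as-fixed matrix: fixed columns then random blocks
design_full_matrix <- function(design) {
  do.call(cbind, c(list(design$fixed), unname(design$random)))
}

# tested terms of a design, with the marginality-respecting conditioning
# exclusions: a main effect is tested without its own interaction levels in
# the conditioning set (they alias it: the four group columns sum to the
# main column); an interaction level is tested given the main term but
# without the other levels of the same family, so the tested direction is
# the level's deviation orthogonal to the main effect (the identifiable
# per-level contrast); the joint interaction class is tested given the
# main term (added rank 3).
design_terms <- function(design, per_level = TRUE, class_terms = FALSE) {
  cm <- design$column_map
  X_names <- cm$column
  out <- list()
  fixed_genetic <- cm[cm$block == "fixed" & !(cm$effect %in% c("mu", "sex")), ]
  inter_cls <- c(a = "ae", d = "de", aa = "aae", ad = "ade", da = "dae", dd = "dde")
  for (i in seq_len(nrow(fixed_genetic))) {
    r <- fixed_genetic[i, ]
    cls <- inter_cls[[r$effect]]
    own <- cm$column[cm$block == cls &
                       (is.na(r$snp2) & cm$snp1 %in% r$snp1 & is.na(cm$snp2) |
                          !is.na(r$snp2) & cm$snp1 %in% r$snp1 & cm$snp2 %in% r$snp2)]
    out[[r$column]] <- list(term = r$column, test = r$column, exclude = own,
                            effect = r$effect, snp1 = r$snp1, snp2 = r$snp2,
                            level = NA_integer_)
  }
  inter <- cm[cm$block %in% c("ae", "de", "aae", "ade", "dae", "dde"), ]
  if (nrow(inter)) {
    main_of <- c(ae = "a", de = "d", aae = "aa", ade = "ad", dae = "da", dde = "dd")
    keys <- unique(inter[, c("block", "snp1", "snp2")])
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      sel <- inter$block == k$block & inter$snp1 == k$snp1 &
        (is.na(k$snp2) & is.na(inter$snp2) |
           !is.na(k$snp2) & !is.na(inter$snp2) & inter$snp2 %in% k$snp2)
      grp_cols <- inter$column[sel]
      main_col <- if (is.na(k$snp2)) paste0(main_of[[k$block]], "_", k$snp1)
        else paste0(main_of[[k$block]], "_", k$snp1, "_", k$snp2)
      main_col <- intersect(main_col, X_names)
      if (per_level) {
        for (cc in grp_cols) {
          h <- inter$level[inter$column == cc]
          out[[cc]] <- list(term = cc, test = cc,
                            exclude = setdiff(grp_cols, cc),
                            effect = k$block, snp1 = k$snp1, snp2 = k$snp2,
                            level = h)
        }
      }
      if (class_terms) {
        nm <- sub("_[1-4]$", "", grp_cols[1])
        out[[paste0(nm, ".class")]] <- list(term = paste0(nm, ".class"),
                                            test = grp_cols, exclude = character(),
                                            effect = k$block, snp1 = k$snp1,
                                            snp2 = k$snp2, level = NA_integer_)
      }
    }
  }
  out
}
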