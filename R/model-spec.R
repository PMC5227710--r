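#' Model specification for the full or additive genetic model
#'
#' Describes which loci and locus pairs enter the model and with which terms.
#' The full model carries additive (`a`) and dominance (`d`) main effects,
#' digenic epistasis terms (`aa`, `ad`, `da`, `dd`) for selected pairs, and
#' random effects for ethnicity (`e`) and locus-by-ethnicity interaction
#' classes (`ae`, `de`, `aae`, `ade`, `dae`, `dde`). The reduced additive
#' model keeps only `a` main terms with `e` and `ae` random classes.
#'
#' @param loci tibble with columns `snp` and `terms` (list-column of subsets
#'   of `c("a", "d")`; may be empty for loci that only appear in pairs), or a
#'   character vector of SNP ids (then every locus gets an `a` term).
#' @param pairs tibble with columns `snp1`, `snp2`, `terms` (list-column of
#'   subsets of `c("aa", "ad", "da", "dd")`), or `NULL`.
#' @param random_classes subset of
#'   `c("e", "ae", "de", "aae", "ade", "dae", "dde")`. Interaction classes
#'   apply to every locus/pair carrying the corresponding fixed term.
#' @param include_sex include the sex block column (default `TRUE`).
#' @param reduced_additive if `TRUE` the spec is restricted to additive main
#'   terms and `e`/`ae` random classes.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(loci,
                       pairs = NULL,
                       random_classes = c("e", "ae", "de", "aae", "ade", "dae", "dde"),
                       include_sex = TRUE,
                       reduced_additive = FALSE) {
  if (is.character(loci)) {
    loci <- tibble::tibble(snp = loci, terms = replicate(length(loci), "a", simplify = FALSE))
  }
  loci <- tibble::as_tibble(loci)
  if (!all(c("snp", "terms") %in% names(loci))) abort("`loci` needs columns snp, terms")
  if (anyDuplicated(loci$snp)) abort("duplicated locus in `loci`")
  ok_terms <- vapply(loci$terms, function(t) all(t %in% c("a", "d")), logical(1))
  if (!all(ok_terms)) abort("locus terms must be subsets of {a, d}")
  if (!is.null(pairs)) {
    pairs <- tibble::as_tibble(pairs)
    if (!all(c("snp1", "snp2", "terms") %in% names(pairs))) {
      abort("`pairs` needs columns snp1, snp2, terms")
    }
    if (any(pairs$snp1 == pairs$snp2)) abort("epistasis pair members must be distinct")
    okp <- vapply(pairs$terms, function(t)
      length(t) >= 1 && all(t %in% c("aa", "ad", "da", "dd")), logical(1))
    if (!all(okp)) abort("pair terms must be non-empty subsets of {aa, ad, da, dd}")
  } else {
    pairs <- tibble::tibble(snp1 = character(), snp2 = character(), terms = list())
  }
  all_classes <- c("e", "ae", "de", "aae", "ade", "dae", "dde")
  if (length(random_classes)) {
    random_classes <- match.arg(random_classes, all_classes, several.ok = TRUE)
  } else {
    random_classes <- character(0)
  }
  if (reduced_additive) {
    loci$terms <- lapply(loci$terms, intersect, x = "a")
    loci <- loci[lengths(loci$terms) > 0, ]
    pairs <- pairs[0, ]
    random_classes <- intersect(random_classes, c("e", "ae"))
  }
  structure(list(loci = loci, pairs = pairs,
                 random_classes = random_classes,
                 include_sex = isTRUE(include_sex),
                 reduced_additive = isTRUE(reduced_additive)),
            class = "model_spec")
}

#' Reduce a model specification to the multi-locus additive model
#'
#' Drops dominance and epistasis terms and restricts random classes to
#' ethnicity and additive-by-ethnicity interaction.
#'
#' @param spec a [model_spec()].
#' @return The reduced `model_spec` with `reduced_additive = TRUE`.
#' @export
reduce_to_additive <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  model_spec(spec$loci, spec$pairs, spec$random_classes,
             include_sex = spec$include_sex, reduced_additive = TRUE)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec>%s %d loci, %d epistasis pairs; random: %s\n",
              if (x$reduced_additive) " [additive]" else "",
              nrow(x$loci), nrow(x$pairs),
              paste(x$random_classes, collapse = ", ")))
  invisible(x)
}

# all SNP ids a spec refers to
spec_snps <- function(spec) {
  unique(c(spec$loci$snp, spec$pairs$snp1, spec$pairs$snp2))
}

#' Build a model specification from a truth set
#'
#' Convenience for simulation studies: derives the loci, pairs and random
#' classes that carry non-zero effects in a truth tibble (as returned by
#' [scenario_truth()]).
#'
#' @param truth tibble with columns `snp1`, `snp2` (`NA` for single loci),
#'   `effect`, `level`, `value`.
#' @param random_classes random classes to include; default: ethnicity plus
#'   every interaction class present in the truth.
#' @param reduced_additive build the additive reduction instead.
#' @return A [model_spec()].
#' @export
spec_from_truth <- function(truth, random_classes = NULL, reduced_additive = FALSE) {
  truth <- tibble::as_tibble(truth)
  single <- truth[is.na(truth$snp2), ]
  pairrows <- truth[!is.na(truth$snp2), ]
  main_of <- function(eff) {
    # ae -> a, de -> d, main terms map to themselves
    c(a = "a", d = "d", ae = "a", de = "d")[[eff]]
  }
  loci_ids <- unique(c(single$snp1, pairrows$snp1, pairrows$snp2))
  loci <- tibble::tibble(
    snp = loci_ids,
    terms = lapply(loci_ids, function(s) {
      eff <- single$effect[single$snp1 == s]
      sort(unique(vapply(eff, main_of, character(1))))
    })
  )
  pairs <- NULL
  if (nrow(pairrows)) {
    key <- paste(pairrows$snp1, pairrows$snp2)
    pairs <- tibble::tibble(
      snp1 = tapply(pairrows$snp1, key, `[`, 1)[unique(key)],
      snp2 = tapply(pairrows$snp2, key, `[`, 1)[unique(key)],
      terms = lapply(unique(key), function(k) {
        sort(unique(sub("e$", "", pairrows$effect[key == k])))
      })
    )
  }
  if (is.null(random_classes)) {
    inter <- unique(truth$effect[!is.na(truth$level)])
    random_classes <- unique(c("e", intersect(c("ae", "de", "aae", "ade", "dae", "dde"),
                                              inter)))
  }
  model_spec(loci, pairs, random_classes, reduced_additive = reduced_additive)
}
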