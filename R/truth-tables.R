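# Truth sets of the two simulation scenarios.
#
# Scenario I: the full-model genetic architecture of the cholesterol trait —
# additive, dominance and ethnicity-interaction effects at 17 loci plus four
# digenic epistasis pairs. Scenario II: the additive-model architecture —
# 13 loci with additive effects only (plus optional user-supplied
# additive-by-ethnicity effects). Ethnic levels: 1 E-A, 2 C-A, 3 A-A, 4 H-A.
# Effect values are in trait units (mg/dL for cholesterol).

.fg_truth_scenario1 <- function() {
  tribble <- tibble::tribble
  tribble(
    ~snp1,          ~snp2,          ~effect, ~level, ~value,
    "rs629301",     NA,             "a",     NA,      4.94,
    "rs629301",     NA,             "ae",    4L,      1.75,
    "rs2499595",    NA,             "a",     NA,      1.86,
    "rs2499595",    NA,             "ae",    1L,      1.36,
    "rs2499595",    NA,             "ae",    2L,     -3.73,
    "rs2499595",    NA,             "ae",    4L,      1.94,
    "rs478442",     NA,             "a",     NA,      5.73,
    "rs478442",     NA,             "ae",    1L,     -2.37,
    "rs478442",     NA,             "de",    1L,     -3.85,
    "rs478442",     NA,             "de",    3L,     -2.91,
    "rs478442",     NA,             "de",    4L,      5.40,
    "rs7624679",    NA,             "a",     NA,      1.47,
    "rs7624679",    NA,             "de",    4L,     -1.81,
    "rs7694118",    NA,             "d",     NA,      3.11,
    "rs7694118",    NA,             "de",    1L,      8.31,
    "rs7694118",    NA,             "de",    3L,     -6.08,
    "rs17409624",   NA,             "a",     NA,      2.14,
    "rs17409624",   NA,             "ae",    3L,      3.14,
    "rs17409624",   NA,             "ae",    4L,     -3.00,
    "rs6465748",    NA,             "a",     NA,     -3.11,
    "rs6465748",    NA,             "d",     NA,      2.14,
    "rs6465748",    NA,             "ae",    1L,      1.55,
    "rs6465748",    NA,             "ae",    3L,     -4.67,
    "rs6465748",    NA,             "ae",    4L,      4.33,
    "rs10503377",   NA,             "a",     NA,      3.16,
    "rs10503377",   NA,             "ae",    1L,     -2.12,
    "rs10503377",   NA,             "ae",    2L,      4.74,
    "rs10503377",   NA,             "ae",    4L,     -2.30,
    "rs10768634",   NA,             "a",     NA,     -1.15,
    "rs10768634",   NA,             "d",     NA,     -3.45,
    "rs7124873",    NA,             "a",     NA,      2.57,
    "rs10483461",   NA,             "a",     NA,      2.35,
    "rs10483461",   NA,             "d",     NA,     -2.73,
    "rs10483461",   NA,             "ae",    3L,      4.02,
    "rs10483461",   NA,             "ae",    4L,     -1.47,
    "rs12595211",   NA,             "a",     NA,     -2.52,
    "rs12595211",   NA,             "de",    4L,      1.94,
    "rs1532625",    NA,             "a",     NA,     -2.85,
    "rs4888652",    NA,             "a",     NA,      1.91,
    "rs2649485",    NA,             "a",     NA,     -2.58,
    "rs9946067",    NA,             "a",     NA,     -2.23,
    "rs9946067",    NA,             "d",     NA,      2.89,
    "rs1654452",    NA,             "a",     NA,     -2.02,
    "rs1654452",    NA,             "d",     NA,      1.62,
    "rs478442",     "rs7694118",    "aa",    NA,      2.38,
    "rs478442",     "rs7694118",    "ad",    NA,     -2.60,
    "rs478442",     "rs7694118",    "da",    NA,      3.59,
    "rs4888652",    "rs9946067",    "da",    NA,      2.64,
    "rs4888652",    "rs9946067",    "dd",    NA,     -1.95,
    "rs2264802",    "rs9548318",    "aa",    NA,     -4.71,
    "rs2264802",    "rs9548318",    "ad",    NA,     -6.14,
    "rs12246594",   "rs12595211",   "aa",    NA,      7.46
  )
}

.fg_truth_scenario2 <- function() {
  tibble::tribble(
    ~snp1,          ~snp2, ~effect, ~level, ~value,
    "rs629301",     NA,    "a",     NA,      4.94,
    "rs2499595",    NA,    "a",     NA,      1.86,
    "rs478442",     NA,    "a",     NA,      5.73,
    "rs7624679",    NA,    "a",     NA,      1.47,
    "rs17409624",   NA,    "a",     NA,      2.14,
    "rs10503377",   NA,    "a",     NA,      3.16,
    "rs10768634",   NA,    "a",     NA,     -1.15,
    "rs12595211",   NA,    "a",     NA,     -2.52,
    "rs1532625",    NA,    "a",     NA,     -2.85,
    "rs4888652",    NA,    "a",     NA,      1.91,
    "rs2649485",    NA,    "a",     NA,     -2.58,
    "rs9946067",    NA,    "a",     NA,     -2.23,
    "rs1654452",    NA,    "a",     NA,     -2.02
  )
}

# chromosome labels of the truth loci (from their panel annotation),
# used to lay the simulated panel out on a genome
.fg_truth_chr <- c(
  rs629301 = "1", rs2499595 = "1", rs478442 = "2", rs7624679 = "3",
  rs7694118 = "4", rs17409624 = "5", rs6465748 = "7", rs2264802 = "7",
  rs10503377 = "8", rs12246594 = "10", rs10768634 = "11", rs7124873 = "11",
  rs9548318 = "13", rs10483461 = "14", rs12595211 = "15", rs1532625 = "16",
  rs4888652 = "16", rs2649485 = "17", rs9946067 = "18", rs1654452 = "19")

#' Truth set of a simulation scenario
#'
#' Scenario `"I"`: the full genetic architecture (additive, dominance,
#' ethnicity-interaction and epistasis effects at 17 loci and 4 pairs).
#' Scenario `"II"`: the additive architecture (13 loci, additive effects
#' only), optionally augmented with additive-by-ethnicity effects.
#'
#' @param scenario `"I"` or `"II"`.
#' @param ae_effects for scenario II only: tibble with columns `snp1`,
#'   `level`, `value` of additive-by-ethnicity effects to add (default none).
#' @return A truth tibble with columns `snp1`, `snp2`, `effect`, `level`,
#'   `value`.
#' @export
scenario_truth <- function(scenario = c("I", "II"), ae_effects = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "I") {
    if (!is.null(ae_effects)) abort("`ae_effects` applies to scenario II only")
    return(.fg_truth_scenario1())
  }
  tr <- .fg_truth_scenario2()
  if (!is.null(ae_effects)) {
    ae <- tibble::as_tibble(ae_effects)
    stopifnot(all(c("snp1", "level", "value") %in% names(ae)))
    bad <- setdiff(ae$snp1, tr$snp1)
    if (length(bad)) abort("ae effects refer to loci outside the scenario-II panel")
    tr <- dplyr::bind_rows(tr, tibble::tibble(snp1 = ae$snp1, snp2 = NA,
                                              effect = "ae",
                                              level = as.integer(ae$level),
                                              value = ae$value))
  }
  tr
}

#' SNP ids of a scenario's locus panel
#'
#' @param scenario `"I"` or `"II"`.
#' @return Character vector of SNP ids, in genome order.
#' @export
scenario_loci <- function(scenario = c("I", "II")) {
  tr <- scenario_truth(match.arg(scenario))
  ids <- unique(c(tr$snp1, tr$snp2))
  ids <- ids[!is.na(ids)]
  ids[order(as.numeric(.fg_truth_chr[ids]))]
}
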