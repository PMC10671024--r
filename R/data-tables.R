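#' Bundled summary of published most-stable complex models
#'
#' The published per-complex summary of the most stable chemokine
#' receptor dimer/isoform models: subject and partner interface
#' composition strings (TM helices in descending contribution order
#' with E/M/I qualifiers; `"Identical"` marks a symmetric homodimer
#' interface) and MMPBSA binding free energies (mean +/- SEM,
#' kcal/mol). The interface strings use the normalised `"TMk (Q)"`
#' spelling throughout. These values are inputs to the triage logic;
#' the package never computes BFEs.
#'
#' @return data.frame with columns `complex`, `subject`, `partner`,
#'   `model`, `interface_subject`, `interface_partner`, `bfe_mean`,
#'   `bfe_sem`.
#' @export
chemokine_model_table <- function() {
  path <- system.file("extdata", "table1_models.tsv",
                      package = "gpcrdimer", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Bundled blocking relationships reported for the receptor panel
#'
#' For each dimer-model / subject-blocker-model pair discussed in the
#' receptor panel: whether the two subject interfaces were reported to
#' overlap (`overlap_stated`; residue-level steric statement, which can
#' differ from coarse helix-set intersection), the interface involved,
#' and the reported verdict (`blocks_reported`). Together with
#' [chemokine_model_table()] this forms the worked-example truth table
#' for [blocking_decision()].
#'
#' @return data.frame with columns `dimer_complex`, `dimer_model`,
#'   `blocker_complex`, `blocker_model`, `interface`, `overlap_stated`,
#'   `blocks_reported`.
#' @export
chemokine_blocking_claims <- function() {
  path <- system.file("extdata", "blocking_claims.tsv",
                      package = "gpcrdimer", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Evaluate the bundled blocking truth table
#'
#' Joins [chemokine_blocking_claims()] with the BFEs of
#' [chemokine_model_table()] and runs [blocking_decision()] on every
#' pair, feeding the stated overlap relationship as the overlap
#' fraction (1 for an overlapping pair, 0 for a non-overlapping one).
#'
#' @param params thresholds from [screen_params()].
#' @return the claims data.frame with added columns `bfe_dimer`,
#'   `bfe_blocker`, `blocks` (computed verdict) and `agrees`
#'   (computed == reported).
#' @export
evaluate_blocking_claims <- function(params = screen_params()) {
  claims <- chemokine_blocking_claims()
  tab <- chemokine_model_table()
  key <- paste(tab$complex, tab$model)
  bfe_of <- function(cx, md) {
    i <- match(paste(cx, md), key)
    if (is.na(i)) stop("model not in the bundled table: ", cx, " ", md)
    tab$bfe_mean[i]
  }
  claims$bfe_dimer <- mapply(bfe_of, claims$dimer_complex,
                             claims$dimer_model)
  claims$bfe_blocker <- mapply(bfe_of, claims$blocker_complex,
                               claims$blocker_model)
  claims$blocks <- mapply(function(ov, bd, bb) {
    blocking_decision(if (ov) 1 else 0, bd, bb,
                      params$overlap_min, params$delta_close)$blocks
  }, claims$overlap_stated, claims$bfe_dimer, claims$bfe_blocker)
  claims$agrees <- claims$blocks == claims$blocks_reported
  claims
}
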