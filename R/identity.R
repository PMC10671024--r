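#' Pairwise percent identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with a standard substitution
#' matrix and affine gap penalties; identity is 100 x identical aligned
#' positions / alignment length, counting gap columns in the length, and
#' is reported to the nearest integer. The alignment parameters are
#' exposed because published identity figures depend on the aligner's
#' defaults; the package default (BLOSUM62, gap open 10, extension 0.5)
#' matches common protein-alignment practice.
#'
#' @param seq_a,seq_b amino-acid sequences (character strings, standard
#'   20-letter alphabet, case-insensitive).
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @param digits rounding of the reported value; `0` (default) reports
#'   to the nearest integer percent.
#' @return numeric percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 75
pairwise_identity <- function(seq_a, seq_b,
                              substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5,
                              digits = 0) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("sequences must be nonempty")
    bad <- setdiff(strsplit(s, "")[[1]], names(AA1TO3))
    if (length(bad) > 0) {
      stop("non-amino-acid characters in sequence: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  # PID1: 100 * identical / alignment length (gap columns included)
  round(Biostrings::pid(al, type = "PID1"), digits)
}

#' Bundled chemokine receptor reference sequences
#'
#' Returns the bundled copies of the UniProt entries for human CCR2
#' (P41597), CCR5 (P51681) and CXCR4 (P61073) as a named character
#' vector. The FASTA under `inst/extdata/` is a plain-text transcription
#' of the database entries bundled so that the package works without
#' network access; see the package vignette for provenance notes.
#'
#' @return named character vector of amino-acid sequences.
#' @export
reference_receptor_seqs <- function() {
  path <- system.file("extdata", "chemokine_receptors.fasta",
                      package = "gpcrdimer", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\|"), `[`, "", 2)
  seqs
}
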