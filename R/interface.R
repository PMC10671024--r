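#' Interface residues of a complex model
#'
#' A residue belongs to the interface when any of its heavy atoms lies
#' strictly within `cutoff_A` of any heavy atom of the other protomer
#' (the 5 A printing rule of per-residue MMPBSA decompositions).
#'
#' @param cm a `complex_model`.
#' @param cutoff_A heavy-atom distance cutoff in Angstrom (default 5).
#' @return list with integer residue-number vectors `subject` and
#'   `partner`, each sorted ascending.
#' @export
interface_residues <- function(cm, cutoff_A = 5) {
  stopifnot(inherits(cm, "complex_model"))
  if (cutoff_A <= 0) stop("cutoff must be > 0")
  xa <- protomer_xyz(cm$subject); ra <- cm$subject$atoms$resseq
  xb <- protomer_xyz(cm$partner); rb <- cm$partner$atoms$resseq
  ct <- residue_contacts(xa, ra, xb, rb, cutoff_A)
  list(subject = sort(unique(ct$res_a)), partner = sort(unique(ct$res_b)))
}

#' Residues contributing significantly to binding
#'
#' Selects residues whose per-residue energy contribution is strictly
#' below the threshold (default -1 kcal/mol, i.e. favourable beyond
#' -1 kcal/mol); a residue at exactly the threshold is excluded.
#'
#' @param energy_table data.frame with `chain`, `resseq`, `contribution`.
#' @param threshold kcal/mol (default -1).
#' @return subset of `energy_table` rows.
#' @export
significant_residues <- function(energy_table, threshold = -1) {
  validate_energy_table(energy_table)
  energy_table[energy_table$contribution < threshold, , drop = FALSE]
}

#' Rank TM helices by their contribution to the interface
#'
#' Scores each annotated subject TM helix (Helix 8 and loops excluded)
#' over its interface residues: when a per-residue energy decomposition
#' is available the score is the summed favourable energy (minus the
#' per-residue contributions); otherwise it falls back to the count of
#' interface residues in the helix. Helices are ordered by descending
#' score, ties broken by ascending helix index; only helices with at
#' least one interface residue are ranked.
#'
#' @param cm a `complex_model`.
#' @param iface interface residue sets from [interface_residues()];
#'   computed at `cutoff_A` when omitted.
#' @param energy_table optional decomposition table (defaults to the
#'   model's own, when present).
#' @param cutoff_A contact cutoff used when `iface` is omitted.
#' @return data.frame with columns `helix`, `score`, `n_residues`,
#'   ordered as described; zero rows for an empty interface.
#' @export
helix_contributions <- function(cm, iface = NULL, energy_table = NULL,
                                cutoff_A = 5) {
  stopifnot(inherits(cm, "complex_model"))
  if (is.null(iface)) iface <- interface_residues(cm, cutoff_A)
  if (is.null(energy_table)) energy_table <- cm$energy_table
  res <- iface$subject
  empty <- data.frame(helix = integer(), score = numeric(),
                      n_residues = integer())
  if (length(res) == 0L) return(empty)
  hx <- tm_index_of(cm$subject, res, include_h8 = FALSE)
  keep <- !is.na(hx)
  if (!any(keep)) return(empty)
  res <- res[keep]; hx <- hx[keep]
  if (!is.null(energy_table)) {
    sub <- energy_table[energy_table$chain == cm$subject$chain_id, , drop = FALSE]
    e <- sub$contribution[match(res, sub$resseq)]
    e[is.na(e)] <- 0
    score <- tapply(-e, hx, sum)
  } else {
    score <- tapply(rep(1L, length(hx)), hx, sum)
  }
  n_res <- tapply(rep(1L, length(hx)), hx, sum)
  out <- data.frame(helix = as.integer(names(score)),
                    score = as.numeric(score),
                    n_residues = as.integer(n_res))
  out <- out[order(-out$score, out$helix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extracellular/middle/intracellular qualifier of a helix interface
#'
#' Splits the helix into three equal-length thirds along the membrane
#' normal (extracellular, middle, intracellular, following the frame's
#' outward normal) and assigns the qualifier of the third that holds at
#' least `qualifier_frac` of the helix's interface residues. When no
#' third dominates the majority of the helix is considered involved and
#' `"none"` is returned (printed without parentheses).
#'
#' @param protomer the protomer carrying the helix.
#' @param helix_index TM index (1..7).
#' @param iface_residues interface residue numbers of this protomer.
#' @param frame `membrane_frame` of this protomer.
#' @param qualifier_frac dominance fraction (default 0.6).
#' @return one of `"E"`, `"M"`, `"I"`, `"none"`.
#' @export
segment_qualifier <- function(protomer, helix_index, iface_residues, frame,
                              qualifier_frac = 0.6) {
  tm <- protomer$tm[!protomer$tm$h8 & protomer$tm$index == helix_index, ,
                    drop = FALSE]
  if (nrow(tm) != 1L) stop("no TM segment with index ", helix_index)
  ca <- protomer_ca(protomer, tm$start:tm$end)
  if (nrow(ca$xyz) == 0L) return("none")
  proj <- as.numeric(ca$xyz %*% frame$normal) -
    sum(frame$midplane_point * frame$normal)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo < .Machine$double.eps) return("none")
  b1 <- lo + (hi - lo) / 3; b2 <- lo + 2 * (hi - lo) / 3
  sel <- ca$resseq %in% iface_residues
  if (!any(sel)) return("none")
  p <- proj[sel]
  counts <- c(E = sum(p > b2), M = sum(p > b1 & p <= b2), I = sum(p <= b1))
  frac <- counts / sum(counts)
  top <- which.max(frac)
  if (frac[top] >= qualifier_frac) names(counts)[top] else "none"
}

#' Full interface profile of a complex model
#'
#' Combines [interface_residues()], [helix_contributions()] and
#' [segment_qualifier()] into the helix-resolution interface summary of
#' the subject protomer, including the formatted interface string.
#'
#' @param cm a `complex_model`.
#' @param params thresholds from [screen_params()].
#' @param energy_table optional decomposition table.
#' @return object of class `interface_profile` with fields
#'   `subject_residues`, `partner_residues`, `ranking` (helix, score,
#'   n_residues, qualifier), `interface_string`, `cutoff_A`.
#' @export
interface_profile <- function(cm, params = screen_params(),
                              energy_table = NULL) {
  iface <- interface_residues(cm, params$cutoff_A)
  rk <- helix_contributions(cm, iface, energy_table, params$cutoff_A)
  if (nrow(rk) > 0L) {
    frame <- fit_membrane_frame(cm$subject, params$half_thickness_A)
    rk$qualifier <- vapply(rk$helix, function(h) {
      segment_qualifier(cm$subject, h, iface$subject, frame,
                        params$qualifier_frac)
    }, character(1))
  } else {
    rk$qualifier <- character(0)
  }
  structure(list(subject_residues = iface$subject,
                 partner_residues = iface$partner,
                 ranking = rk,
                 interface_string = format_interface_string(rk),
                 cutoff_A = params$cutoff_A),
            class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  cat("<interface_profile>",
      length(x$subject_residues), "subject /",
      length(x$partner_residues), "partner residues at",
      x$cutoff_A, "A\n  interface:",
      if (nzchar(x$interface_string)) x$interface_string else "(empty)", "\n")
  invisible(x)
}

#' Format a helix ranking as an interface string
#'
#' Produces the tabular interface dialect: helices in descending
#' contribution order, `"TMk"`, with the E/M/I qualifier appended in
#' parentheses when a single helix third dominates, e.g.
#' `"TM2, TM1, TM3 (E), TM4 (I)"`.
#'
#' @param ranking data.frame with columns `helix` and `qualifier`
#'   (already ordered), e.g. from [helix_contributions()] plus
#'   qualifiers, or from [parse_interface_string()].
#' @return character string; empty ranking gives `""`.
#' @export
format_interface_string <- function(ranking) {
  if (is.null(ranking) || nrow(ranking) == 0L) return("")
  q <- ranking$qualifier %||% rep("none", nrow(ranking))
  paste(ifelse(q == "none", paste0("TM", ranking$helix),
               paste0("TM", ranking$helix, " (", q, ")")),
        collapse = ", ")
}

#' Parse an interface string into helices and qualifiers
#'
#' Inverse of [format_interface_string()]; tolerant of missing space
#' before the qualifier parenthesis (`"TM4(I)"`).
#'
#' @param s interface string such as `"TM2, TM1, TM3 (E), TM4 (I)"`.
#' @return data.frame with columns `helix` (integer, in listed order)
#'   and `qualifier` (`"E"`, `"M"`, `"I"` or `"none"`).
#' @export
parse_interface_string <- function(s) {
  empty <- data.frame(helix = integer(), qualifier = character())
  if (is.na(s) || !nzchar(trimws(s))) return(empty)
  parts <- trimws(strsplit(s, ",")[[1]])
  m <- regmatches(parts, regexec("^TM([1-9])\\s*(?:\\(([EMI])\\))?$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("cannot parse interface term(s): ",
                     paste(parts[bad], collapse = "; "))
  data.frame(helix = as.integer(vapply(m, `[`, "", 2)),
             qualifier = ifelse(nzchar(vapply(m, `[`, "", 3)),
                                vapply(m, `[`, "", 3), "none"))
}

## helix set {1..7} named in an interface string ("Identical" -> NULL)
interface_helix_set <- function(s) {
  if (is.na(s) || identical(trimws(s), "Identical")) return(NULL)
  parse_interface_string(s)$helix
}
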