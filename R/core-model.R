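#' Construct a protomer
#'
#' A protomer is one chain of a receptor complex: its heavy-atom
#' coordinates, derived one-letter sequence, transmembrane (TM) segment
#' annotation and role within the complex. TM segments use 1-based
#' inclusive residue ranges in the numbering of the input coordinates
#' (UniProt convention). Helix 8, the short amphipathic helix following
#' TM7, may be annotated with `h8 = TRUE`; it is excluded from the TM
#' count and from interface strings but participates in contact
#' computations like any other annotated segment.
#'
#' @param chain_id single character chain identifier.
#' @param atoms data.frame with columns `resseq` (integer), `resname`
#'   (3-letter code), `elety` (atom name), `x`, `y`, `z` (Angstrom).
#'   Hydrogens are not expected here; callers strip them on read.
#' @param tm data.frame with columns `index` (integer >= 1), `start`,
#'   `end` (residue numbers, 1-based inclusive) and optionally `h8`
#'   (logical, default `FALSE`).
#' @param role one of `"subject"`, `"partner"`, `"isoform"`.
#' @return object of class `protomer`.
#' @export
new_protomer <- function(chain_id, atoms, tm, role = "subject") {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  role <- match.arg(role, c("subject", "partner", "isoform"))
  req <- c("resseq", "resname", "elety", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("protomer '", chain_id, "' has no atoms")
  atoms$resseq <- as.integer(atoms$resseq)
  # one residue name per residue number
  nm <- tapply(atoms$resname, atoms$resseq, function(z) length(unique(z)))
  if (any(nm > 1L)) {
    stop("residue numbers are not unique within chain '", chain_id, "'")
  }
  if (is.null(tm)) tm <- data.frame(index = integer(), start = integer(),
                                    end = integer(), h8 = logical())
  if (!("h8" %in% names(tm))) tm$h8 <- FALSE
  tm <- tm[order(tm$index), c("index", "start", "end", "h8"), drop = FALSE]
  tm$index <- as.integer(tm$index); tm$start <- as.integer(tm$start)
  tm$end <- as.integer(tm$end); tm$h8 <- as.logical(tm$h8)
  validate_tm(tm, atoms$resseq, chain_id)
  res_order <- sort(unique(atoms$resseq))
  resnames <- atoms$resname[match(res_order, atoms$resseq)]
  p <- list(chain_id = chain_id,
            atoms = atoms[order(atoms$resseq), , drop = FALSE],
            sequence = paste(aa3to1(resnames), collapse = ""),
            tm = tm,
            role = role)
  class(p) <- "protomer"
  p
}

validate_tm <- function(tm, resseq, chain_id) {
  if (nrow(tm) == 0L) return(invisible(TRUE))
  if (any(tm$start > tm$end)) stop("TM segment with start > end")
  if (any(tm$index < 1L)) stop("TM index must be >= 1")
  if (anyDuplicated(tm$index)) stop("duplicated TM index")
  if (nrow(tm) > 1L) {
    for (i in seq_len(nrow(tm) - 1L)) {
      if (tm$end[i] >= tm$start[i + 1L]) {
        stop("TM segments overlap or are not index-ordered")
      }
    }
  }
  for (i in seq_len(nrow(tm))) {
    rng <- tm$start[i]:tm$end[i]
    if (!any(rng %in% resseq)) {
      stop("TM range ", tm$start[i], "-", tm$end[i],
           " is outside the residue numbering of chain '", chain_id, "'")
    }
  }
  invisible(TRUE)
}

#' Number of transmembrane helices of a protomer
#'
#' Counts annotated TM segments with index 1..7; Helix 8 (`h8 = TRUE`)
#' is not counted.
#' @param protomer a `protomer`.
#' @return integer.
#' @export
n_tm <- function(protomer) {
  stopifnot(inherits(protomer, "protomer"))
  sum(!protomer$tm$h8 & protomer$tm$index <= 7L)
}

#' @export
print.protomer <- function(x, ...) {
  cat("<protomer> chain", x$chain_id, "role", x$role, "-",
      length(unique(x$atoms$resseq)), "residues,",
      nrow(x$atoms), "heavy atoms,", n_tm(x), "TM segments",
      if (any(x$tm$h8)) "(+H8)" else "", "\n")
  invisible(x)
}

## C-alpha coordinates of a protomer (optionally restricted to residues)
protomer_ca <- function(p, residues = NULL) {
  a <- p$atoms[p$atoms$elety == "CA", , drop = FALSE]
  if (!is.null(residues)) a <- a[a$resseq %in% residues, , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resseq = a$resseq)
}

protomer_xyz <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])

## residue numbers covered by TM segments (optionally excluding H8)
tm_residues <- function(p, include_h8 = TRUE) {
  tm <- p$tm
  if (!include_h8) tm <- tm[!tm$h8, , drop = FALSE]
  if (nrow(tm) == 0L) return(integer())
  sort(unique(unlist(lapply(seq_len(nrow(tm)),
                            function(i) tm$start[i]:tm$end[i]))))
}

## map residue numbers to TM index (NA for loops), excluding H8 if asked
tm_index_of <- function(p, resseq, include_h8 = FALSE) {
  tm <- p$tm
  if (!include_h8) tm <- tm[!tm$h8, , drop = FALSE]
  out <- rep(NA_integer_, length(resseq))
  for (i in seq_len(nrow(tm))) {
    out[resseq >= tm$start[i] & resseq <= tm$end[i]] <- tm$index[i]
  }
  out
}

#' Binding free energy value
#'
#' MMPBSA-style binding free energy of a complex model, in kcal/mol
#' (more negative = stronger binding), with its standard error of the
#' mean. The package consumes these values; it never computes them.
#'
#' @param mean numeric mean BFE in kcal/mol.
#' @param sem non-negative standard error of the mean.
#' @return object of class `binding_energy`.
#' @export
new_binding_energy <- function(mean, sem = 0) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sem), length(sem) == 1L, is.finite(sem))
  if (sem < 0) stop("sem must be >= 0")
  structure(list(mean = mean, sem = sem), class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f kcal/mol\n", x$mean, x$sem))
  invisible(x)
}

#' Construct a two-protomer complex model
#'
#' @param subject,partner `protomer` objects with distinct chain ids.
#'   The subject is the receptor whose interface is characterised; the
#'   partner is the other protomer (a receptor or a truncated isoform).
#' @param designation optional `model_designation` (see
#'   [parse_model_designation()]).
#' @param bfe optional `binding_energy`.
#' @param energy_table optional per-residue energy decomposition
#'   data.frame with columns `chain`, `resseq`, `contribution` (kcal/mol).
#' @param complex_name optional text such as `"CXCR2-Iso_2TM"`.
#' @return object of class `complex_model`.
#' @export
new_complex_model <- function(subject, partner, designation = NULL,
                              bfe = NULL, energy_table = NULL,
                              complex_name = "") {
  stopifnot(inherits(subject, "protomer"), inherits(partner, "protomer"))
  if (identical(subject$chain_id, partner$chain_id)) {
    stop("subject and partner must have distinct chain ids")
  }
  if (!is.null(bfe) && !inherits(bfe, "binding_energy")) {
    bfe <- new_binding_energy(bfe[[1]], bfe[[2]] %||% 0)
  }
  if (!is.null(energy_table)) validate_energy_table(energy_table)
  m <- list(subject = subject, partner = partner,
            designation = designation, bfe = bfe,
            energy_table = energy_table, complex_name = complex_name)
  class(m) <- "complex_model"
  m
}

validate_energy_table <- function(et) {
  req <- c("chain", "resseq", "contribution")
  if (!all(req %in% names(et))) {
    stop("energy table must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(is.finite(et$contribution))) {
    stop("energy table contains non-finite contributions")
  }
  invisible(TRUE)
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model>", if (nzchar(x$complex_name)) x$complex_name else "",
      if (!is.null(x$designation)) paste0("[", x$designation$label, "]") else "",
      "\n  subject: chain", x$subject$chain_id, sprintf("(%d TM)", n_tm(x$subject)),
      "\n  partner: chain", x$partner$chain_id, sprintf("(%d TM)", n_tm(x$partner)), "\n")
  if (!is.null(x$bfe)) {
    cat(sprintf("  BFE: %.2f +/- %.2f kcal/mol\n", x$bfe$mean, x$bfe$sem))
  }
  invisible(x)
}

## TRUE when the two protomers carry the same sequence (homodimer rule)
is_homodimer <- function(cm) {
  identical(cm$subject$sequence, cm$partner$sequence)
}

#' Parse a model designation label
#'
#' Labels follow the docking/prediction dialect: `"AF-k"` is the rank-k
#' AlphaFold-Multimer model, `"CP-n"` the ClusPro model number n obtained
#' with the default Balanced scoring, and `"CP-Hn"` the ClusPro model
#' number n obtained with the Hydrophobic-favored scoring.
#'
#' @param label designation text, e.g. `"AF-1"`, `"CP-12"`, `"CP-H18"`.
#' @return object of class `model_designation` with fields `source`
#'   (`"alphafold"` or `"cluspro"`), `mode` (`"none"`, `"balanced"` or
#'   `"hydrophobic"`), `number` and the canonical `label`.
#' @export
#' @examples
#' parse_model_designation("AF-1")
#' parse_model_designation("CP-H18")
parse_model_designation <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (grepl("^AF-[0-9]+$", label)) {
    src <- "alphafold"; mode <- "none"
    num <- as.integer(sub("^AF-", "", label))
  } else if (grepl("^CP-H[0-9]+$", label)) {
    src <- "cluspro"; mode <- "hydrophobic"
    num <- as.integer(sub("^CP-H", "", label))
  } else if (grepl("^CP-[0-9]+$", label)) {
    src <- "cluspro"; mode <- "balanced"
    num <- as.integer(sub("^CP-", "", label))
  } else {
    stop("unknown model designation: '", label, "'")
  }
  if (num < 1L) stop("model number must be >= 1")
  structure(list(source = src, mode = mode, number = num,
                 label = format_model_designation_parts(src, mode, num)),
            class = "model_designation")
}

format_model_designation_parts <- function(source, mode, number) {
  switch(source,
         alphafold = paste0("AF-", number),
         cluspro = if (mode == "hydrophobic") paste0("CP-H", number)
                   else paste0("CP-", number),
         stop("unknown source: ", source))
}

#' Canonical label of a model designation
#' @param x a `model_designation`.
#' @return character label.
#' @export
format_model_designation <- function(x) {
  stopifnot(inherits(x, "model_designation"))
  format_model_designation_parts(x$source, x$mode, x$number)
}

#' @export
print.model_designation <- function(x, ...) {
  cat("<model_designation>", x$label, sprintf("(%s, %s, #%d)\n",
      x$source, x$mode, x$number))
  invisible(x)
}
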