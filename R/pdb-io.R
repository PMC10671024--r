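#' Read a two-chain complex from a PDB file
#'
#' Loads heavy-atom coordinates for the chains named in `chain_roles`,
#' attaches TM annotations, and assembles a [new_complex_model()].
#' Hydrogens are dropped on read; all distance criteria downstream are
#' heavy-atom based. If `chain_roles`/`tm_annotations` are omitted the
#' JSON sidecar written by [write_complex_pdb()] (`<path>.json`) is used.
#'
#' @param path PDB file.
#' @param chain_roles named character vector mapping chain id to role
#'   (`"subject"`, `"partner"` or `"isoform"`); exactly one subject.
#' @param tm_annotations named list mapping chain id to a TM data.frame
#'   (`index`, `start`, `end`, optional `h8`).
#' @param designation optional designation label (e.g. `"CP-12"`).
#' @param bfe optional `binding_energy` or `c(mean, sem)`.
#' @param complex_name optional complex name.
#' @return a `complex_model`.
#' @export
read_complex_pdb <- function(path, chain_roles = NULL, tm_annotations = NULL,
                             designation = NULL, bfe = NULL,
                             complex_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(chain_roles)) {
    if (is.null(meta)) stop("chain_roles not given and no sidecar found")
    chain_roles <- unlist(meta$chain_roles)
  }
  if (is.null(tm_annotations)) {
    if (is.null(meta)) stop("tm_annotations not given and no sidecar found")
    tm_annotations <- lapply(meta$tm_annotations, as.data.frame)
  }
  if (is.null(complex_name)) complex_name <- meta$complex_name %||% ""
  if (is.null(designation) && !is.null(meta$designation)) {
    designation <- meta$designation
  }
  if (is.null(bfe) && !is.null(meta$bfe)) bfe <- unlist(meta$bfe)
  if (length(chain_roles) < 2L) stop("need at least two chains in chain_roles")
  if (sum(chain_roles == "subject") != 1L) {
    stop("chain_roles must name exactly one subject chain")
  }

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  # drop hydrogens by element symbol, fall back to atom-name heuristics
  if ("elesy" %in% names(at)) {
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  }
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]

  protomers <- lapply(names(chain_roles), function(ch) {
    sel <- at[at$chain == ch, , drop = FALSE]
    if (nrow(sel) == 0L) stop("chain ", ch, " absent from ", path)
    atoms <- data.frame(resseq = sel$resno, resname = sel$resid,
                        elety = sel$elety, x = sel$x, y = sel$y, z = sel$z,
                        stringsAsFactors = FALSE)
    tm <- tm_annotations[[ch]]
    if (is.null(tm)) stop("no TM annotation for chain ", ch)
    new_protomer(ch, atoms, tm, role = unname(chain_roles[ch]))
  })
  names(protomers) <- names(chain_roles)

  subj <- protomers[[which(chain_roles == "subject")]]
  part <- protomers[[which(chain_roles != "subject")[1]]]
  des <- if (is.character(designation)) parse_model_designation(designation)
         else designation
  new_complex_model(subj, part, designation = des, bfe = bfe,
                    complex_name = complex_name)
}

#' Write a complex model to a PDB file with a JSON sidecar
#'
#' Coordinates are written at standard PDB precision (0.001 A). Chain
#' roles, TM annotations, the designation label, complex name and BFE
#' travel in `<path>.json` so that [read_complex_pdb()] round-trips the
#' full model.
#'
#' @param model a `complex_model`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(model, path) {
  stopifnot(inherits(model, "complex_model"))
  chains <- list(model$subject, model$partner)
  for (p in chains) {
    if (nrow(p$atoms) == 0L) stop("cannot write an empty protomer")
  }
  at <- do.call(rbind, lapply(chains, function(p) {
    cbind(p$atoms, chain = p$chain_id, stringsAsFactors = FALSE)
  }))
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resseq, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  roles <- c(model$subject$role, model$partner$role)
  roles[1] <- "subject"  # the subject slot defines the subject role
  meta <- list(
    chain_roles = as.list(structure(roles,
      names = c(model$subject$chain_id, model$partner$chain_id))),
    tm_annotations = structure(
      list(model$subject$tm, model$partner$tm),
      names = c(model$subject$chain_id, model$partner$chain_id)),
    complex_name = model$complex_name,
    designation = if (!is.null(model$designation)) model$designation$label,
    bfe = if (!is.null(model$bfe)) list(mean = model$bfe$mean,
                                        sem = model$bfe$sem))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a per-residue energy decomposition table
#'
#' Expects a CSV/TSV with columns `chain`, `resseq`, `resname` and
#' `contribution_kcal_mol` (or `contribution`), one row per residue, as
#' exported from an MMPBSA per-residue decomposition.
#'
#' @param path file path; separator inferred from the extension.
#' @return data.frame with columns `chain`, `resseq`, `resname`,
#'   `contribution`.
#' @export
read_energy_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  et <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("contribution_kcal_mol" %in% names(et)) {
    et$contribution <- et$contribution_kcal_mol
  }
  validate_energy_table(et)
  if (!("resname" %in% names(et))) et$resname <- NA_character_
  et[, c("chain", "resseq", "resname", "contribution")]
}

#' Write a per-residue energy decomposition table as CSV
#' @param energy_table data.frame as returned by [synth_energy_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(energy_table, path) {
  validate_energy_table(energy_table)
  out <- data.frame(chain = energy_table$chain,
                    resseq = energy_table$resseq,
                    resname = energy_table$resname %||% NA_character_,
                    contribution_kcal_mol = energy_table$contribution)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
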