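#' Start a higher-order oligomer assembly from a seed protomer
#'
#' @param protomer the seed `protomer`; placed with the identity
#'   transform (its coordinates are never moved afterwards).
#' @param label placement label (default `"P1"`).
#' @return object of class `oligomer_assembly`.
#' @export
new_oligomer <- function(protomer, label = "P1") {
  stopifnot(inherits(protomer, "protomer"))
  structure(list(placements = list(list(
    label = label, protomer = protomer, parent = NA_character_,
    dimer_label = NA_character_,
    iface_anchor = integer(), iface_partner = integer()))),
    class = "oligomer_assembly")
}

#' Extend an oligomer by one protomer using a dimer model
#'
#' Superposes the dimer model's subject protomer onto an already placed
#' anchor protomer (C-alpha TM atoms, Kabsch) and adds the dimer's
#' partner with the induced rigid transform. Previously placed
#' protomers are never moved; alternating distinct interfaces on the
#' shared protomer is what lets chains extend without running into
#' themselves.
#'
#' @param assembly an `oligomer_assembly`.
#' @param dimer_model a `complex_model` whose subject sequence equals
#'   the anchor's protomer sequence.
#' @param anchor_label label of the placement to extend from.
#' @param new_label label for the added protomer (default `"P<k>"`).
#' @param cutoff_A contact cutoff used to record the designed interface
#'   of this extension (for clash-report exclusions).
#' @return the extended `oligomer_assembly`.
#' @export
extend_oligomer <- function(assembly, dimer_model, anchor_label,
                            new_label = NULL, cutoff_A = 5) {
  stopifnot(inherits(assembly, "oligomer_assembly"),
            inherits(dimer_model, "complex_model"))
  labels <- vapply(assembly$placements, `[[`, "", "label")
  k <- match(anchor_label, labels)
  if (is.na(k)) stop("anchor '", anchor_label, "' not in assembly")
  anchor <- assembly$placements[[k]]$protomer
  if (!identical(dimer_model$subject$sequence, anchor$sequence)) {
    stop("dimer subject sequence does not match the anchor protomer")
  }
  ca_s <- protomer_ca(dimer_model$subject, tm_residues(dimer_model$subject))
  ca_a <- protomer_ca(anchor, tm_residues(anchor))
  shared <- intersect(ca_s$resseq, ca_a$resseq)
  if (length(shared) < 3L) stop("fewer than 3 common TM C-alpha atoms")
  fit <- kabsch(ca_s$xyz[match(shared, ca_s$resseq), , drop = FALSE],
                ca_a$xyz[match(shared, ca_a$resseq), , drop = FALSE])
  placed <- apply_transform(dimer_model$partner, fit$rotation,
                            fit$translation)
  ifc <- interface_residues(dimer_model, cutoff_A)
  if (is.null(new_label)) {
    new_label <- paste0("P", length(assembly$placements) + 1L)
  }
  assembly$placements[[length(assembly$placements) + 1L]] <- list(
    label = new_label, protomer = placed, parent = anchor_label,
    dimer_label = if (!is.null(dimer_model$designation))
      dimer_model$designation$label else NA_character_,
    iface_anchor = ifc$subject, iface_partner = ifc$partner)
  assembly
}

#' Steric clash report of an oligomer assembly
#'
#' Lists residue pairs of distinct placements whose heavy atoms come
#' closer than `clash_cutoff_A`. For placements joined by an extension
#' (anchor and its added partner) the residue pairs belonging to that
#' extension's designed interface are excluded, since those contacts
#' are intentional; everything else that approaches below the cutoff is
#' reported. The assembly is clash-free when the report is empty.
#'
#' @param assembly an `oligomer_assembly` with >= 2 placements.
#' @param clash_cutoff_A heavy-atom clash threshold in Angstrom
#'   (default 2). Clashes are detected, never repaired.
#' @return data.frame with columns `placement_a`, `placement_b`,
#'   `res_a`, `res_b`, `min_dist`; zero rows when clash-free.
#' @export
clash_check <- function(assembly, clash_cutoff_A = 2) {
  stopifnot(inherits(assembly, "oligomer_assembly"))
  pl <- assembly$placements
  if (length(pl) < 2L) stop("need at least 2 placements")
  out <- list()
  for (i in seq_len(length(pl) - 1L)) {
    for (j in (i + 1L):length(pl)) {
      a <- pl[[i]]; b <- pl[[j]]
      ct <- residue_contacts(protomer_xyz(a$protomer),
                             a$protomer$atoms$resseq,
                             protomer_xyz(b$protomer),
                             b$protomer$atoms$resseq,
                             clash_cutoff_A)
      if (nrow(ct) == 0L) next
      # drop designed-interface pairs of the extension joining a and b
      if (identical(b$parent, a$label)) {
        drop <- ct$res_a %in% b$iface_anchor & ct$res_b %in% b$iface_partner
        ct <- ct[!drop, , drop = FALSE]
      } else if (identical(a$parent, b$label)) {
        drop <- ct$res_b %in% a$iface_anchor & ct$res_a %in% a$iface_partner
        ct <- ct[!drop, , drop = FALSE]
      }
      if (nrow(ct) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          placement_a = a$label, placement_b = b$label,
          res_a = ct$res_a, res_b = ct$res_b, min_dist = ct$min_dist)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(placement_a = character(), placement_b = character(),
                      res_a = integer(), res_b = integer(),
                      min_dist = numeric()))
  }
  do.call(rbind, out)
}

#' @export
print.oligomer_assembly <- function(x, ...) {
  cat("<oligomer_assembly>", length(x$placements), "placements:\n")
  for (p in x$placements) {
    cat("  ", p$label,
        if (is.na(p$parent)) "(seed)" else paste0("<- ", p$parent),
        "\n")
  }
  invisible(x)
}

#' Apply a rigid transform to a whole assembly
#' @export
#' @rdname apply_transform
apply_transform.oligomer_assembly <- function(x, rotation, translation) {
  x$placements <- lapply(x$placements, function(p) {
    p$protomer <- apply_transform(p$protomer, rotation, translation)
    p
  })
  x
}

#' Write an oligomer assembly as a multi-chain PDB
#'
#' Placements are renamed to chains A, B, C, ... in placement order.
#'
#' @param assembly an `oligomer_assembly`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(assembly, path) {
  stopifnot(inherits(assembly, "oligomer_assembly"))
  pl <- assembly$placements
  if (length(pl) > 26L) stop("more than 26 placements")
  at <- do.call(rbind, lapply(seq_along(pl), function(i) {
    a <- pl[[i]]$protomer$atoms
    cbind(a, chain = LETTERS[i], stringsAsFactors = FALSE)
  }))
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resseq,
                   resid = at$resname, eleno = seq_len(nrow(at)),
                   elety = at$elety, chain = at$chain,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}
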