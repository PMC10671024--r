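#' Fit a membrane frame from TM annotations
#'
#' Infers the putative membrane geometry of a protomer from its
#' transmembrane segments alone (no lipid placement). Each TM helix
#' contributes an axis estimated from the C-alpha centroids of its two
#' end caps; because GPCR helices alternate direction through the
#' membrane (odd-indexed helices run extracellular to intracellular),
#' odd-index axes are flipped before averaging so that all axes point
#' toward the extracellular side. The membrane normal is the normalised
#' mean axis; the midplane point is the centroid of the per-segment
#' C-alpha midpoints. The normal sign is checked against the N-terminal
#' end of the first TM helix, which for chemokine receptors lies
#' extracellular, and flipped if needed.
#'
#' @param protomer a `protomer` with at least two TM segments.
#' @param half_thickness membrane slab half-thickness in Angstrom
#'   (annotation-driven default 15).
#' @return object of class `membrane_frame` with fields `normal` (unit
#'   3-vector pointing extracellular), `midplane_point`, `half_thickness`
#'   and `fit_residual` (RMS distance of TM midpoints to the midplane, A).
#' @export
fit_membrane_frame <- function(protomer, half_thickness = 15) {
  stopifnot(inherits(protomer, "protomer"))
  tm <- protomer$tm[!protomer$tm$h8, , drop = FALSE]
  if (nrow(tm) < 2L) stop("cannot infer membrane: fewer than 2 TM segments")

  axes <- matrix(NA_real_, nrow(tm), 3)
  mids <- matrix(NA_real_, nrow(tm), 3)
  starts <- matrix(NA_real_, nrow(tm), 3)
  for (i in seq_len(nrow(tm))) {
    ca <- protomer_ca(protomer, tm$start[i]:tm$end[i])
    if (nrow(ca$xyz) < 4L) stop("TM segment ", tm$index[i], " too short to fit")
    # centroid of 18 consecutive residues (5 turns at 3.6 res/turn)
    # cancels the helical phase and sits on the axis; fall back to
    # short end caps for helices under 19 residues
    ncap <- if (nrow(ca$xyz) >= 19L) 18L
            else max(2L, min(4L, nrow(ca$xyz) %/% 3L))
    head_c <- colMeans(ca$xyz[seq_len(ncap), , drop = FALSE])
    tail_c <- colMeans(ca$xyz[nrow(ca$xyz) - seq_len(ncap) + 1L, , drop = FALSE])
    ax <- unitv(tail_c - head_c)            # N-end -> C-end of the helix
    if (tm$index[i] %% 2L == 1L) ax <- -ax  # odd helices run EC -> IC
    axes[i, ] <- ax
    mids[i, ] <- colMeans(ca$xyz)
    starts[i, ] <- head_c
  }
  normal <- unitv(colMeans(axes))
  midplane <- colMeans(mids)
  # sign check: the N-terminal cap of the lowest-index TM is extracellular
  first <- which.min(tm$index)
  if (sum((starts[first, ] - midplane) * normal) < 0) normal <- -normal
  resid <- sqrt(mean((mids %*% normal - sum(midplane * normal))^2))
  structure(list(normal = as.numeric(normal),
                 midplane_point = as.numeric(midplane),
                 half_thickness = half_thickness,
                 fit_residual = as.numeric(resid)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> normal (%.3f, %.3f, %.3f), midplane (%.1f, %.1f, %.1f), residual %.2f A\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$midplane_point[1], x$midplane_point[2], x$midplane_point[3],
              x$fit_residual))
  invisible(x)
}

#' Orientation consistency between two membrane frames
#'
#' Topology rule (i): both protomers must sit in the membrane with a
#' typical receptor orientation, i.e. their inferred membrane normals
#' must agree within a tolerance angle.
#'
#' @param frame_a,frame_b `membrane_frame` objects.
#' @param tol_angle_deg tolerance in degrees (default 30).
#' @return list with `pass` (logical) and `angle` (degrees, in [0, 180]).
#' @export
orientation_consistent <- function(frame_a, frame_b, tol_angle_deg = 30) {
  d <- sum(frame_a$normal * frame_b$normal)
  d <- max(-1, min(1, d))
  angle <- rad2deg(acos(d))
  list(pass = angle <= tol_angle_deg, angle = angle)
}

#' Membrane layer consistency between two membrane frames
#'
#' Topology rule (ii): the membrane slabs inferred from the two
#' protomers must be spatially consistent; quantified as the offset of
#' the two midplane points along the mean normal. When the normals are
#' anti-parallel (an upside-down protomer, already failing rule i) the
#' first frame's normal is used as the reference direction.
#'
#' @param frame_a,frame_b `membrane_frame` objects.
#' @param tol_offset_a tolerance in Angstrom (default 8).
#' @return list with `pass` (logical) and `offset` (A).
#' @export
layers_consistent <- function(frame_a, frame_b, tol_offset_a = 8) {
  s <- frame_a$normal + frame_b$normal
  axis <- if (vnorm(s) < 1e-6) frame_a$normal else unitv(s)
  offset <- abs(sum((frame_a$midplane_point - frame_b$midplane_point) * axis))
  list(pass = offset <= tol_offset_a, offset = offset)
}

#' Topology-compliance filter for a docked complex model
#'
#' Applies the three topology rules used to triage docked dimer poses:
#' (i) both protomers adopt a consistent, typical membrane orientation;
#' (ii) the membrane layers inferred from their TM segments are
#' spatially consistent; (iii) for homodimers (identical protomer
#' sequences) the interface composition of the two protomers, compared
#' at the TM-helix-set level, is identical. Rule (iii) is reported as
#' not applicable (`NA`) for heterodimers. The pose is compliant when
#' all applicable rules pass.
#'
#' @param cm a `complex_model` with TM-annotated protomers.
#' @param params thresholds from [screen_params()] (`orientation_tol_deg`,
#'   `layer_tol_A`, `cutoff_A`).
#' @return object of class `compliance_report`: `rule_orientation`,
#'   `rule_layers`, `rule_symmetry` (pass/fail/NA plus the helix sets
#'   compared), and `compliant`.
#' @export
topology_filter <- function(cm, params = screen_params()) {
  stopifnot(inherits(cm, "complex_model"))
  fa <- fit_membrane_frame(cm$subject, params$half_thickness_A)
  fb <- fit_membrane_frame(cm$partner, params$half_thickness_A)
  r1 <- orientation_consistent(fa, fb, params$orientation_tol_deg)
  r2 <- layers_consistent(fa, fb, params$layer_tol_A)

  if (is_homodimer(cm)) {
    ifc <- interface_residues(cm, params$cutoff_A)
    hs <- sort(unique(stats::na.omit(tm_index_of(cm$subject, ifc$subject))))
    hp <- sort(unique(stats::na.omit(tm_index_of(cm$partner, ifc$partner))))
    r3 <- list(pass = setequal(hs, hp), subject_helices = hs,
               partner_helices = hp)
  } else {
    r3 <- list(pass = NA, subject_helices = NULL, partner_helices = NULL)
  }
  applicable <- c(r1$pass, r2$pass, if (!is.na(r3$pass)) r3$pass)
  structure(list(rule_orientation = r1, rule_layers = r2,
                 rule_symmetry = r3, compliant = all(applicable)),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("<compliance_report>\n",
      sprintf("  (i) orientation: %s (angle %.1f deg)\n",
              if (x$rule_orientation$pass) "pass" else "FAIL",
              x$rule_orientation$angle),
      sprintf("  (ii) layers: %s (offset %.1f A)\n",
              if (x$rule_layers$pass) "pass" else "FAIL",
              x$rule_layers$offset),
      if (is.na(x$rule_symmetry$pass)) "  (iii) symmetry: not applicable (heterodimer)\n"
      else sprintf("  (iii) symmetry: %s (subject {%s} vs partner {%s})\n",
                   if (x$rule_symmetry$pass) "pass" else "FAIL",
                   paste(x$rule_symmetry$subject_helices, collapse = ","),
                   paste(x$rule_symmetry$partner_helices, collapse = ",")),
      sprintf("  compliant: %s\n", x$compliant), sep = "")
  invisible(x)
}
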