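#' Specification of an idealized TM helix bundle
#'
#' Describes a synthetic protomer: `n_tm` straight alpha-helices
#' (backbone N, CA, C, O plus a CB marker) arranged on a circle and
#' alternating up/down through a planar membrane, notionally connected
#' by loops (loop residues occupy numbering but carry no atoms). These
#' bundles emulate receptor protomers and their truncated Iso_XTM
#' isoforms: `n_tm = 2` yields an "Iso_2TM"-style protomer.
#'
#' Each helix is built from ideal geometry: 1.5 A rise per residue,
#' 100 degrees of turn per residue, C-alpha at 2.3 A from the helix
#' axis. Every helix uses a distinct marker residue type so interface
#' residue sets can be verified by sequence inspection.
#'
#' @param n_tm number of TM helices (2-7).
#' @param residues_per_tm residues per helix (default 26).
#' @param loop_len numbering gap between helices (default 6).
#' @param bundle_radius circle radius for helix axes in A (default 12).
#' @param rise_per_res,twist_deg,ca_radius ideal helix geometry.
#' @param markers 3-letter marker residue per helix.
#' @param jitter_sd optional Gaussian coordinate noise (A, default 0).
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_tm = 7, residues_per_tm = 26, loop_len = 6,
                        bundle_radius = 12, rise_per_res = 1.5,
                        twist_deg = 100, ca_radius = 2.3,
                        markers = c("LEU", "ILE", "VAL", "PHE",
                                    "TRP", "MET", "TYR"),
                        jitter_sd = 0, seed = 1) {
  if (!(n_tm %in% 2:7)) stop("n_tm must be in 2..7")
  stopifnot(residues_per_tm > 3, loop_len >= 0, bundle_radius > 0,
            rise_per_res > 0, ca_radius > 0, jitter_sd >= 0)
  if (length(markers) < n_tm) stop("need one marker residue per helix")
  structure(list(n_tm = as.integer(n_tm),
                 residues_per_tm = as.integer(residues_per_tm),
                 loop_len = as.integer(loop_len),
                 bundle_radius = bundle_radius,
                 rise_per_res = rise_per_res, twist_deg = twist_deg,
                 ca_radius = ca_radius, markers = markers[seq_len(n_tm)],
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Build an idealized TM bundle protomer
#'
#' Deterministic for a given spec and seed. The membrane midplane of
#' the constructed bundle is the z = 0 plane with the extracellular
#' side at +z; odd-indexed helices run top to bottom (extracellular to
#' intracellular), even-indexed ones bottom to top, as in a GPCR fold.
#'
#' @param spec a [bundle_spec()].
#' @param chain_id chain identifier (default `"A"`).
#' @param role protomer role (default `"subject"`).
#' @return a `protomer` with attached TM annotations.
#' @export
build_ideal_bundle <- function(spec, chain_id = "A", role = "subject") {
  stopifnot(inherits(spec, "bundle_spec"))
  rpt <- spec$residues_per_tm
  height <- (rpt - 1) * spec$rise_per_res
  rows <- vector("list", spec$n_tm)
  tm <- data.frame(index = integer(), start = integer(), end = integer(),
                   h8 = logical())
  for (k in seq_len(spec$n_tm)) {
    # seven-helix angular pitch regardless of truncation, so a 2-5 TM
    # isoform bundle is an arc of the full seven-helix circle
    phi <- 2 * pi * (k - 1) / 7
    centre <- spec$bundle_radius * c(cos(phi), sin(phi))
    down <- (k %% 2L == 1L)                 # odd helices run EC -> IC
    dirz <- if (down) -1 else 1
    start <- (k - 1L) * (rpt + spec$loop_len) + 1L
    j <- seq_len(rpt)
    zc <- if (down) height / 2 - (j - 1) * spec$rise_per_res
          else -height / 2 + (j - 1) * spec$rise_per_res
    th <- deg2rad(rad2deg(phi) + 180 + (j - 1) * spec$twist_deg)
    atom_of <- function(name, r, dth_deg, dz) {
      a <- th + deg2rad(dth_deg)
      data.frame(resseq = start + j - 1L, resname = spec$markers[k],
                 elety = name,
                 x = centre[1] + r * cos(a), y = centre[2] + r * sin(a),
                 z = zc + dirz * dz, stringsAsFactors = FALSE)
    }
    rows[[k]] <- rbind(atom_of("N", 1.6, -28, -0.9),
                       atom_of("CA", spec$ca_radius, 0, 0),
                       atom_of("C", 1.7, 25, 0.6),
                       atom_of("O", 1.7, 25, 1.8),
                       atom_of("CB", spec$ca_radius + 1.53, 0, 0))
    tm <- rbind(tm, data.frame(index = k, start = start,
                               end = start + rpt - 1L, h8 = FALSE))
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$resseq, match(atoms$elety,
                                           c("N", "CA", "C", "O", "CB"))), ]
  if (spec$jitter_sd > 0) {
    set.seed(spec$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$jitter_sd)
  }
  new_protomer(chain_id, atoms, tm, role = role)
}

#' Specification of a designed dimer pose
#'
#' @param facing_subject,facing_partner helix indices that form the
#'   designed interface on each bundle.
#' @param axis_separation separation between the facing helix axes in A
#'   (default 10).
#' @param partner_twist_deg extra rotation of the partner about its own
#'   bundle axis after facing alignment (perturbation, default 0).
#' @param max_clashes placement fails when more heavy-atom pairs than
#'   this come closer than 2 A (default 0).
#' @param seed RNG seed (reserved for stochastic variants).
#' @return object of class `dimer_pose_spec`.
#' @export
dimer_pose_spec <- function(facing_subject, facing_partner = facing_subject,
                            axis_separation = 10, partner_twist_deg = 0,
                            max_clashes = 0, seed = 1) {
  stopifnot(length(facing_subject) >= 1, length(facing_partner) >= 1,
            axis_separation > 0)
  structure(list(facing_subject = as.integer(facing_subject),
                 facing_partner = as.integer(facing_partner),
                 axis_separation = axis_separation,
                 partner_twist_deg = partner_twist_deg,
                 max_clashes = max_clashes, seed = as.integer(seed)),
            class = "dimer_pose_spec")
}

## xy centroid of the axes of the given helices, from C-alpha coords
facing_centroid_xy <- function(bundle, helices) {
  tm <- bundle$tm[!bundle$tm$h8, , drop = FALSE]
  if (!all(helices %in% tm$index)) {
    stop("facing helices not present in the bundle: ",
         paste(setdiff(helices, tm$index), collapse = ","))
  }
  xy <- t(vapply(helices, function(h) {
    row <- tm[tm$index == h, ]
    ca <- protomer_ca(bundle, row$start:row$end)
    colMeans(ca$xyz[, 1:2, drop = FALSE])
  }, numeric(2)))
  colMeans(xy)
}

#' Place two bundles into a designed dimer pose
#'
#' Rotates the partner bundle about its own axis so that its facing
#' helices point at the subject's facing helices, then translates it in
#' the membrane plane to the requested axis separation. Both bundles
#' share the membrane frame (z = 0 midplane). The placement emulates a
#' topology-compliant docked pose with a designed facing-helix
#' interface.
#'
#' @param bundle_a subject bundle (kept fixed at the origin).
#' @param bundle_b partner bundle (moved); roles are preserved, chain
#'   id is forced to differ from the subject's.
#' @param pose a [dimer_pose_spec()].
#' @param designation designation label for the resulting model
#'   (default `"CP-1"`).
#' @param complex_name optional complex name.
#' @param bfe optional `binding_energy` or `c(mean, sem)`.
#' @return a `complex_model`.
#' @export
place_dimer <- function(bundle_a, bundle_b, pose,
                        designation = "CP-1", complex_name = "",
                        bfe = NULL) {
  stopifnot(inherits(bundle_a, "protomer"), inherits(bundle_b, "protomer"),
            inherits(pose, "dimer_pose_spec"))
  va <- facing_centroid_xy(bundle_a, pose$facing_subject)
  vb <- facing_centroid_xy(bundle_b, pose$facing_partner)
  if (vnorm(va) < 1e-6 || vnorm(vb) < 1e-6) {
    stop("facing helices are arranged symmetrically about the bundle axis; ",
         "their centroid direction is undefined")
  }
  u <- unitv(c(va, 0))[1:2]
  r_a <- sum(va * u)
  r_b <- vnorm(vb)
  # rotate partner so its facing centroid points along -u
  ang <- rad2deg(atan2(-u[2], -u[1]) - atan2(vb[2], vb[1]))
  rot <- rotation_about(c(0, 0, 1), ang)
  b <- apply_transform(bundle_b, rot, c(0, 0, 0))
  if (pose$partner_twist_deg != 0) {
    b <- apply_transform(b, rotation_about(c(0, 0, 1),
                                           pose$partner_twist_deg),
                         c(0, 0, 0))
  }
  shift <- c(u * (r_a + r_b + pose$axis_separation), 0)
  b <- apply_transform(b, diag(3), shift)
  if (identical(b$chain_id, bundle_a$chain_id)) {
    b$chain_id <- if (bundle_a$chain_id == "B") "C" else "B"
  }
  if (b$role == "subject") b$role <- "partner"
  a <- bundle_a; a$role <- "subject"
  # interpenetration guard
  ct <- residue_contacts(protomer_xyz(a), a$atoms$resseq,
                         protomer_xyz(b), b$atoms$resseq, 2)
  if (nrow(ct) > pose$max_clashes) {
    stop("bundles interpenetrate at separation ", pose$axis_separation,
         " A (", nrow(ct), " clashing residue pairs)")
  }
  des <- if (is.character(designation)) parse_model_designation(designation)
         else designation
  new_complex_model(a, b, designation = des, bfe = bfe,
                    complex_name = complex_name)
}

#' Generate a topology decoy from a complex model
#'
#' Negative controls violating one targeted topology rule each:
#' `"flip"` turns the partner upside down (180 degrees about an
#' in-plane axis; violates orientation rule i), `"offset"` translates
#' the partner along the membrane normal (violates layer rule ii),
#' `"tilt"` tilts the partner by `magnitude` degrees (compliant at
#' small angles), `"asymmetric"` rotates the partner about its own
#' bundle axis by `magnitude` helix steps so that a homodimer's two
#' interface helix sets differ (violates symmetry rule iii).
#'
#' @param cm a `complex_model` (typically from [place_dimer()]).
#' @param mode one of `"flip"`, `"offset"`, `"tilt"`, `"asymmetric"`.
#' @param magnitude mode-specific: A for `"offset"` (default 15),
#'   degrees for `"tilt"` (default 10), helix steps for `"asymmetric"`
#'   (default 2).
#' @param seed reserved for stochastic variants.
#' @return the decoy `complex_model`.
#' @export
make_decoy <- function(cm, mode, magnitude = NULL, seed = 1) {
  stopifnot(inherits(cm, "complex_model"))
  mode <- match.arg(mode, c("flip", "offset", "tilt", "asymmetric"))
  p <- cm$partner
  centroid <- colMeans(protomer_xyz(p))
  about_centroid <- function(prot, rot) {
    apply_transform(prot, rot, centroid - as.numeric(rot %*% centroid))
  }
  cm$partner <- switch(mode,
    flip = about_centroid(p, rotation_about(c(1, 0, 0), 180)),
    offset = apply_transform(p, diag(3),
                             c(0, 0, magnitude %||% 15)),
    tilt = about_centroid(p, rotation_about(c(1, 0, 0),
                                            magnitude %||% 10)),
    asymmetric = about_centroid(p, rotation_about(c(0, 0, 1),
      (magnitude %||% 2) * 360 / max(1L, n_tm(p)))))
  cm
}

#' Synthesize a per-residue energy decomposition table
#'
#' Emulates an MMPBSA per-residue decomposition for a designed pose:
#' `interface_frac` of the total binding free energy is spread over the
#' interface residues of both protomers proportionally to their contact
#' counts, the remainder evenly over non-interface residues, and
#' Gaussian noise is added. Deterministic for a given seed.
#'
#' @param cm a `complex_model` with a nonempty interface.
#' @param total_bfe_mean total BFE to distribute (kcal/mol, < 0).
#' @param interface_frac fraction assigned to interface residues
#'   (default 0.9).
#' @param noise_sd Gaussian noise per residue (kcal/mol, default 0.1).
#' @param seed RNG seed.
#' @param cutoff_A contact cutoff (default 5).
#' @return data.frame with columns `chain`, `resseq`, `resname`,
#'   `contribution`.
#' @export
synth_energy_table <- function(cm, total_bfe_mean = -100,
                               interface_frac = 0.9, noise_sd = 0.1,
                               seed = 1, cutoff_A = 5) {
  stopifnot(inherits(cm, "complex_model"))
  if (total_bfe_mean >= 0) stop("total_bfe_mean must be negative")
  ct <- residue_contacts(protomer_xyz(cm$subject), cm$subject$atoms$resseq,
                         protomer_xyz(cm$partner), cm$partner$atoms$resseq,
                         cutoff_A)
  if (nrow(ct) == 0L) stop("empty interface: nothing to decompose")
  rows <- rbind(
    residue_table(cm$subject),
    residue_table(cm$partner))
  counts <- c(table(ct$res_a)[as.character(rows$resseq[rows$chain ==
                                             cm$subject$chain_id])],
              table(ct$res_b)[as.character(rows$resseq[rows$chain ==
                                             cm$partner$chain_id])])
  counts[is.na(counts)] <- 0
  w <- as.numeric(counts)
  on_iface <- w > 0
  contribution <- numeric(nrow(rows))
  contribution[on_iface] <- total_bfe_mean * interface_frac *
    w[on_iface] / sum(w[on_iface])
  if (any(!on_iface)) {
    contribution[!on_iface] <- total_bfe_mean * (1 - interface_frac) /
      sum(!on_iface)
  }
  set.seed(seed)
  rows$contribution <- contribution + stats::rnorm(nrow(rows), 0, noise_sd)
  rows
}

residue_table <- function(p) {
  rs <- sort(unique(p$atoms$resseq))
  data.frame(chain = p$chain_id, resseq = rs,
             resname = p$atoms$resname[match(rs, p$atoms$resseq)],
             stringsAsFactors = FALSE)
}
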