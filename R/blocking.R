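#' Overlap between two interface residue sets on the same subject
#'
#' Both sets must be drawn from the same subject residue numbering
#' (position matching is by residue number after the complexes are
#' identified on their shared subject).
#'
#' @param iface_dimer interface residue numbers of the subject in the
#'   dimer model (must be nonempty).
#' @param iface_blocker interface residue numbers of the subject in the
#'   subject-blocker model.
#' @return object of class `overlap_result` with `shared` (count),
#'   `jaccard` (0-1) and `frac_of_dimer` (shared / dimer interface size).
#' @export
interface_overlap <- function(iface_dimer, iface_blocker) {
  iface_dimer <- unique(iface_dimer); iface_blocker <- unique(iface_blocker)
  if (length(iface_dimer) == 0L) stop("empty dimer interface")
  shared <- length(intersect(iface_dimer, iface_blocker))
  structure(list(shared = shared,
                 jaccard = shared / length(union(iface_dimer, iface_blocker)),
                 frac_of_dimer = shared / length(iface_dimer)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> shared %d, jaccard %.3f, frac_of_dimer %.3f\n",
              x$shared, x$jaccard, x$frac_of_dimer))
  invisible(x)
}

#' Blocking decision from overlap and binding energies
#'
#' Core decision rule: a blocker is judged able to block a dimerization
#' interface when (i) the blocker's interface on the subject overlaps a
#' significant fraction of the dimer's interface on the subject
#' (`frac_of_dimer >= overlap_min`), and (ii) the subject-blocker BFE is
#' lower than, or close to, the dimer BFE
#' (`bfe_blocker <= bfe_dimer + delta_close`). SEMs are reported but do
#' not enter the decision.
#'
#' @param frac_of_dimer overlap fraction of the dimer interface (0-1).
#' @param bfe_dimer_mean,bfe_blocker_mean mean BFEs in kcal/mol.
#' @param overlap_min minimum overlap fraction (default 0.25).
#' @param delta_close "close to" allowance on means in kcal/mol
#'   (default 15).
#' @return list with `blocks`, `overlap_pass`, `energy_pass`, and the
#'   thresholds used.
#' @export
blocking_decision <- function(frac_of_dimer, bfe_dimer_mean,
                              bfe_blocker_mean, overlap_min = 0.25,
                              delta_close = 15) {
  overlap_pass <- frac_of_dimer >= overlap_min
  energy_pass <- bfe_blocker_mean <= bfe_dimer_mean + delta_close
  list(blocks = overlap_pass && energy_pass,
       overlap_pass = overlap_pass, energy_pass = energy_pass,
       overlap_min = overlap_min, delta_close = delta_close)
}

#' Blocking verdict for a dimer / subject-blocker model pair
#'
#' Computes both subject interfaces at the contact cutoff, measures
#' their overlap on the shared subject numbering, compares binding free
#' energies, and issues the verdict of [blocking_decision()].
#'
#' @param dimer `complex_model` of the receptor dimer (subject + partner
#'   receptor), with a BFE.
#' @param blocker `complex_model` of the subject-blocker complex
#'   (same subject sequence; partner typically a truncated isoform),
#'   with a BFE.
#' @param params thresholds from [screen_params()] (`cutoff_A`,
#'   `overlap_min`, `delta_close`).
#' @return object of class `blocking_verdict`: `blocks`, `overlap`
#'   (an `overlap_result`), `overlap_pass`, `energy_pass`, `bfe_dimer`,
#'   `bfe_blocker`, `delta_used`, `overlap_min_used`.
#' @export
blocking_verdict <- function(dimer, blocker, params = screen_params()) {
  stopifnot(inherits(dimer, "complex_model"),
            inherits(blocker, "complex_model"))
  if (!identical(dimer$subject$sequence, blocker$subject$sequence)) {
    stop("dimer and blocker do not share the same subject sequence")
  }
  if (is.null(dimer$bfe) || is.null(blocker$bfe)) {
    stop("both models need a binding free energy")
  }
  id <- interface_residues(dimer, params$cutoff_A)$subject
  ib <- interface_residues(blocker, params$cutoff_A)$subject
  ov <- interface_overlap(id, ib)
  dec <- blocking_decision(ov$frac_of_dimer, dimer$bfe$mean,
                           blocker$bfe$mean, params$overlap_min,
                           params$delta_close)
  structure(list(blocks = dec$blocks, overlap = ov,
                 overlap_pass = dec$overlap_pass,
                 energy_pass = dec$energy_pass,
                 bfe_dimer = dimer$bfe, bfe_blocker = blocker$bfe,
                 delta_used = params$delta_close,
                 overlap_min_used = params$overlap_min),
            class = "blocking_verdict")
}

#' @export
print.blocking_verdict <- function(x, ...) {
  cat(sprintf(paste0("<blocking_verdict> blocks: %s\n",
                     "  overlap frac_of_dimer %.3f (min %.2f): %s\n",
                     "  BFE blocker %.2f vs dimer %.2f + %.1f: %s\n"),
              x$blocks, x$overlap$frac_of_dimer, x$overlap_min_used,
              if (x$overlap_pass) "pass" else "fail",
              x$bfe_blocker$mean, x$bfe_dimer$mean, x$delta_used,
              if (x$energy_pass) "pass" else "fail"))
  invisible(x)
}

#' Competition groups among complexes sharing a subject
#'
#' Builds a graph over complex models that share the same subject
#' protomer, connecting two models when each one's subject interface
#' covers at least `overlap_min` of the other's (mutual
#' `frac_of_dimer`). Connected components of size >= 2 are groups of
#' models competing for the same subject surface.
#'
#' @param complexes list of `complex_model`s with identical subject
#'   sequences.
#' @param params thresholds from [screen_params()].
#' @return list of integer vectors (indices into `complexes`), possibly
#'   empty; single complexes form no group.
#' @export
competition_groups <- function(complexes, params = screen_params()) {
  n <- length(complexes)
  if (n < 2L) return(list())
  seqs <- vapply(complexes, function(cm) cm$subject$sequence, character(1))
  if (length(unique(seqs)) != 1L) {
    stop("all complexes must share the same subject sequence")
  }
  ifaces <- lapply(complexes, function(cm) {
    interface_residues(cm, params$cutoff_A)$subject
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(ifaces[[i]]) == 0L || length(ifaces[[j]]) == 0L) next
      fij <- interface_overlap(ifaces[[i]], ifaces[[j]])$frac_of_dimer
      fji <- interface_overlap(ifaces[[j]], ifaces[[i]])$frac_of_dimer
      adj[i, j] <- adj[j, i] <- (fij >= params$overlap_min &&
                                 fji >= params$overlap_min)
    }
  }
  # connected components by BFS
  seen <- rep(FALSE, n); groups <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    if (length(comp) >= 2L) groups[[length(groups) + 1L]] <- sort(comp)
  }
  groups
}
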