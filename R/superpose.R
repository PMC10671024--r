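#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' RMSD of `R p + t` against `q` over paired points, via the SVD of the
#' cross-covariance matrix with the determinant sign correction that
#' excludes reflections.
#'
#' @param p,q n x 3 coordinate matrices (n >= 3), row i of `p` paired
#'   with row i of `q`.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (3-vector) and `rmsd` (A).
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 3L || ncol(q) != 3L) {
    stop("p and q must be matched n x 3 matrices")
  }
  if (nrow(p) < 3L) stop("need at least 3 paired atoms to superpose")
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  h <- crossprod(pp, qq)               # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- qc - as.numeric(rot %*% pc)
  moved <- t(rot %*% t(p)) + matrix(tr, nrow(p), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  list(rotation = rot, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates, a protomer or a complex
#'
#' @param x an n x 3 matrix, `protomer` or `complex_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed object of the same class.
#' @export
apply_transform <- function(x, rotation, translation) UseMethod("apply_transform")

#' @export
apply_transform.matrix <- function(x, rotation, translation) {
  t(rotation %*% t(x)) + matrix(translation, nrow(x), 3, byrow = TRUE)
}

#' @export
apply_transform.protomer <- function(x, rotation, translation) {
  xyz <- apply_transform(as.matrix(x$atoms[, c("x", "y", "z")]),
                         rotation, translation)
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' @export
apply_transform.complex_model <- function(x, rotation, translation) {
  x$subject <- apply_transform(x$subject, rotation, translation)
  x$partner <- apply_transform(x$partner, rotation, translation)
  x
}

#' Superpose two complexes on their shared subject protomer
#'
#' Computes the rigid transform that maps the subject protomer of
#' `complex_b` onto the subject protomer of `complex_a`, fitted over
#' the C-alpha atoms of TM residues common to both numbering schemes.
#' Used to place a subject-blocker model into the frame of a dimer
#' model when inspecting interface overlap sterically.
#'
#' @param complex_a,complex_b `complex_model`s whose subjects carry the
#'   same sequence.
#' @return object of class `superposition`: `rotation`, `translation`,
#'   `rmsd` (A over the fitted C-alphas), `n_atoms`, and `aligned_b`
#'   (`complex_b` moved into `complex_a`'s frame).
#' @export
superpose_on_subject <- function(complex_a, complex_b) {
  stopifnot(inherits(complex_a, "complex_model"),
            inherits(complex_b, "complex_model"))
  if (!identical(complex_a$subject$sequence, complex_b$subject$sequence)) {
    stop("complexes do not share the same subject sequence")
  }
  ra <- tm_residues(complex_a$subject)
  rb <- tm_residues(complex_b$subject)
  common <- intersect(ra, rb)
  ca_a <- protomer_ca(complex_a$subject, common)
  ca_b <- protomer_ca(complex_b$subject, common)
  shared <- intersect(ca_a$resseq, ca_b$resseq)
  if (length(shared) < 3L) stop("fewer than 3 common subject TM C-alpha atoms")
  pa <- ca_a$xyz[match(shared, ca_a$resseq), , drop = FALSE]
  pb <- ca_b$xyz[match(shared, ca_b$resseq), , drop = FALSE]
  fit <- kabsch(pb, pa)   # move B onto A
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_atoms = length(shared),
                 aligned_b = apply_transform(complex_b, fit$rotation,
                                             fit$translation)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d C-alpha atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}
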