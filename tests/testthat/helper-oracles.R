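# Independent oracles used to cross-check the implementation.

## Horn's closed-form quaternion superposition: rotation/translation
## mapping p onto q, independent of the SVD route used by kabsch().
quaternion_superpose <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  s <- crossprod(pp, qq)
  nmat <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2], s[3,1]-s[1,3], s[1,2]-s[2,1],
    s[2,3]-s[3,2], s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1], s[3,1]+s[1,3],
    s[3,1]-s[1,3], s[1,2]+s[2,1], -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1], s[3,1]+s[1,3], s[2,3]+s[3,2], -s[1,1]-s[2,2]+s[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(nmat, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  tr <- qc - as.numeric(rot %*% pc)
  moved <- t(rot %*% t(p)) + matrix(tr, nrow(p), 3, byrow = TRUE)
  list(rotation = rot, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - q)^2))))
}

## Total-least-squares plane through a point cloud (SVD): unit normal.
svd_plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0)
  sv$v[, 3]
}

## Brute-force interface scan via stats::dist over all heavy atoms of
## both protomers (different distance code path than the package's).
brute_force_interface <- function(cm, cutoff = 5) {
  xa <- as.matrix(cm$subject$atoms[, c("x", "y", "z")])
  xb <- as.matrix(cm$partner$atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(rbind(xa, xb)))
  cross <- d[seq_len(nrow(xa)), nrow(xa) + seq_len(nrow(xb)), drop = FALSE]
  hit <- which(cross < cutoff, arr.ind = TRUE)
  list(subject = sort(unique(cm$subject$atoms$resseq[hit[, 1]])),
       partner = sort(unique(cm$partner$atoms$resseq[hit[, 2]])))
}

## Count interface residues per subject TM helix from an oracle scan.
oracle_helix_counts <- function(cm, iface_subject) {
  tm <- cm$subject$tm[!cm$subject$tm$h8, , drop = FALSE]
  counts <- vapply(seq_len(nrow(tm)), function(i) {
    sum(iface_subject >= tm$start[i] & iface_subject <= tm$end[i])
  }, integer(1))
  names(counts) <- tm$index
  counts
}

## Uniform random rotation from a normalised Gaussian quaternion.
random_rotation <- function() {
  qv <- stats::rnorm(4); qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}
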