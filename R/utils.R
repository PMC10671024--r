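# internal geometry / misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## rotation about an arbitrary unit axis (Rodrigues), angle in degrees
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## squared-distance matrix between two n x 3 coordinate matrices
cross_dist2 <- function(a, b) {
  # (|a|^2 + |b|^2 - 2 a.b), clamped at 0 for numerical safety
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## per-residue minimum cross distances: coords n x 3, resseq length n
## returns list(pairs = data.frame(res_a, res_b, min_dist)) for pairs < cutoff
residue_contacts <- function(xa, ra, xb, rb, cutoff) {
  d2 <- cross_dist2(xa, xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(res_a = integer(), res_b = integer(),
                      min_dist = numeric()))
  }
  key <- paste(ra[hit[, 1]], rb[hit[, 2]], sep = "_")
  d <- sqrt(d2[hit])
  agg <- tapply(d, key, min)
  parts <- do.call(rbind, strsplit(names(agg), "_", fixed = TRUE))
  out <- data.frame(res_a = as.integer(parts[, 1]),
                    res_b = as.integer(parts[, 2]),
                    min_dist = as.numeric(agg))
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

## 3-letter -> 1-letter residue codes (standard 20)
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

aa3to1 <- function(x) {
  out <- unname(AA3TO1[toupper(x)])
  out[is.na(out)] <- "X"
  out
}
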