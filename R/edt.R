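# Exact Euclidean distance transform on an anisotropic voxel lattice,
# computed as three separable axis passes of the squared-distance
# minimization min_p f(p) + w^2 (q - p)^2. Each pass is brute-force over
# source planes but vectorized across lines, which is fast at the grid
# sizes used here and trivially correct.

BIG_SQ <- 1e18

sqdist_pass <- function(fsq, axis, spacing) {
  d <- dim(fsq)
  perm <- c(axis, setdiff(1:3, axis))
  f <- matrix(aperm(fsq, perm), nrow = d[axis])
  n <- nrow(f)
  res <- matrix(BIG_SQ, n, ncol(f))
  w2 <- spacing^2
  q2 <- (seq_len(n))^2
  for (p in seq_len(n)) {
    fp <- f[p, ]
    if (min(fp) >= BIG_SQ) next
    dd <- w2 * (seq_len(n) - p)^2
    for (q in seq_len(n)) {
      res[q, ] <- pmin(res[q, ], fp + dd[q])
    }
  }
  aperm(array(res, dim = d[perm]), order(perm))
}

#' Euclidean distance to a voxel set
#'
#' Distance (mm) from every voxel center to the nearest voxel center of the
#' set `mask`. Voxels inside the set get 0; if the set is empty, all
#' distances are `Inf`.
#'
#' @param mask A [binary_mask()].
#' @return Numeric 3D array of distances in mm, same shape as the mask.
#' @export
distance_to_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  fsq <- array(ifelse(mask$voxels, 0, BIG_SQ), dim = dim(mask$voxels))
  for (axis in 1:3) {
    fsq <- sqdist_pass(fsq, axis, mask$grid$spacing[axis])
  }
  out <- sqrt(fsq)
  out[fsq >= BIG_SQ] <- Inf
  out
}
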