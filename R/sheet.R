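#' Chiral (rolling) indices
#'
#' The integer pair (n1, n2) whose vector sum n1*a1 + n2*a2 of replicated
#' unit-cell vectors is the rolling vector.  Negative values replicate in
#' the opposite direction; one index may be zero but not both.
#'
#' @param n1,n2 integers.
#' @param cap maximum allowed magnitude per direction (default 100, the
#'   web-scale replication limit; raise it for library use).
#' @return an object of class `chiral_indices`.
#' @export
chiral_indices <- function(n1, n2, cap = 100) {
  if (n1 != round(n1) || n2 != round(n2)) stop("chiral indices must be integers")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 == 0 && n2 == 0) stop("chiral indices cannot both be zero")
  if (abs(n1) > cap || abs(n2) > cap)
    stop("chiral index magnitude exceeds the replication cap (", cap,
         "); pass a larger `cap` to override")
  structure(list(n1 = n1, n2 = n2), class = "chiral_indices")
}

as_chiral <- function(idx, cap = 100) {
  if (inherits(idx, "chiral_indices")) idx
  else chiral_indices(idx[[1]], idx[[2]], cap = cap)
}

#' Rolling vector
#'
#' The vector sum of the replicated unit-cell vectors, n1*a1 + n2*a2.  Its
#' length is the circumference of the tube at the reference (mid-plane)
#' surface; its direction sets the wrap angle.
#'
#' @param cell a `unitcell2d`.
#' @param idx chiral indices (a [chiral_indices()] object or length-2 vector).
#' @return length-3 numeric vector in Angstrom.
#' @export
rolling_vector <- function(cell, idx) {
  idx <- as_chiral(idx)
  idx$n1 * cell$a1 + idx$n2 * cell$a2
}

#' Wrap angle
#'
#' Unsigned angle between the rolling vector and the first lattice vector
#' a1, in degrees within \[0, 180\].  Human-readable reports print it to two
#' decimals.
#'
#' @inheritParams rolling_vector
#' @return angle in degrees.
#' @export
#' @examples
#' wrap_angle(get_material("MoS2"), chiral_indices(10, 10))  # 60
wrap_angle <- function(cell, idx) {
  ch <- rolling_vector(cell, idx)
  a1 <- cell$a1
  cosang <- sum(ch * a1) / (sqrt(sum(ch^2)) * sqrt(sum(a1^2)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Replicate a unit cell into a periodic sheet
#'
#' @param cell a `unitcell2d`.
#' @param reps1,reps2 positive replication counts along a1 and a2.
#' @return an `atomistic` sheet with `reps1 * reps2 * nrow(basis)` atoms and
#'   an in-plane periodic cell (`reps1*a1`, `reps2*a2`).
#' @export
build_sheet <- function(cell, reps1, reps2) {
  if (reps1 < 1 || reps2 < 1 || reps1 != round(reps1) || reps2 != round(reps2))
    stop("replication counts must be positive integers")
  basis <- cell$basis
  nb <- nrow(basis)
  grid <- expand.grid(i = 0:(reps1 - 1), j = 0:(reps2 - 1))
  shift <- outer(grid$i, cell$a1) + outer(grid$j, cell$a2)  # (reps1*reps2) x 3
  bpos <- as.matrix(basis[, c("x", "y", "z")])
  pos <- matrix(0, nb * nrow(grid), 3)
  spc <- character(nb * nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rows <- ((g - 1) * nb + 1):(g * nb)
    pos[rows, ] <- bpos + matrix(shift[g, ], nb, 3, byrow = TRUE)
    spc[rows] <- basis$species
  }
  cellmat <- rbind(reps1 * cell$a1, reps2 * cell$a2, c(0, 0, 1))
  atomistic_structure(spc, pos, cell = cellmat, pbc = c(TRUE, TRUE, FALSE),
                      tags = list(material = cell$name, stage = "sheet",
                                  reps = c(reps1, reps2)))
}

# Rotation taking the rolling vector onto +x.  Returns the 2x2 in-plane
# rotation matrix (z is untouched).
strip_frame <- function(cell, idx) {
  ch <- rolling_vector(cell, idx)
  L <- sqrt(sum(ch^2))
  if (L < 1e-12) stop("degenerate rolling vector")
  u <- ch[1:2] / L
  rbind(c(u[1], u[2]), c(-u[2], u[1]))   # rows: new x, new y axes
}

#' Extract the strip that rolls into a tube
#'
#' Rotates the lattice so the rolling vector Ch lies along +x, generates
#' enough lattice translations of the basis to cover the rectangle
#' `[0, |Ch|) x [0, length)`, and keeps atoms inside it.  Both intervals are
#' half-open so that the seam and the axial boundary carry each atom exactly
#' once; points within 1e-6 Angstrom of a boundary are snapped onto it
#' before the test so floating-point jitter cannot drop or duplicate atoms.
#' Heights (z) are preserved.
#'
#' @param cell a `unitcell2d`.
#' @param idx chiral indices.
#' @param length strip extent along the tube axis, Angstrom (> 0).
#' @param snap boundary snap tolerance in Angstrom.
#' @return an `atomistic` strip in the rolled frame (x along Ch, y axial).
#' @export
extract_strip <- function(cell, idx, length, snap = 1e-6) {
  idx <- as_chiral(idx)
  if (!is.finite(length) || length <= 0) stop("strip length must be positive")
  R <- strip_frame(cell, idx)
  ch <- rolling_vector(cell, idx)
  W <- sqrt(sum(ch^2))
  a1r <- as.numeric(R %*% cell$a1[1:2])
  a2r <- as.numeric(R %*% cell$a2[1:2])
  bpos <- as.matrix(cell$basis[, c("x", "y", "z")])
  bxy <- t(R %*% t(bpos[, 1:2, drop = FALSE]))
  # lattice translation range covering the rectangle: invert [a1r a2r] on corners
  Minv <- solve(cbind(a1r, a2r))
  corners <- rbind(c(0, 0), c(W, 0), c(0, length), c(W, length))
  fr <- corners %*% t(Minv)
  pad <- 2
  i_rng <- (floor(min(fr[, 1])) - pad):(ceiling(max(fr[, 1])) + pad)
  j_rng <- (floor(min(fr[, 2])) - pad):(ceiling(max(fr[, 2])) + pad)
  grid <- expand.grid(i = i_rng, j = j_rng)
  nb <- nrow(bpos)
  ng <- nrow(grid)
  sx <- outer(grid$i, rep(1, nb)) * a1r[1] + outer(grid$j, rep(1, nb)) * a2r[1] +
    outer(rep(1, ng), bxy[, 1])
  sy <- outer(grid$i, rep(1, nb)) * a1r[2] + outer(grid$j, rep(1, nb)) * a2r[2] +
    outer(rep(1, ng), bxy[, 2])
  x <- as.numeric(t(sx)); y <- as.numeric(t(sy))
  z <- rep(bpos[, 3], ng); spc <- rep(cell$basis$species, ng)
  # snap to boundaries, then half-open membership
  x[abs(x) < snap] <- 0; x[abs(x - W) < snap] <- W
  y[abs(y) < snap] <- 0; y[abs(y - length) < snap] <- length
  keep <- x >= 0 & x < W & y >= 0 & y < length
  if (!any(keep)) stop("strip contains no atoms; length too small?")
  atomistic_structure(spc[keep], cbind(x, y, z)[keep, , drop = FALSE],
                      tags = list(material = cell$name, stage = "strip",
                                  n1 = idx$n1, n2 = idx$n2,
                                  Ch_length = W, strip_length = length))
}
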