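# Shared fixtures and independent oracles, all built in code.

# toy 1-atom square lattice cell
square_cell <- function(a = 2.0) {
  unit_cell_2d("toy-square", c(a, 0, 0), c(0, a, 0),
               data.frame(species = "C", x = 0, y = 0, z = 0))
}

# independent brute-force oracle for strip membership: enumerate lattice
# translations over a generous range, rotate so Ch lies along +x, keep the
# half-open rectangle
oracle_strip <- function(cell, n1, n2, len, range = 60, snap = 1e-6) {
  ch <- n1 * cell$a1 + n2 * cell$a2
  W <- sqrt(sum(ch^2))
  ang <- atan2(ch[2], ch[1])
  Rm <- rbind(c(cos(-ang), -sin(-ang)), c(sin(-ang), cos(-ang)))
  out <- NULL
  for (i in -range:range) for (j in -range:range) {
    for (b in seq_len(nrow(cell$basis))) {
      p <- i * cell$a1 + j * cell$a2 +
        as.numeric(cell$basis[b, c("x", "y", "z")])
      xy <- as.numeric(Rm %*% p[1:2])
      x <- xy[1]; y <- xy[2]
      if (abs(x) < snap) x <- 0
      if (abs(x - W) < snap) x <- W
      if (abs(y) < snap) y <- 0
      if (abs(y - len) < snap) y <- len
      if (x >= 0 && x < W && y >= 0 && y < len)
        out <- rbind(out, c(x, y, p[3]))
    }
  }
  out
}

# independent brute-force translational-period oracle: smallest |T| with
# T exactly perpendicular to Ch over all |t1|,|t2| <= tmax
oracle_period <- function(cell, n1, n2, tmax = 50) {
  ch <- n1 * cell$a1 + n2 * cell$a2
  W <- sqrt(sum(ch^2))
  best <- NULL
  for (t1 in -tmax:tmax) for (t2 in -tmax:tmax) {
    if (t1 == 0 && t2 == 0) next
    Tv <- t1 * cell$a1 + t2 * cell$a2
    if (abs(sum(Tv * ch)) / W < 1e-8 * max(1, W)) {
      L <- sqrt(sum(Tv^2))
      if (is.null(best) || L < best$L - 1e-12)
        best <- list(t1 = t1, t2 = t2, L = L)
    }
  }
  best
}

# small MoS2-like cluster with non-trivial geometry for force tests
random_mx2_cluster <- function(n = 6, seed = 42) {
  set.seed(seed)
  sp <- rep(c("Mo", "S"), length.out = n)
  base <- cbind(seq(0, by = 1.9, length.out = n),
                rep(c(0, 1.1), length.out = n),
                rep(c(0, 1.4, -1.4), length.out = n))
  atomistic_structure(sp, base + matrix(rnorm(3 * n, 0, 0.08), n, 3))
}

# periodic FCC crystal (2x2x2 conventional cells)
fcc_crystal <- function(a0 = 3.6, reps = 2) {
  frac <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  pos <- NULL
  for (i in 0:(reps - 1)) for (j in 0:(reps - 1)) for (k in 0:(reps - 1))
    pos <- rbind(pos, (frac + matrix(c(i, j, k), 4, 3, byrow = TRUE)) * a0)
  atomistic_structure(rep("Cu", nrow(pos)), pos,
                      cell = diag(rep(a0 * reps, 3)),
                      pbc = c(TRUE, TRUE, TRUE))
}

# numerical central-difference gradient of the SW energy
numerical_forces <- function(model, structure, h = 1e-5) {
  n <- n_atoms(structure)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    sp <- structure; sp$positions[i, d] <- sp$positions[i, d] + h
    sm <- structure; sm$positions[i, d] <- sm$positions[i, d] - h
    out[i, d] <- -(evaluate(model, sp, forces = FALSE)$total_energy -
                   evaluate(model, sm, forces = FALSE)$total_energy) / (2 * h)
  }
  out
}
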