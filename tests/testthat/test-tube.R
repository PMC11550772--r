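test_that("rolling preserves radii, arc lengths and atom count", {
  g <- get_material("graphene")
  idx <- chiral_indices(8, 0)
  W <- sqrt(sum(rolling_vector(g, idx)^2))
  strip <- extract_strip(g, idx, 8)
  tube <- roll(strip, W)
  expect_identical(n_atoms(tube), n_atoms(strip))
  rad <- sqrt(tube$positions[, 1]^2 + tube$positions[, 2]^2)
  expect_equal(rad, rep(W / (2 * pi), n_atoms(tube)), tolerance = 1e-9)
  expect_equal(sort(tube$positions[, 3]), sort(strip$positions[, 2]),
               tolerance = 1e-12)   # axial coordinates preserved
  # MoS2: three radial shells at R - h, R, R + h
  mos2 <- get_material("MoS2")
  idx2 <- chiral_indices(12, 0)
  W2 <- sqrt(sum(rolling_vector(mos2, idx2)^2))
  t2 <- roll(extract_strip(mos2, idx2, 6), W2)
  r2 <- sqrt(t2$positions[, 1]^2 + t2$positions[, 2]^2)
  R <- W2 / (2 * pi); h <- max(mos2$basis$z)
  shells <- sort(unique(round(r2, 6)))
  expect_equal(shells, c(R - h, R, R + h), tolerance = 1e-6)
  # arc-length preservation at the mid-plane
  mid <- which(abs(r2 - R) < 1e-9)
  th <- atan2(t2$positions[mid, 2], t2$positions[mid, 1])
  th[th < 0] <- th[th < 0] + 2 * pi
  strip2 <- extract_strip(mos2, idx2, 6)
  xs <- sort(unique(round(strip2$positions[abs(strip2$positions[, 3]) < 1e-9, 1], 9)))
  expect_equal(sort(unique(round(R * th, 6))), round(xs, 6), tolerance = 1e-5)
})

test_that("rolling rejects degenerate and self-intersecting tubes", {
  g <- get_material("graphene")
  strip <- extract_strip(g, chiral_indices(3, 0), 4)
  expect_error(roll(strip, 0), "positive")
  deep <- strip; deep$positions[, 3] <- deep$positions[, 3] - 2
  expect_error(roll(deep, 3), "self-intersect")
})

test_that("fixed-length tubes keep the strip count and nominal geometry", {
  hb <- get_material("hexagonal-bilayer-silica")
  idx <- chiral_indices(12, 10)
  built <- build_tube_fixed_length(hb, idx, 10)
  expect_false(any(built$structure$pbc))
  expect_null(built$geometry$period_length)
  expect_equal(built$geometry$perimeter,
               sqrt(sum(rolling_vector(hb, idx)^2)), tolerance = 1e-9)
  expect_identical(n_atoms(built$structure),
                   n_atoms(extract_strip(hb, idx, 10)))
  # doubling a commensurate length doubles the atom count
  mos2 <- get_material("MoS2")
  P <- find_translational_period(mos2, chiral_indices(6, 3))$period_length
  one <- build_tube_fixed_length(mos2, chiral_indices(6, 3), P)
  two <- build_tube_fixed_length(mos2, chiral_indices(6, 3), 2 * P)
  expect_identical(n_atoms(two$structure), 2L * n_atoms(one$structure))
})

test_that("translational periods match the brute-force integer-pair oracle", {
  mos2 <- get_material("MoS2")
  a <- sqrt(sum(mos2$a1^2))
  p <- find_translational_period(mos2, chiral_indices(20, 10))
  expect_equal(p$period_length, a, tolerance = 1e-8)
  expect_identical(sort(abs(c(p$t1, p$t2))), c(0L, 1L))
  p2 <- find_translational_period(mos2, chiral_indices(10, 0))
  expect_equal(p2$period_length, sqrt(3) * a, tolerance = 1e-8)
  expect_identical(sort(abs(c(p2$t1, p2$t2))), c(1L, 2L))
  sq <- square_cell(2.5)
  p3 <- find_translational_period(sq, chiral_indices(1, 0))
  expect_equal(p3$period_length, 2.5, tolerance = 1e-12)
  expect_identical(abs(p3$t2), 1L)
  # oracle equivalence across all hexagonal materials and index patterns
  for (nm in c("graphene", "graphane", "silicene", "MoS2", "WS2",
               "gamma-graphyne", "hexagonal-bilayer-silica")) {
    cell <- get_material(nm)
    for (nn in list(c(20, 10), c(7, 3), c(5, -2))) {
      got <- find_translational_period(cell, chiral_indices(nn[1], nn[2]))
      want <- oracle_period(cell, nn[1], nn[2])
      expect_false(is.null(want))
      expect_equal(got$period_length, want$L, tolerance = 1e-7,
                   label = sprintf("%s (%d,%d)", nm, nn[1], nn[2]))
    }
  }
})

test_that("primitive tubes tile axially onto the fixed-length construction", {
  for (nm in c("MoS2", "graphane")) {
    cell <- get_material(nm)
    idx <- chiral_indices(6, 3)
    prim <- build_primitive_tube(cell, idx)
    P <- prim$geometry$period_length
    expect_identical(prim$structure$pbc, c(FALSE, FALSE, TRUE))
    expect_equal(prim$structure$cell[3, 3], P)
    fixed <- build_tube_fixed_length(cell, idx, 2 * P)
    rep2 <- rbind(prim$structure$positions,
                  sweep(prim$structure$positions, 2, c(0, 0, P), "+"))
    expect_identical(nrow(rep2), n_atoms(fixed$structure))
    for (i in seq_len(nrow(rep2))) {
      d <- sqrt(colSums((t(fixed$structure$positions) - rep2[i, ])^2))
      expect_lt(min(d), 1e-4)
    }
    # no spurious close contacts after replication
    expect_gt(min(dist(rep2)), 0.5)
  }
})

test_that("unrolling a tube recovers the strip coordinates", {
  cell <- get_material("silicene")
  idx <- chiral_indices(9, 2)
  W <- sqrt(sum(rolling_vector(cell, idx)^2))
  strip <- extract_strip(cell, idx, 7)
  tube <- roll(strip, W)
  back <- unroll(tube, W)
  expect_equal(back$positions[, 1], strip$positions[, 1], tolerance = 1e-9)
  expect_equal(back$positions[, 2], strip$positions[, 2], tolerance = 1e-9)
  expect_equal(back$positions[, 3], strip$positions[, 3], tolerance = 1e-9)
})

test_that("(n1,n2) and (n2,n1) tubes are mirror images", {
  g <- get_material("graphene")
  t1 <- build_tube_fixed_length(g, chiral_indices(6, 2), 8)$structure
  t2 <- build_tube_fixed_length(g, chiral_indices(2, 6), 8)$structure
  expect_identical(n_atoms(t1), n_atoms(t2))
  expect_equal(sort(as.numeric(dist(t1$positions))),
               sort(as.numeric(dist(t2$positions))), tolerance = 1e-6)
})
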