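test_that("force-field discovery orders models by specificity and respects coverage", {
  mos2 <- build_sheet(get_material("MoS2"), 1, 1)
  av <- available_forcefields(mos2)
  expect_gt(length(av), 0)
  expect_identical(av[[1]]$name, "sw-mx2-mos2")
  ws2 <- build_sheet(get_material("WS2"), 1, 1)
  expect_identical(available_forcefields(ws2)[[1]]$name, "sw-mx2-ws2")
  he <- atomistic_structure("He", matrix(0, 1, 3))
  expect_length(available_forcefields(he), 0)
  withext <- available_forcefields(he, include_external = TRUE)
  expect_identical(withext[[length(withext)]]$form, "external_adapter")
  expect_error(evaluate(get_forcefield("sw-mx2-mos2"), he), "no parameters")
})

test_that("pair interactions vanish beyond the cutoff", {
  m <- get_forcefield("sw-mx2-mos2")
  far <- atomistic_structure(c("Mo", "Mo"),
                             rbind(c(0, 0, 0), c(10, 0, 0)))
  r <- evaluate(m, far)
  expect_identical(r$total_energy, 0)
  expect_true(all(r$forces == 0))
})

test_that("analytic forces match the central-difference gradient", {
  m <- get_forcefield("sw-mx2-mos2")
  cl <- random_mx2_cluster(6)
  r <- evaluate(m, cl)
  expect_lt(max(abs(r$forces - numerical_forces(m, cl))), 1e-4)
  # periodic case: compressed primitive tube section
  pt <- build_primitive_tube(get_material("MoS2"), chiral_indices(5, 2))
  rp <- evaluate(m, pt$structure)
  num <- numerical_forces(m, pt$structure)
  expect_lt(max(abs(rp$forces - num)), 1e-4)
})

test_that("energies are invariant under rigid motion and forces sum to zero", {
  m <- get_forcefield("sw-mx2-mos2")
  cl <- random_mx2_cluster(6)
  e0 <- evaluate(m, cl)
  expect_lt(max(abs(colSums(e0$forces))), 1e-8)
  shifted <- cl; shifted$positions <- cl$positions +
    matrix(c(1.3, -0.7, 2.9), n_atoms(cl), 3, byrow = TRUE)
  expect_equal(evaluate(m, shifted)$total_energy, e0$total_energy,
               tolerance = 1e-9)
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- cl; rotated$positions <- cl$positions %*% t(Rz)
  expect_equal(evaluate(m, rotated)$total_energy, e0$total_energy,
               tolerance = 1e-9)
})

test_that("per-atom energies sum to the total and partition as documented", {
  m <- get_forcefield("sw-mx2-mos2")
  sh <- build_sheet(get_material("MoS2"), 2, 2)
  r <- evaluate(m, sh)
  expect_equal(sum(r$per_atom_energy), r$total_energy, tolerance = 1e-10)
  # every Mo site is equivalent, and every S site is equivalent
  expect_lt(diff(range(r$per_atom_energy[sh$species == "Mo"])), 1e-9)
  expect_lt(diff(range(r$per_atom_energy[sh$species == "S"])), 1e-9)
})

test_that("energy is extensive under axial supercelling of a periodic tube", {
  pt <- build_primitive_tube(get_material("MoS2"), chiral_indices(6, 3))
  m <- get_forcefield("sw-mx2-mos2")
  e1 <- evaluate(m, pt$structure, forces = FALSE)$total_energy
  P <- pt$geometry$period_length
  double <- pt$structure
  double$positions <- rbind(double$positions,
                            sweep(pt$structure$positions, 2, c(0, 0, P), "+"))
  double$species <- rep(pt$structure$species, 2)
  double$cell[3, 3] <- 2 * P
  e2 <- evaluate(m, double, forces = FALSE)$total_energy
  expect_equal(e2, 2 * e1, tolerance = 1e-6)
})

test_that("minimization is monotone, honours both tolerances and fixes the cell", {
  m <- get_forcefield("sw-mx2-mos2")
  sh <- build_sheet(get_material("MoS2"), 3, 3)
  set.seed(11)
  pert <- sh
  pert$positions <- sh$positions + matrix(rnorm(3 * n_atoms(sh), 0, 0.06),
                                          ncol = 3)
  res <- minimize(m, pert, minimization_settings(1e-8, 1e-5, 2000, 50000))
  expect_true(all(diff(res$report$trajectory) <= 1e-8))
  expect_lte(res$report$total_energy,
             evaluate(m, pert, forces = FALSE)$total_energy)
  expect_equal(res$structure$cell, sh$cell)   # cell untouched
  # relaxes back to the crystalline sheet energy
  flat <- minimize(m, sh, minimization_settings())
  expect_equal(res$report$total_energy, flat$report$total_energy,
               tolerance = 1e-4)
  # an already-minimal sheet is a fixed point: reconverges immediately
  again <- minimize(m, flat$structure, minimization_settings())
  expect_true(again$report$converged)
  expect_lt(again$report$iterations, 5)
  expect_equal(again$report$total_energy, flat$report$total_energy,
               tolerance = 1e-9)
})

test_that("a single atom converges immediately with zero force", {
  m <- get_forcefield("sw-mx2-mos2")
  one <- atomistic_structure("Mo", matrix(0, 1, 3))
  r <- minimize(m, one)
  expect_true(r$report$converged)
  expect_identical(r$report$total_energy, 0)
  expect_true(all(r$report$forces == 0))
})

test_that("steepest descent also relaxes, just more slowly", {
  m <- get_forcefield("sw-mx2-mos2")
  sh <- build_sheet(get_material("MoS2"), 2, 2)
  set.seed(5)
  sh$positions <- sh$positions + matrix(rnorm(3 * n_atoms(sh), 0, 0.04), ncol = 3)
  fire <- minimize(m, sh, minimization_settings(algorithm = "fire"))
  sd <- minimize(m, sh, minimization_settings(algorithm = "steepest_descent"))
  expect_true(all(diff(sd$report$trajectory) <= 1e-12))
  expect_equal(sd$report$total_energy, fire$report$total_energy,
               tolerance = 1e-3)
})

test_that("minimization settings validate and record the tolerance reference", {
  s <- minimization_settings()
  expect_equal(s$energy_tol, 0.001)
  expect_equal(s$force_tol, 1e-6)
  expect_identical(s$max_iterations, 1000L)
  expect_identical(s$max_evaluations, 100000L)
  expect_identical(s$energy_tol_reference, "initial")
  expect_error(minimization_settings(energy_tol = -1))
  expect_error(minimization_settings(algorithm = "annealing"))
})

test_that("sub-plane typing survives a file round trip of a tube", {
  # S1/S2 (outer/inner shell) assignment must not depend on construction
  # tags: a tube re-read from disk evaluates to the same energy
  m <- get_forcefield("sw-mx2-mos2")
  pt <- build_primitive_tube(get_material("MoS2"), chiral_indices(6, 3))
  e0 <- evaluate(m, pt$structure, forces = FALSE)$total_energy
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(pt$structure, path)
  back <- read_extxyz(path)
  expect_null(back$tags$stage)
  expect_equal(evaluate(m, back, forces = FALSE)$total_energy, e0,
               tolerance = 1e-9)
})
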