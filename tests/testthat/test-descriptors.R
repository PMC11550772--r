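test_that("coordination numbers count honeycomb and trigonal-prismatic shells", {
  g <- get_material("graphene")
  sh <- build_sheet(g, 3, 3)
  bond <- sqrt(sum(g$a1^2)) / sqrt(3)
  cn <- coordination_numbers(sh, c("C-C" = 1.2 * bond))
  expect_true(all(cn == 3L))
  mos2 <- build_sheet(get_material("MoS2"), 3, 3)
  cn2 <- coordination_numbers(mos2, c("Mo-S" = 1.2 * 2.417,
                                      "Mo-Mo" = 0, "S-S" = 0))
  expect_true(all(cn2[mos2$species == "Mo"] == 6L))
  expect_true(all(cn2[mos2$species == "S"] == 3L))
  iso <- atomistic_structure("C", matrix(0, 1, 3))
  expect_identical(coordination_numbers(iso, c("C-C" = 2)), 0L)
  expect_error(coordination_numbers(mos2, c("Mo-S" = 2.9)), "missing cutoff")
})

test_that("default cutoffs derive from the shortest pair distances", {
  co <- default_cutoffs(get_material("MoS2"))
  expect_equal(unname(co["Mo-S"]), 1.2 * 2.417, tolerance = 1e-3)
  expect_equal(unname(co["Mo-Mo"]), 1.2 * 3.16, tolerance = 1e-3)
})

test_that("CNP vanishes for ideal FCC, is zero for a dimer and positive when perturbed", {
  fcc <- fcc_crystal(3.6, 2)
  rc <- c("Cu-Cu" = 1.2 * 3.6 / sqrt(2))
  cnp <- common_neighborhood_parameter(fcc, rc)
  expect_lt(max(abs(cnp)), 1e-8)
  dimer <- atomistic_structure(c("Cu", "Cu"), rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_identical(common_neighborhood_parameter(dimer, rc), c(0, 0))
  set.seed(3)
  pert <- fcc
  pert$positions <- fcc$positions + matrix(rnorm(3 * n_atoms(fcc), 0, 0.08),
                                           ncol = 3)
  expect_true(all(common_neighborhood_parameter(pert, rc) > 0))
})

test_that("hex parameters are 1 for pristine sheets and drop with a vacancy", {
  g <- get_material("graphene")
  sh <- build_sheet(g, 4, 4)
  hx <- hex_parameters(sh, g)
  expect_equal(mean(hx$first), 1.0)
  expect_equal(mean(hx$second), 1.0)
  vac <- atomistic_structure(sh$species[-1], sh$positions[-1, ],
                             cell = sh$cell, pbc = sh$pbc)
  hxv <- hex_parameters(vac, g)
  expect_lt(mean(hxv$first), 1.0)
})

test_that("geometric descriptors follow the radius formulas", {
  g <- get_material("graphene")
  built <- build_tube_fixed_length(g, chiral_indices(8, 0), 6)
  gd <- geometric_descriptors(built$structure, built$geometry)
  R <- built$geometry$nominal_radius
  expect_equal(unname(gd["D24"]), R, tolerance = 1e-9)
  expect_equal(unname(gd["D25"]), R, tolerance = 1e-9)
  expect_equal(unname(gd["D29"]), 0, tolerance = 1e-9)
  expect_equal(unname(gd["D28"]), 0, tolerance = 1e-6)
  expect_equal(unname(gd["D9"]), 2 * R)
  expect_equal(unname(gd["D11"]), pi * R^2)
  mos2 <- get_material("MoS2")
  bm <- build_tube_fixed_length(mos2, chiral_indices(12, 0), 6)
  gm <- geometric_descriptors(bm$structure, bm$geometry)
  expect_equal(unname(gm["D29"]), thickness(mos2), tolerance = 1e-9)
})

test_that("the full descriptor set obeys its arithmetic identities on varied tubes", {
  mos2 <- get_material("MoS2")
  m <- get_forcefield("sw-mx2-mos2")
  sheet <- build_sheet(mos2, 3, 3)
  es <- evaluate(m, sheet)
  for (nn in list(c(6, 3), c(5, -2), c(4, 4))) {
    idx <- chiral_indices(nn[1], nn[2])
    built <- build_primitive_tube(mos2, idx)
    et <- evaluate(m, built$structure)
    ds <- compile_descriptors(sheet, built$structure, es, et, idx,
                              built$geometry, mos2, stage = "geometric")
    d <- stats::setNames(ds$value, ds$id)
    expect_equal(unname(d["D3"]), unname(d["D1"] - d["D2"]), tolerance = 1e-9)
    expect_equal(unname(d["D4"]), unname(d["D1"] / d["D2"]), tolerance = 1e-9)
    expect_equal(unname(d["D7"]), unname(d["D5"] - d["D6"]), tolerance = 1e-9)
    expect_equal(unname(d["D8"]), unname(d["D5"] / d["D6"]), tolerance = 1e-9)
    expect_equal(unname(d["D10"]), unname(pi * d["D9"]), tolerance = 1e-9)
    expect_equal(unname(d["D14"]), abs(nn[1] - nn[2]))
    expect_equal(unname(d["D15"]), nn[2] / nn[1])
    expect_equal(unname(d["D26"]), unname(2 * pi * d["D24"]), tolerance = 1e-9)
    expect_equal(unname(d["D27"]), unname(2 * pi * d["D25"]), tolerance = 1e-9)
    expect_equal(unname(d["D29"]), unname(d["D25"] - d["D24"]), tolerance = 1e-9)
    expect_equal(unname(d["D28"]),
                 unname(pi * (d["D25"]^2 - d["D24"]^2)), tolerance = 1e-8)
    expect_gte(d["D25"], d["D24"])
    expect_gte(d["D24"], 0)
    expect_equal(unname(d["D30"]), thickness(mos2), tolerance = 1e-9)
  }
})

test_that("self-comparison and determinism of descriptor compilation", {
  mos2 <- get_material("MoS2")
  m <- get_forcefield("sw-mx2-mos2")
  idx <- chiral_indices(6, 3)
  built <- build_primitive_tube(mos2, idx)
  et <- evaluate(m, built$structure)
  ds <- compile_descriptors(built$structure, built$structure, et, et, idx,
                            built$geometry, mos2, stage = "geometric")
  d <- stats::setNames(ds$value, ds$id)
  expect_equal(unname(d["D3"]), 0)
  expect_equal(unname(d["D4"]), 1)
  expect_equal(unname(d["D7"]), 0)
  expect_equal(unname(d["D8"]), 1)
  sheet <- build_sheet(mos2, 3, 3)
  es <- evaluate(m, sheet)
  a <- compile_descriptors(sheet, built$structure, es, et, idx,
                           built$geometry, mos2)
  b <- compile_descriptors(sheet, built$structure, es, et, idx,
                           built$geometry, mos2)
  expect_identical(a$value, b$value)
  # n1 = 0 reports an undefined (NA) index ratio rather than erroring
  idx0 <- chiral_indices(0, 5)
  b0 <- build_tube_fixed_length(mos2, idx0, 6)
  e0 <- evaluate(m, b0$structure)
  ds0 <- compile_descriptors(sheet, b0$structure, es, e0, idx0, b0$geometry,
                             mos2, stage = "geometric")
  expect_true(is.na(ds0$value[ds0$id == "D15"]))
})

test_that("descriptor tables export to CSV and JSON", {
  mos2 <- get_material("MoS2")
  m <- get_forcefield("sw-mx2-mos2")
  idx <- chiral_indices(6, 3)
  built <- build_primitive_tube(mos2, idx)
  sheet <- build_sheet(mos2, 3, 3)
  ds <- compile_descriptors(sheet, built$structure, evaluate(m, sheet),
                            evaluate(m, built$structure), idx, built$geometry,
                            mos2, stage = "geometric")
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_descriptors(ds, csv); write_descriptors(ds, jsn)
  back <- utils::read.csv(csv)
  expect_true(all(paste0("D", 1:30) %in% names(back)))
  expect_equal(back$D12, 6)
  jj <- jsonlite::read_json(jsn)
  expect_equal(jj[[1]]$D13, 3)
})
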