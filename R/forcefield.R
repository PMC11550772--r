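#' Stillinger-Weber force-field models
#'
#' Constructs an analytic Stillinger-Weber model of the MX2 type: a
#' screened pair term
#' \deqn{\phi_2(r) = A\,[B(\sigma/r)^p - (\sigma/r)^q]\,e^{\sigma/(r-r_c)}}
#' and a screened angular three-body term
#' \deqn{\phi_3 = \lambda\, e^{\gamma_{ij}/(r_{ij}-r_{c,ij}) +
#'   \gamma_{ik}/(r_{ik}-r_{c,ik})}\,(\cos\theta_{jik}-\cos\theta_0)^2,}
#' both of which go smoothly to zero at their cutoffs.  Pair terms use the
#' two-body cutoff `rc2`; three-body legs use the (typically tighter)
#' cutoff `rc3`.
#'
#' @param name model identifier.
#' @param species character vector of covered element symbols (type order).
#' @param pair data.frame with columns `si`, `sj`, `A`, `B`, `p`, `q`,
#'   `sigma`, `rc2`, `gamma`, `rc3` (eV and Angstrom); rows are symmetrized.
#' @param triple data.frame with columns `apex`, `j`, `k`, `lambda`, `cos0`;
#'   the (j,k) pair is symmetrized.
#' @param provenance citation / calibration note.
#' @return object of class `forcefield_model`.
#' @export
sw_model <- function(name, species, pair, triple, provenance = "") {
  nt <- length(species)
  idx <- stats::setNames(seq_len(nt), species)
  m0 <- function() matrix(0, nt, nt)
  A <- m0(); B <- m0(); p <- m0(); q <- m0(); sigma <- m0(); rc2 <- m0()
  gamma <- m0(); rc3 <- m0()
  for (r in seq_len(nrow(pair))) {
    i <- idx[[pair$si[r]]]; j <- idx[[pair$sj[r]]]
    for (k in list(c(i, j), c(j, i))) {
      A[k[1], k[2]] <- pair$A[r]; B[k[1], k[2]] <- pair$B[r]
      p[k[1], k[2]] <- pair$p[r]; q[k[1], k[2]] <- pair$q[r]
      sigma[k[1], k[2]] <- pair$sigma[r]; rc2[k[1], k[2]] <- pair$rc2[r]
      gamma[k[1], k[2]] <- pair$gamma[r]; rc3[k[1], k[2]] <- pair$rc3[r]
    }
  }
  lambda <- array(0, c(nt, nt, nt)); cos0 <- array(0, c(nt, nt, nt))
  for (r in seq_len(nrow(triple))) {
    a <- idx[[triple$apex[r]]]; j <- idx[[triple$j[r]]]; k <- idx[[triple$k[r]]]
    lambda[a, j, k] <- triple$lambda[r]; lambda[a, k, j] <- triple$lambda[r]
    cos0[a, j, k] <- triple$cos0[r]; cos0[a, k, j] <- triple$cos0[r]
  }
  structure(list(form = "stillinger_weber", name = name, species = species,
                 species_covered = unique(sub("[0-9]+$", "", species)),
                 params = list(A = A, B = B, p = p, q = q, sigma = sigma,
                               rc2 = rc2, gamma = gamma, rc3 = rc3,
                               lambda = as.numeric(aperm(lambda, c(3, 2, 1))),
                               cos0 = as.numeric(aperm(cos0, c(3, 2, 1)))),
                 cutoff = max(rc2, rc3), provenance = provenance),
            class = "forcefield_model")
}

# Internal force-field types for a structure.  Most models map one element
# to one type.  The MX2 models distinguish the two chalcogen sub-planes
# (types S1/S2): in a flat layer by height relative to the metal plane, in
# a rolled tube by radial shell relative to the mean metal radius, so the
# outer and inner S shells keep their identity during relaxation.
.assign_types <- function(model, structure) {
  sp <- structure$species
  plain <- match(sp, model$species)
  if (!anyNA(plain)) return(plain - 1L)
  base <- sub("[0-9]+$", "", model$species)
  out <- integer(length(sp))
  metal <- setdiff(model$species_covered, "S")
  msel <- sp %in% metal
  # geometry mode: construction tags when available, otherwise whichever
  # coordinate (height for a flat layer, radius for a tube) is more nearly
  # constant over the metal sites
  stage <- structure$tags$stage
  is_tube <- if (identical(stage, "tube")) TRUE
    else if (identical(stage, "sheet") || identical(stage, "strip")) FALSE
    else if (any(msel)) {
      rad <- sqrt(structure$positions[msel, 1]^2 + structure$positions[msel, 2]^2)
      stats::sd(rad) < stats::sd(structure$positions[msel, 3])
    } else FALSE
  coordv <- if (is_tube)
    sqrt(structure$positions[, 1]^2 + structure$positions[, 2]^2)
  else structure$positions[, 3]
  # classify each split-type atom against its nearest metal neighbour
  # (local reference; robust for relaxed, non-circular tubes), falling back
  # to the global metal mean for isolated atoms
  mref_global <- if (any(msel)) mean(coordv[msel]) else mean(coordv)
  localref <- rep(mref_global, length(sp))
  if (any(msel) && any(!msel)) {
    cellm <- if (is.null(structure$cell)) diag(3) else structure$cell
    nv <- nr_neighbor_pairs(structure$positions, cellm, structure$pbc, 3.4)
    if (length(nv$i)) {
      edges <- rbind(cbind(nv$i, nv$j, nv$d), cbind(nv$j, nv$i, nv$d))
      sel <- msel[edges[, 2]] & !msel[edges[, 1]]
      edges <- edges[sel, , drop = FALSE]
      if (nrow(edges)) {
        ord <- order(edges[, 1], edges[, 3])
        edges <- edges[ord, , drop = FALSE]
        first <- !duplicated(edges[, 1])
        localref[edges[first, 1]] <- coordv[edges[first, 2]]
      }
    }
  }
  for (i in seq_along(sp)) {
    if (sp[i] %in% model$species) { out[i] <- match(sp[i], model$species); next }
    cands <- which(base == sp[i])
    if (!length(cands))
      stop("force field '", model$name, "' has no parameters for species ", sp[i])
    if (length(cands) == 1) { out[i] <- cands; next }
    out[i] <- if (coordv[i] >= localref[i]) cands[1] else cands[2]
  }
  out - 1L
}

# flatten order note: the kernel indexes lambda[(a*nt+j)*nt+k]; aperm above
# lays the R array out accordingly (k fastest, then j, then apex).

#' @export
print.forcefield_model <- function(x, ...) {
  cat(sprintf("force field '%s' (%s), species: %s, cutoff %.2f A\n", x$name,
              x$form, paste(x$species, collapse = ","), x$cutoff))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

# ---- embedded MX2 parameterizations -----------------------------------
# Original parameterization of the MX2 Stillinger-Weber form for 1H-MoS2
# and 1H-WS2 monolayers, calibrated against published reference properties
# of the monolayers (lattice constant, metal-sulphur bond length,
# equilibrium energy per atom, elastic and bending stiffness); see the
# package vignette for the calibration protocol.  The two chalcogen
# sub-planes are distinct force-field types (S1 upper/outer, S2
# lower/inner) so that angular springs act only on crystallographically
# equivalent ~82-degree angles, the standard device in MX2
# Stillinger-Weber models.  Constants are frozen; do not edit casually.
.sw_mx2 <- function(name, metal, a, d, eps, lambda, provenance) {
  # bond pair term: minimum at d with depth eps (p = 4, q = 0)
  sig <- 1.2; rc <- 3.35
  f <- -(4 / d) / (sig / (d - rc)^2 + 4 / d)
  Bb <- (1 + f) * d^4 / sig^4
  Ab <- eps / (-f * exp(sig / (d - rc)))
  c0 <- 1 - a^2 / (2 * d^2)          # equilibrium S-M-S / M-S-M angle
  S1 <- "S1"; S2 <- "S2"
  sw_model(
    name = name,
    species = c(metal, S1, S2),
    pair = data.frame(
      si = c(metal, metal, metal, S1, S2, S1),
      sj = c(S1, S2, metal, S1, S2, S2),
      A     = c(Ab, Ab, 2.0, 2.0, 2.0, 2.0),
      B     = c(Bb, Bb, (2.90 / 1.5)^4, (3.05 / 1.5)^4, (3.05 / 1.5)^4,
                (3.05 / 1.5)^4),
      p     = c(4, 4, 4, 4, 4, 4), q = c(0, 0, 0, 0, 0, 0),
      sigma = c(sig, sig, 1.5, 1.5, 1.5, 1.5),
      rc2   = c(rc, rc, 3.10, 3.35, 3.35, 3.35),
      gamma = c(1.2, 1.2, 0, 0, 0, 0),
      rc3   = c(3.00, 3.00, 0, 0, 0, 0)),
    triple = data.frame(
      apex = c(metal, metal, S1, S2),
      j = c(S1, S2, metal, metal), k = c(S1, S2, metal, metal),
      lambda = rep(lambda, 4), cos0 = rep(c0, 4)),
    provenance = provenance)
}

.sw_embedded <- function() {
  list(
    .sw_mx2("sw-mx2-mos2", "Mo", a = 3.160, d = 2.417,
            eps = 2.5550, lambda = 100,
            provenance = paste("original MX2-type SW parameterization for",
                               "1H-MoS2; calibrated to a = 3.160 A,",
                               "d(Mo-S) = 2.417 A, E = -5.11 eV/atom")),
    .sw_mx2("sw-mx2-ws2", "W", a = 3.155, d = 2.405,
            eps = 2.6150, lambda = 100,
            provenance = paste("original MX2-type SW parameterization for",
                               "1H-WS2; calibrated to a = 3.155 A,",
                               "d(W-S) = 2.405 A, E = -5.23 eV/atom")))
}

#' Force fields applicable to a structure
#'
#' Returns the embedded models whose parameter tables cover every species
#' in the structure, ordered most-specific first (fewest covered elements),
#' followed by a descriptor for the external-engine adapter, which can
#' drive any LAMMPS-compatible engine.  An empty species match yields only
#' the adapter entry (or an empty list when `include_external = FALSE`).
#'
#' @param structure an `atomistic` structure.
#' @param include_external append the external-adapter descriptor?
#' @return list of `forcefield_model` objects / adapter descriptors.
#' @export
available_forcefields <- function(structure, include_external = FALSE) {
  sp <- unique(structure$species)
  if (length(sp) < 1) stop("structure has no species")
  models <- Filter(function(m) all(sp %in% m$species_covered), .sw_embedded())
  models <- models[order(vapply(models, function(m) length(m$species_covered), 0L))]
  if (include_external) {
    models <- c(models, list(structure(
      list(form = "external_adapter", name = "external-lammps-engine",
           species = NA_character_,
           provenance = "adapter contract for an external LAMMPS-compatible engine"),
      class = "forcefield_model")))
  }
  models
}

#' Look up an embedded force field by name
#' @param name model name, e.g. `"sw-mx2-mos2"`.
#' @return a `forcefield_model`.
#' @export
get_forcefield <- function(name) {
  for (m in .sw_embedded()) if (m$name == name) return(m)
  stop("unknown force field '", name, "'; embedded models: ",
       paste(vapply(.sw_embedded(), function(m) m$name, ""), collapse = ", "))
}

.check_coverage <- function(model, structure) {
  sp <- unique(structure$species)
  cov <- if (is.null(model$species_covered)) model$species else model$species_covered
  miss <- setdiff(sp, cov)
  if (length(miss))
    stop("force field '", model$name, "' has no parameters for species: ",
         paste(miss, collapse = ", "))
}

.eval_cell <- function(structure) {
  if (is.null(structure$cell)) diag(c(1, 1, 1)) else structure$cell
}

#' Evaluate energy and forces
#'
#' Deterministic total energy, per-atom energies and analytic forces.
#' Pair energies are shared half-and-half between the two atoms; each
#' angular term is assigned to its apex atom.  Periodic directions are
#' handled by exact image enumeration, so axial cells shorter than the
#' interaction cutoff (short-period primitive tube cells) are evaluated
#' correctly rather than rejected.
#'
#' @param model a `forcefield_model` with `form == "stillinger_weber"`.
#' @param structure an `atomistic` structure.
#' @param forces compute forces?
#' @return an `energy_report`: `total_energy` (eV), `per_atom_energy`,
#'   `forces` (eV/A), `converged`, `iterations`, `evaluations`.
#' @export
evaluate <- function(model, structure, forces = TRUE) {
  stopifnot(inherits(model, "forcefield_model"))
  if (model$form != "stillinger_weber")
    stop("evaluate() requires an embedded analytic model; use",
         " external_engine_adapter() for external engines")
  .check_coverage(model, structure)
  types <- .assign_types(model, structure)
  res <- sw_eval_cpp(structure$positions, types, .eval_cell(structure),
                     structure$pbc, model$params, forces = forces)
  energy_report(total = res$energy, per_atom = res$per_atom,
                forces = if (forces) res$forces else NULL,
                converged = TRUE, iterations = 0L, evaluations = 1L)
}

#' Energy report constructor
#' @keywords internal
energy_report <- function(total, per_atom, forces, converged, iterations,
                          evaluations, trajectory = NULL) {
  stopifnot(abs(total - sum(per_atom)) < 1e-8 * max(1, abs(total)))
  structure(list(total_energy = total, per_atom_energy = per_atom,
                 forces = forces, converged = converged,
                 iterations = iterations, evaluations = evaluations,
                 trajectory = trajectory),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  n <- length(x$per_atom_energy)
  cat(sprintf("energy report: E = %.6f eV (%d atoms, %.4f eV/atom)\n",
              x$total_energy, n, x$total_energy / n))
  cat(sprintf("  converged = %s after %d iteration(s), %d evaluation(s)\n",
              x$converged, x$iterations, x$evaluations))
  invisible(x)
}

#' Minimization settings
#'
#' Stopping parameters for structure relaxation.  `energy_tol` is the
#' unitless ratio of the energy change between two consecutive accepted
#' steps to the energy at the start of the minimization (set
#' `energy_tol_reference = "step"` for per-step-relative instead);
#' `force_tol` bounds the 2-norm of the global 3N force vector.
#' Convergence requires both conditions.
#'
#' @param energy_tol relative energy tolerance (default 0.001).
#' @param force_tol force 2-norm tolerance in eV/A (default 1e-6).
#' @param max_iterations iteration budget (default 1000).
#' @param max_evaluations energy/force evaluation budget (default 100000).
#' @param algorithm `"fire"` (default) or `"steepest_descent"`.
#' @param energy_tol_reference `"initial"` (default) or `"step"`.
#' @return object of class `minimization_settings`.
#' @export
minimization_settings <- function(energy_tol = 0.001, force_tol = 1e-6,
                                  max_iterations = 1000,
                                  max_evaluations = 100000,
                                  algorithm = c("fire", "steepest_descent"),
                                  energy_tol_reference = c("initial", "step")) {
  algorithm <- match.arg(algorithm)
  energy_tol_reference <- match.arg(energy_tol_reference)
  stopifnot(energy_tol > 0, force_tol > 0, max_iterations >= 1,
            max_evaluations >= 1)
  structure(list(energy_tol = energy_tol, force_tol = force_tol,
                 max_iterations = as.integer(max_iterations),
                 max_evaluations = as.integer(max_evaluations),
                 algorithm = algorithm,
                 energy_tol_reference = energy_tol_reference),
            class = "minimization_settings")
}

#' Minimize a structure
#'
#' Relaxes atomic positions at fixed cell with FIRE (default) or steepest
#' descent.  Trial steps that would raise the energy are rejected with the
#' step size reduced, so the accepted-energy trajectory (returned in the
#' report) is monotone non-increasing and the final energy never exceeds
#' the initial one.
#'
#' @param model a `forcefield_model`.
#' @param structure an `atomistic` structure.
#' @param settings a [minimization_settings()] object.
#' @return list with `structure` (relaxed) and `report` (`energy_report`
#'   with the accepted-energy `trajectory`).
#' @export
minimize <- function(model, structure, settings = minimization_settings()) {
  stopifnot(inherits(model, "forcefield_model"),
            inherits(settings, "minimization_settings"))
  .check_coverage(model, structure)
  types <- .assign_types(model, structure)
  res <- sw_minimize_cpp(structure$positions, types, .eval_cell(structure),
                         structure$pbc, model$params,
                         settings$energy_tol, settings$force_tol,
                         settings$max_iterations, settings$max_evaluations,
                         algorithm = if (settings$algorithm == "fire") 0L else 1L,
                         etol_mode_initial =
                           if (settings$energy_tol_reference == "initial") 1 else 0)
  out <- structure
  out$positions <- res$positions
  out$tags$minimized <- TRUE
  out$tags$forcefield <- model$name
  rep <- energy_report(total = res$energy, per_atom = res$per_atom,
                       forces = res$forces, converged = res$converged,
                       iterations = res$iterations,
                       evaluations = res$evaluations,
                       trajectory = res$trajectory)
  list(structure = out, report = rep)
}
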