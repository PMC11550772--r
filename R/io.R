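# Structure writers/readers: LAMMPS data (atomic style) and extended XYZ.
# Coordinates are Cartesian Angstrom; the tube axis is +z.  These
# conventions are recorded in every file's comment/header line.

.box_from_structure <- function(structure, pad = 10) {
  pos <- structure$positions
  cell <- structure$cell
  lo <- numeric(3); hi <- numeric(3); tilt_xy <- 0
  for (k in 1:3) {
    if (structure$pbc[k]) {
      v <- cell[k, ]
      # require LAMMPS-compatible (lower-triangular) orientation
      if (k == 1 && (abs(v[2]) > 1e-9 || abs(v[3]) > 1e-9))
        stop("periodic cell vector 1 must lie along x for LAMMPS export")
      if (k == 2 && abs(v[3]) > 1e-9)
        stop("periodic cell vector 2 must lie in the xy plane for LAMMPS export")
      if (k == 3 && (abs(v[1]) > 1e-9 || abs(v[2]) > 1e-9))
        stop("periodic cell vector 3 must lie along z for LAMMPS export")
      lo[k] <- 0
      hi[k] <- v[k]
      if (k == 2) tilt_xy <- v[1]
    } else {
      lo[k] <- min(pos[, k]) - pad
      hi[k] <- max(pos[, k]) + pad
    }
  }
  list(lo = lo, hi = hi, xy = tilt_xy)
}

#' Write a LAMMPS data file (atomic style)
#'
#' Header counts, box bounds (periodic axes span the cell vector;
#' non-periodic axes are padded), Masses and Atoms sections.  Tubes built
#' by [build_primitive_tube()] get a periodic z span equal to the
#' translational period.  Species symbols are recorded as comments on the
#' Masses lines and recovered by [read_lammps_data()].
#'
#' @param structure an `atomistic` structure.
#' @param path output file.
#' @param pad padding for non-periodic box directions, Angstrom.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(structure, path, pad = 10) {
  sp_levels <- sort(unique(structure$species))
  types <- match(structure$species, sp_levels)
  box <- .box_from_structure(structure, pad)
  con <- file(path, "w"); on.exit(close(con))
  lines <- c(
    sprintf("LAMMPS data file (Cartesian Angstrom, tube axis +z; pbc %s)",
            paste(ifelse(structure$pbc, "p", "f"), collapse = " ")),
    "",
    sprintf("%d atoms", n_atoms(structure)),
    sprintf("%d atom types", length(sp_levels)),
    "",
    sprintf("%.8f %.8f xlo xhi", box$lo[1], box$hi[1]),
    sprintf("%.8f %.8f ylo yhi", box$lo[2], box$hi[2]),
    sprintf("%.8f %.8f zlo zhi", box$lo[3], box$hi[3]))
  if (abs(box$xy) > 1e-12)
    lines <- c(lines, sprintf("%.8f 0.0 0.0 xy xz yz", box$xy))
  lines <- c(lines, "", "Masses", "",
             sprintf("%d %.6f  # %s", seq_along(sp_levels),
                     element_mass(sp_levels), sp_levels),
             "", "Atoms  # atomic", "",
             sprintf("%d %d %.8f %.8f %.8f", seq_len(n_atoms(structure)),
                     types, structure$positions[, 1],
                     structure$positions[, 2], structure$positions[, 3]))
  writeLines(lines, con)
  invisible(path)
}

#' Read a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path file path.
#' @return an `atomistic` structure (species from the Masses comments, or
#'   the nearest tabulated atomic mass when absent).
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pbc <- c(FALSE, FALSE, FALSE)
  m <- regmatches(lines[1], regexec("pbc ([pf]) ([pf]) ([pf])", lines[1]))[[1]]
  if (length(m) == 4) pbc <- m[2:4] == "p"
  natoms <- as.integer(sub(" atoms.*", "", grep("[0-9]+ atoms", lines, value = TRUE)[1]))
  grab <- function(pat) {
    ln <- grep(pat, lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][1:2])
  }
  xb <- grab("xlo xhi"); yb <- grab("ylo yhi"); zb <- grab("zlo zhi")
  tilt <- grep("xy xz yz", lines, value = TRUE)
  xy <- if (length(tilt)) as.numeric(strsplit(trimws(tilt[1]), "[[:space:]]+")[[1]][1]) else 0
  # masses section -> species
  mi <- grep("^Masses", lines)
  sp_map <- character(0)
  if (length(mi)) {
    k <- mi[1] + 1
    while (k <= length(lines)) {
      ln <- trimws(lines[k]); k <- k + 1
      if (!nzchar(ln)) { if (length(sp_map)) break else next }
      if (grepl("^[A-Za-z]", ln)) break
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      ty <- as.integer(tok[1]); mass <- as.numeric(tok[2])
      cm <- regmatches(ln, regexec("#\\s*([A-Za-z]+)", ln))[[1]]
      sp_map[ty] <- if (length(cm) == 2) cm[2] else
        names(.element_masses)[which.min(abs(.element_masses - mass))]
    }
  }
  ai <- grep("^Atoms", lines)
  if (!length(ai)) stop("no Atoms section in ", path)
  k <- ai[1] + 1
  ids <- integer(natoms); types <- integer(natoms); pos <- matrix(0, natoms, 3)
  got <- 0
  while (k <= length(lines) && got < natoms) {
    ln <- trimws(lines[k]); k <- k + 1
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    got <- got + 1
    ids[got] <- as.integer(tok[1]); types[got] <- as.integer(tok[2])
    pos[got, ] <- as.numeric(tok[3:5])
  }
  ord <- order(ids)
  types <- types[ord]; pos <- pos[ord, , drop = FALSE]
  cell <- rbind(c(xb[2] - xb[1], 0, 0), c(xy, yb[2] - yb[1], 0),
                c(0, 0, zb[2] - zb[1]))
  atomistic_structure(sp_map[types], pos, cell = cell, pbc = pbc)
}

#' Write an extended-XYZ file
#'
#' Standard extended XYZ: atom count, a comment line carrying
#' `Lattice="..."` (cell vectors, row major), `Properties` and `pbc`
#' fields, then one `species x y z` line per atom.
#'
#' @param structure an `atomistic` structure (or a `unitcell2d`, exported
#'   as its basis with the two lattice vectors and a unit z vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(structure, path) {
  if (inherits(structure, "unitcell2d")) {
    cell <- structure
    structure <- atomistic_structure(
      cell$basis$species, as.matrix(cell$basis[, c("x", "y", "z")]),
      cell = rbind(cell$a1, cell$a2, c(0, 0, 1)),
      pbc = c(TRUE, TRUE, FALSE), tags = list(material = cell$name))
  }
  con <- file(path, "w"); on.exit(close(con))
  hdr <- "Properties=species:S:1:pos:R:3"
  if (!is.null(structure$cell)) {
    hdr <- sprintf('Lattice="%s" %s pbc="%s"',
                   paste(sprintf("%.10f", t(structure$cell)), collapse = " "),
                   hdr, paste(ifelse(structure$pbc, "T", "F"), collapse = " "))
  }
  writeLines(c(sprintf("%d", n_atoms(structure)), hdr,
               sprintf("%s %.10f %.10f %.10f", structure$species,
                       structure$positions[, 1], structure$positions[, 2],
                       structure$positions[, 3])), con)
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' @param path file path.
#' @return an `atomistic` structure.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  hdr <- lines[2]
  cell <- NULL; pbc <- c(FALSE, FALSE, FALSE)
  lm <- regmatches(hdr, regexec('Lattice="([^"]+)"', hdr))[[1]]
  if (length(lm) == 2) {
    v <- as.numeric(strsplit(trimws(lm[2]), "[[:space:]]+")[[1]])
    cell <- matrix(v, 3, 3, byrow = TRUE)
  }
  pm <- regmatches(hdr, regexec('pbc="([^"]+)"', hdr))[[1]]
  if (length(pm) == 2)
    pbc <- toupper(strsplit(trimws(pm[2]), "[[:space:]]+")[[1]]) == "T"
  tok <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  sp <- vapply(tok, `[`, "", 1)
  pos <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  atomistic_structure(sp, pos, cell = cell, pbc = pbc)
}
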