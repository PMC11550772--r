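#' Two-dimensional unit cells
#'
#' A `unitcell2d` object describes the primitive cell of a single-layer
#' material: two in-plane lattice vectors `a1`, `a2` (Angstrom, z component
#' zero) and a basis of atomic sites given in Cartesian coordinates with the
#' layer mid-plane at z = 0.  Non-zero thickness layers (buckled silicene,
#' three-plane MoS2, silica bilayers) simply carry basis sites at several
#' heights; the rolling transform later reads each atom's radial offset
#' directly from its z coordinate.
#'
#' @param name identifier of the material.
#' @param a1,a2 numeric length-3 lattice vectors in Angstrom (z must be 0).
#' @param basis data.frame with columns `species`, `x`, `y`, `z` (Angstrom).
#' @param source_note citation string for the geometry used.
#' @return an object of class `unitcell2d`.
#' @export
unit_cell_2d <- function(name, a1, a2, basis, source_note = "") {
  a1 <- as.numeric(a1); a2 <- as.numeric(a2)
  stopifnot(length(a1) == 3, length(a2) == 3)
  cell <- structure(
    list(name = as.character(name), a1 = a1, a2 = a2,
         basis = as.data.frame(basis), source_note = source_note),
    class = "unitcell2d")
  validate_unit_cell(cell)
}

#' Validate a 2-D unit cell
#'
#' Checks all structural invariants: in-plane, linearly independent lattice
#' vectors; a non-empty basis of valid element symbols with finite
#' coordinates; basis sites inside one cell (fractional in-plane coordinates
#' in `[0, 1)`); no coincident sites (minimum pair distance 0.1 Angstrom).
#'
#' @param cell a `unitcell2d` object (or a bare list with the same fields).
#' @return the validated cell, invisibly classed as `unitcell2d`.
#' @export
validate_unit_cell <- function(cell) {
  a1 <- cell$a1; a2 <- cell$a2
  if (!all(is.finite(c(a1, a2)))) stop("lattice vectors must be finite")
  if (abs(a1[3]) > 1e-12 || abs(a2[3]) > 1e-12)
    stop("out-of-plane lattice vector: a1 and a2 must have zero z component")
  cr <- a1[1] * a2[2] - a1[2] * a2[1]
  if (abs(cr) < 1e-9 * max(1, sqrt(sum(a1^2)) * sqrt(sum(a2^2))))
    stop("lattice vectors linearly dependent")
  b <- cell$basis
  if (is.null(b) || nrow(b) == 0) stop("empty basis")
  if (!all(c("species", "x", "y", "z") %in% names(b)))
    stop("basis must have columns species, x, y, z")
  if (!all(is_valid_element(b$species)))
    stop("invalid element symbol in basis: ",
         paste(unique(b$species[!is_valid_element(b$species)]), collapse = ", "))
  pos <- as.matrix(b[, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  if (!all(is.finite(pos))) stop("non-finite basis coordinates")
  frac <- cell_fractional(cell, pos)
  tol <- 1e-9
  if (any(frac < -tol | frac >= 1 - tol))
    stop("basis sites must lie within one cell (fractional coordinates in [0,1))")
  if (nrow(b) > 1) {
    dmin <- min_image_pair_distance(pos, rbind(c(a1), c(a2), c(0, 0, 0)))
    if (dmin < 0.1)
      stop("coincident sites: minimum pair distance ", format(dmin),
           " Angstrom < 0.1 Angstrom")
  }
  cell$basis$species <- as.character(b$species)
  class(cell) <- "unitcell2d"
  invisible(cell)
}

# In-plane fractional coordinates of Cartesian positions (z is ignored).
cell_fractional <- function(cell, pos) {
  M <- rbind(cell$a1[1:2], cell$a2[1:2])   # rows are lattice vectors
  t(solve(t(M), t(pos[, 1:2, drop = FALSE])))
}

# Minimum over all in-plane periodic images of all pair distances.
min_image_pair_distance <- function(pos, latt) {
  n <- nrow(pos)
  shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1))
  best <- Inf
  for (s in seq_len(nrow(shifts))) {
    off <- shifts[s, 1] * latt[1, ] + shifts[s, 2] * latt[2, ]
    for (i in seq_len(n)) {
      d2 <- rowSums((pos - matrix(pos[i, ] + off, n, 3, byrow = TRUE))^2)
      if (all(shifts[s, ] == 0)) d2[i] <- Inf
      best <- min(best, min(d2))
    }
  }
  sqrt(best)
}

#' Layer thickness of a unit cell
#'
#' The thickness is the height span of the basis, `max(z) - min(z)`; zero for
#' planar materials such as graphene, 0.46 Angstrom for buckled silicene,
#' the S-plane separation for MoS2.
#'
#' @param cell a `unitcell2d`.
#' @return thickness in Angstrom.
#' @export
thickness <- function(cell) {
  stopifnot(inherits(cell, "unitcell2d"))
  max(cell$basis$z) - min(cell$basis$z)
}

#' Validate a user-supplied unit-cell definition
#'
#' Accepts either a path to a cell definition file (see Details) or a list
#' with fields `a1`, `a2`, `basis` (and optionally `name`, `source_note`),
#' and returns a validated [unit_cell_2d()] or raises an error naming the
#' violated invariant.
#'
#' @details The file format is a small line-oriented key/value text format:
#' ```
#' name my-material
#' a1 2.46 0.0 0.0
#' a2 -1.23 2.1304224 0.0
#' atom C 0.0 0.0 0.0
#' atom C 1.23 0.7101408 0.0
#' source literature citation
#' ```
#' Lengths are in Angstrom; `atom` lines give the element symbol and
#' Cartesian coordinates; lines starting with `#` are comments.
#'
#' @param raw path to a cell file, or a list.
#' @return a validated `unitcell2d`.
#' @export
validate_user_cell <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- read_cell_file(raw)
  if (inherits(raw, "unitcell2d")) return(validate_unit_cell(raw))
  stopifnot(is.list(raw))
  if (is.null(raw$a1) || is.null(raw$a2)) stop("cell definition must provide a1 and a2")
  unit_cell_2d(name = if (is.null(raw$name)) "user-cell" else raw$name,
               a1 = raw$a1, a2 = raw$a2, basis = raw$basis,
               source_note = if (is.null(raw$source_note)) "" else raw$source_note)
}

#' Read a unit-cell definition file
#'
#' @param path file in the format documented in [validate_user_cell()].
#' @return an unvalidated list with fields `name`, `a1`, `a2`, `basis`,
#'   `source_note`; pass through [validate_user_cell()] to check it.
#' @export
read_cell_file <- function(path) {
  if (!file.exists(path)) stop("cell file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(name = "user-cell", source_note = "")
  sp <- character(0); xyz <- matrix(numeric(0), 0, 3)
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "name") out$name <- paste(tok[-1], collapse = " ")
    else if (key == "source") out$source_note <- paste(tok[-1], collapse = " ")
    else if (key %in% c("a1", "a2")) out[[key]] <- as.numeric(tok[2:4])
    else if (key == "atom") {
      sp <- c(sp, tok[2]); xyz <- rbind(xyz, as.numeric(tok[3:5]))
    } else stop("unrecognised line in cell file: '", ln, "'")
  }
  out$basis <- data.frame(species = sp, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE)
  out
}

#' Write a unit-cell definition file
#'
#' @param cell a `unitcell2d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_file <- function(cell, path) {
  stopifnot(inherits(cell, "unitcell2d"))
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(v) paste(sprintf("%.10f", v), collapse = " ")
  writeLines(c(
    paste("name", cell$name),
    paste("a1", fmt(cell$a1)),
    paste("a2", fmt(cell$a2)),
    sprintf("atom %s %s", cell$basis$species,
            vapply(seq_len(nrow(cell$basis)), function(i)
              fmt(as.numeric(cell$basis[i, c("x", "y", "z")])), "")),
    if (nzchar(cell$source_note)) paste("source", cell$source_note)
  ), con)
  invisible(path)
}

#' @export
print.unitcell2d <- function(x, ...) {
  cat("2-D unit cell:", x$name, "\n")
  cat(sprintf("  a1 = (%.4f, %.4f, 0)  |a1| = %.4f A\n", x$a1[1], x$a1[2],
              sqrt(sum(x$a1^2))))
  cat(sprintf("  a2 = (%.4f, %.4f, 0)  |a2| = %.4f A\n", x$a2[1], x$a2[2],
              sqrt(sum(x$a2^2))))
  cat(sprintf("  basis: %d site(s) [%s], thickness %.3f A\n", nrow(x$basis),
              paste(unique(x$basis$species), collapse = ","), thickness(x)))
  if (nzchar(x$source_note)) cat("  source:", x$source_note, "\n")
  invisible(x)
}
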