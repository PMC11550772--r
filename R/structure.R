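#' Atomistic structures
#'
#' The workhorse container for sheets, strips and tubes: element symbols,
#' an N x 3 matrix of Cartesian positions in Angstrom, an optional 3 x 3
#' matrix of periodic cell vectors (rows), per-axis periodicity flags, and a
#' free-form `tags` list recording provenance (material, chiral indices,
#' construction stage).
#'
#' @param species character vector of element symbols (length N).
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param cell optional 3 x 3 matrix whose rows are the cell vectors.
#' @param pbc logical length-3 periodicity flags.
#' @param tags named list of provenance metadata.
#' @return an object of class `atomistic`.
#' @export
atomistic_structure <- function(species, positions, cell = NULL,
                                pbc = c(FALSE, FALSE, FALSE), tags = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (nrow(positions) < 1) stop("structure must contain at least one atom")
  if (length(species) != nrow(positions))
    stop("species and positions disagree in length")
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (!is.null(cell)) {
    cell <- as.matrix(cell); storage.mode(cell) <- "double"
    stopifnot(all(dim(cell) == c(3, 3)))
  }
  pbc <- as.logical(pbc)
  stopifnot(length(pbc) == 3)
  for (k in 1:3) {
    if (pbc[k] && (is.null(cell) || sum(cell[k, ]^2) < 1e-20))
      stop("periodic axis ", k, " has a zero cell vector")
  }
  structure(list(species = as.character(species), positions = positions,
                 cell = cell, pbc = pbc, tags = tags),
            class = "atomistic")
}

#' Number of atoms
#' @param s an `atomistic` structure.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$positions)

#' @export
print.atomistic <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("atomistic structure: %d atoms (%s)\n", n_atoms(x),
              paste(sprintf("%s%d", names(tab), tab), collapse = " ")))
  if (!is.null(x$cell)) {
    cat("  cell (rows, A):\n")
    for (k in 1:3)
      cat(sprintf("    [%8.4f %8.4f %8.4f]  pbc=%s\n", x$cell[k, 1],
                  x$cell[k, 2], x$cell[k, 3], x$pbc[k]))
  }
  if (length(x$tags))
    cat("  tags:", paste(names(x$tags), vapply(x$tags, function(t)
      paste(format(t), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' All interatomic distances under periodic boundary conditions
#'
#' Returns the full set of pair distances up to `cutoff`, counting every
#' periodic image pair separately.  Backed by the compiled neighbor-list
#' kernel; used by the coordination and order-parameter descriptors.
#'
#' @param s an `atomistic` structure.
#' @param cutoff maximum distance in Angstrom.
#' @return data.frame with columns `i`, `j` (1-based atom indices) and `d`
#'   (distance, Angstrom); each unordered pair/image appears once.
#' @export
neighbor_pairs <- function(s, cutoff) {
  cell <- if (is.null(s$cell)) diag(3) else s$cell
  res <- nr_neighbor_pairs(s$positions, cell, s$pbc, as.numeric(cutoff))
  data.frame(i = res$i, j = res$j, d = res$d)
}

# Sorted multiset of all pair distances below cutoff (finite cluster use).
pair_distance_multiset <- function(s, cutoff = Inf) {
  p <- s$positions
  d <- as.numeric(dist(p))
  sort(d[d <= cutoff])
}
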