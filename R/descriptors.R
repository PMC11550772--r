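#' Pair-key helper for per-species-pair cutoffs
#'
#' Cutoffs are named numeric vectors with names like `"Mo-S"`; the two
#' symbols are sorted alphabetically, so `"Mo-S"` and `"S-Mo"` are the same
#' key.
#'
#' @param s1,s2 element symbols.
#' @return character key.
#' @export
pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "-")
}

#' Default neighbor cutoffs for a material
#'
#' For every species pair present in the material, 1.2 times the shortest
#' pair distance in the pristine periodic sheet.  Individual pairs can be
#' overridden by name in the functions that consume cutoffs.
#'
#' @param cell a `unitcell2d` (or material name).
#' @return named numeric vector of cutoffs in Angstrom, names per [pair_key()].
#' @export
default_cutoffs <- function(cell) {
  if (is.character(cell)) cell <- get_material(cell)
  sheet <- build_sheet(cell, 1, 1)
  sp <- sheet$species
  # generous search radius: 1.3x the largest in-plane lattice parameter
  rmax <- 1.3 * max(sqrt(sum(cell$a1^2)), sqrt(sum(cell$a2^2)), thickness(cell) + 1)
  np <- neighbor_pairs(sheet, rmax)
  key <- pair_key(sp[np$i], sp[np$j])
  out <- 1.2 * tapply(np$d, key, min)
  stats::setNames(as.numeric(out), names(out))
}

.cutoff_lookup <- function(cutoffs, s1, s2) {
  k <- pair_key(s1, s2)
  v <- cutoffs[k]
  if (anyNA(v))
    stop("missing cutoff for species pair(s): ",
         paste(unique(k[is.na(v)]), collapse = ", "))
  as.numeric(v)
}

# directed neighbor entries filtered by per-pair cutoffs
.neighbor_entries <- function(structure, cutoffs) {
  # every species pair present must have a cutoff (possibly zero)
  sps <- sort(unique(structure$species))
  need <- unique(as.character(outer(sps, sps, pair_key)))
  miss <- setdiff(need, names(cutoffs))
  if (length(miss))
    stop("missing cutoff for species pair(s): ", paste(miss, collapse = ", "))
  cellm <- if (is.null(structure$cell)) diag(3) else structure$cell
  nv <- nr_neighbor_vectors(structure$positions, cellm, structure$pbc,
                            max(cutoffs))
  sp <- structure$species
  if (length(nv$i) == 0)
    return(data.frame(i = integer(0), j = integer(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0), d = numeric(0)))
  rc <- .cutoff_lookup(cutoffs, sp[nv$i], sp[nv$j])
  keep <- nv$d < rc
  data.frame(i = nv$i[keep], j = nv$j[keep], dx = nv$dx[keep],
             dy = nv$dy[keep], dz = nv$dz[keep], d = nv$d[keep])
}

#' Per-atom coordination numbers
#'
#' Counts neighbors within the species-pair cutoff, with periodic images
#' counted on periodic axes.
#'
#' @param structure an `atomistic` structure.
#' @param cutoffs named cutoff vector (see [default_cutoffs()]); must cover
#'   every species pair present.
#' @return integer vector, one count per atom.
#' @export
coordination_numbers <- function(structure, cutoffs) {
  ne <- .neighbor_entries(structure, cutoffs)
  cnt <- tabulate(ne$i, nbins = n_atoms(structure))
  as.integer(cnt)
}

#' Per-atom common-neighborhood parameter (CNP)
#'
#' The structural-order measure of Tsuzuki, Branicio and Rino: for atom i
#' with neighbor set N(i),
#' \deqn{CNP_i = \frac{1}{|N(i)|}\sum_{j \in N(i)}
#'   \Big|\sum_{k \in N(i)\cap N(j)} (\mathbf r_{ik} + \mathbf r_{jk})\Big|^2,}
#' where k runs over the common neighbors of i and j.  It vanishes in an
#' ideal close-packed crystal and grows with local disorder.  Atoms with no
#' neighbors, or whose neighbors share no common neighbors, score 0.
#'
#' @inheritParams coordination_numbers
#' @return numeric vector, Angstrom^2.
#' @export
common_neighborhood_parameter <- function(structure, cutoffs) {
  ne <- .neighbor_entries(structure, cutoffs)
  n <- n_atoms(structure)
  sp <- structure$species
  out <- numeric(n)
  if (nrow(ne) == 0) return(out)
  byatom <- split(seq_len(nrow(ne)), ne$i)
  for (i in as.integer(names(byatom))) {
    rows <- byatom[[as.character(i)]]
    nb <- ne[rows, , drop = FALSE]
    acc <- 0
    for (r in seq_len(nrow(nb))) {
      j <- nb$j[r]
      dj <- c(nb$dx[r], nb$dy[r], nb$dz[r])
      # common neighbors: entries k of i that are also within cutoff of j
      rjk_x <- nb$dx - dj[1]; rjk_y <- nb$dy - dj[2]; rjk_z <- nb$dz - dj[3]
      rjk <- sqrt(rjk_x^2 + rjk_y^2 + rjk_z^2)
      rc <- .cutoff_lookup(cutoffs, sp[j], sp[nb$j])
      common <- rjk > 1e-9 & rjk < rc & seq_len(nrow(nb)) != r
      if (!any(common)) next
      sx <- sum(nb$dx[common] + rjk_x[common])
      sy <- sum(nb$dy[common] + rjk_y[common])
      sz <- sum(nb$dz[common] + rjk_z[common])
      acc <- acc + sx^2 + sy^2 + sz^2
    }
    out[i] <- acc / nrow(nb)
  }
  out
}

# admissible first/second shell counts per species in the pristine sheet,
# plus the second-shell cutoffs, derived from the material's own geometry
reference_shell_counts <- function(cell, cutoffs = default_cutoffs(cell)) {
  sheet <- build_sheet(cell, 1, 1)
  sp <- sheet$species
  rmax <- 1.3 * max(sqrt(sum(cell$a1^2)), sqrt(sum(cell$a2^2)),
                    thickness(cell) + 1)
  np <- neighbor_pairs(sheet, rmax)
  # second-shell cutoff per pair: 1.2x the smallest distance beyond the
  # first-shell cutoff
  keys <- pair_key(sp[np$i], sp[np$j])
  cut2 <- cutoffs
  for (k in unique(keys)) {
    beyond <- np$d[keys == k & np$d >= cutoffs[k]]
    cut2[k] <- if (length(beyond)) 1.2 * min(beyond) else cutoffs[k]
  }
  c1 <- coordination_numbers(sheet, cutoffs)
  ctot <- coordination_numbers(sheet, cut2)
  c2 <- ctot - c1
  list(cutoffs2 = cut2,
       first = split(c1, sp), second = split(c2, sp))
}

#' First and second hex (ring-coordination) parameters
#'
#' Operational ring-order indicators: the first hex parameter of an atom is
#' 1 when its first-shell neighbor count equals the count that its species
#' has in the pristine material sheet, else 0; the second hex parameter
#' applies the same test to the second shell (between the first- and
#' second-shell cutoffs).  Averages over atoms are fractions in \[0, 1\];
#' vacancies and rolled-surface distortions lower them.
#'
#' @param structure an `atomistic` structure.
#' @param cell the material `unitcell2d` providing the reference counts.
#' @param cutoffs first-shell cutoffs (default [default_cutoffs()]).
#' @return list with per-atom 0/1 vectors `first` and `second`.
#' @export
hex_parameters <- function(structure, cell, cutoffs = default_cutoffs(cell)) {
  ref <- reference_shell_counts(cell, cutoffs)
  sp <- structure$species
  c1 <- coordination_numbers(structure, cutoffs)
  ctot <- coordination_numbers(structure, ref$cutoffs2)
  c2 <- ctot - c1
  ok1 <- ok2 <- numeric(length(sp))
  for (i in seq_along(sp)) {
    s <- sp[i]
    ok1[i] <- as.numeric(s %in% names(ref$first) && c1[i] %in% ref$first[[s]])
    ok2[i] <- as.numeric(s %in% names(ref$second) && c2[i] %in% ref$second[[s]])
  }
  list(first = ok1, second = ok2)
}

.descriptor_units <- c(
  D1 = "eV", D2 = "eV", D3 = "eV", D4 = "", D5 = "", D6 = "", D7 = "",
  D8 = "", D9 = "A", D10 = "A", D11 = "A^2", D12 = "", D13 = "", D14 = "",
  D15 = "", D16 = "A^2", D17 = "A^2", D18 = "A^2", D19 = "", D20 = "",
  D21 = "", D22 = "", D23 = "", D24 = "A", D25 = "A", D26 = "A", D27 = "A",
  D28 = "A^2", D29 = "A", D30 = "A")

.descriptor_names <- c(
  D1 = "mean potential energy of nanosheet atoms",
  D2 = "mean potential energy of nanotube atoms",
  D3 = "mean sheet-tube potential energy difference",
  D4 = "sheet/tube potential energy ratio",
  D5 = "mean coordination number of nanosheet atoms",
  D6 = "mean coordination number of nanotube atoms",
  D7 = "sheet-tube coordination difference",
  D8 = "sheet/tube coordination ratio",
  D9 = "nanotube diameter (nominal)",
  D10 = "nanotube perimeter (nominal)",
  D11 = "nanotube entrance surface (nominal disc)",
  D12 = "replications in direction 1 (n1)",
  D13 = "replications in direction 2 (n2)",
  D14 = "absolute index difference |n1 - n2|",
  D15 = "index ratio n2/n1",
  D16 = "mean CNP of nanosheet atoms",
  D17 = "mean CNP of nanotube atoms",
  D18 = "sheet-tube CNP difference",
  D19 = "sheet/tube CNP ratio",
  D20 = "mean first hex parameter of nanosheet atoms",
  D21 = "mean first hex parameter of nanotube atoms",
  D22 = "mean second hex parameter of nanosheet atoms",
  D23 = "mean second hex parameter of nanotube atoms",
  D24 = "minimum nanotube radius",
  D25 = "maximum nanotube radius",
  D26 = "minimum nanotube perimeter",
  D27 = "maximum nanotube perimeter",
  D28 = "actual entrance surface (atom-derived annulus)",
  D29 = "nanotube wall thickness",
  D30 = "nanosheet thickness")

#' Geometric tube descriptors
#'
#' Computes the purely geometric descriptors of a tube: nominal diameter,
#' perimeter and entrance disc (D9-D11) from the rolling vector, and the
#' atom-derived radial extrema and the quantities that follow from them
#' (D24-D29).  `D11` uses the nominal-radius disc; `D28`, the "actual"
#' entrance surface, uses the annulus between the smallest and largest atom
#' radii.
#'
#' @param tube an `atomistic` tube (axis = z).
#' @param geom its [tube_geometry()].
#' @return named numeric vector with elements D9, D10, D11, D24..D29.
#' @export
geometric_descriptors <- function(tube, geom) {
  rad <- sqrt(tube$positions[, 1]^2 + tube$positions[, 2]^2)
  r0 <- geom$nominal_radius
  d24 <- min(rad); d25 <- max(rad)
  c(D9 = 2 * r0, D10 = geom$perimeter, D11 = pi * r0^2,
    D24 = d24, D25 = d25, D26 = 2 * pi * d24, D27 = 2 * pi * d25,
    D28 = pi * (d25^2 - d24^2), D29 = d25 - d24)
}

#' Compile the full 30-descriptor set
#'
#' Assembles descriptors D1-D30 for a nanosheet/nanotube pair: energetics
#' (D1-D4) from the supplied energy reports, coordination statistics
#' (D5-D8), geometry (D9-D11, D24-D29), chiral indices (D12-D15),
#' common-neighborhood parameter statistics (D16-D19), ring-order ("hex")
#' parameters (D20-D23) and the sheet thickness (D30).  The difference
#' convention is sheet minus tube (D3 positive when the tube is the more
#' stable structure); ratios are sheet over tube; `D15 = n2/n1` is `NA`
#' when `n1 = 0`.
#'
#' @param sheet,tube `atomistic` structures built from the same material.
#' @param sheet_energy,tube_energy `energy_report`s from the same force
#'   field (or `NULL` for a geometry-only record).
#' @param idx chiral indices.
#' @param geom the tube's [tube_geometry()].
#' @param cell the material `unitcell2d` (reference for cutoffs and ring
#'   counts).
#' @param cutoffs optional cutoff overrides.
#' @param stage `"geometric"` or `"minimized"` provenance tag.
#' @return a `descriptor_set`: data.frame with columns `id`, `value`,
#'   `unit`, `description` and attributes `stage`, `inputs`, `verdict`.
#' @export
compile_descriptors <- function(sheet, tube, sheet_energy = NULL,
                                tube_energy = NULL, idx, geom, cell,
                                cutoffs = default_cutoffs(cell),
                                stage = c("minimized", "geometric")) {
  stage <- match.arg(stage)
  idx <- as_chiral(idx)
  if (!setequal(unique(sheet$species), unique(tube$species)))
    stop("sheet and tube contain different species")
  d <- stats::setNames(rep(NA_real_, 30), paste0("D", 1:30))
  if (!is.null(sheet_energy)) d["D1"] <- mean(sheet_energy$per_atom_energy)
  if (!is.null(tube_energy)) d["D2"] <- mean(tube_energy$per_atom_energy)
  d["D3"] <- d["D1"] - d["D2"]
  d["D4"] <- if (!is.na(d["D2"]) && d["D2"] != 0) d["D1"] / d["D2"] else NA
  d["D5"] <- mean(coordination_numbers(sheet, cutoffs))
  d["D6"] <- mean(coordination_numbers(tube, cutoffs))
  d["D7"] <- d["D5"] - d["D6"]
  d["D8"] <- if (d["D6"] != 0) d["D5"] / d["D6"] else NA
  d[c("D9", "D10", "D11", "D24", "D25", "D26", "D27", "D28", "D29")] <-
    geometric_descriptors(tube, geom)[c("D9", "D10", "D11", "D24", "D25",
                                        "D26", "D27", "D28", "D29")]
  d["D12"] <- idx$n1; d["D13"] <- idx$n2
  d["D14"] <- abs(idx$n1 - idx$n2)
  d["D15"] <- if (idx$n1 != 0) idx$n2 / idx$n1 else NA
  d["D16"] <- mean(common_neighborhood_parameter(sheet, cutoffs))
  d["D17"] <- mean(common_neighborhood_parameter(tube, cutoffs))
  d["D18"] <- d["D16"] - d["D17"]
  d["D19"] <- if (d["D17"] != 0) d["D16"] / d["D17"] else NA
  hx_s <- hex_parameters(sheet, cell, cutoffs)
  hx_t <- hex_parameters(tube, cell, cutoffs)
  d["D20"] <- mean(hx_s$first); d["D21"] <- mean(hx_t$first)
  d["D22"] <- mean(hx_s$second); d["D23"] <- mean(hx_t$second)
  d["D30"] <- max(sheet$positions[, 3]) - min(sheet$positions[, 3])
  out <- data.frame(id = names(d), value = as.numeric(d),
                    unit = unname(.descriptor_units[names(d)]),
                    description = unname(.descriptor_names[names(d)]),
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- stage
  attr(out, "inputs") <- list(material = cell$name, n1 = idx$n1, n2 = idx$n2,
                              forcefield = tube$tags$forcefield)
  attr(out, "verdict") <- if (is.na(d["D3"])) NA_character_
    else if (d["D3"] > 0) "nanotube more stable" else "nanosheet more stable"
  class(out) <- c("descriptor_set", "data.frame")
  out
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("descriptor set (%s stage)", attr(x, "stage")))
  inp <- attr(x, "inputs")
  if (!is.null(inp))
    cat(sprintf(" - %s (%d,%d)", inp$material, inp$n1, inp$n2))
  cat("\n")
  if (!is.na(attr(x, "verdict"))) cat("  stability:", attr(x, "verdict"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write a descriptor set as CSV or JSON
#'
#' One row/object per descriptor set, columns D1-D30 plus metadata, as a
#' machine-learning feature table.
#'
#' @param dsets a `descriptor_set` or list of them.
#' @param path output path; format from the extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(dsets, path) {
  if (inherits(dsets, "descriptor_set")) dsets <- list(dsets)
  rows <- lapply(dsets, function(ds) {
    inp <- attr(ds, "inputs")
    c(list(material = inp$material, n1 = inp$n1, n2 = inp$n2,
           forcefield = if (is.null(inp$forcefield)) NA else inp$forcefield,
           stage = attr(ds, "stage"), verdict = attr(ds, "verdict")),
      stats::setNames(as.list(ds$value), ds$id))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
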