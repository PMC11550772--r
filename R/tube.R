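#' Tube geometry record
#'
#' @param nominal_radius mid-plane radius |Ch| / 2*pi, Angstrom.
#' @param wrap_angle degrees.
#' @param perimeter |Ch|, Angstrom.
#' @param period_length axial repeat length, Angstrom, or `NULL`.
#' @param period_indices integer pair (t1, t2) or `NULL`.
#' @return object of class `tube_geometry`.
#' @export
tube_geometry <- function(nominal_radius, wrap_angle, perimeter,
                          period_length = NULL, period_indices = NULL) {
  stopifnot(abs(perimeter - 2 * pi * nominal_radius) < 1e-6 * max(1, perimeter))
  if (!is.null(period_length)) stopifnot(period_length > 0)
  structure(list(nominal_radius = nominal_radius, wrap_angle = wrap_angle,
                 perimeter = perimeter, axis = c(0, 0, 1),
                 period_length = period_length, period_indices = period_indices),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("tube geometry: R = %.2f A, wrap angle = %.2f deg, perimeter = %.2f A\n",
              x$nominal_radius, x$wrap_angle, x$perimeter))
  if (!is.null(x$period_length))
    cat(sprintf("  translational period = %.6f A, (t1,t2) = (%d,%d)\n",
                x$period_length, x$period_indices[1], x$period_indices[2]))
  invisible(x)
}

#' Roll a strip into a cylinder
#'
#' Mid-plane arc length is preserved: the reference radius is
#' R = Ch_length / 2*pi and an atom at (x, y, z) in the rolled frame maps to
#' ((R+z) cos t, (R+z) sin t, y) with t = 2*pi*x/Ch_length, so atoms above
#' or below the mid-plane sit on radial shells offset by their layer height.
#' The tube axis is +z and the seam sits at t = 0.
#'
#' @param strip an `atomistic` strip in the rolled frame (x along Ch).
#' @param Ch_length rolling-vector length (tube perimeter), Angstrom.
#' @return an `atomistic` tube (non-periodic; same atom count).
#' @export
roll <- function(strip, Ch_length) {
  if (!is.finite(Ch_length) || Ch_length <= 0) stop("Ch_length must be positive")
  R <- Ch_length / (2 * pi)
  z <- strip$positions[, 3]
  if (R + min(z) <= 0.2)
    stop("tube would self-intersect: smallest shell radius ",
         format(R + min(z)), " A (<= 0.2 A)")
  theta <- 2 * pi * strip$positions[, 1] / Ch_length
  rad <- R + z
  pos <- cbind(rad * cos(theta), rad * sin(theta), strip$positions[, 2])
  tags <- strip$tags; tags$stage <- "tube"
  atomistic_structure(strip$species, pos, tags = tags)
}

#' Build a non-periodic tube of fixed length
#'
#' Extracts the strip `[0,|Ch|) x [0,length)` and rolls it.  The result is
#' an open-ended tube with no periodic boundary conditions.
#'
#' @param cell a `unitcell2d`.
#' @param idx chiral indices.
#' @param length tube length along the axis, Angstrom.
#' @return list with elements `structure` (`atomistic`) and `geometry`
#'   ([tube_geometry()]).
#' @export
build_tube_fixed_length <- function(cell, idx, length) {
  idx <- as_chiral(idx)
  strip <- extract_strip(cell, idx, length)
  W <- sqrt(sum(rolling_vector(cell, idx)^2))
  tube <- roll(strip, W)
  tube$tags$mode <- "fixed_length"
  geom <- tube_geometry(W / (2 * pi), wrap_angle(cell, idx), W)
  list(structure = tube, geometry = geom)
}

# Projection of lattice vector T = t1 a1 + t2 a2 onto the rolling direction
# (alpha, beta are the metric contractions with Ch).
.period_metrics <- function(cell, idx) {
  g11 <- sum(cell$a1 * cell$a1); g22 <- sum(cell$a2 * cell$a2)
  g12 <- sum(cell$a1 * cell$a2)
  list(alpha = g11 * idx$n1 + g12 * idx$n2, beta = g12 * idx$n1 + g22 * idx$n2)
}

#' Find the translational period of a nanotube
#'
#' Searches for the smallest non-zero lattice vector T = t1*a1 + t2*a2 that
#' is perpendicular to the rolling vector Ch, i.e. whose projection onto Ch
#' vanishes.  When the metric ratio beta/alpha is rational (all built-in
#' cells) the solution comes from exact integer reduction; otherwise an
#' incremental search accepts the first T whose seam mismatch (projection
#' of T on the rolling direction) is below `threshold`.
#'
#' @param cell a `unitcell2d`.
#' @param idx chiral indices.
#' @param threshold seam-mismatch acceptance threshold in Angstrom for the
#'   search branch (default 1e-4).
#' @param max_rep search cap on |t1|, |t2| (default 1000).
#' @return list with `t1`, `t2`, `period_length` (Angstrom), `mismatch`
#'   (Angstrom, 0 for the exact branch) and `exact` (logical).
#' @export
find_translational_period <- function(cell, idx, threshold = 1e-4,
                                      max_rep = 1000) {
  idx <- as_chiral(idx, cap = Inf)
  m <- .period_metrics(cell, idx)
  alpha <- m$alpha; beta <- m$beta
  ch <- rolling_vector(cell, idx); W <- sqrt(sum(ch^2))
  Tvec <- function(t1, t2) t1 * cell$a1 + t2 * cell$a2
  mismatch <- function(t1, t2) abs(sum(Tvec(t1, t2) * ch)) / W
  canonical <- function(t1, t2) {
    # orient T along the +90-degree rotation of Ch (right-handed axial sense)
    nhat <- c(-ch[2], ch[1]) / W
    s <- t1 * cell$a1[1:2] %*% nhat + t2 * cell$a2[1:2] %*% nhat
    if (s < 0) c(-t1, -t2) else c(t1, t2)
  }
  # exact branch: alpha*t1 + beta*t2 = 0 with rational beta/alpha
  rat <- .as_rational(beta, alpha)
  if (!is.null(rat)) {
    t1 <- rat$num; t2 <- -rat$den
    if (t1 == 0 && t2 == 0) t2 <- 1L
    g <- .gcd(abs(t1), abs(t2)); if (g > 0) { t1 <- t1 / g; t2 <- t2 / g }
    if (mismatch(t1, t2) < 1e-9 * max(1, W)) {
      tt <- canonical(t1, t2)
      Tv <- Tvec(tt[1], tt[2])
      perp <- Tv - as.numeric(sum(Tv * ch) / W^2) * ch
      return(list(t1 = as.integer(tt[1]), t2 = as.integer(tt[2]),
                  period_length = sqrt(sum(perp^2)), mismatch = 0,
                  exact = TRUE))
    }
  }
  # incremental search: grow the axial extent until the seam mismatch drops
  # below threshold
  best <- NULL
  for (rmax in seq_len(max_rep)) {
    cand <- rbind(cbind(rmax, -rmax:rmax), cbind(-rmax, -rmax:rmax),
                  cbind(-(rmax - 1):(rmax - 1), rmax),
                  cbind(-(rmax - 1):(rmax - 1), -rmax))
    for (r in seq_len(nrow(cand))) {
      t1 <- cand[r, 1]; t2 <- cand[r, 2]
      mm <- mismatch(t1, t2)
      if (is.null(best) || mm < best$mismatch) best <- list(t1 = t1, t2 = t2, mismatch = mm)
      if (mm < threshold) {
        tt <- canonical(t1, t2)
        Tv <- Tvec(tt[1], tt[2])
        perp <- Tv - as.numeric(sum(Tv * ch) / W^2) * ch
        return(list(t1 = as.integer(tt[1]), t2 = as.integer(tt[2]),
                    period_length = sqrt(sum(perp^2)), mismatch = mm,
                    exact = FALSE))
      }
    }
  }
  stop("no translational period found within |t| <= ", max_rep,
       "; best seam mismatch ", format(best$mismatch), " Angstrom")
}

# continued-fraction rational reconstruction of x = num/den; NULL if x is not
# (numerically) rational with a modest denominator
.as_rational <- function(num, den, tol = 1e-9, max_den = 1e6) {
  scale <- max(abs(num), abs(den), 1)
  if (abs(den) < tol * scale) {
    return(list(num = 1L, den = 0L))   # alpha = 0: T = a1 is exactly axial
  }
  if (abs(num) < tol * scale) {
    return(list(num = 0L, den = 1L))   # beta = 0: a2 is exactly axial
  }
  x <- num / den
  pm1 <- 1; qm1 <- 0; p <- round(x); q <- 1; xr <- x
  for (k in 1:64) {
    if (abs(p / q - x) < tol * max(1, abs(x))) break
    frac <- xr - round(xr)
    if (abs(frac) < 1e-15) break
    xr <- 1 / frac
    an <- round(xr)
    pn <- an * p + pm1; qn <- an * q + qm1
    pm1 <- p; qm1 <- q; p <- pn; q <- qn
    if (abs(q) > max_den) return(NULL)
  }
  if (abs(p / q - x) >= tol * max(1, abs(x))) return(NULL)
  list(num = as.integer(p), den = as.integer(q))
}

.gcd <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

#' Build the primitive (translational) unit cell of a nanotube
#'
#' Constructs the tube whose axial length is the translational period, with
#' periodic boundary conditions along the axis only.  Replicating it axially
#' reproduces the fixed-length construction atom for atom; every atom's
#' axial periodic image coincides with an atom of the next repeat within the
#' seam threshold.
#'
#' @param cell a `unitcell2d`.
#' @param idx chiral indices.
#' @param threshold,max_rep passed to [find_translational_period()].
#' @param padding in-plane box padding beyond the largest shell radius,
#'   Angstrom (for exported orthogonal boxes).
#' @return list with `structure`, `geometry`, `period`.
#' @export
build_primitive_tube <- function(cell, idx, threshold = 1e-4, max_rep = 1000,
                                 padding = 10) {
  idx <- as_chiral(idx)
  per <- find_translational_period(cell, idx, threshold, max_rep)
  strip <- extract_strip(cell, idx, per$period_length)
  W <- sqrt(sum(rolling_vector(cell, idx)^2))
  tube <- roll(strip, W)
  rmax <- max(sqrt(rowSums(tube$positions[, 1:2, drop = FALSE]^2)))
  L <- 2 * (rmax + padding)
  tube$cell <- rbind(c(L, 0, 0), c(0, L, 0), c(0, 0, per$period_length))
  tube$pbc <- c(FALSE, FALSE, TRUE)
  tube$tags$mode <- "primitive"
  tube$tags$period <- per$period_length
  geom <- tube_geometry(W / (2 * pi), wrap_angle(cell, idx), W,
                        period_length = per$period_length,
                        period_indices = c(per$t1, per$t2))
  list(structure = tube, geometry = geom, period = per)
}

#' Unroll a tube back onto the plane
#'
#' Inverse of [roll()] for tubes with all shell radii positive: recovers the
#' rolled-frame strip coordinates (x along Ch from the seam at angle 0,
#' y axial, z the radial offset from the reference radius).
#'
#' @param tube an `atomistic` tube produced by [roll()].
#' @param Ch_length perimeter used when rolling, Angstrom.
#' @return an `atomistic` strip.
#' @export
unroll <- function(tube, Ch_length) {
  R <- Ch_length / (2 * pi)
  p <- tube$positions
  rad <- sqrt(p[, 1]^2 + p[, 2]^2)
  theta <- atan2(p[, 2], p[, 1])
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  pos <- cbind(theta * Ch_length / (2 * pi), p[, 3], rad - R)
  tags <- tube$tags; tags$stage <- "strip"
  atomistic_structure(tube$species, pos, tags = tags)
}
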