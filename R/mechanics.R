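# Protein cross-section area profiles A(z), area differences between
# conformations, and the work done against the lateral pressure profile
# for a change in cross-section area:
#   W = integral of deltaA(z) * pi(z) dz        [bar A^3 -> kcal/mol]
# Areas are computed by slicing the van der Waals spheres of the protein
# atoms at each slab center and measuring the area of the union of the
# resulting disks on a 2-D occupancy grid.

#' Default van der Waals radii (Angstrom)
#'
#' @return named numeric vector for elements H, C, N, O, S, P.
#' @export
default_vdw_radii <- function() {
  c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
}

# Element of an atom from its PDB atom name (first non-digit character).
atom_element <- function(elety) {
  sub("^[0-9]*([A-Za-z]).*$", "\\1", elety)
}

#' Area profile container
#'
#' @param z regular z grid (slab centers), Angstrom.
#' @param area non-negative areas A(z), Angstrom^2.
#' @param ... provenance fields stored alongside.
#' @return object of class `area_profile`.
#' @export
area_profile <- function(z, area, ...) {
  if (length(z) != length(area)) stop("z and area lengths differ")
  if (any(area < -1e-9)) stop("areas must be non-negative")
  if (length(z) > 1 && any(diff(z) <= 0)) stop("z grid must be increasing")
  structure(list(z = as.numeric(z), area = pmax(as.numeric(area), 0), ...),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile> %d slabs, z = %.1f..%.1f A, max A = %.1f A^2\n",
              length(x$z), min(x$z), max(x$z), max(x$area)))
  invisible(x)
}

#' Protein cross-section area profile along z
#'
#' For each slab center z_c, every atom whose van der Waals sphere crosses
#' the plane z = z_c contributes a disk of radius
#' `sqrt(R^2 - (z_c - z_atom)^2)`; the slab area is the area of the union of
#' these disks, measured by counting occupancy-grid cells of the stated
#' resolution whose centers fall inside any disk.
#'
#' @param frame a [mol_frame()]; only non-lipid atoms are used.
#' @param radii named per-element radii in Angstrom
#'   (default [default_vdw_radii()]).
#' @param slab_width z spacing of the profile (default 0.2 Angstrom).
#' @param grid_resolution xy occupancy-cell edge (default 0.1 Angstrom).
#' @param z_range optional c(lo, hi) to restrict the profile; default spans
#'   the protein extent padded by the largest radius.
#' @return an [area_profile()].
#' @export
cross_section_profile <- function(frame, radii = default_vdw_radii(),
                                  slab_width = 0.2, grid_resolution = 0.1,
                                  z_range = NULL) {
  stopifnot(inherits(frame, "mol_frame"))
  at <- frame$atoms[!is_lipid_atom(frame$atoms), , drop = FALSE]
  if (!nrow(at)) stop("no protein atoms in frame")
  el <- atom_element(at$elety)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(radii[el])
  if (is.null(z_range))
    z_range <- c(min(at$z - r), max(at$z + r))
  zgrid <- seq(floor(z_range[1] / slab_width) * slab_width,
               ceiling(z_range[2] / slab_width) * slab_width,
               by = slab_width)
  g <- grid_resolution
  xg <- seq(floor(min(at$x - r) / g) * g, ceiling(max(at$x + r) / g) * g, by = g)
  yg <- seq(floor(min(at$y - r) / g) * g, ceiling(max(at$y + r) / g) * g, by = g)
  nx <- length(xg); ny <- length(yg)
  areas <- numeric(length(zgrid))
  for (s in seq_along(zgrid)) {
    dz <- zgrid[s] - at$z
    hit <- which(abs(dz) < r)
    if (!length(hit)) next
    occ <- matrix(FALSE, nx, ny)
    rd <- sqrt(r[hit]^2 - dz[hit]^2)
    for (j in seq_along(hit)) {
      a <- hit[j]
      ix <- which(abs(xg - at$x[a]) <= rd[j])
      iy <- which(abs(yg - at$y[a]) <= rd[j])
      if (!length(ix) || !length(iy)) next
      dx2 <- (xg[ix] - at$x[a])^2
      dy2 <- (yg[iy] - at$y[a])^2
      occ[ix, iy] <- occ[ix, iy] | (outer(dx2, dy2, "+") <= rd[j]^2)
    }
    areas[s] <- sum(occ) * g * g
  }
  area_profile(zgrid, areas,
               slab_width = slab_width, grid_resolution = grid_resolution,
               n_frames = 1L)
}

#' Mean cross-section profile over trajectory frames
#'
#' Frames are rigid-body superposed (least-squares on the C-alpha trace)
#' onto the first selected frame before slicing, then the per-frame profiles
#' are averaged on a common grid.
#'
#' @param traj a [mol_trajectory()].
#' @param frames indices of frames to use (default: 15 frames regularly
#'   spaced over the final 30 ns).
#' @param align superpose frames on the reference before slicing
#'   (default TRUE).
#' @param ... passed to [cross_section_profile()].
#' @return an [area_profile()] (averaged).
#' @export
mean_cross_section <- function(traj, frames = NULL, align = TRUE, ...) {
  stopifnot(inherits(traj, "mol_trajectory"))
  tt <- trajectory_times(traj)
  if (is.null(frames)) {
    sel <- which(tt >= max(tt) - 30)
    frames <- sel[unique(round(seq(1, length(sel), length.out = min(15, length(sel)))))]
  }
  ref <- traj$frames[[frames[1]]]
  ref_ca <- as.matrix(ref$atoms[ref$atoms$elety == "CA" &
                                !is_lipid_atom(ref$atoms), c("x", "y", "z")])
  profs <- lapply(frames, function(i) {
    fr <- traj$frames[[i]]
    if (align && i != frames[1]) {
      ca <- as.matrix(fr$atoms[fr$atoms$elety == "CA" &
                               !is_lipid_atom(fr$atoms), c("x", "y", "z")])
      fit <- kabsch(ca, ref_ca)
      xyz <- as.matrix(fr$atoms[, c("x", "y", "z")]) %*% fit$rotation
      xyz <- sweep(xyz, 2, fit$translation, "+")
      fr$atoms[, c("x", "y", "z")] <- xyz
    }
    cross_section_profile(fr, ...)
  })
  zlo <- max(vapply(profs, function(p) min(p$z), numeric(1)))
  zhi <- min(vapply(profs, function(p) max(p$z), numeric(1)))
  grid <- profs[[1]]$z[profs[[1]]$z >= zlo - 1e-9 & profs[[1]]$z <= zhi + 1e-9]
  avg <- rowMeans(vapply(profs, function(p)
    stats::approx(p$z, p$area, xout = grid)$y, numeric(length(grid))))
  area_profile(grid, avg, slab_width = profs[[1]]$slab_width,
               grid_resolution = profs[[1]]$grid_resolution,
               n_frames = length(frames))
}

#' Mean area over a z range
#'
#' @param profile an [area_profile()].
#' @param z_lo,z_hi range bounds in Angstrom, inclusive.
#' @return arithmetic mean of A(z) over slabs within the range, Angstrom^2.
#' @export
mean_area_range <- function(profile, z_lo = 0, z_hi = 20) {
  sel <- profile$z >= z_lo & profile$z <= z_hi
  if (!any(sel)) stop("range [", z_lo, ", ", z_hi, "] is outside the grid")
  mean(profile$area[sel])
}

#' Pointwise area difference of two profiles
#'
#' @param profile_a,profile_b [area_profile()]s on identical grids.
#' @return an `area_profile`-shaped object whose `area` field holds
#'   `A_a(z) - A_b(z)` (may be negative).
#' @export
delta_area <- function(profile_a, profile_b) {
  if (length(profile_a$z) != length(profile_b$z) ||
      any(abs(profile_a$z - profile_b$z) > 1e-9))
    stop("area profiles are on different z grids")
  structure(list(z = profile_a$z, area = profile_a$area - profile_b$area,
                 delta = TRUE),
            class = "area_profile")
}

#' Volume enclosed by an area (difference) profile
#'
#' Trapezoidal integral of the profile over a z range.
#'
#' @param delta an [area_profile()] (typically from [delta_area()]).
#' @param z_lo,z_hi integration bounds in Angstrom.
#' @return volume in Angstrom^3.
#' @export
enclosed_volume <- function(delta, z_lo = 0, z_hi = 20) {
  sel <- delta$z >= z_lo & delta$z <= z_hi
  if (sum(sel) < 2L) stop("range [", z_lo, ", ", z_hi, "] has fewer than 2 grid points")
  trapz(delta$z[sel], delta$area[sel])
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Work against the lateral pressure profile
#'
#' `W = integral of deltaA(z) pi(z) dz` over the given range, evaluated by
#' the trapezoidal rule after resampling the pressure profile onto the area
#' grid, and converted from bar Angstrom^3 to kcal/mol
#' (1 bar A^3 = 1.4393e-5 kcal/mol).
#'
#' @param delta area-difference profile (from [delta_area()]), Angstrom^2.
#' @param profile a [lateral_pressure_profile()] (bar).
#' @param z_lo,z_hi integration bounds in Angstrom.
#' @return work in kcal/mol.
#' @export
pressure_work <- function(delta, profile, z_lo = 0, z_hi = 20) {
  sel <- delta$z >= z_lo & delta$z <= z_hi
  if (sum(sel) < 2L) stop("integration range has fewer than 2 grid points")
  z <- delta$z[sel]
  if (min(z) < min(profile$z) - 1e-9 || max(z) > max(profile$z) + 1e-9)
    stop("pressure profile does not cover the integration range [",
         z_lo, ", ", z_hi, "]")
  pz <- stats::approx(profile$z, profile$pi, xout = z)$y
  trapz(z, delta$area[sel] * pz) * BAR_A3_TO_KCAL_MOL
}
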