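# Lateral pressure profile pipeline and bulk membrane property measures.
#
# The lateral pressure at depth z and time t is
#   pi(z,t) = (pxx(z,t) + pyy(z,t))/2 - pzz(z,t)          [bar]
# computed per slab from the diagonal pressure-tensor elements. The profile
# pi(z) is obtained by (1) computing raw pi(z,t), (2) shifting each
# instantaneous profile so that the lipid-phosphorus barycenter z_P(t) maps
# to z = 0 (drift correction), (3) time-averaging from t_min (default 20 ns)
# onwards, and (4) smoothing with a 3-point running mean.

#' Per-slab pressure tensor series
#'
#' @param z slab-center positions in Angstrom (regular, strictly increasing
#'   grid; the engine convention is 100 slabs spanning the box).
#' @param times time points in ns.
#' @param pxx,pyy,pzz numeric matrices (time x slab) of the diagonal
#'   pressure-tensor elements in bar.
#' @param Lz cell heights in Angstrom, one per time point.
#' @param z_P lipid-phosphorus barycenter per time point, in Angstrom
#'   (drift reference; zero means no drift correction).
#' @return object of class `pressure_slab_series`.
#' @export
pressure_slab_series <- function(z, times, pxx, pyy, pzz,
                                 Lz = NULL, z_P = NULL) {
  z <- as.numeric(z); times <- as.numeric(times)
  nt <- length(times); nz <- length(z)
  if (nz < 3L) stop("need at least 3 slabs")
  dz <- diff(z)
  if (any(dz <= 0) || diff(range(dz)) > 1e-6 * mean(dz))
    stop("slab grid must be regular and strictly increasing")
  for (m in list(pxx = pxx, pyy = pyy, pzz = pzz)) {
    if (!is.matrix(m) || nrow(m) != nt || ncol(m) != nz)
      stop("pressure matrices must be time x slab (", nt, " x ", nz, ")")
    if (!all(is.finite(m))) stop("non-finite pressures")
  }
  if (is.null(z_P)) z_P <- numeric(nt)
  if (is.null(Lz)) Lz <- rep(diff(range(z)) + mean(dz), nt)
  if (length(z_P) != nt || length(Lz) != nt)
    stop("Lz and z_P need one value per time point")
  structure(list(z = z, times = times, pxx = pxx, pyy = pyy, pzz = pzz,
                 Lz = as.numeric(Lz), z_P = as.numeric(z_P)),
            class = "pressure_slab_series")
}

#' @export
print.pressure_slab_series <- function(x, ...) {
  cat(sprintf("<pressure_slab_series> %d slabs x %d times, t = %g..%g ns\n",
              length(x$z), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Instantaneous lateral pressure from the diagonal tensor elements
#'
#' @param pxx,pyy,pzz pressures in bar (vectorized).
#' @return `(pxx + pyy)/2 - pzz` in bar.
#' @export
instantaneous_lateral_pressure <- function(pxx, pyy, pzz) {
  (pxx + pyy) / 2 - pzz
}

#' Three-point running mean
#'
#' Interior points are replaced by the mean of themselves and their two
#' neighbours; endpoints by the mean of the two available points. Length is
#' preserved.
#'
#' @param values numeric vector, length >= 1.
#' @return smoothed vector of the same length.
#' @export
smooth3 <- function(values) {
  n <- length(values)
  if (n < 1L) stop("empty input")
  if (n <= 2L) return(rep(mean(values), n))
  out <- values
  out[1] <- mean(values[1:2])
  out[n] <- mean(values[(n - 1):n])
  mid <- 2:(n - 1)
  out[mid] <- (values[mid - 1] + values[mid] + values[mid + 1]) / 3
  out
}

#' Time-averaged, drift-corrected lateral pressure profile
#'
#' @param series a [pressure_slab_series()].
#' @param t_min discard times before this (ns); default 20 ns, allowing the
#'   box to stabilize.
#' @param smooth apply the 3-point running mean (default TRUE).
#' @param drift_mode `"interp"` (linear interpolation of each shifted
#'   instantaneous profile back onto the fixed grid) or `"nearest"`
#'   (nearest-slab shifting).
#' @return object of class `lateral_pressure_profile`: list with `z`
#'   (Angstrom, bilayer-centered), `pi` (bar) and provenance fields.
#' @export
pressure_profile <- function(series, t_min = 20, smooth = TRUE,
                             drift_mode = c("interp", "nearest")) {
  stopifnot(inherits(series, "pressure_slab_series"))
  drift_mode <- match.arg(drift_mode)
  keep <- which(series$times >= t_min)
  if (!length(keep))
    stop("t_min = ", t_min, " ns is beyond the series end (",
         max(series$times), " ns)")
  box <- diff(range(series$z))
  if (any(abs(series$z_P[keep]) > box))
    stop("drift reference exceeds the box; cannot re-center")
  grid <- series$z
  dz <- grid[2] - grid[1]
  acc <- numeric(length(grid))
  cnt <- numeric(length(grid))
  for (i in keep) {
    prof <- instantaneous_lateral_pressure(series$pxx[i, ], series$pyy[i, ],
                                           series$pzz[i, ])
    if (drift_mode == "interp") {
      shifted <- stats::approx(x = grid - series$z_P[i], y = prof,
                               xout = grid, rule = 1)$y
    } else {
      k <- round(series$z_P[i] / dz)
      shifted <- rep(NA_real_, length(grid))
      src <- seq_along(grid) + k
      ok <- src >= 1 & src <= length(grid)
      shifted[ok] <- prof[src[ok]]
    }
    ok <- !is.na(shifted)
    acc[ok] <- acc[ok] + shifted[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  prof <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  ok <- !is.na(prof)
  z <- grid[ok]; prof <- prof[ok]
  if (smooth) prof <- smooth3(prof)
  structure(list(z = z, pi = prof,
                 t_min = t_min, smoothed = smooth,
                 n_times = length(keep), drift_mode = drift_mode),
            class = "lateral_pressure_profile")
}

#' @export
print.lateral_pressure_profile <- function(x, ...) {
  cat(sprintf(
    "<lateral_pressure_profile> %d slabs, z = %.1f..%.1f A, peak |pi| = %.0f bar (%d times averaged%s)\n",
    length(x$z), min(x$z), max(x$z), max(abs(x$pi)), x$n_times,
    if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Bilayer thickness from the phosphorus z distribution
#'
#' Peak-to-peak distance of the pooled z histogram of lipid phosphorus
#' atoms; each leaflet mode is refined by a parabolic fit through the top
#' bin and its neighbours.
#'
#' @param phosphorus_z numeric vector (or list of per-frame vectors, pooled)
#'   of phosphorus z positions in Angstrom.
#' @param bin_width histogram bin width in Angstrom (default 0.5).
#' @param min_separation minimum mode separation accepted as two leaflets
#'   (default 10 Angstrom); a unimodal distribution is rejected.
#' @return thickness in Angstrom.
#' @export
bilayer_thickness <- function(phosphorus_z, bin_width = 0.5,
                              min_separation = 10) {
  zz <- unlist(phosphorus_z, use.names = FALSE)
  if (length(zz) < 4L) stop("too few phosphorus atoms")
  rng <- range(zz)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width - bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(zz, breaks = breaks, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  i1 <- which.max(counts)
  far <- abs(mids - mids[i1]) >= min_separation
  if (!any(far) || max(counts[far]) == 0)
    stop("phosphorus z distribution is unimodal: cannot separate leaflets")
  i2 <- which(far)[which.max(counts[far])]
  refine <- function(i) {
    if (i <= 1L || i >= length(counts)) return(mids[i])
    cl <- counts[i - 1]; cc <- counts[i]; cr <- counts[i + 1]
    den <- cl - 2 * cc + cr
    if (den == 0) return(mids[i])
    mids[i] + 0.5 * bin_width * (cl - cr) / den
  }
  abs(refine(i1) - refine(i2))
}

#' Area per lipid in the presence of an embedded protein
#'
#' @param cell_area lateral box area in Angstrom^2.
#' @param protein_cross_section protein cross-section area to subtract,
#'   Angstrom^2 (0 for a pure bilayer).
#' @param n_lipids_per_leaflet lipid count per leaflet.
#' @return `(cell_area - protein_cross_section) / n` in Angstrom^2.
#' @export
area_per_lipid <- function(cell_area, protein_cross_section,
                           n_lipids_per_leaflet) {
  if (protein_cross_section < 0) stop("protein cross-section must be >= 0")
  if (n_lipids_per_leaflet <= 0) stop("need a positive lipid count")
  if (cell_area <= protein_cross_section)
    stop("free area is non-positive: cell ", cell_area,
         " <= protein ", protein_cross_section)
  (cell_area - protein_cross_section) / n_lipids_per_leaflet
}

#' Acyl-chain order parameter S_CH
#'
#' `S_CH = < 3 cos^2(theta) - 1 > / 2`, theta the angle between each C-H
#' bond vector and the membrane normal (z). 1 = aligned with the normal,
#' -0.5 = perpendicular, 0 = isotropic.
#'
#' @param ch_vectors numeric n x 3 matrix of C-H bond vectors (any nonzero
#'   length; normalized internally).
#' @return scalar order parameter.
#' @export
order_parameter <- function(ch_vectors) {
  v <- as.matrix(ch_vectors)
  if (!nrow(v)) stop("empty vector set")
  nn <- sqrt(rowSums(v^2))
  if (any(nn < 1e-12)) stop("zero-length C-H vector")
  cth <- v[, 3] / nn
  mean((3 * cth^2 - 1) / 2)
}

#' Surface tension from normal and tangential pressures
#'
#' `gamma = Lz (Pz - PT)`, converted from bar * Angstrom to dyn/cm
#' (1 bar A = 0.01 dyn/cm). Positive gamma corresponds to stretching.
#'
#' @param Pz pressure normal to the membrane, bar.
#' @param PT tangential pressure, bar.
#' @param Lz cell height, Angstrom.
#' @return surface tension in dyn/cm.
#' @export
surface_tension_check <- function(Pz, PT, Lz) {
  if (Lz <= 0) stop("cell height must be positive")
  Lz * (Pz - PT) * BAR_A_TO_DYN_CM
}

# -- TSV input/output for pressure series ------------------------------------

#' Write a pressure slab series as documented TSV files
#'
#' Main table: columns `time` (ns), `slab_index` (1-based), `z` (A),
#' `pxx`, `pyy`, `pzz` (bar). Sidecar: `time`, `Lz` (A), `z_P` (A).
#' Both are tab-separated with a header line; `#` lines are comments.
#'
#' @param series a [pressure_slab_series()].
#' @param path main table path.
#' @param sidecar_path sidecar path (default `<path>.box.tsv`).
#' @return `path`, invisibly.
#' @export
write_pressure_tsv <- function(series, path,
                               sidecar_path = paste0(path, ".box.tsv")) {
  stopifnot(inherits(series, "pressure_slab_series"))
  nt <- length(series$times); nz <- length(series$z)
  main <- data.frame(time = rep(series$times, each = nz),
                     slab_index = rep(seq_len(nz), nt),
                     z = rep(series$z, nt),
                     pxx = as.vector(t(series$pxx)),
                     pyy = as.vector(t(series$pyy)),
                     pzz = as.vector(t(series$pzz)))
  utils::write.table(main, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- data.frame(time = series$times, Lz = series$Lz, z_P = series$z_P)
  utils::write.table(side, sidecar_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pressure slab series from TSV files
#'
#' @param path main table path (see [write_pressure_tsv()] for the dialect).
#' @param sidecar_path sidecar path; if the file is absent, Lz is derived
#'   from the grid and z_P is zero.
#' @return a [pressure_slab_series()].
#' @export
read_pressure_tsv <- function(path, sidecar_path = paste0(path, ".box.tsv")) {
  main <- utils::read.delim(path, comment.char = "#")
  needed <- c("time", "slab_index", "z", "pxx", "pyy", "pzz")
  if (!all(needed %in% names(main)))
    stop("pressure TSV must have columns: ", paste(needed, collapse = ", "))
  main <- main[order(main$time, main$slab_index), ]
  times <- sort(unique(main$time))
  nz <- length(unique(main$slab_index))
  if (nrow(main) != nz * length(times))
    stop("ragged pressure table: not every time has every slab")
  z <- main$z[seq_len(nz)]
  shape <- function(col) matrix(main[[col]], nrow = length(times), ncol = nz,
                                byrow = TRUE)
  Lz <- NULL; z_P <- NULL
  if (file.exists(sidecar_path)) {
    side <- utils::read.delim(sidecar_path, comment.char = "#")
    side <- side[match(times, side$time), ]
    Lz <- side$Lz; z_P <- side$z_P
  }
  pressure_slab_series(z, times, shape("pxx"), shape("pyy"), shape("pzz"),
                       Lz = Lz, z_P = z_P)
}
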