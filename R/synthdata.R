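# Synthetic inputs with known ground truth: toy 7-TM receptors with
# Ballesteros-Weinstein numbering, TM6-opening trajectories, head-group
# bilayers, per-slab pressure-tensor series and H-bond scenes. These
# generators encode the geometric and statistical structure the analysis
# operations measure (marker distances, rotation schedules, leaflet
# separation, a known pi(z), the internal-lipid inequalities); they make no
# attempt at force-field realism. Every generator is deterministic under
# the seed carried by the spec.

# BW offset ranges (relative to x.50) spanned by each toy helix. Chosen so
# that residue numbers never collide under the default anchors and so that
# TM6 covers 6.32-6.48 (the steered segment) and TM7 reaches 7.62 (the last
# C-terminal basic position).
TOY_HELIX_RANGES <- list(c(35, 60), c(38, 62), c(35, 60), c(40, 60),
                         c(40, 60), c(30, 55), c(38, 62))
# z of each helix's x.50 anchor; odd helices run N->C toward +z
# (intracellular), even helices toward -z. Values put the 3.50/6.34/7.55
# markers on the intracellular side (z in 4.5-12 A).
TOY_Z50 <- c(4.5, -4.5, 4.5, -4.5, 4.5, -12, 4.5)

#' Generator specification
#'
#' Bundles every knob of the synthetic-data generators with its default.
#' Defaults mirror the study conditions: a 35-degree TM6 opening pulled over
#' 20 ns then relaxed for 70 ns, an initial TM3-TM7 distance of 20 A
#' (inactive), leaflet separation 38.8 A, and TM7 scenario targets 14.7 A
#' (inward) and 23.2 A (outward).
#'
#' @param seed integer seed fixing every stochastic draw.
#' @param n_helix helix count (must be 7).
#' @param bundle_radius radius of the helix-center circle, Angstrom.
#' @param d36,d37 initial marker distances (C-alpha 3.50-6.34 and
#'   3.50-7.55), Angstrom.
#' @param tm6_target TM6 opening target angle, degrees.
#' @param pull_ns,relax_ns steering schedule durations, ns.
#' @param n_frames frames in a generated trajectory.
#' @param tm7_scenario one of `"static"`, `"inward"`, `"outward"`.
#' @param tm7_target final TM3-TM7 distance for the scenario (defaults:
#'   inward 14.7 A, outward 23.2 A, static = `d37`).
#' @param tm7_ramp_ns time over which d37 ramps to its target (default 40).
#' @param noise_sd isotropic positional jitter on trajectory coordinates,
#'   Angstrom.
#' @param with_bilayer append a synthetic bilayer to every frame.
#' @param leaflet_sep leaflet separation (P-to-P), Angstrom.
#' @param lipids_per_leaflet lipid count per leaflet.
#' @param pc_fraction fraction of phosphatidylcholine heads (rest PG);
#'   0.9 emulates the 9:1 POPC:DOPG mixed bilayer.
#' @param lipid_jitter_sd in-plane/z jitter of lipid placement, Angstrom.
#' @param internal_fraction_target fraction of trajectory frames in which
#'   one anionic lipid is placed to satisfy the internal-lipid criterion.
#' @param n_slab,box_Lz pressure grid: slab count and box height (A).
#' @param head_center,head_height,head_width positive (head-group) Gaussian
#'   peaks of the ground-truth pi(z): center +/- (A), height (bar), sd (A).
#' @param interface_center,interface_width negative (interface) peaks;
#'   their common height is set from `pressure_integral`.
#' @param pressure_integral target integral of pi(z) in bar Angstrom
#'   (0 = tensionless; -2000 corresponds to 20 dyn/cm).
#' @param pressure_noise_sd white noise on the tensor elements, bar.
#' @param drift_rate linear leaflet drift, Angstrom/ns.
#' @param n_times,t_max pressure time series: sample count and span (ns).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_helix = 7L, bundle_radius = 12,
                           d36 = 8.5, d37 = 20,
                           tm6_target = 35, pull_ns = 20, relax_ns = 70,
                           n_frames = 12L,
                           tm7_scenario = c("static", "inward", "outward"),
                           tm7_target = NULL, tm7_ramp_ns = 40,
                           noise_sd = 0,
                           with_bilayer = FALSE, leaflet_sep = 38.8,
                           lipids_per_leaflet = 20L, pc_fraction = 1,
                           lipid_jitter_sd = 0.8,
                           internal_fraction_target = 0,
                           n_slab = 100L, box_Lz = 100,
                           head_center = 15, head_height = 400, head_width = 3,
                           interface_center = 8, interface_width = 3,
                           pressure_integral = 0, pressure_noise_sd = 0,
                           drift_rate = 0, n_times = 54L, t_max = 135) {
  tm7_scenario <- match.arg(tm7_scenario)
  if (is.null(tm7_target))
    tm7_target <- switch(tm7_scenario, static = d37, inward = 14.7,
                         outward = 23.2)
  if (n_helix != 7L) stop("the toy receptor is a 7-helix bundle")
  if (d36 <= 0 || d37 <= 0 || leaflet_sep <= 0 || bundle_radius <= 0)
    stop("lengths must be positive")
  if (pc_fraction < 0 || pc_fraction > 1) stop("pc_fraction must be in [0, 1]")
  spec <- as.list(environment())
  structure(spec, class = "generator_spec")
}

#' Ideal alpha-helix C-alpha trace
#'
#' C-alpha i (0-based) at
#' `(radius cos(i twist), radius sin(i twist), i rise)`.
#'
#' @param n_res residue count (>= 2).
#' @param rise rise per residue, Angstrom (default 1.5).
#' @param twist twist per residue, degrees (default 100, i.e. 3.6
#'   residues/turn).
#' @param radius helix radius, Angstrom (default 2.3).
#' @return n_res x 3 coordinate matrix.
#' @export
ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3) {
  if (n_res < 2L) stop("need at least 2 residues")
  i <- seq_len(n_res) - 1
  ang <- i * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = i * rise)
}

# Residue numbers covered by toy helix h under a scheme.
toy_helix_residues <- function(scheme, h) {
  rng <- TOY_HELIX_RANGES[[h]]
  scheme$anchors[h] + (rng[1]:rng[2] - 50L)
}

# Build one toy helix as an atom table (CA only; side-chain donors are
# added separately for the C-terminal basic positions).
build_toy_helix <- function(scheme, h, bundle_radius) {
  res <- toy_helix_residues(scheme, h)
  n <- length(res)
  dir <- if (h %% 2L == 1L) 1 else -1
  hel <- ideal_helix(n)
  phi <- (h - 1) * 2 * pi / 7
  cx <- bundle_radius * cos(phi)
  cy <- bundle_radius * sin(phi)
  anchor_i <- which(res == scheme$anchors[h]) - 1L
  z <- TOY_Z50[h] + dir * (seq_len(n) - 1 - anchor_i) * 1.5
  data.frame(eleno = 0L, elety = "CA", resid = "ALA", chain = "A",
             resno = res, x = cx + hel[, 1], y = cy + hel[, 2], z = z,
             helix = h, stringsAsFactors = FALSE)
}

# Translate one helix in the xy plane so that the distance between a fixed
# point p_ref and the helix's marker atom reaches `target`.
solve_marker_placement <- function(atoms, helix, marker_resno, p_ref, target) {
  sel <- atoms$helix == helix
  mk <- atoms[sel & atoms$resno == marker_resno & atoms$elety == "CA", ]
  q <- c(mk$x, mk$y, mk$z)
  dz <- q[3] - p_ref[3]
  if (target^2 < dz^2)
    stop("infeasible geometry: target distance ", target,
         " A is below the fixed z offset ", round(abs(dz), 2), " A")
  e <- q[1:2] - p_ref[1:2]
  dxy <- sqrt(sum(e^2))
  e <- if (dxy < 1e-9) c(1, 0) else e / dxy
  s <- sqrt(target^2 - dz^2) - dxy
  atoms$x[sel] <- atoms$x[sel] + s * e[1]
  atoms$y[sel] <- atoms$y[sel] + s * e[2]
  atoms
}

# Side-chain donor pseudo-atoms (N + H pointing radially outward) for the
# C-terminal basic positions 7.58, 7.59, 7.61 (Lys) and 7.62 (Arg).
add_cterm_sidechains <- function(atoms, scheme) {
  basics <- data.frame(bw = c("7.58", "7.59", "7.61", "7.62"),
                       resid = c("LYS", "LYS", "LYS", "ARG"),
                       natom = c("NZ", "NZ", "NZ", "NH1"),
                       hatom = c("HZ1", "HZ1", "HZ1", "HH11"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(basics))) {
    resno <- bw_residue(scheme, basics$bw[i])
    ca <- atoms[atoms$resno == resno & atoms$elety == "CA", ]
    if (!nrow(ca)) next
    atoms$resid[atoms$resno == resno] <- basics$resid[i]
    u <- c(ca$x, ca$y)
    u <- if (sqrt(sum(u^2)) < 1e-9) c(1, 0) else u / sqrt(sum(u^2))
    np <- c(ca$x + 2 * u[1], ca$y + 2 * u[2], ca$z)
    hp <- np + c(u, 0) * 1.0
    atoms <- rbind(atoms,
      data.frame(eleno = 0L, elety = c(basics$natom[i], basics$hatom[i]),
                 resid = basics$resid[i], chain = "A", resno = resno,
                 x = c(np[1], hp[1]), y = c(np[2], hp[2]),
                 z = c(np[3], hp[3]), helix = 7, stringsAsFactors = FALSE))
  }
  atoms[order(atoms$resno, atoms$elety != "CA"), ]
}

#' Toy 7-TM receptor frame
#'
#' Seven ideal helices on a circle, alternating up/down, numbered per the
#' BW scheme, with helices 6 and 7 placed so that the marker distances
#' (C-alpha 3.50-6.34 and 3.50-7.55) hit the spec's `d36` and `d37` exactly.
#' The four C-terminal basic positions carry side-chain N-H donor
#' pseudo-atoms for the H-bond detector.
#'
#' @param spec a [generator_spec()].
#' @param scheme a [bw_scheme()].
#' @return a [mol_frame()] with a `helix` column in the atom table.
#' @export
toy_receptor <- function(spec = generator_spec(), scheme = bw_scheme()) {
  stopifnot(inherits(spec, "generator_spec"))
  atoms <- do.call(rbind, lapply(1:7, build_toy_helix,
                                 scheme = scheme,
                                 bundle_radius = spec$bundle_radius))
  p3 <- {
    mk <- atoms[atoms$resno == bw_residue(scheme, "3.50") & atoms$elety == "CA", ]
    c(mk$x, mk$y, mk$z)
  }
  atoms <- solve_marker_placement(atoms, 6, bw_residue(scheme, "6.34"),
                                  p3, spec$d36)
  atoms <- solve_marker_placement(atoms, 7, bw_residue(scheme, "7.55"),
                                  p3, spec$d37)
  atoms <- add_cterm_sidechains(atoms, scheme)
  atoms$eleno <- seq_len(nrow(atoms))
  mol_frame(atoms, time = 0)
}

# Rotation setup for the TM6 opening: axis perpendicular to the TM6 helix
# axis and to the outward radial direction, signed so that a positive angle
# increases the TM3-TM6 marker distance; pivot at the 6.48 C-alpha.
tm6_rotation_setup <- function(frame, scheme) {
  seg <- select_bw_segment(frame, scheme, "6.32", "6.48")
  ax <- helix_axis(seg)
  pivot <- as.numeric(select_calpha(frame, bw_residue(scheme, "6.48")))
  center <- colMeans(seg)
  radial <- c(center[1], center[2], 0)
  radial <- radial / vnorm(radial)
  axis <- vcross(ax, radial)
  axis <- axis / vnorm(axis)
  p3 <- as.numeric(select_calpha(frame, bw_residue(scheme, "3.50")))
  m6 <- as.numeric(select_calpha(frame, bw_residue(scheme, "6.34")))
  d0 <- vnorm(m6 - p3)
  probe <- apply_rotation(axis_angle_quaternion(5, axis), m6 - pivot) + pivot
  if (vnorm(probe - p3) < d0) axis <- -axis
  list(axis = axis, pivot = pivot)
}

rotate_rows <- function(xyz, q, pivot) {
  t(apply(xyz, 1, function(p) apply_rotation(q, p - pivot) + pivot))
}

#' Synthetic TM6-opening trajectory
#'
#' The TM6 segment 6.32-6.48 is rigidly rotated by a scheduled angle
#' (linear ramp over the pull phase, then held), TM7 is translated so that
#' the TM3-TM7 distance follows the scenario's linear ramp to its target,
#' and optional Gaussian jitter is added. The programmed schedule is stored
#' as the `ground_truth` attribute (per-frame theta and d37) and is
#' recoverable by the quaternion and distance analyses.
#'
#' @param spec a [generator_spec()].
#' @param scheme a [bw_scheme()].
#' @return a [mol_trajectory()] with attribute `ground_truth`.
#' @export
opening_trajectory <- function(spec = generator_spec(), scheme = bw_scheme()) {
  stopifnot(inherits(spec, "generator_spec"))
  base <- toy_receptor(spec, scheme)
  setup <- if (spec$tm6_target != 0) tm6_rotation_setup(base, scheme) else NULL
  total <- spec$pull_ns + spec$relax_ns
  dt <- total / spec$n_frames
  times <- (seq_len(spec$n_frames) - 1) * dt
  theta <- spec$tm6_target * pmin(times / spec$pull_ns, 1)
  d37 <- spec$d37 + (spec$tm7_target - spec$d37) *
    pmin(times / spec$tm7_ramp_ns, 1)
  seg_res <- seq(bw_residue(scheme, "6.32"), bw_residue(scheme, "6.48"))
  p3 <- as.numeric(select_calpha(base, bw_residue(scheme, "3.50")))
  m7 <- bw_residue(scheme, "7.55")
  internal_in_frame <- rep(FALSE, spec$n_frames)
  if (spec$with_bilayer && spec$internal_fraction_target > 0) {
    k <- round(spec$internal_fraction_target * spec$n_frames)
    internal_in_frame[seq_len(k)] <- TRUE
  }
  frames <- vector("list", spec$n_frames)
  with_seed(spec$seed, {
    lipids <- if (spec$with_bilayer)
      build_bilayer_atoms(spec, scheme, base) else NULL
    for (i in seq_len(spec$n_frames)) {
      at <- base$atoms
      if (!is.null(setup) && theta[i] > 0) {
        q <- axis_angle_quaternion(theta[i], setup$axis)
        sel <- at$resno %in% seg_res & at$helix == 6
        at[sel, c("x", "y", "z")] <-
          rotate_rows(as.matrix(at[sel, c("x", "y", "z")]), q, setup$pivot)
      }
      at <- solve_marker_placement(at, 7, m7, p3, d37[i])
      if (!is.null(lipids)) {
        li <- lipids
        ir <- attr(lipids, "internal_resno")
        if (!is.na(ir)) {
          sel <- li$resno == ir
          if (internal_in_frame[i]) {
            # re-center the programmed lipid on the midpoint of the current
            # marker positions, so the criterion holds whatever TM7 does
            r350 <- bw_residue(scheme, "3.50")
            r756 <- bw_residue(scheme, "7.56")
            mk <- at[at$elety == "CA" & at$resno %in% c(r350, r756), ]
            mid <- c(mean(mk$x), mean(mk$y), mean(mk$z))
            psel <- which(sel & li$elety == "P")
            shift <- mid - c(li$x[psel], li$y[psel], li$z[psel])
            li$x[sel] <- li$x[sel] + shift[1]
            li$y[sel] <- li$y[sel] + shift[2]
            li$z[sel] <- li$z[sel] + shift[3]
          } else {
            # park the programmed internal lipid far outside the cavity
            li$x[sel] <- li$x[sel] + 60
          }
        }
        li$helix <- NA_real_
        at <- rbind(at, li)
      }
      if (spec$noise_sd > 0) {
        at$x <- at$x + stats::rnorm(nrow(at), 0, spec$noise_sd)
        at$y <- at$y + stats::rnorm(nrow(at), 0, spec$noise_sd)
        at$z <- at$z + stats::rnorm(nrow(at), 0, spec$noise_sd)
      }
      at$eleno <- seq_len(nrow(at))
      frames[[i]] <- mol_frame(at, time = times[i])
    }
  })
  traj <- mol_trajectory(frames,
                         condition = paste0("synthetic/", spec$tm7_scenario),
                         replica = spec$seed)
  attr(traj, "ground_truth") <- list(times = times, theta = theta, d37 = d37,
                                     internal_in_frame = internal_in_frame)
  traj
}

# Lipid head-group atom table for one bilayer (P + two ester oxygens per
# lipid). Called inside a with_seed() scope.
build_bilayer_atoms <- function(spec, scheme, protein_frame) {
  n <- spec$lipids_per_leaflet
  n_pc <- round(spec$pc_fraction * n)
  resnames <- c(rep("POPC", n_pc), rep("DOPG", n - n_pc))
  # ring placement outside the protein footprint
  place_leaflet <- function(zsign, resno0) {
    rr <- spec$bundle_radius + 8 + 4 * (seq_len(n) %% 3)
    aa <- 2 * pi * seq_len(n) / n + 0.3 * zsign
    x <- rr * cos(aa) + stats::rnorm(n, 0, spec$lipid_jitter_sd)
    y <- rr * sin(aa) + stats::rnorm(n, 0, spec$lipid_jitter_sd)
    z <- zsign * spec$leaflet_sep / 2 + stats::rnorm(n, 0, spec$lipid_jitter_sd)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(eleno = 0L, elety = c("P", "O11", "O12"),
                 resid = resnames[i], chain = "L",
                 resno = resno0 + i,
                 x = x[i] + c(0, 1.5, -1.5), y = y[i] + c(0, 0.5, -0.5),
                 z = z[i] + c(0, 0.8, 0.8),
                 helix = NA_real_, stringsAsFactors = FALSE)
    }))
  }
  top <- place_leaflet(+1, 1000L)    # intracellular
  bot <- place_leaflet(-1, 2000L)
  out <- rbind(top, bot)
  internal_resno <- NA_integer_
  if (spec$internal_fraction_target > 0 || isTRUE(spec$with_bilayer)) {
    # move one intracellular PG (or the first lipid) head to the midpoint of
    # the 3.50-7.56 markers so it satisfies the internal criterion
    if (spec$internal_fraction_target > 0) {
      mk <- select_calpha(protein_frame, c(bw_residue(scheme, "3.50"),
                                           bw_residue(scheme, "7.56")))
      mid <- colMeans(mk)
      pg <- which(out$resno >= 1000L & out$resno < 2000L &
                    out$resid == "DOPG" & out$elety == "P")
      cand <- if (length(pg)) pg[1] else which(out$resno == 1001L &
                                                 out$elety == "P")
      internal_resno <- out$resno[cand]
      sel <- out$resno == internal_resno
      shift <- c(mid[1] - out$x[cand], mid[2] - out$y[cand],
                 mid[3] - out$z[cand])
      out$x[sel] <- out$x[sel] + shift[1]
      out$y[sel] <- out$y[sel] + shift[2]
      out$z[sel] <- out$z[sel] + shift[3]
    }
  }
  attr(out, "internal_resno") <- internal_resno
  out
}

#' Synthetic bilayer appended to a frame
#'
#' Two leaflets of head-group pseudo-atoms (P plus two oxygens per lipid) at
#' plus/minus half the leaflet separation with Gaussian jitter, head types
#' assigned per the PC fraction. With `internal = TRUE` one
#' intracellular-leaflet anionic lipid is placed at the midpoint of the
#' 3.50-7.56 markers, which satisfies all four internal-lipid inequalities.
#'
#' @param spec a [generator_spec()].
#' @param frame protein [mol_frame()] to append to (default: the spec's toy
#'   receptor).
#' @param scheme a [bw_scheme()].
#' @param internal place the programmed internal lipid (default per
#'   `spec$internal_fraction_target > 0`).
#' @return a [mol_frame()] with lipid records appended.
#' @export
synthetic_bilayer <- function(spec = generator_spec(), frame = NULL,
                              scheme = bw_scheme(),
                              internal = spec$internal_fraction_target > 0) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(frame)) frame <- toy_receptor(spec, scheme)
  spec$internal_fraction_target <- if (internal) 1 else 0
  lip <- with_seed(spec$seed, build_bilayer_atoms(spec, scheme, frame))
  at <- frame$atoms
  if (is.null(at$helix)) at$helix <- NA_real_
  attr_res <- attr(lip, "internal_resno")
  at <- rbind(at, lip)
  at$eleno <- seq_len(nrow(at))
  out <- mol_frame(at, time = frame$time, box = frame$box)
  attr(out, "internal_resno") <- attr_res
  out
}

#' Ground-truth lateral pressure function of a spec
#'
#' Sum of four Gaussians: a symmetric positive pair at the head-group
#' positions and a symmetric negative pair at the polar-apolar interface,
#' the negative height chosen so that the profile integrates to
#' `spec$pressure_integral` (bar Angstrom).
#'
#' @param spec a [generator_spec()].
#' @return function of z (Angstrom) returning pi(z) in bar.
#' @export
true_pressure_profile <- function(spec) {
  hh <- spec$head_height; hc <- spec$head_center; hw <- spec$head_width
  ic <- spec$interface_center; iw <- spec$interface_width
  ih <- (spec$pressure_integral / sqrt(2 * pi) - 2 * hh * hw) / (2 * iw)
  force(ih)
  function(z) {
    hh * exp(-(z - hc)^2 / (2 * hw^2)) + hh * exp(-(z + hc)^2 / (2 * hw^2)) +
      ih * exp(-(z - ic)^2 / (2 * iw^2)) + ih * exp(-(z + ic)^2 / (2 * iw^2))
  }
}

#' Synthetic per-slab pressure tensor series
#'
#' Builds tensors with `pzz` at a 1 bar baseline and
#' `pxx = pyy = pzz + pi(z - drift(t)) + noise`, where pi is the spec's
#' ground-truth profile; the leaflet drift translates the profile and the
#' recorded phosphorus barycenter together, so the drift correction in
#' [pressure_profile()] can undo it.
#'
#' @param spec a [generator_spec()].
#' @return a [pressure_slab_series()] with attributes `pi_true` (ground
#'   truth evaluated on the slab grid) and `spec`.
#' @export
synthetic_pressure_series <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$head_center + 3 * spec$head_width > spec$box_Lz / 2)
    stop("pressure peaks exceed the box")
  nz <- spec$n_slab
  dz <- spec$box_Lz / nz
  z <- (seq_len(nz) - 0.5) * dz - spec$box_Lz / 2
  times <- seq_len(spec$n_times) * (spec$t_max / spec$n_times)
  pi_fun <- true_pressure_profile(spec)
  z_P <- spec$drift_rate * times
  pzz <- matrix(1, length(times), nz)
  pxx <- matrix(NA_real_, length(times), nz)
  with_seed(spec$seed, {
    for (i in seq_along(times)) {
      prof <- pi_fun(z - z_P[i])
      noise <- if (spec$pressure_noise_sd > 0)
        stats::rnorm(nz, 0, spec$pressure_noise_sd) else 0
      pxx[i, ] <- pzz[i, ] + prof + noise
    }
  })
  out <- pressure_slab_series(z, times, pxx, pxx, pzz,
                              Lz = rep(spec$box_Lz, length(times)), z_P = z_P)
  attr(out, "pi_true") <- pi_fun(z)
  attr(out, "spec") <- spec
  out
}

#' Constructed H-bond scene
#'
#' Donor at the origin, hydrogen 1.0 A along x, acceptor at the requested
#' donor-acceptor distance and donor-centered angle (in the xy plane).
#'
#' @param distance donor-acceptor distance, Angstrom (> 1.2).
#' @param angle donor-hydrogen / donor-acceptor angle, degrees, in
#'   \[0, 180\].
#' @return an [hbond_geometry()].
#' @export
hbond_scene <- function(distance, angle) {
  if (distance <= 1.2) stop("donor-acceptor distance must exceed 1.2 A")
  if (angle < 0 || angle > 180) stop("angle must be in [0, 180] degrees")
  a <- angle * pi / 180
  hbond_geometry(donor = c(0, 0, 0), hydrogen = c(1, 0, 0),
                 acceptor = distance * c(cos(a), sin(a), 0))
}

#' Place a conforming (or near-miss) lipid contact at a C-terminal position
#'
#' Appends a single-headed lipid whose oxygen acceptor sits at the given
#' distance and angle from the side-chain donor of the given BW position,
#' in the plane of the donor's N-H bond.
#'
#' @param frame a [mol_frame()] containing the toy receptor.
#' @param scheme a [bw_scheme()].
#' @param position BW label of the basic position (e.g. "7.58").
#' @param distance donor-acceptor distance, Angstrom.
#' @param angle donor-hydrogen / donor-acceptor angle, degrees.
#' @param resid lipid residue name (default "DOPG").
#' @return the frame with one lipid appended.
#' @export
add_contact_lipid <- function(frame, scheme, position, distance, angle,
                              resid = "DOPG") {
  at <- frame$atoms
  resno <- bw_residue(scheme, position)
  res <- at[at$resno == resno & !is_lipid_atom(at), , drop = FALSE]
  don <- res[res$elety %in% unlist(DONOR_ATOMS, use.names = FALSE), ,
             drop = FALSE]
  if (!nrow(don)) stop("BW ", position, " has no side-chain donor atom")
  d <- as.numeric(don[1, c("x", "y", "z")])
  hyd <- res[grepl("^H", res$elety), , drop = FALSE]
  hd <- sqrt((hyd$x - d[1])^2 + (hyd$y - d[2])^2 + (hyd$z - d[3])^2)
  h <- as.numeric(hyd[which.min(hd), c("x", "y", "z")])
  u <- (h - d) / vnorm(h - d)
  # perpendicular in-plane direction for the angular offset
  w <- vcross(u, c(0, 0, 1))
  if (vnorm(w) < 1e-9) w <- vcross(u, c(1, 0, 0))
  w <- w / vnorm(w)
  a <- angle * pi / 180
  acc <- d + distance * (cos(a) * u + sin(a) * w)
  new_resno <- max(at$resno) + 1L
  extra <- data.frame(eleno = 0L, elety = c("O11", "P"),
                      resid = resid, chain = "L", resno = new_resno,
                      x = c(acc[1], acc[1] + 2), y = c(acc[2], acc[2]),
                      z = c(acc[3], acc[3]), stringsAsFactors = FALSE)
  if (!is.null(at$helix)) extra$helix <- NA_real_
  at <- rbind(at, extra)
  at$eleno <- seq_len(nrow(at))
  mol_frame(at, time = frame$time, box = frame$box)
}
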