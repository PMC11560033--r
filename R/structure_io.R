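# Carriers for coordinate data and the multi-model PDB reader/writer.
#
# A mol_frame holds one snapshot as a flat atom table (PDB-like columns);
# a mol_trajectory is a time-ordered list of frames sharing one atom roster.
# Coordinate convention throughout the package: z is the membrane normal,
# the bilayer center is at z = 0 and the intracellular side is at positive z.

LIPID_RESNAMES <- c("POPC", "DOPC", "POPG", "DOPG")

#' Construct a molecular frame
#'
#' @param atoms data.frame with columns `eleno` (atom serial), `elety`
#'   (atom name), `resid` (residue name), `chain`, `resno` (residue sequence
#'   number), `x`, `y`, `z` (Angstrom).
#' @param time frame time in ns.
#' @param box optional numeric length-3 box edges (Lx, Ly, Lz) in Angstrom.
#' @return object of class `mol_frame`.
#' @export
mol_frame <- function(atoms, time = 0, box = NULL) {
  needed <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (!is.null(box)) {
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive edge lengths (Lx, Ly, Lz)")
  }
  structure(list(atoms = atoms, time = as.numeric(time), box = box),
            class = "mol_frame")
}

#' @export
print.mol_frame <- function(x, ...) {
  np <- sum(!is_lipid_atom(x$atoms))
  nl <- sum(is_lipid_atom(x$atoms))
  cat(sprintf("<mol_frame> t = %g ns, %d atoms (%d protein, %d lipid)\n",
              x$time, nrow(x$atoms), np, nl))
  invisible(x)
}

is_lipid_atom <- function(atoms) atoms$resid %in% LIPID_RESNAMES

#' Construct a trajectory from frames
#'
#' @param frames list of [mol_frame()] objects with strictly increasing times
#'   and identical atom rosters.
#' @param condition free-form condition label (e.g. bilayer and tension).
#' @param replica replica identifier.
#' @return object of class `mol_trajectory`.
#' @export
mol_trajectory <- function(frames, condition = NA_character_, replica = NA) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  ref <- frames[[1L]]$atoms
  for (i in seq_along(frames)[-1L]) {
    a <- frames[[i]]$atoms
    if (nrow(a) != nrow(ref) ||
        !identical(paste(a$elety, a$resid, a$chain, a$resno),
                   paste(ref$elety, ref$resid, ref$chain, ref$resno)))
      stop("atom roster of frame ", i, " differs from frame 1")
  }
  structure(list(frames = frames, condition = condition, replica = replica),
            class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  tt <- trajectory_times(x)
  cat(sprintf("<mol_trajectory> %d frames, t = %g..%g ns, %d atoms",
              length(x$frames), min(tt), max(tt), nrow(x$frames[[1L]]$atoms)))
  if (!is.na(x$condition)) cat(", condition:", x$condition)
  cat("\n")
  invisible(x)
}

#' @export
length.mol_trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory (ns)
#' @param traj a [mol_trajectory()].
#' @export
trajectory_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}

# -- multi-model PDB ---------------------------------------------------------

parse_pdb_atom <- function(line, lineno) {
  # PDB fixed columns: serial 7-11, name 13-16, resName 18-20(21), chain 22,
  # resSeq 23-26, x 31-38, y 39-46, z 47-54
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz))
    stop("unparseable coordinate field at line ", lineno, ": ", line)
  list(eleno = suppressWarnings(as.integer(substr(line, 7, 11))),
       elety = trimws(substr(line, 13, 16)),
       resid = trimws(substr(line, 18, 21)),
       chain = trimws(substr(line, 22, 22)),
       resno = suppressWarnings(as.integer(substr(line, 23, 26))),
       x = xyz[1], y = xyz[2], z = xyz[3])
}

#' Read a multi-model PDB file as a trajectory
#'
#' Reads standard MODEL/ENDMDL-delimited coordinate files (ATOM and HETATM
#' records). Every model must carry the same atom roster; a mismatch is
#' reported with the offending model number. A file without MODEL records is
#' read as a single frame.
#'
#' @param path file path.
#' @param dt_ns frame spacing in ns used to assign times 0, dt, 2 dt, ...;
#'   the default 7.5 ns matches 12 snapshots over a 90 ns window.
#' @param condition,replica trajectory metadata, see [mol_trajectory()].
#' @return a [mol_trajectory()].
#' @export
load_multimodel_pdb <- function(path, dt_ns = 7.5, condition = NA_character_,
                                replica = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rectype <- substr(lines, 1, 6)
  is_atom <- rectype %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  # assign a model index to every line; files without MODEL records are model 1
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_idx <- which(is_atom)
  if (!length(atom_idx)) stop("no ATOM/HETATM records in ", path)
  mid <- model_id[atom_idx]
  mid[mid == 0L] <- 1L
  models <- split(atom_idx, mid)

  frames <- vector("list", length(models))
  ref_roster <- NULL
  for (m in seq_along(models)) {
    idx <- models[[m]]
    recs <- lapply(idx, function(i) parse_pdb_atom(lines[i], i))
    atoms <- data.frame(
      eleno = vapply(recs, `[[`, integer(1), "eleno"),
      elety = vapply(recs, `[[`, character(1), "elety"),
      resid = vapply(recs, `[[`, character(1), "resid"),
      chain = vapply(recs, `[[`, character(1), "chain"),
      resno = vapply(recs, `[[`, integer(1), "resno"),
      x = vapply(recs, `[[`, numeric(1), "x"),
      y = vapply(recs, `[[`, numeric(1), "y"),
      z = vapply(recs, `[[`, numeric(1), "z"),
      stringsAsFactors = FALSE)
    roster <- paste(atoms$elety, atoms$resid, atoms$chain, atoms$resno)
    if (is.null(ref_roster)) {
      ref_roster <- roster
    } else if (!identical(roster, ref_roster)) {
      stop("inconsistent atom roster in model ", m, " of ", path,
           " (", length(roster), " atoms vs ", length(ref_roster),
           " in model 1)")
    }
    frames[[m]] <- mol_frame(atoms, time = (m - 1) * dt_ns)
  }
  mol_trajectory(frames, condition = condition, replica = replica)
}

format_pdb_atom <- function(a) {
  name <- a$elety
  # atom names of <= 3 characters start in column 14 by convention
  name <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          a$eleno %% 100000L, name, a$resid, a$chain, a$resno, a$x, a$y, a$z)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the format's 0.001 Angstrom precision; reloading
#' with [load_multimodel_pdb()] round-trips to that precision.
#'
#' @param traj a [mol_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "mol_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    atoms <- traj$frames[[m]]$atoms
    for (i in seq_len(nrow(atoms))) writeLines(format_pdb_atom(atoms[i, ]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract ordered C-alpha coordinates for given residues
#'
#' @param frame a [mol_frame()].
#' @param residues integer residue sequence numbers; coordinates are returned
#'   in this order.
#' @return numeric matrix (length(residues) x 3) of xyz in Angstrom.
#' @export
select_calpha <- function(frame, residues) {
  stopifnot(inherits(frame, "mol_frame"))
  at <- frame$atoms
  ca <- at[at$elety == "CA" & !is_lipid_atom(at), , drop = FALSE]
  out <- matrix(NA_real_, length(residues), 3L,
                dimnames = list(residues, c("x", "y", "z")))
  for (i in seq_along(residues)) {
    hit <- which(ca$resno == residues[i])
    if (!length(hit)) {
      if (residues[i] %in% at$resno)
        stop("residue ", residues[i], " has no CA atom")
      stop("residue ", residues[i], " absent from frame")
    }
    if (length(hit) > 1L)
      stop("residue ", residues[i], " has multiple CA atoms")
    out[i, ] <- as.numeric(ca[hit, c("x", "y", "z")])
  }
  out
}

#' C-alpha coordinates for a BW segment
#'
#' Convenience wrapper resolving an inclusive BW range, e.g. 6.32-6.48, to
#' residue numbers and extracting the C-alpha trace.
#'
#' @param frame a [mol_frame()].
#' @param scheme a [bw_scheme()].
#' @param from,to BW labels bounding the segment (same helix).
#' @return coordinate matrix as from [select_calpha()].
#' @export
select_bw_segment <- function(frame, scheme, from, to) {
  r1 <- bw_residue(scheme, from)
  r2 <- bw_residue(scheme, to)
  if (r2 < r1) stop("segment end precedes start")
  select_calpha(frame, seq(r1, r2))
}

#' Leaflet assignment of lipid phosphorus atoms
#'
#' @param frame a [mol_frame()].
#' @param z_center bilayer center (Angstrom); atoms with z above it are
#'   assigned to the intracellular leaflet per the package convention.
#' @return data.frame of lipid P atoms with columns `resno`, `resid`, `z`,
#'   `leaflet` ("intracellular"/"extracellular").
#' @export
lipid_phosphorus <- function(frame, z_center = 0) {
  at <- frame$atoms
  p <- at[is_lipid_atom(at) & at$elety == "P", , drop = FALSE]
  data.frame(resno = p$resno, resid = p$resid,
             x = p$x, y = p$y, z = p$z,
             leaflet = ifelse(p$z > z_center, "intracellular", "extracellular"),
             stringsAsFactors = FALSE)
}
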