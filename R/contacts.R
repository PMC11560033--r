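# Hydrogen-bond detection between lipid head groups and the receptor
# C-terminus, and the internal-lipid criterion.
#
# H-bond rule (heavy-atom convention of the source analysis tooling):
# donor-acceptor distance <= 3.5 A and donor-hydrogen / donor-acceptor
# angle <= 30 degrees. A lipid in the intracellular leaflet is "internal"
# when its phosphorus P satisfies all four strict inequalities
#   d(P, CA 3.50) < 15,  d(P, CA 7.56) < 12,
#   d(P, CA 3.50) < d(CA 3.50, CA 7.56),  d(P, CA 7.56) < d(CA 3.50, CA 7.56).

#' Hydrogen-bond geometry
#'
#' @param donor,hydrogen,acceptor length-3 coordinates in Angstrom. The
#'   hydrogen must be covalently attached to the donor (within 1.2 A).
#' @return object of class `hbond_geometry`.
#' @export
hbond_geometry <- function(donor, hydrogen, acceptor) {
  if (vnorm(hydrogen - donor) > 1.2)
    stop("hydrogen is not attached to the donor (> 1.2 A)")
  structure(list(donor = as.numeric(donor), hydrogen = as.numeric(hydrogen),
                 acceptor = as.numeric(acceptor)),
            class = "hbond_geometry")
}

#' Hydrogen-bond test
#'
#' @param geom an [hbond_geometry()].
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff cutoff on the angle between the donor-to-hydrogen and
#'   donor-to-acceptor directions, degrees (default 30).
#' @return logical: TRUE iff both cutoffs are satisfied (boundary values
#'   included).
#' @export
is_hbond <- function(geom, dist_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(inherits(geom, "hbond_geometry"))
  da <- geom$acceptor - geom$donor
  dh <- geom$hydrogen - geom$donor
  d <- vnorm(da)
  if (d > dist_cutoff) return(FALSE)
  cosang <- sum(da * dh) / (d * vnorm(dh))
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  ang <= angle_cutoff
}

# Side-chain donor nitrogen atom names by residue type.
DONOR_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

#' H-bond counts between lipid heads and the C-terminal basic positions
#'
#' Counts donor-acceptor atom pairs satisfying [is_hbond()] between the
#' side-chain N-H groups of the basic residues at BW 7.58, 7.59, 7.61 and
#' 7.62 and lipid head-group oxygen acceptors. A position whose side-chain
#' donor atoms are absent is skipped with a warning.
#'
#' @param frame a [mol_frame()].
#' @param scheme a [bw_scheme()].
#' @param positions BW labels of the C-terminal positions (default the four
#'   basic positions above).
#' @param acceptor_pattern regular expression selecting lipid acceptor atom
#'   names (default: oxygens).
#' @param dist_cutoff,angle_cutoff cutoffs passed to [is_hbond()].
#' @return named integer vector of per-position counts plus a `total`
#'   attribute-free sum as the last element.
#' @export
cterm_hbond_counts <- function(frame, scheme,
                               positions = c("7.58", "7.59", "7.61", "7.62"),
                               acceptor_pattern = "^O",
                               dist_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(inherits(frame, "mol_frame"))
  at <- frame$atoms
  lip <- at[is_lipid_atom(at) & grepl(acceptor_pattern, at$elety), ,
            drop = FALSE]
  counts <- stats::setNames(integer(length(positions)), positions)
  if (!nrow(lip)) return(c(counts, total = 0L))
  prot <- at[!is_lipid_atom(at), , drop = FALSE]
  acc <- as.matrix(lip[, c("x", "y", "z")])
  for (p in positions) {
    resno <- bw_residue(scheme, p)
    res <- prot[prot$resno == resno, , drop = FALSE]
    donor_names <- unlist(DONOR_ATOMS[unique(res$resid)], use.names = FALSE)
    don <- res[res$elety %in% donor_names, , drop = FALSE]
    if (!nrow(don)) {
      warning("no side-chain donor atoms for BW ", p, " (residue ", resno,
              "); position skipped")
      next
    }
    hyd <- res[grepl("^[0-9]*H", res$elety), , drop = FALSE]
    n <- 0L
    for (di in seq_len(nrow(don))) {
      d <- as.numeric(don[di, c("x", "y", "z")])
      hd <- sqrt((hyd$x - d[1])^2 + (hyd$y - d[2])^2 + (hyd$z - d[3])^2)
      hs <- hyd[hd <= 1.2, , drop = FALSE]
      if (!nrow(hs)) next
      da <- sqrt((acc[, 1] - d[1])^2 + (acc[, 2] - d[2])^2 + (acc[, 3] - d[3])^2)
      for (ai in which(da <= dist_cutoff)) {
        for (hi in seq_len(nrow(hs))) {
          g <- hbond_geometry(d, as.numeric(hs[hi, c("x", "y", "z")]),
                              acc[ai, ])
          if (is_hbond(g, dist_cutoff, angle_cutoff)) n <- n + 1L
        }
      }
    }
    counts[p] <- n
  }
  c(counts, total = sum(counts))
}

#' Internal-lipid flags for intracellular-leaflet lipids
#'
#' @param frame a [mol_frame()].
#' @param scheme a [bw_scheme()].
#' @param d3_cutoff,d7_cutoff distance cutoffs to the TM3 (BW 3.50) and TM7
#'   (BW 7.56) C-alpha markers, Angstrom (defaults 15 and 12).
#' @param z_center bilayer center used for the leaflet assignment.
#' @return named logical vector, one flag per intracellular-leaflet lipid
#'   (names = lipid residue numbers); TRUE = internal.
#' @export
internal_lipid_flags <- function(frame, scheme, d3_cutoff = 15,
                                 d7_cutoff = 12, z_center = 0) {
  mk <- select_calpha(frame, c(bw_residue(scheme, "3.50"),
                               bw_residue(scheme, "7.56")))
  d_ref <- vnorm(mk[2, ] - mk[1, ])
  p <- lipid_phosphorus(frame, z_center = z_center)
  p <- p[p$leaflet == "intracellular", , drop = FALSE]
  if (!nrow(p)) return(stats::setNames(logical(0), character(0)))
  d3 <- sqrt((p$x - mk[1, 1])^2 + (p$y - mk[1, 2])^2 + (p$z - mk[1, 3])^2)
  d7 <- sqrt((p$x - mk[2, 1])^2 + (p$y - mk[2, 2])^2 + (p$z - mk[2, 3])^2)
  stats::setNames(d3 < d3_cutoff & d7 < d7_cutoff & d3 < d_ref & d7 < d_ref,
                  p$resno)
}

#' Fraction of frames with at least one internal lipid
#'
#' @param traj a [mol_trajectory()].
#' @param scheme a [bw_scheme()].
#' @param ... passed to [internal_lipid_flags()].
#' @return ratio in \[0, 1\].
#' @export
internal_fraction <- function(traj, scheme, ...) {
  stopifnot(inherits(traj, "mol_trajectory"))
  hits <- vapply(traj$frames, function(f)
    any(internal_lipid_flags(f, scheme, ...)), logical(1))
  mean(hits)
}
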