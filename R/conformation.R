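# Inter-helix marker distances and the three-state classification of the
# TM7 position. Receptor conformations are monitored by the C-alpha
# distances 3.50-6.34 (TM3-TM6) and 3.50-7.55 (TM3-TM7); the state reached
# is classified from the TM3-TM7 distance averaged over an analysis window
# (by default the final 30 ns of a 90 ns run):
#   < 16 A        pre-active   (inward TM7)
#   16 to < 19 A  non-canonical
#   >= 19 A       atypical     (TM7 at or beyond its inactive position)
# Heatmaps use a finer four-bin code that splits the atypical range at 21 A.

#' TM3-TM6 and TM3-TM7 marker distances for one frame
#'
#' @param frame a [mol_frame()].
#' @param scheme a [bw_scheme()].
#' @return named numeric `c(d36, d37)` in Angstrom: C-alpha distances
#'   3.50-6.34 and 3.50-7.55.
#' @export
tm_marker_distances <- function(frame, scheme) {
  res <- vapply(c("3.50", "6.34", "7.55"), function(l) bw_residue(scheme, l),
                integer(1))
  xyz <- tryCatch(select_calpha(frame, res), error = function(e) {
    bad <- regmatches(conditionMessage(e), regexpr("[0-9]+", conditionMessage(e)))
    lbl <- names(res)[match(as.integer(bad), res)]
    stop("marker residue ", bad,
         if (!is.na(lbl)) paste0(" (BW ", lbl, ")"), " unavailable: ",
         conditionMessage(e), call. = FALSE)
  })
  c(d36 = vnorm(xyz[2, ] - xyz[1, ]), d37 = vnorm(xyz[3, ] - xyz[1, ]))
}

#' Marker-distance series over a trajectory
#'
#' @param traj a [mol_trajectory()].
#' @param scheme a [bw_scheme()].
#' @return data.frame of class `distance_series` with columns `time`, `d36`,
#'   `d37` plus condition/replica metadata as attributes.
#' @export
distance_series <- function(traj, scheme) {
  dd <- t(vapply(traj$frames, tm_marker_distances, numeric(2), scheme = scheme))
  out <- data.frame(time = trajectory_times(traj), d36 = dd[, 1], d37 = dd[, 2])
  attr(out, "condition") <- traj$condition
  attr(out, "replica") <- traj$replica
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Windowed mean of a distance series
#'
#' @param series a [distance_series()] (or data.frame with `time`, `d36`,
#'   `d37`).
#' @param t_start,t_end window bounds in ns, inclusive.
#' @return named numeric `c(d36, d37)` of arithmetic means over frames with
#'   `t_start <= t <= t_end`.
#' @export
window_mean <- function(series, t_start, t_end) {
  if (t_start >= t_end) stop("t_start must precede t_end")
  sel <- series$time >= t_start & series$time <= t_end
  if (!any(sel)) stop("window [", t_start, ", ", t_end,
                      "] contains no frames (series spans ",
                      min(series$time), "-", max(series$time), " ns)")
  c(d36 = mean(series$d36[sel]), d37 = mean(series$d37[sel]))
}

#' Classify the TM7 state from a mean TM3-TM7 distance
#'
#' @param d37_mean mean TM3-TM7 distance in Angstrom (positive).
#' @return one of `"pre-active"` (< 16), `"non-canonical"` (16 to < 19),
#'   `"atypical"` (>= 19).
#' @export
classify_tm7_state <- function(d37_mean) {
  if (!is.numeric(d37_mean) || any(d37_mean <= 0))
    stop("d37 must be a positive distance")
  cut_states <- function(d) {
    if (d < 16) "pre-active" else if (d < 19) "non-canonical" else "atypical"
  }
  vapply(d37_mean, cut_states, character(1))
}

#' Four-bin heatmap color for a TM3-TM7 distance
#'
#' Splits the atypical range at 21 A to distinguish inactive-like (green,
#' 19 to < 21 A) from clearly opened TM7 (yellow, >= 21 A).
#'
#' @param d37 TM3-TM7 distance(s) in Angstrom (positive).
#' @return character: `"red"` (< 16), `"blue"` (16 to < 19), `"green"`
#'   (19 to < 21), `"yellow"` (>= 21).
#' @export
heatmap_bin <- function(d37) {
  if (!is.numeric(d37) || any(d37 <= 0)) stop("d37 must be a positive distance")
  bins <- c("red", "blue", "green", "yellow")
  bins[findInterval(d37, c(16, 19, 21)) + 1L]
}

#' Integer code 0-3 of a heatmap bin (for CSV export)
#' @param d37 TM3-TM7 distance(s) in Angstrom.
#' @return integer 0 (red) .. 3 (yellow).
#' @export
heatmap_bin_code <- function(d37) {
  match(heatmap_bin(d37), c("red", "blue", "green", "yellow")) - 1L
}

#' Collective variable: sum of the TM3-TM6 and TM3-TM7 distances
#'
#' @param d36,d37 distances in Angstrom (positive).
#' @return `d36 + d37` in Angstrom.
#' @export
collective_variable <- function(d36, d37) {
  if (any(d36 <= 0) || any(d37 <= 0)) stop("distances must be positive")
  d36 + d37
}
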