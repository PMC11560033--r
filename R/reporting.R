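# Statistical comparisons and per-replica summary tables.
#
# Distances and cross-section areas are compared with the unequal-variance
# (Welch) t-test; H-bond counts and internal-lipid ratios, whose replica
# distributions are spread and skewed, with the two-sided Wilcoxon rank-sum
# test (exact when the pooled sample is small and tie-free). Raw p-values
# are reported; no multiple-testing correction is applied.

#' Welch two-sample t-test
#'
#' @param a,b numeric samples, each n >= 2 with nonzero variance.
#' @param var_equal use the pooled-variance (classical Student) form
#'   instead of the Welch-Satterthwaite default.
#' @return list with `statistic` (t), `df` and `p.value` (two-sided).
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate samples: both have zero variance")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the pooled sample has at most 12 tie-free
#' observations; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param a,b numeric samples, each n >= 3.
#' @return two-sided p-value.
#' @export
ranksum_test <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("each sample needs n >= 3")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Quartile/mean summary of a sample (boxplot statistics)
#'
#' @param values numeric sample, n >= 1.
#' @return named numeric `c(q1, median, q3, mean)` with
#'   linear-interpolation quantiles.
#' @export
box_summary <- function(values) {
  if (!length(values)) stop("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3], mean = mean(values))
}

#' Per-replica summary over the analysis window
#'
#' One row per trajectory: window means of the marker distances, the
#' collective variable (their sum), the conformational state, the
#' internal-lipid frame fraction and (when lipids are present) the mean
#' H-bond counts per C-terminal position.
#'
#' @param traj a [mol_trajectory()].
#' @param scheme a [bw_scheme()].
#' @param window analysis window in ns (default `c(60, 90)`, the final
#'   30 ns of the standard 90 ns protocol).
#' @param hbonds also compute per-frame H-bond counts (slower;
#'   default TRUE when lipid atoms are present).
#' @return one-row data.frame.
#' @export
replica_summary <- function(traj, scheme, window = c(60, 90),
                            hbonds = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"))
  has_lipids <- any(is_lipid_atom(traj$frames[[1]]$atoms))
  if (is.null(hbonds)) hbonds <- has_lipids
  ds <- distance_series(traj, scheme)
  wm <- window_mean(ds, window[1], window[2])
  out <- data.frame(condition = traj$condition, replica = traj$replica,
                    d36 = unname(wm["d36"]), d37 = unname(wm["d37"]),
                    cv_sum = collective_variable(wm["d36"], wm["d37"]),
                    state = classify_tm7_state(wm["d37"]),
                    internal_fraction = if (has_lipids)
                      internal_fraction(traj, scheme) else NA_real_,
                    stringsAsFactors = FALSE)
  if (hbonds && has_lipids) {
    sel <- which(ds$time >= window[1] & ds$time <= window[2])
    hb <- t(vapply(traj$frames[sel],
                   function(f) as.numeric(cterm_hbond_counts(f, scheme)),
                   numeric(5)))
    colnames(hb) <- names(cterm_hbond_counts(traj$frames[[sel[1]]], scheme))
    hbm <- colMeans(hb)
    names(hbm) <- paste0("hb_", sub("\\.", "", names(hbm)))
    out <- cbind(out, as.data.frame(as.list(hbm)))
  }
  rownames(out) <- NULL
  out
}
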