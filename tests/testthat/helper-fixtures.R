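# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

default_scheme <- function() bw_scheme()

# A minimal single-atom protein frame.
point_frame <- function(x = 0, y = 0, z = 0, elety = "CA", resno = 1L,
                        resid = "ALA") {
  mol_frame(data.frame(eleno = seq_along(x), elety = elety, resid = resid,
                       chain = "A", resno = resno, x = x, y = y, z = z,
                       stringsAsFactors = FALSE))
}

# Random unit 3-vector(s).
runit3 <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Monte-Carlo area of a union of disks (centers cx, cy; radii rd) by
# rejection sampling over the bounding box; independent oracle for the
# occupancy-grid cross-section areas.
mc_disk_union_area <- function(cx, cy, rd, n_samples = 2e5) {
  xlo <- min(cx - rd); xhi <- max(cx + rd)
  ylo <- min(cy - rd); yhi <- max(cy + rd)
  px <- stats::runif(n_samples, xlo, xhi)
  py <- stats::runif(n_samples, ylo, yhi)
  inside <- rep(FALSE, n_samples)
  for (j in seq_along(cx))
    inside <- inside | ((px - cx[j])^2 + (py - cy[j])^2 <= rd[j]^2)
  mean(inside) * (xhi - xlo) * (yhi - ylo)
}

# Exact two-sided rank-sum p-value by enumeration of all labelings.
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
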