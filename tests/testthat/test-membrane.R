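# Lateral pressure profile pipeline and membrane property measures.

test_that("instantaneous lateral pressure is the tangential-normal difference", {
  expect_equal(instantaneous_lateral_pressure(100, 100, 100), 0)
  expect_equal(instantaneous_lateral_pressure(300, 100, 0), 200)
  expect_equal(instantaneous_lateral_pressure(0, 0, 500), -500)
})

test_that("3-point smoothing handles interiors, endpoints and constants", {
  expect_equal(smooth3(c(1, 2, 3)), c(1.5, 2, 2.5))
  expect_equal(smooth3(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(smooth3(rep(4, 10)), rep(4, 10))
  expect_equal(smooth3(5), 5)
  # the mean is preserved when the ends are constant-extended
  set.seed(1)
  x <- c(2, 2, runif(20), 2, 2)
  expect_equal(mean(smooth3(x)), mean(x), tolerance = 1e-12)
  # idempotent on constants
  expect_equal(smooth3(smooth3(rep(3, 7))), rep(3, 7))
})

test_that("noise-free profiles are recovered up to the smoothing stencil", {
  spec <- generator_spec(pressure_integral = -2000)
  ser <- synthetic_pressure_series(spec)
  truth <- attr(ser, "pi_true")
  pp <- pressure_profile(ser, t_min = 20)
  expect_equal(pp$pi, smooth3(truth), tolerance = 1e-9)
  # smoothing disabled: exact time mean of the instantaneous profiles
  raw <- pressure_profile(ser, t_min = 20, smooth = FALSE)
  keep <- ser$times >= 20
  manual <- colMeans((ser$pxx[keep, ] + ser$pyy[keep, ]) / 2 - ser$pzz[keep, ])
  expect_equal(raw$pi, manual, tolerance = 1e-12)
  expect_error(pressure_profile(ser, t_min = 1e4), "beyond")
})

test_that("drift correction recenters a drifting bilayer", {
  still <- pressure_profile(synthetic_pressure_series(generator_spec()),
                            t_min = 20)
  drift <- synthetic_pressure_series(generator_spec(drift_rate = 0.05))
  corr <- pressure_profile(drift, t_min = 20)
  common <- intersect(round(still$z, 6), round(corr$z, 6))
  i1 <- match(common, round(still$z, 6)); i2 <- match(common, round(corr$z, 6))
  peak <- max(abs(still$pi))
  expect_lt(max(abs(still$pi[i1] - corr$pi[i2])) / peak, 0.02)
})

test_that("noisy profiles keep their peak positions within one slab", {
  spec <- generator_spec(pressure_noise_sd = 50, n_times = 2000, seed = 3)
  ser <- synthetic_pressure_series(spec)
  pp <- pressure_profile(ser, t_min = 20)
  truth <- attr(ser, "pi_true")
  slab <- ser$z[2] - ser$z[1]
  # the two positive head-group peaks
  for (side in list(pp$z > 0, pp$z < 0)) {
    z_hat <- pp$z[side][which.max(pp$pi[side])]
    z_true <- ser$z[side][which.max(truth[side])]
    expect_lte(abs(z_hat - z_true), slab + 1e-9)
  }
})

test_that("thickness is the peak-to-peak phosphorus mode distance", {
  set.seed(5)
  zz <- c(rnorm(4000, -19.4, 1), rnorm(4000, 19.4, 1))
  expect_equal(bilayer_thickness(zz, bin_width = 0.5), 38.8, tolerance = 0.5)
  zz2 <- c(rnorm(4000, -18.15, 1), rnorm(4000, 18.15, 1))
  expect_equal(bilayer_thickness(zz2, bin_width = 0.5), 36.3, tolerance = 0.5)
  expect_error(bilayer_thickness(rnorm(500, 10, 1)), "unimodal")
  # generator round trip at modest leaflet spread
  for (sep in c(36.3, 38.8)) {
    bl <- synthetic_bilayer(generator_spec(leaflet_sep = sep,
                                           lipids_per_leaflet = 60L,
                                           lipid_jitter_sd = 1.5))
    got <- bilayer_thickness(lipid_phosphorus(bl)$z, bin_width = 0.5)
    expect_equal(got, sep, tolerance = 1.0)
  }
})

test_that("area per lipid subtracts the protein footprint", {
  expect_equal(area_per_lipid(4900, 1300, 60), 60)
  expect_equal(area_per_lipid(4900, 0, 70), 70)
  expect_error(area_per_lipid(1000, 1200, 60), "non-positive")
})

test_that("order parameter hits its closed-form limits", {
  up <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_equal(order_parameter(up), 1)
  flat <- cbind(runit3(50)[, 1:2] * 0 + cbind(cos(1:50), sin(1:50)), 0)
  expect_equal(order_parameter(flat), -0.5)
  magic <- 54.7356 * pi / 180
  v <- cbind(sin(magic) * cos(1:100), sin(magic) * sin(1:100), cos(magic))
  expect_equal(order_parameter(v), 0, tolerance = 1e-4)
  set.seed(9)
  expect_equal(order_parameter(runit3(1e5)), 0, tolerance = 0.01)
  expect_error(order_parameter(matrix(0, 2, 3)), "zero-length")
})

test_that("surface tension follows gamma = Lz (Pz - PT) in dyn/cm", {
  expect_equal(surface_tension_check(100, 100, 80), 0)
  expect_equal(surface_tension_check(21, 1, 100), 20)   # 20 bar over 100 A
  # slab-integrated synthetic tensors with integral(pi) = -2000 bar A
  ser <- synthetic_pressure_series(generator_spec(pressure_integral = -2000))
  PT <- mean((ser$pxx + ser$pyy) / 2)
  Pz <- mean(ser$pzz)
  spec_Lz <- attr(ser, "spec")$box_Lz
  expect_equal(surface_tension_check(Pz, PT, spec_Lz), 20, tolerance = 0.02)
  expect_error(surface_tension_check(1, 1, -5), "positive")
})

test_that("pressure TSV files round-trip the series", {
  ser <- synthetic_pressure_series(generator_spec(pressure_noise_sd = 20,
                                                  drift_rate = 0.02,
                                                  n_times = 10L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pressure_tsv(ser, path)
  back <- read_pressure_tsv(path)
  expect_equal(back$z, ser$z)
  expect_equal(back$pxx, ser$pxx, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$z_P, ser$z_P, tolerance = 1e-6)
  expect_equal(pressure_profile(back, t_min = 20)$pi,
               pressure_profile(ser, t_min = 20)$pi, tolerance = 1e-4)
})
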