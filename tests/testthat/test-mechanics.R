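# Cross-section area profiles and the work against the lateral pressure.

sphere_frame <- function(x, y, z, r_label = "C") {
  mol_frame(data.frame(eleno = seq_along(x), elety = r_label, resid = "ALA",
                       chain = "A", resno = seq_along(x), x = x, y = y, z = z,
                       stringsAsFactors = FALSE))
}

test_that("sliced spheres match analytic disk areas", {
  f <- sphere_frame(0, 0, 0)
  prof <- cross_section_profile(f, radii = c(C = 2), grid_resolution = 0.1)
  mid <- which.min(abs(prof$z))
  expect_equal(prof$area[mid], pi * 4, tolerance = 0.02 * pi * 4)
  # slab above the sphere is empty
  expect_equal(prof$area[length(prof$z)], 0)
  # disk radius shrinks away from the center: analytic at z = 1
  i1 <- which.min(abs(prof$z - 1))
  expect_equal(prof$area[i1], pi * (4 - prof$z[i1]^2),
               tolerance = 0.02 * pi * 4)
  expect_error(cross_section_profile(f, radii = c(N = 2)), "radius")
})

test_that("a sphere-built cylinder has the analytic interior area", {
  # vertical cylinder of radius 10: overlapping radius-10 spheres stacked
  # densely along z, so every interior slab's disk union has radius ~10
  zz <- seq(-6, 6, by = 0.5)
  f <- sphere_frame(rep(0, length(zz)), rep(0, length(zz)), zz)
  prof <- cross_section_profile(f, radii = c(C = 10), slab_width = 0.5,
                                grid_resolution = 0.1, z_range = c(-4, 4))
  interior <- prof$z >= -4 & prof$z <= 4
  expect_equal(mean(prof$area[interior]), pi * 100,
               tolerance = 0.02 * pi * 100)
  # refining the grid converges to the analytic area: the discretization
  # error shrinks from coarse to fine and is < 0.1% at 0.1 A cells
  errs <- vapply(c(0.8, 0.1), function(g) {
    p <- cross_section_profile(f, radii = c(C = 10), slab_width = 2,
                               grid_resolution = g, z_range = c(0, 0))
    abs(p$area[1] - pi * 100)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2] / (pi * 100), 0.001)
})

test_that("grid areas agree with Monte-Carlo disk unions on random clusters", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:12, 1)
    cx <- runif(n, -3, 3); cy <- runif(n, -3, 3); cz <- runif(n, -1, 1)
    f <- sphere_frame(cx, cy, cz)
    prof <- cross_section_profile(f, radii = c(C = 1.7), slab_width = 1,
                                  grid_resolution = 0.05, z_range = c(0, 0))
    i0 <- which.min(abs(prof$z))
    hit <- abs(cz) < 1.7
    rd <- sqrt(1.7^2 - cz[hit]^2)
    oracle <- mc_disk_union_area(cx[hit], cy[hit], rd, n_samples = 1e6)
    expect_equal(prof$area[i0], oracle, tolerance = 0.01 * oracle)
  }
})

test_that("range means and profile differences follow the arithmetic", {
  z <- seq(0, 20, by = 0.2)
  const <- area_profile(z, rep(200, length(z)))
  expect_equal(mean_area_range(const, 0, 20), 200)
  ramp <- area_profile(z, seq(0, 100, length.out = length(z)))
  expect_equal(mean_area_range(ramp, 0, 20), 50)
  expect_error(mean_area_range(const, 30, 40), "outside")
  d0 <- delta_area(const, const)
  expect_true(all(d0$area == 0))
  d50 <- delta_area(area_profile(z, rep(250, length(z))), const)
  expect_true(all(d50$area == 50))
  other <- area_profile(z + 0.1, rep(1, length(z)))
  expect_error(delta_area(const, other), "grids")
})

test_that("the constant 50 A^2 difference over 0-20 A encloses 1000 A^3", {
  z <- seq(0, 20, by = 0.2)
  d50 <- delta_area(area_profile(z, rep(250, length(z))),
                    area_profile(z, rep(200, length(z))))
  expect_equal(enclosed_volume(d50, 0, 20), 1000, tolerance = 1e-9)
  expect_equal(enclosed_volume(delta_area(d50, d50), 0, 20), 0)
  # triangular difference peaking at 100 A^2 also integrates to 1000 A^3
  tri <- area_profile(z, 100 * (1 - abs(z - 10) / 10))
  expect_equal(enclosed_volume(tri, 0, 20), 1000, tolerance = 1e-9)
})

test_that("the work integral is bilinear with the stated unit conversion", {
  z <- seq(0, 20, by = 0.2)
  d50 <- structure(list(z = z, area = rep(50, length(z))),
                   class = "area_profile")
  pconst <- structure(list(z = z, pi = rep(100, length(z))),
                      class = "lateral_pressure_profile")
  w <- pressure_work(d50, pconst, 0, 20)
  expect_equal(w, 1e5 * 1.4393e-5, tolerance = 1e-9)   # 1.439 kcal/mol
  pneg <- pconst; pneg$pi <- -pconst$pi
  expect_equal(pressure_work(d50, pneg, 0, 20), -w)
  d0 <- d50; d0$area <- d0$area * 0
  expect_equal(pressure_work(d0, pconst, 0, 20), 0)
  dd <- d50; dd$area <- 2 * d50$area
  expect_equal(pressure_work(dd, pconst, 0, 20), 2 * w, tolerance = 1e-12)
  p2 <- pconst; p2$pi <- 2 * pconst$pi
  expect_equal(pressure_work(d50, p2, 0, 20), 2 * w, tolerance = 1e-12)
  short <- structure(list(z = seq(5, 10, 0.2), pi = rep(1, 26)),
                     class = "lateral_pressure_profile")
  expect_error(pressure_work(d50, short, 0, 20), "cover")
})

test_that("realistic profiles put the 1000 A^3 work in the low-kcal range", {
  spec <- generator_spec(pressure_integral = -2000)
  ser <- synthetic_pressure_series(spec)
  pp <- pressure_profile(ser, t_min = 20)
  z <- seq(0, 20, by = 0.2)
  d50 <- structure(list(z = z, area = rep(50, length(z))),
                   class = "area_profile")
  w <- abs(pressure_work(d50, pp, 0, 20))
  expect_gt(w, 0.1); expect_lt(w, 10)
})

test_that("trajectory-averaged cross-sections track conformational opening", {
  sc <- default_scheme()
  spec_o <- generator_spec(tm7_scenario = "outward", n_frames = 6L)
  spec_i <- generator_spec(tm7_scenario = "inward", n_frames = 6L)
  a_out <- mean_cross_section(opening_trajectory(spec_o), radii = c(C = 2.5, N = 2.5, H = 1.2),
                              slab_width = 2, grid_resolution = 0.25)
  a_in <- mean_cross_section(opening_trajectory(spec_i), radii = c(C = 2.5, N = 2.5, H = 1.2),
                             slab_width = 2, grid_resolution = 0.25)
  expect_gt(mean_area_range(a_out, 0, 20), mean_area_range(a_in, 0, 20))
})
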