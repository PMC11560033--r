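# Lipid-receptor H-bond detection and the internal-lipid criterion.

test_that("the H-bond rule applies both cutoffs with boundary inclusion", {
  expect_true(is_hbond(hbond_scene(2.9, 15)))
  expect_false(is_hbond(hbond_scene(3.6, 5)))    # distance fails
  expect_false(is_hbond(hbond_scene(3.0, 35)))   # angle fails
  expect_true(is_hbond(hbond_scene(3.5, 30)))    # boundary: <= cutoffs
  expect_false(is_hbond(hbond_scene(3.51, 0)))
  expect_error(hbond_scene(1.0, 10), "exceed")
  expect_error(hbond_scene(3.0, 200), "angle")
  expect_error(hbond_geometry(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "attached")
})

test_that("the H-bond verdict is invariant under rigid motion", {
  set.seed(31)
  for (i in 1:100) {
    d <- runif(1, 2.5, 4); a <- runif(1, 0, 60)
    g <- hbond_scene(d, a)
    base <- is_hbond(g)
    ax <- runit3(); ang <- runif(1, 0, 360)
    q <- axis_angle_quaternion(ang, as.numeric(ax))
    shift <- rnorm(3, 0, 20)
    g2 <- hbond_geometry(apply_rotation(q, g$donor) + shift,
                         apply_rotation(q, g$hydrogen) + shift,
                         apply_rotation(q, g$acceptor) + shift)
    expect_identical(is_hbond(g2), base)
  }
})

test_that("C-terminal H-bond counts match a brute-force pair check", {
  sc <- default_scheme()
  fr <- toy_receptor()
  expect_equal(unname(cterm_hbond_counts(fr, sc)), rep(0, 5))  # no lipids
  fr2 <- add_contact_lipid(fr, sc, "7.58", 2.9, 15)
  fr2 <- add_contact_lipid(fr2, sc, "7.58", 3.0, 10)
  got <- cterm_hbond_counts(fr2, sc)
  expect_equal(unname(got["7.58"]), 2)
  expect_equal(unname(got["total"]), 2)
  # one conforming (3.4 A / 29 deg) + one rejected (3.6 A / 10 deg)
  fr3 <- add_contact_lipid(fr, sc, "7.61", 3.4, 29)
  fr3 <- add_contact_lipid(fr3, sc, "7.62", 3.6, 10)
  got3 <- cterm_hbond_counts(fr3, sc)
  expect_equal(unname(got3["total"]), 1)
  expect_equal(unname(got3["7.61"]), 1)
  # monotonicity: adding a conforming contact never decreases a count
  fr4 <- add_contact_lipid(fr3, sc, "7.59", 3.2, 5)
  got4 <- cterm_hbond_counts(fr4, sc)
  expect_true(all(got4 >= got3))
  # brute force over all donor/H/acceptor triples agrees
  brute <- function(frame) {
    at <- frame$atoms
    lip_o <- at[at$resid %in% c("POPC", "DOPC", "POPG", "DOPG") &
                  grepl("^O", at$elety), ]
    n <- 0L
    for (p in c("7.58", "7.59", "7.61", "7.62")) {
      res <- at[at$resno == bw_residue(sc, p) &
                  !at$resid %in% c("POPC", "DOPC", "POPG", "DOPG"), ]
      dons <- res[res$elety %in% c("NZ", "NE", "NH1", "NH2"), ]
      hyds <- res[grepl("^H", res$elety), ]
      for (di in seq_len(nrow(dons))) for (hi in seq_len(nrow(hyds)))
        for (ai in seq_len(nrow(lip_o))) {
          dv <- as.numeric(dons[di, c("x", "y", "z")])
          hv <- as.numeric(hyds[hi, c("x", "y", "z")])
          av <- as.numeric(lip_o[ai, c("x", "y", "z")])
          if (sqrt(sum((hv - dv)^2)) > 1.2) next
          if (is_hbond(hbond_geometry(dv, hv, av))) n <- n + 1L
        }
    }
    n
  }
  expect_equal(unname(got4["total"]), brute(fr4))
  expect_equal(unname(got["total"]), brute(fr2))
})

test_that("internal-lipid flags reproduce the four-inequality rule", {
  sc <- default_scheme()
  fr <- synthetic_bilayer(generator_spec(internal_fraction_target = 1,
                                         pc_fraction = 0.9))
  flags <- internal_lipid_flags(fr, sc)
  expect_identical(names(flags)[flags],
                   as.character(attr(fr, "internal_resno")))
  expect_identical(sum(flags), 1L)
  # oracle identity: re-evaluate the inequalities for every lipid
  mk <- select_calpha(fr, c(bw_residue(sc, "3.50"), bw_residue(sc, "7.56")))
  dref <- sqrt(sum((mk[1, ] - mk[2, ])^2))
  p <- lipid_phosphorus(fr)
  p <- p[p$leaflet == "intracellular", ]
  for (i in seq_len(nrow(p))) {
    d3 <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - mk[1, ])^2))
    d7 <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - mk[2, ])^2))
    expect_identical(unname(flags[as.character(p$resno[i])]),
                     d3 < 15 && d7 < 12 && d3 < dref && d7 < dref)
  }
})

test_that("the inequality truth table excludes near-cleft external lipids", {
  sc <- default_scheme()
  fr <- toy_receptor()
  mk <- select_calpha(fr, c(bw_residue(sc, "3.50"), bw_residue(sc, "7.56")))
  dref <- sqrt(sum((mk[1, ] - mk[2, ])^2))
  place_p <- function(pos) {
    at <- fr$atoms; at$helix <- NULL
    extra <- data.frame(eleno = 0L, elety = "P", resid = "DOPG", chain = "L",
                        resno = 5000L, x = pos[1], y = pos[2],
                        z = abs(pos[3]), stringsAsFactors = FALSE)
    at <- rbind(at[, names(extra)], extra)
    at$eleno <- seq_len(nrow(at))
    mol_frame(at)
  }
  # midpoint of the markers: d3 = d7 = dref/2 < min(15, 12, dref)
  mid <- colMeans(mk)
  expect_true(all(internal_lipid_flags(place_p(mid), sc)))
  # far away: external
  expect_false(any(internal_lipid_flags(place_p(mid + c(40, 0, 0)), sc)))
  # satisfies the absolute cutoffs (d3 = 14 < 15, d7 = 11 < 12) but not the
  # relative ones when the markers are only 10 A apart: external
  bespoke <- function(px, py, pz) {
    mol_frame(data.frame(
      eleno = 1:3, elety = c("CA", "CA", "P"),
      resid = c("ALA", "ALA", "DOPG"), chain = c("A", "A", "L"),
      resno = c(126L, 305L, 5000L),
      x = c(0, 10, px), y = c(0, 0, py), z = c(5, 5, pz),
      stringsAsFactors = FALSE))
  }
  fr_rel <- bespoke(8.75, sqrt(196 - 8.75^2), 5)
  p <- lipid_phosphorus(fr_rel)
  expect_equal(sqrt((p$x - 0)^2 + p$y^2), 14, tolerance = 1e-9)
  expect_equal(sqrt((p$x - 10)^2 + p$y^2), 11, tolerance = 1e-9)
  expect_false(any(internal_lipid_flags(bespoke(8.75, sqrt(196 - 8.75^2), 5), sc)))
  # boundary equality is not internal (strict inequalities): with markers
  # 20 A apart, P on the axis 12 A from the 7.56 marker hits d7 = 12 exactly
  bespoke20 <- function(px) {
    mol_frame(data.frame(
      eleno = 1:3, elety = c("CA", "CA", "P"),
      resid = c("ALA", "ALA", "DOPG"), chain = c("A", "A", "L"),
      resno = c(126L, 305L, 5000L),
      x = c(0, 20, px), y = 0, z = 5, stringsAsFactors = FALSE))
  }
  expect_false(any(internal_lipid_flags(bespoke20(8), sc)))   # d7 = 12
  expect_true(all(internal_lipid_flags(bespoke20(10), sc)))   # midpoint
})

test_that("internal frame fractions recover the programmed ratio", {
  sc <- default_scheme()
  spec <- generator_spec(n_frames = 10L, with_bilayer = TRUE,
                         internal_fraction_target = 0.3, pc_fraction = 0.9)
  traj <- opening_trajectory(spec)
  expect_equal(internal_fraction(traj, sc), 0.3, tolerance = 1e-9)
  # no lipids anywhere: fraction 0
  traj0 <- opening_trajectory(generator_spec(n_frames = 4L))
  expect_equal(internal_fraction(traj0, sc), 0)
})
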