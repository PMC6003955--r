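test_that("angle wrapping and bearings follow the clockwise-positive frame", {
  expect_equal(wrap_angle(c(-180, 180, 360, 540, -190)),
               c(-180, -180, 0, -180, 170))
  # bearing of a point straight ahead along +x is 0; clockwise is positive
  expect_equal(bearing_deg(c(0, 0), c(1, 0)), 0)
  expect_equal(bearing_deg(c(0, 0), c(0, -1)), 90)
  expect_equal(bearing_deg(c(0, 0), c(-1, 0)), -180)
})

test_that("geometry constructor validates its invariants", {
  geo <- room_geometry()
  expect_equal(geo$room_size, c(3.5, 2.5))
  expect_equal(geo$drivable_size, c(3.1, 2.4))
  expect_error(room_geometry(drivable_size = c(4, 2)), "drivable")
  expect_error(room_geometry(start_xy = rbind(c(2, 0))), "start")
})

make_poses <- function(x, y, ch, hh, dt = 0.1) {
  n <- length(x)
  data.frame(t = seq_len(n) * dt - dt, x = x, y = y,
             chair_heading = ch, head_heading = hh)
}

test_that("covariates reproduce the alignment, antipodal and distance cases", {
  geo <- room_geometry()
  # chair at the central start point facing the dispenser, head aligned
  p <- make_poses(rep(1, 5), rep(0, 5), rep(-180, 5), rep(-180, 5))
  cov <- compute_covariates(p, geo)
  expect_equal(cov$alpha, rep(0, 5))
  expect_equal(cov$beta, rep(0, 5))
  expect_equal(cov$r, rep(2.75, 5))
  # facing directly away from the dispenser
  p2 <- make_poses(rep(1, 5), rep(0, 5), rep(0, 5), rep(0, 5))
  cov2 <- compute_covariates(p2, geo)
  expect_equal(cov2$beta, rep(-180, 5))
})

test_that("position reconstructs from (r, theta) and headings wrap freely", {
  geo <- room_geometry()
  poses <- simulate_trajectories(geo, 4, seed = 3)
  cov <- compute_covariates(poses, geo)
  xr <- geo$dispenser_xy[1] + cov$r * cos(cov$theta * pi / 180)
  yr <- geo$dispenser_xy[2] - cov$r * sin(cov$theta * pi / 180)
  expect_lt(max(abs(xr - cov$x)), 1e-9)
  expect_lt(max(abs(yr - cov$y)), 1e-9)
  # rotating every heading by a full turn changes nothing
  poses2 <- poses
  poses2$chair_heading <- poses$chair_heading + 360
  poses2$head_heading <- poses$head_heading - 360
  cov2 <- compute_covariates(poses2, geo)
  expect_equal(cov2, cov)
})

test_that("zone labels are nested by distance", {
  geo <- room_geometry()
  r <- seq(0, 2, by = 0.05)
  z <- zone_label(r, geo)
  expect_true(all(z[r <= geo$reach_radius] == "reach"))
  expect_true(all(z[r > geo$reach_radius & r <= geo$docking_radius] ==
                    "docking"))
  expect_true(all(z[r > geo$docking_radius] == "navigation"))
})

test_that("malformed pose tracks are rejected", {
  geo <- room_geometry()
  p <- make_poses(1:5 / 10, rep(0, 5), rep(0, 5), rep(0, 5))
  p$t[3] <- p$t[2]  # non-monotone
  expect_error(compute_covariates(p, geo), "increasing")
  p2 <- make_poses(1:5 / 10, rep(0, 5), rep(0, 5), rep(0, 5))
  p2$t[4:5] <- p2$t[4:5] + 0.5  # gap
  expect_error(compute_covariates(p2, geo), "gap")
})

test_that("z-scoring uses the population convention and flags silent units", {
  counts <- rbind(c(0L, 2L), c(3L, 3L))
  expect_warning(z <- zscore_counts(counts), "zero-variance")
  expect_equal(z[1, ], c(-1, 1))
  expect_equal(z[2, ], c(0, 0))
  expect_equal(attr(z, "zero_variance"), c(FALSE, TRUE))
  # 3-point moving average: center of (0, 3, 0) is 1
  expect_equal(moving_average3(c(0, 3, 0))[2], 1)
})

test_that("sessions round-trip through plain-text files", {
  s <- small_session()
  prefix <- file.path(tempdir(), "roundtrip")
  write_session(s, prefix)
  s2 <- read_session(prefix)
  expect_identical(unname(s2$spikes), unname(s$spikes))
  for (col in c("x", "y", "v", "w", "r", "theta", "alpha", "beta")) {
    expect_lt(max(abs(s2$covariates[[col]] - s$covariates[[col]])), 1e-12)
  }
  expect_identical(s2$covariates$zone, s$covariates$zone)
  expect_identical(s2$covariates$trial_id, s$covariates$trial_id)
  expect_equal(s2$geometry, s$geometry)
})
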