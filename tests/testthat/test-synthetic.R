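test_that("trials cycle the three start points and end docked", {
  geo <- room_geometry()
  poses <- simulate_trajectories(geo, 6, seed = 11)
  firsts <- do.call(rbind, lapply(split(poses, poses$trial_id),
                                  function(d) d[1, c("x", "y")]))
  # 6 trials -> each start used exactly twice (first pose may have moved
  # one controller step from the exact start point)
  d2start <- apply(firsts, 1, function(p) {
    min(sqrt(rowSums((geo$start_xy - matrix(p, 3, 2, byrow = TRUE))^2)))
  })
  expect_true(all(d2start < 0.1))
  assign <- apply(firsts, 1, function(p) {
    which.min(sqrt(rowSums((geo$start_xy - matrix(p, 3, 2, byrow = TRUE))^2)))
  })
  expect_equal(as.integer(table(assign)), rep(2L, 3))
  lasts <- do.call(rbind, lapply(split(poses, poses$trial_id),
                                 function(d) d[nrow(d), c("x", "y")]))
  rend <- sqrt((lasts$x - geo$dispenser_xy[1])^2 +
                 (lasts$y - geo$dispenser_xy[2])^2)
  expect_true(all(rend <= geo$docking_radius))
})

test_that("generated sessions are deterministic and respect velocity limits", {
  geo <- room_geometry()
  a <- simulate_trajectories(geo, 5, seed = 99)
  b <- simulate_trajectories(geo, 5, seed = 99)
  expect_identical(a, b)
  cov <- compute_covariates(a, geo)
  expect_lte(max(abs(cov$v)), 0.28 + 1e-9)
  expect_lte(max(abs(cov$w)), 46 + 1e-9)
  half <- geo$drivable_size / 2
  expect_true(all(abs(cov$x) <= half[1] & abs(cov$y) <= half[2]))
})

test_that("50 trials cover most of the drivable area at 0.4 m resolution", {
  geo <- room_geometry()
  poses <- simulate_trajectories(geo, 50, seed = 3)
  half <- geo$drivable_size / 2
  xe <- seq(-half[1], half[1] + 0.4, by = 0.4)
  ye <- seq(-half[2], half[2] + 0.4, by = 0.4)
  cells <- paste(findInterval(poses$x, xe), findInterval(poses$y, ye))
  frac <- length(unique(cells)) / ((length(xe) - 1) * (length(ye) - 1))
  expect_gte(frac, 0.6)
})

test_that("requested class mixture is realized exactly", {
  gt <- make_population(n_position = 7, n_orientation = 5, n_mixed = 3,
                        n_untuned = 4, seed = 1)
  expect_equal(as.integer(table(factor(gt$class,
                                       c("position", "orientation", "mixed",
                                         "untuned")))),
               c(7L, 5L, 3L, 4L))
  for (i in seq_along(gt$neurons)) {
    sp <- gt$neurons[[i]]
    switch(gt$class[i],
      position = {
        expect_gt(sp$position_gain, 0)
        expect_identical(c(sp$alpha_gain, sp$beta_gain), c(0, 0))
      },
      orientation = {
        expect_identical(sp$position_gain, 0)
        expect_gt(sp$alpha_gain + sp$beta_gain, 0)
      },
      mixed = {
        expect_gt(sp$position_gain, 0)
        expect_gt(sp$alpha_gain + sp$beta_gain, 0)
      },
      untuned = {
        expect_identical(c(sp$position_gain, sp$alpha_gain, sp$beta_gain),
                         c(0, 0, 0))
      })
  }
})

test_that("an untuned neuron fires at its planted baseline rate", {
  gt <- make_population(n_position = 0, n_orientation = 0, n_untuned = 1,
                        seed = 2)
  s <- simulate_session(gt, n_trials = 45, seed = 3)
  n <- ncol(s$spikes)
  expect_gt(n, 10000)
  m <- mean(s$spikes[1, ])
  se <- sqrt(0.5 / n)
  expect_lt(abs(m - 0.5), 3 * se)
})

test_that("a strong planted place field is recovered by the tuning map", {
  gt <- make_population(n_position = 1, n_orientation = 0, n_untuned = 0,
                        seed = 8)
  s <- simulate_session(gt, n_trials = 40, seed = 9)
  dg <- position_tuning_diagram(s, 1)
  am <- which(dg$raw == max(dg$raw, na.rm = TRUE), arr.ind = TRUE)[1, ]
  xc <- dg$xedges[-1] - 0.025
  yc <- dg$yedges[-1] - 0.025
  ctr <- gt$neurons[[1]]$field_center
  expect_lt(sqrt((xc[am[2]] - ctr[1])^2 + (yc[am[1]] - ctr[2])^2), 0.3)
})

test_that("reach gain multiplies the in-zone rate", {
  gt <- make_population(n_position = 0, n_orientation = 0, n_untuned = 1,
                        reach_fraction = 1, reach_gain = 2, seed = 4)
  s <- simulate_session(gt, n_trials = 40, seed = 5)
  inr <- s$covariates$zone == "reach"
  ratio <- mean(s$spikes[1, inr]) / mean(s$spikes[1, !inr])
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("stable and remapped multi-session conditions behave as planted", {
  gt <- make_population(n_position = 3, n_orientation = 0, n_untuned = 0,
                        seed = 6)
  st <- generate_multi_session(gt, 2, n_trials = 3, condition = "stable")
  expect_identical(st[[1]]$metadata$ground_truth,
                   st[[2]]$metadata$ground_truth)
  rm <- generate_multi_session(gt, 2, n_trials = 3, condition = "remap")
  c1 <- t(vapply(rm[[1]]$metadata$ground_truth$neurons, `[[`,
                 numeric(2), "field_center"))
  c2 <- t(vapply(rm[[2]]$metadata$ground_truth$neurons, `[[`,
                 numeric(2), "field_center"))
  expect_true(all(rowSums(abs(c1 - c2)) > 0))
})

test_that("excessive rates trip the cap guard", {
  gt <- make_population(n_position = 1, n_orientation = 0, n_untuned = 0,
                        position_gain = 9, baseline_log_rate = log(5),
                        seed = 10)
  poses <- simulate_trajectories(room_geometry(), 10, seed = 11)
  cov <- compute_covariates(poses, room_geometry())
  expect_error(generate_spikes(cov, gt, seed = 1), "rate cap")
})
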