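ramp_surface <- function(geometry) {
  grid <- navtune:::position_grid(geometry, 0.05)
  xc <- grid$xedges[-1] - 0.025
  yc <- grid$yedges[-1] - 0.025
  list(surface = matrix(seq_len(grid$ny * grid$nx) / 100, grid$ny, grid$nx),
       xcenters = xc, ycenters = yc)
}

test_that("place fields threshold strictly above the median", {
  geo <- room_geometry()
  pf <- extract_place_field(ramp_surface(geo), geo)
  vals <- pf$field[!is.na(pf$field)]
  # a strictly increasing surface puts exactly the upper half in-field
  expect_equal(sum(vals), floor(length(vals) / 2))
  expect_false(pf$degenerate)
  # constant surface: nothing exceeds the median
  const <- ramp_surface(geo)
  const$surface[] <- 1
  pfc <- extract_place_field(const, geo)
  expect_true(pfc$degenerate)
  expect_equal(sum(pfc$field, na.rm = TRUE), 0)
})

test_that("docking-zone bins are masked out of the place field", {
  geo <- room_geometry()
  pf <- extract_place_field(ramp_surface(geo), geo)
  xc <- pf$xcenters
  yc <- pf$ycenters
  inside <- outer(yc, xc, function(yy, xx) {
    sqrt((xx - geo$dispenser_xy[1])^2 + (yy - geo$dispenser_xy[2])^2) <=
      geo$docking_radius
  })
  expect_true(all(is.na(pf$field[inside])))
})

test_that("a planted place cell's field contains its center", {
  a <- small_assessment()
  gt <- small_population()
  i <- which(gt$class == "position")[1]
  surf <- extract_position_surface(a$fits[[i]])
  pf <- extract_place_field(surf, room_geometry())
  ctr <- gt$neurons[[i]]$field_center
  bx <- which.min(abs(pf$xcenters - ctr[1]))
  by <- which.min(abs(pf$ycenters - ctr[2]))
  expect_true(isTRUE(pf$field[by, bx]))
})

test_that("ensemble heatmaps stay in [0, 1] and ignore session order", {
  a <- small_assessment()
  gt <- small_population()
  geo <- room_geometry()
  flds <- lapply(which(gt$class == "position"), function(i) {
    extract_place_field(extract_position_surface(a$fits[[i]]), geo)
  })
  hm <- ensemble_place_field_heatmap(list(flds, rev(flds)))
  expect_true(all(hm$heatmap >= 0 & hm$heatmap <= 1, na.rm = TRUE))
  hm2 <- ensemble_place_field_heatmap(list(rev(flds), flds))
  expect_equal(hm2$heatmap, hm$heatmap)
  # single session, single neuron: the heatmap is that neuron's 0/1 field
  hm1 <- ensemble_place_field_heatmap(list(flds[1]))
  expect_equal(hm1$heatmap, flds[[1]]$field + 0)
})

test_that("clustered place fields are detected as non-uniform", {
  geo <- room_geometry()
  base <- ramp_surface(geo)
  set.seed(9)
  flds <- lapply(1:12, function(i) {
    s <- base
    cx <- runif(1, 0.5, 1.2); cy <- runif(1, 0.3, 0.9)  # one quadrant
    s$surface <- outer(s$ycenters, s$xcenters, function(yy, xx) {
      exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * 0.16))
    })
    extract_place_field(s, geo)
  })
  hm <- ensemble_place_field_heatmap(list(flds))
  expect_lt(hm$ks_p, 0.01)
})

test_that("preferred directions take the argmax with stated tie handling", {
  crv <- list(angle = seq(-180, 179), value = rep(0, 360))
  crv$value[91] <- 1  # -90 degrees
  expect_equal(preferred_direction(crv)$direction, -90)
  flat <- list(angle = seq(-180, 179), value = rep(0.3, 360))
  pd <- preferred_direction(flat)
  expect_true(pd$degenerate)
  expect_true(is.na(pd$direction))
})

test_that("direction histograms are per-session proportions", {
  h <- direction_histogram(list(c(-170, 10, 20, 100), c(0, 45)))
  expect_equal(sum(h$proportion), 1, tolerance = 1e-12)
  expect_length(h$proportion, 8)
})

test_that("planted preferred directions are recovered within a half bin", {
  a <- small_assessment()
  gt <- small_population()
  hits <- 0; tot <- 0
  for (i in which(gt$class == "orientation")) {
    sp <- gt$neurons[[i]]
    var <- if (sp$alpha_gain > 0) "alpha" else "beta"
    mu <- if (sp$alpha_gain > 0) sp$alpha_mu else sp$beta_mu
    pd <- preferred_direction(extract_angle_curve(a$fits[[i]], var))
    tot <- tot + 1
    if (abs(wrap_angle(pd$direction - mu)) <= 22.5) hits <- hits + 1
  }
  expect_gte(hits / tot, 0.8)
})
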