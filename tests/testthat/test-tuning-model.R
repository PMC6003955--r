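test_that("tuning depth follows McFadden's pseudo R-squared exactly", {
  expect_equal(mcfadden_td(90, 100), 0.1)
  expect_equal(mcfadden_td(100, 100), 0)
  expect_equal(mcfadden_td(110, 100), 0)  # clamped
  expect_error(mcfadden_td(1, 0), "positive")
})

test_that("planted tuning classes are recovered with correct preference", {
  a <- small_assessment()
  tab <- a$table
  cls <- small_population()$class
  # position neurons: TD_position dominates and is significant
  for (i in which(cls == "position")) {
    expect_gt(tab$td_position[i], tab$td_orientation[i])
    expect_lt(tab$p_position[i], 0.005)
    expect_identical(tab$preference[i], "position")
  }
  for (i in which(cls == "orientation")) {
    expect_gt(tab$td_orientation[i], tab$td_position[i])
    expect_lt(tab$p_orientation[i], 0.005)
    expect_identical(tab$preference[i], "orientation")
  }
})

test_that("nested deviances satisfy DF <= DP and TD lies in [0, 1]", {
  a <- small_assessment()
  for (f in a$fits) {
    for (grp in c("position", "orientation")) {
      td <- tuning_depth(f, grp)
      if (!td$clamped) expect_lte(td$df_full, td$df_partial)
      expect_gte(td$td, 0)
      expect_lte(td$td, 1)
    }
  }
})

test_that("fitted surfaces and curves recover the planted parameters", {
  a <- small_assessment()
  gt <- small_population()
  cls <- gt$class
  i <- which(cls == "position")[1]
  surf <- extract_position_surface(a$fits[[i]])
  am <- which(surf$surface == max(surf$surface, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ctr <- gt$neurons[[i]]$field_center
  expect_lt(sqrt((surf$xcenters[am[2]] - ctr[1])^2 +
                   (surf$ycenters[am[1]] - ctr[2])^2), 0.3)
  for (i in which(cls == "orientation")) {
    sp <- gt$neurons[[i]]
    var <- if (sp$alpha_gain > 0) "alpha" else "beta"
    mu <- if (sp$alpha_gain > 0) sp$alpha_mu else sp$beta_mu
    crv <- extract_angle_curve(a$fits[[i]], var)
    pk <- crv$angle[which.max(crv$value)]
    expect_lt(abs(wrap_angle(pk - mu)), 15)
  }
})

test_that("untuned neurons show no significant covariate group", {
  a <- small_assessment()
  cls <- small_population()$class
  for (i in which(cls == "untuned")) {
    expect_gt(a$table$p_position[i], 0.005)
    expect_gt(a$table$p_orientation[i], 0.005)
    expect_true(is.na(a$table$preference[i]))
  }
})

test_that("preference classification applies the stated tie and median rules", {
  tab <- data.frame(td_position = c(0.2, 0.01, 0.05, 0.08),
                    p_position = c(1e-5, 0.5, 1e-4, 1e-4),
                    td_orientation = c(0.05, 0.02, 0.05, 0.02),
                    p_orientation = c(1e-3, 0.6, 1e-3, 0.5))
  out <- classify_preference(tab)
  expect_identical(out$preference,
                   c("position", NA, "position", "position"))
  # exact TD tie broken by the smaller p (row 3: p_position smaller)
  # strict median rule: no more than half the assessed neurons highly tuned
  expect_lte(sum(out$highly_tuned), sum(!is.na(out$preference)) / 2)
})

test_that("tuning depth is invariant to rescaling the spatial units", {
  s <- small_session()
  s_cm <- s
  s_cm$covariates$x <- s$covariates$x * 100
  s_cm$covariates$y <- s$covariates$y * 100
  f_m <- small_assessment()$fits[[1]]
  f_cm <- fit_full_model(s_cm, 1)
  td_m <- tuning_depth(f_m, "position")$td
  td_cm <- tuning_depth(f_cm, "position")$td
  expect_equal(td_cm, td_m, tolerance = 0.05)
})

test_that("the full second-order interaction structure is accepted", {
  s <- small_session()
  spec <- tuning_model_spec(interactions = TRUE, k_int = c(6, 4))
  f <- fit_full_model(s, 1, spec)
  labs <- vapply(f$fit$smooth, function(sm) sm$label, "")
  expect_true(any(grepl("^ti\\(x,yy,v,w", labs)))
  expect_true(any(grepl("^ti\\(x,yy,alpha", labs)))
  expect_true(any(grepl("^ti\\(v,w,beta", labs)))
  td <- tuning_depth(f, "position")
  expect_gt(td$td, 0)
  expect_lt(td$p, 0.005)
})
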