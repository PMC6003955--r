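cheap_spec <- function(...) {
  decoder_spec(folds = 5, restarts = 2, max_rounds = 15, max_train = 1500,
               ...)
}

test_that("angle metrics behave at the three reference points", {
  set.seed(1)
  ang <- runif(500, -180, 180)
  P <- cbind(sin(ang * pi / 180), cos(ang * pi / 180))
  perfect <- angle_metrics(P, ang)
  expect_equal(perfect$cc, 1)
  expect_lt(perfect$circ_err_deg, 1e-9)
  flipped <- angle_metrics(-P, ang)
  expect_equal(flipped$cc, -1)
  indep <- angle_metrics(P[sample(500), ], ang)
  expect_lt(abs(indep$cc), 0.15)
})

test_that("centroid MPE closed form matches a brute-force oracle", {
  set.seed(2)
  xy <- cbind(runif(400, -1.5, 1.5), runif(400, -1.2, 1.2))
  ctr <- c(mean(xy[, 1]), mean(xy[, 2]))
  oracle <- 0
  for (i in seq_len(nrow(xy))) {
    oracle <- oracle + sqrt(sum((xy[i, ] - ctr)^2))
  }
  oracle <- oracle / nrow(xy)
  expect_equal(centroid_mpe(xy), oracle, tolerance = 1e-9)
})

test_that("lagged inputs stack the preceding window without lookahead", {
  z <- matrix(seq_len(20), nrow = 2)  # 2 neurons x 10 bins
  X <- navtune:::lagged_inputs(z, 3)
  expect_false(attr(X, "valid")[2])
  expect_true(attr(X, "valid")[3])
  expect_equal(X[5, ], c(z[, 5], z[, 4], z[, 3]))
})

test_that("noiseless position-coding inputs decode to high accuracy", {
  s <- small_session()
  cov <- s$covariates
  centers <- expand.grid(x = c(-1.1, -0.4, 0.4, 1.1),
                         y = c(-0.8, 0, 0.8))
  counts <- t(apply(centers, 1, function(ctr) {
    as.integer(round(20 * exp(-((cov$x - ctr[1])^2 + (cov$y - ctr[2])^2) /
                                (2 * 0.35^2))))
  }))
  rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  dec <- crossvalidated_decode(s, "position", neurons = seq_len(nrow(counts)),
                               spec = cheap_spec(), seed = 5, counts = counts)
  expect_lt(dec$session_metric, 0.15)
})

test_that("folds are disjoint, trial-aligned and cover the usable bins", {
  s <- small_session()
  spec <- cheap_spec()
  dec <- crossvalidated_decode(s, "position", spec = spec, seed = 6)
  bins <- dec$bin_index
  expect_equal(anyDuplicated(bins), 0L)
  # every pre-docking bin with a full input window is tested exactly once
  usable <- which(seq_len(ncol(s$spikes)) >= spec$window &
                    s$covariates$zone == "navigation")
  expect_setequal(bins, usable)
  # no trial is split across folds: each trial's bins are contiguous in
  # exactly one fold
  expect_true(all(table(s$covariates$trial_id[bins]) ==
                    table(s$covariates$trial_id[usable])))
})

test_that("decoding is deterministic under a fixed seed", {
  s <- small_session()
  spec <- decoder_spec(folds = 2, restarts = 1, max_rounds = 4,
                       max_train = 500)
  a <- crossvalidated_decode(s, "alpha", spec = spec, seed = 9)
  b <- crossvalidated_decode(s, "alpha", spec = spec, seed = 9)
  expect_identical(a$fold_metric, b$fold_metric)
  expect_identical(a$predictions, b$predictions)
})

test_that("tiny populations are refused", {
  s <- small_session()
  expect_error(crossvalidated_decode(s, "position", neurons = 1:2),
               "at least 3")
})

test_that("the spatial error map is constant for constant errors", {
  s <- small_session()
  spec <- decoder_spec(folds = 2, restarts = 1, max_rounds = 2,
                       max_train = 300)
  dec <- crossvalidated_decode(s, "position", spec = spec, seed = 4)
  dec$errors <- rep(0.25, length(dec$errors))
  m <- spatial_error_map(dec, s)
  expect_equal(max(abs(m$map - 0.25)), 0, tolerance = 1e-9)
})

test_that("the output-feedback architecture trains and evaluates closed loop", {
  s <- small_session()
  spec <- decoder_spec(architecture = "output-feedback", folds = 2,
                       restarts = 1, max_rounds = 5, max_train = 800)
  dec <- crossvalidated_decode(s, "position", spec = spec, seed = 8)
  expect_true(is.finite(dec$session_metric))
  expect_gt(dec$session_metric, 0)
})
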