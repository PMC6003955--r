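#' Reach-state labels from zone geometry
#'
#' Every 100 ms bin inside the reach zone is labeled reach-related; all
#' other bins are navigation-related. The labeling is purely geometric.
#'
#' @param session a [session_data()].
#' @return list: `labels` (logical per bin, TRUE = reach), `imbalance`
#'   (navigation:reach ratio).
#' @export
reach_labels <- function(session) {
  lab <- session$covariates$zone == "reach"
  list(labels = lab, imbalance = sum(!lab) / max(1L, sum(lab)))
}

#' Peri-event population histograms around reach-zone entry
#'
#' Smoothed z-scored counts are averaged across trials in a +/- 2 s window
#' around each trial's first reach-zone entry; neurons are ordered by the
#' OLS slope of their trace (most positively ramping first).
#'
#' @param session a [session_data()].
#' @param window_s half-window in seconds.
#' @param min_entries minimum reach-zone entries required.
#' @return list: `traces` (neurons x time, slope-ordered), `order`,
#'   `slopes`, `time_s`.
#' @export
peth_reach <- function(session, window_s = 2, min_entries = 5) {
  cov <- session$covariates
  entries <- vapply(split(seq_len(nrow(cov)), cov$trial_id), function(ix) {
    hit <- ix[cov$zone[ix] == "reach"]
    if (length(hit)) hit[1] else NA_integer_
  }, 0L)
  entries <- entries[!is.na(entries)]
  if (length(entries) < min_entries) {
    stop("need at least ", min_entries, " reach-zone entries")
  }
  z <- zscore_counts(session$spikes, smooth = TRUE)
  hw <- round(window_s / 0.1)
  off <- -hw:hw
  nb <- ncol(z)
  traces <- matrix(0, nrow(z), length(off))
  for (e in entries) {
    idx <- pmin(pmax(e + off, 1L), nb)
    traces <- traces + z[, idx, drop = FALSE]
  }
  traces <- traces / length(entries)
  tt <- off * 0.1
  slopes <- apply(traces, 1, function(tr) stats::cov(tt, tr) / stats::var(tt))
  ord <- order(slopes, decreasing = TRUE)
  list(traces = traces[ord, , drop = FALSE], order = ord,
       slopes = slopes[ord], time_s = tt)
}

#' Cohen's kappa for binary agreement
#'
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from the product of
#' the marginal label distributions; chance-corrected and appropriate for
#' imbalanced classes.
#'
#' @param actual,predicted logical or two-level vectors of equal length.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  a <- as.integer(as.logical(actual))
  p <- as.integer(as.logical(predicted))
  n <- length(a)
  po <- mean(a == p)
  pe <- mean(a) * mean(p) + mean(1 - a) * mean(1 - p)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

# ---- boosted trees with random undersampling ------------------------------

# AdaBoost over rpart trees; each round fits on the full minority class
# plus an equally sized weighted draw from the majority class
rusboost_fit <- function(X, y, n_trees = 400, min_leaf = 20,
                         learn_rate = 1, seed = 1) {
  set.seed(seed)
  y <- as.logical(y)
  n <- length(y)
  minority <- if (mean(y) <= 0.5) TRUE else FALSE
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(FALSE, TRUE))
  ctrl <- rpart::rpart.control(minbucket = min_leaf, cp = 1e-3,
                               maxdepth = 8, xval = 0)
  for (t in seq_len(n_trees)) {
    min_idx <- which(y == minority)
    maj_idx <- which(y != minority)
    draw <- sample(maj_idx, min(length(min_idx), length(maj_idx)),
                   replace = TRUE, prob = w[maj_idx])
    idx <- c(min_idx, draw)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class", control = ctrl,
                        weights = w[idx] / sum(w[idx]))
    pred <- stats::predict(fit, df, type = "class") == "TRUE"
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 0) { trees[[t]] <- fit; alphas[t] <- 10; break }
    if (err >= 0.5) { w <- rep(1 / n, n); next }
    a <- learn_rate * 0.5 * log((1 - err) / err)
    trees[[length(alphas) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(a * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  structure(list(trees = trees[!vapply(trees, is.null, TRUE)],
                 alphas = alphas, minority = minority),
            class = "rusboost")
}

# mean terminal-leaf probability of reach across trees, alpha-weighted
rusboost_score <- function(model, X) {
  df <- as.data.frame(X)
  s <- rep(0, nrow(df))
  wsum <- sum(model$alphas)
  for (t in seq_along(model$trees)) {
    p <- stats::predict(model$trees[[t]], df, type = "prob")[, "TRUE"]
    s <- s + model$alphas[t] * p
  }
  s / wsum
}

#' Train and cross-validate the reach-state classifier
#'
#' The smoothed z-scored population activity is reduced to its top five
#' principal components (PCA fit on training folds only) and a boosted
#' ensemble of 400 decision trees (minimum leaf size 20) is trained with
#' random undersampling of the majority class in every boosting round.
#' Stratified contiguous-block 5-fold cross-validation at trial granularity
#' yields per-fold Cohen's kappa on held-out bins; their mean is the
#' session performance. Held-out reach scores (mean terminal-leaf
#' probabilities) are retained for the spatial map.
#'
#' @param session a [session_data()].
#' @param neurons neuron indices (default all).
#' @param n_trees,min_leaf,learn_rate boosting settings.
#' @param n_pc principal components kept.
#' @param folds cross-validation folds.
#' @param seed RNG seed.
#' @return an object of class `reach_classifier_result`: `fold_kappa`,
#'   `mean_kappa`, `scores`, `predicted`, `actual`, `bin_index`,
#'   `imbalance`.
#' @export
train_reach_classifier <- function(session, neurons = NULL, n_trees = 400,
                                   min_leaf = 20, learn_rate = 1, n_pc = 5,
                                   folds = 5, seed = 1) {
  if (is.null(neurons)) neurons <- seq_len(nrow(session$spikes))
  lab <- reach_labels(session)
  y <- lab$labels
  if (!any(y) || all(y)) stop("both reach and navigation bins are required")
  z <- t(zscore_counts(session$spikes[neurons, , drop = FALSE],
                       smooth = TRUE))  # bins x neurons
  tf <- trial_folds(session$covariates$trial_id, folds)
  # every trial ends near the dispenser, so contiguous trial blocks are
  # stratified by construction; verify and fail loudly otherwise
  for (f in seq_along(tf)) {
    sel <- session$covariates$trial_id %in% tf[[f]]
    if (!any(y[sel]) || !any(!y[sel])) {
      stop("fold ", f, " is missing a class; supply more trials")
    }
  }
  fold_kappa <- numeric(length(tf))
  scores <- pred <- act <- bins <- list()
  for (f in seq_along(tf)) {
    test <- which(session$covariates$trial_id %in% tf[[f]])
    train <- setdiff(seq_len(nrow(z)), test)
    pca <- stats::prcomp(z[train, , drop = FALSE], center = TRUE,
                         scale. = FALSE)
    k <- min(n_pc, ncol(pca$rotation))
    tr <- pca$x[, seq_len(k), drop = FALSE]
    te <- scale(z[test, , drop = FALSE], center = pca$center,
                scale = FALSE) %*% pca$rotation[, seq_len(k), drop = FALSE]
    model <- rusboost_fit(tr, y[train], n_trees = n_trees,
                          min_leaf = min_leaf, learn_rate = learn_rate,
                          seed = seed + f)
    sc <- rusboost_score(model, te)
    ph <- sc > 0.5
    fold_kappa[f] <- cohens_kappa(y[test], ph)
    scores[[f]] <- sc; pred[[f]] <- ph; act[[f]] <- y[test]
    bins[[f]] <- test
  }
  structure(list(fold_kappa = fold_kappa, mean_kappa = mean(fold_kappa),
                 scores = unlist(scores), predicted = unlist(pred),
                 actual = unlist(act), bin_index = unlist(bins),
                 imbalance = lab$imbalance, n_pc = n_pc),
            class = "reach_classifier_result")
}

#' @export
print.reach_classifier_result <- function(x, ...) {
  cat(sprintf("reach_classifier_result: mean kappa %.3f over %d folds (imbalance %.1f:1)\n",
              x$mean_kappa, length(x$fold_kappa), x$imbalance))
  invisible(x)
}

#' Spatial map of held-out reach scores
#'
#' Reach probabilities from the test folds are binned on the 5 cm grid,
#' averaged, filled and Gaussian-smoothed (5 x 5 kernel, sigma = 2 bins).
#'
#' @param result a [train_reach_classifier()] result.
#' @param session the classified [session_data()].
#' @return list: `map` (values in \[0, 1\]), `occupancy`.
#' @export
spatial_reach_map <- function(result, session) {
  grid <- position_grid(session$geometry, 0.05)
  cov <- session$covariates[result$bin_index, ]
  ix <- grid_bin_index(cov$x, grid$xedges)
  iy <- grid_bin_index(cov$y, grid$yedges)
  ok <- !is.na(ix) & !is.na(iy)
  cell <- (ix[ok] - 1L) * grid$ny + iy[ok]
  occ <- tabulate(cell, nbins = grid$ny * grid$nx)
  sums <- rep(0, grid$ny * grid$nx)
  agg <- rowsum(result$scores[ok], cell)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  raw <- matrix(NA_real_, grid$ny, grid$nx)
  raw[occ > 0] <- sums[occ > 0] / occ[occ > 0]
  map <- fill_and_smooth(raw, kernel_size = 5, sigma = 2)
  map <- pmin(pmax(map, 0), 1)
  list(map = map, occupancy = matrix(occ, grid$ny, grid$nx))
}
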