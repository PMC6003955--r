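#' Decoder architecture and training settings
#'
#' A single-hidden-layer network maps a sliding window of five 100 ms bins
#' of z-scored spike counts (times t .. t-4) to either (x, y) position or
#' the (sine, cosine) of a target angle. Hidden units use the hyperbolic
#' tangent, output units are linear. Training minimizes mean squared error
#' by conjugate gradient with Fletcher-Reeves updates, run in short rounds
#' with early stopping after 15 validation failures. In the
#' `output-feedback` architecture the three past predictions (t-1 .. t-3)
#' are appended to the input; training uses teacher forcing and evaluation
#' feeds back the decoder's own predictions.
#'
#' @param architecture `"feedforward"` (default) or `"output-feedback"`.
#' @param hidden hidden units: 30 for position, 10 for angles (set by
#'   [crossvalidated_decode()] when NULL).
#' @param window input window length in bins.
#' @param feedback_taps past predictions fed back (output-feedback only).
#' @param folds cross-validation folds.
#' @param restarts random restarts per fold (best by validation loss).
#' @param val_fraction contiguous fraction of training bins held out for
#'   early stopping.
#' @param val_failures validation failures tolerated before stopping.
#' @param cg_iters conjugate-gradient iterations per round.
#' @param max_rounds cap on training rounds.
#' @param max_train cap on training bins per fold (a deterministic stride
#'   subsample keeps fits tractable at desk scale).
#' @param l2 ridge penalty on the weights.
#' @return an object of class `decoder_spec`.
#' @export
decoder_spec <- function(architecture = c("feedforward", "output-feedback"),
                         hidden = NULL, window = 5, feedback_taps = 3,
                         folds = 10, restarts = 5, val_fraction = 0.15,
                         val_failures = 15, cg_iters = 8, max_rounds = 40,
                         max_train = 3000, l2 = 1e-4) {
  architecture <- match.arg(architecture)
  structure(list(architecture = architecture, hidden = hidden,
                 window = window, feedback_taps = feedback_taps,
                 folds = folds, restarts = restarts,
                 val_fraction = val_fraction, val_failures = val_failures,
                 cg_iters = cg_iters, max_rounds = max_rounds,
                 max_train = max_train, l2 = l2),
            class = "decoder_spec")
}

# ---- multilayer perceptron with tanh hidden layer -------------------------

mlp_init <- function(d, h, m, seed) {
  set.seed(seed)
  r1 <- 1 / sqrt(d + 1)
  r2 <- 1 / sqrt(h + 1)
  list(W1 = matrix(stats::runif(h * d, -r1, r1), h, d),
       b1 = stats::runif(h, -r1, r1),
       W2 = matrix(stats::runif(m * h, -r2, r2), m, h),
       b2 = stats::runif(m, -r2, r2))
}

mlp_pack <- function(w) c(w$W1, w$b1, w$W2, w$b2)

mlp_unpack <- function(par, d, h, m) {
  i1 <- h * d
  list(W1 = matrix(par[seq_len(i1)], h, d),
       b1 = par[i1 + seq_len(h)],
       W2 = matrix(par[i1 + h + seq_len(m * h)], m, h),
       b2 = par[i1 + h + m * h + seq_len(m)])
}

mlp_forward <- function(w, X) {
  A <- tanh(tcrossprod(w$W1, X) + w$b1)
  t(w$W2 %*% A + w$b2)
}

mlp_loss <- function(w, X, Y, l2) {
  P <- mlp_forward(w, X)
  mean(rowSums((P - Y)^2)) / 2 +
    l2 * (sum(w$W1^2) + sum(w$W2^2)) / 2
}

# objective/gradient pair sharing one cached forward pass (optim calls fn
# and gr at the same parameter vector; recomputing the hidden layer would
# double the cost of every conjugate-gradient step)
mlp_obj <- function(Xt, Yt, d, h, m, l2) {
  n <- ncol(Xt)
  cache <- new.env(parent = emptyenv())
  forward <- function(par) {
    if (!identical(par, cache$par)) {
      w <- mlp_unpack(par, d, h, m)
      A <- tanh(w$W1 %*% Xt + w$b1)   # h x n
      cache$par <- par
      cache$w <- w
      cache$A <- A
      cache$E <- w$W2 %*% A + w$b2 - Yt  # m x n
    }
    NULL
  }
  fn <- function(par) {
    forward(par)
    w <- cache$w
    sum(cache$E^2) / (2 * n) + l2 * (sum(w$W1^2) + sum(w$W2^2)) / 2
  }
  gr <- function(par) {
    forward(par)
    w <- cache$w; A <- cache$A; E <- cache$E
    dW2 <- tcrossprod(E, A) / n + l2 * w$W2
    db2 <- rowMeans(E)
    dZ <- crossprod(w$W2, E) * (1 - A^2)  # h x n
    dW1 <- tcrossprod(dZ, Xt) / n + l2 * w$W1
    db1 <- rowMeans(dZ)
    c(dW1, db1, dW2, db2)
  }
  list(fn = fn, gr = gr)
}

#' Train the decoder network with early stopping
#'
#' Conjugate-gradient (Fletcher-Reeves) rounds on the training loss; after
#' each round the validation loss is checked and the best weights kept;
#' training stops after `val_failures` rounds without improvement.
#'
#' @param X,Y training inputs (n x d) and targets (n x m).
#' @param Xval,Yval validation split for early stopping.
#' @param hidden hidden units.
#' @param spec a [decoder_spec()].
#' @param seed RNG seed for the weight initialization.
#' @return list: `weights`, `val_loss`, `rounds`.
#' @export
train_mlp <- function(X, Y, Xval, Yval, hidden, spec = decoder_spec(),
                      seed = 1) {
  d <- ncol(X); m <- ncol(Y); h <- hidden
  w <- mlp_init(d, h, m, seed)
  par <- mlp_pack(w)
  obj <- mlp_obj(t(X), t(Y), d, h, m, spec$l2)
  fn <- obj$fn
  gr <- obj$gr
  best <- par
  best_val <- mlp_loss(w, Xval, Yval, 0)
  failures <- 0L
  rounds <- 0L
  while (rounds < spec$max_rounds && failures < spec$val_failures) {
    rounds <- rounds + 1L
    opt <- stats::optim(par, fn, gr, method = "CG",
                        control = list(maxit = spec$cg_iters, type = 1))
    par <- opt$par
    val <- mlp_loss(mlp_unpack(par, d, h, m), Xval, Yval, 0)
    if (val < best_val - 1e-10) {
      best_val <- val
      best <- par
      failures <- 0L
    } else {
      failures <- failures + 1L
    }
  }
  list(weights = mlp_unpack(best, d, h, m), val_loss = best_val,
       rounds = rounds)
}

# ---- input/target assembly ------------------------------------------------

# lagged design: row t holds z-counts at t, t-1, ..., t-(window-1)
lagged_inputs <- function(z, window) {
  nb <- ncol(z)
  nn <- nrow(z)
  X <- matrix(0, nb, nn * window)
  for (k in seq_len(window)) {
    src <- pmax(seq_len(nb) - (k - 1L), 1L)
    X[, (k - 1L) * nn + seq_len(nn)] <- t(z[, src, drop = FALSE])
  }
  valid <- seq_len(nb) >= window
  attr(X, "valid") <- valid
  X
}

decode_targets <- function(session, target) {
  cov <- session$covariates
  if (target == "position") {
    cbind(cov$x, cov$y)
  } else {
    a <- cov[[target]] * pi / 180
    cbind(sin(a), cos(a))
  }
}

# contiguous fold assignment at trial granularity
trial_folds <- function(trial_id, folds) {
  trials <- unique(trial_id)
  grp <- ceiling(seq_along(trials) / (length(trials) / folds))
  grp[grp > folds] <- folds
  split(trials, grp)
}

#' Mean prediction error of the occupancy-centroid predictor
#'
#' The constant predictor that always outputs the centroid of the occupied
#' positions; its MPE (mean Euclidean distance from the centroid) is the
#' closed-form chance-level ceiling any trained position decoder must beat.
#'
#' @param xy two-column matrix of positions.
#' @return mean distance from the centroid.
#' @export
centroid_mpe <- function(xy) {
  ctr <- colMeans(xy)
  mean(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
}

#' Correlation metrics for angular decoding
#'
#' Pearson correlation computed per component (sine, cosine) between
#' predictions and targets and averaged; the angle reconstructed by the
#' two-argument arctangent gives a mean absolute circular error.
#'
#' @param pred n x 2 matrix of predicted (sin, cos).
#' @param actual_deg actual angles in degrees.
#' @return list: `cc`, `cc_sin`, `cc_cos`, `circ_err_deg`.
#' @export
angle_metrics <- function(pred, actual_deg) {
  a <- actual_deg * pi / 180
  cs <- stats::cor(pred[, 1], sin(a))
  cc <- stats::cor(pred[, 2], cos(a))
  ang <- atan2(pred[, 1], pred[, 2]) * 180 / pi
  ce <- mean(abs(wrap_angle(ang - actual_deg)))
  list(cc = mean(c(cs, cc)), cc_sin = cs, cc_cos = cc, circ_err_deg = ce)
}

#' Cross-validated decoding of position or orientation
#'
#' Pre-docking bins are split into contiguous folds at trial granularity
#' (no trial straddles folds); per fold the network is trained
#' `spec$restarts` times from random initializations with a contiguous 15%
#' validation split for early stopping, the restart with the lowest
#' validation loss is evaluated on the held-out fold, and the session
#' metric is the median over folds (MPE in meters for position, CC for
#' angles).
#'
#' @param session a [session_data()].
#' @param target `"position"`, `"alpha"` or `"beta"`.
#' @param neurons neuron indices forming the decoded population (>= 3).
#' @param spec a [decoder_spec()].
#' @param seed RNG seed (folds are deterministic; restarts derive sub-seeds).
#' @param counts optional replacement counts matrix (used by the chance
#'   machinery); defaults to the session's spikes.
#' @return an object of class `decoder_result`: `fold_metric`,
#'   `session_metric`, per-bin test `predictions`, `actuals`, `bin_index`,
#'   plus `errors` (position only).
#' @export
crossvalidated_decode <- function(session, target = "position",
                                  neurons = NULL, spec = decoder_spec(),
                                  seed = 1, counts = NULL) {
  target <- match.arg(target, c("position", "alpha", "beta"))
  if (is.null(neurons)) neurons <- seq_len(nrow(session$spikes))
  if (length(neurons) < 3) stop("decoding needs at least 3 neurons")
  if (is.null(counts)) counts <- session$spikes
  hidden <- if (!is.null(spec$hidden)) spec$hidden else
    if (target == "position") 30 else 10
  z <- zscore_counts(counts[neurons, , drop = FALSE])
  X <- lagged_inputs(z, spec$window)
  Y <- decode_targets(session, target)
  usable <- which(attr(X, "valid") &
                    session$covariates$zone == "navigation")
  tf <- trial_folds(session$covariates$trial_id[usable], spec$folds)
  fb <- spec$architecture == "output-feedback"
  taps <- if (fb) spec$feedback_taps else 0L

  fold_metric <- numeric(length(tf))
  preds <- acts <- list()
  bin_idx <- list()
  for (f in seq_along(tf)) {
    test <- usable[session$covariates$trial_id[usable] %in% tf[[f]]]
    train_all <- setdiff(usable, test)
    nval <- max(1L, round(length(train_all) * spec$val_fraction))
    val <- train_all[(length(train_all) - nval + 1L):length(train_all)]
    train <- setdiff(train_all, val)

    add_feedback <- function(rows) {
      if (!fb) return(X[rows, , drop = FALSE])
      FB <- do.call(cbind, lapply(seq_len(taps), function(k) {
        Y[pmax(rows - k, 1L), , drop = FALSE]  # teacher forcing
      }))
      cbind(X[rows, , drop = FALSE], FB)
    }
    if (length(train) > spec$max_train) {
      train <- train[round(seq(1, length(train), length.out = spec$max_train))]
    }
    Xtr <- add_feedback(train); Ytr <- Y[train, , drop = FALSE]
    Xva <- add_feedback(val); Yva <- Y[val, , drop = FALSE]
    best <- NULL
    for (rst in seq_len(spec$restarts)) {
      m <- train_mlp(Xtr, Ytr, Xva, Yva, hidden, spec,
                     seed = seed * 1000L + f * 10L + rst)
      if (is.null(best) || m$val_loss < best$val_loss) best <- m
    }
    P <- if (!fb) {
      mlp_forward(best$weights, X[test, , drop = FALSE])
    } else {
      # closed-loop evaluation: feed back own predictions
      P <- matrix(0, length(test), ncol(Y))
      hist_pred <- Y[pmax(test[1] - seq_len(taps), 1L), , drop = FALSE]
      for (i in seq_along(test)) {
        xi <- c(X[test[i], ], t(hist_pred))
        P[i, ] <- mlp_forward(best$weights, matrix(xi, 1))
        hist_pred <- rbind(P[i, , drop = FALSE],
                           hist_pred[-taps, , drop = FALSE])
      }
      P
    }
    A <- Y[test, , drop = FALSE]
    fold_metric[f] <- if (target == "position") {
      mean(sqrt(rowSums((P - A)^2)))
    } else {
      angle_metrics(P, session$covariates[[target]][test])$cc
    }
    preds[[f]] <- P; acts[[f]] <- A; bin_idx[[f]] <- test
  }
  pred_all <- do.call(rbind, preds)
  act_all <- do.call(rbind, acts)
  bins_all <- unlist(bin_idx)
  res <- list(target = target, fold_metric = fold_metric,
              session_metric = stats::median(fold_metric),
              predictions = pred_all, actuals = act_all,
              bin_index = bins_all, neurons = neurons, spec = spec)
  if (target == "position") {
    res$errors <- sqrt(rowSums((pred_all - act_all)^2))
  }
  structure(res, class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  unit <- if (x$target == "position") "m (MPE)" else "(CC)"
  cat(sprintf("decoder_result: %s, session metric %.3f %s over %d folds\n",
              x$target, x$session_metric, unit, length(x$fold_metric)))
  invisible(x)
}

#' Shuffle-based chance decoding distribution
#'
#' Each repetition first circularly shifts the spike counts by a random 10
#' to 50 s relative to the covariates, then permutes the time order of the
#' count vectors (destroying autocorrelation), retrains the decoder and
#' records the session metric. The empirical 2.5/97.5% quantiles give the
#' chance 95% CI and the actual performance's p-value is its rank in the
#' chance distribution.
#'
#' Chance repetitions use a lighter training schedule (`chance_folds`
#' folds, one restart) than the actual decode; the chance statistic is the
#' same session-median metric.
#'
#' @inheritParams crossvalidated_decode
#' @param n repetitions.
#' @param actual optional observed session metric to score.
#' @param chance_folds folds per chance repetition.
#' @return list: `ci` (2.5/97.5% quantiles), `values`, `p` (when `actual`
#'   given), `significant`.
#' @export
chance_distribution <- function(session, target = "position", neurons = NULL,
                                spec = decoder_spec(), n = 100, seed = 1,
                                actual = NULL, chance_folds = 2) {
  set.seed(seed)
  nb <- ncol(session$spikes)
  cspec <- spec
  cspec$folds <- chance_folds
  cspec$restarts <- 1
  vals <- numeric(n)
  for (i in seq_len(n)) {
    sh <- sample(100:500, 1) * sample(c(-1L, 1L), 1)
    idx <- ((seq_len(nb) - 1L + sh) %% nb) + 1L
    shuffled <- sample(nb)
    cnt <- session$spikes[, idx, drop = FALSE][, shuffled, drop = FALSE]
    r <- crossvalidated_decode(session, target, neurons, cspec,
                               seed = seed + i, counts = cnt)
    vals[i] <- r$session_metric
  }
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  out <- list(ci = ci, values = vals)
  if (!is.null(actual)) {
    if (target == "position") {
      out$p <- (1 + sum(vals <= actual)) / (1 + n)
      out$significant <- actual < ci[1]
    } else {
      out$p <- (1 + sum(vals >= actual)) / (1 + n)
      out$significant <- actual > ci[2]
    }
  }
  out
}

#' Spatial map of decoding error
#'
#' Held-out position errors are binned on the 5 cm grid, averaged, filled
#' and Gaussian-smoothed (5 x 5 kernel, sigma = 2 bins).
#'
#' @param result a position [crossvalidated_decode()] result.
#' @param session the decoded [session_data()].
#' @return list: `map` (ny x nx), `occupancy`.
#' @export
spatial_error_map <- function(result, session) {
  stopifnot(result$target == "position")
  grid <- position_grid(session$geometry, 0.05)
  cov <- session$covariates[result$bin_index, ]
  ix <- grid_bin_index(cov$x, grid$xedges)
  iy <- grid_bin_index(cov$y, grid$yedges)
  ok <- !is.na(ix) & !is.na(iy)
  cell <- (ix[ok] - 1L) * grid$ny + iy[ok]
  occ <- tabulate(cell, nbins = grid$ny * grid$nx)
  sums <- rep(0, grid$ny * grid$nx)
  agg <- rowsum(result$errors[ok], cell)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  raw <- matrix(NA_real_, grid$ny, grid$nx)
  raw[occ > 0] <- sums[occ > 0] / occ[occ > 0]
  list(map = fill_and_smooth(raw, kernel_size = 5, sigma = 2),
       occupancy = matrix(occ, grid$ny, grid$nx))
}
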