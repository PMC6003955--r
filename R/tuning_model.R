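#' Specification of the additive tuning model
#'
#' The full model regresses 100 ms spike counts on smooth functions of the
#' navigation covariates with a log link and quasi-Poisson variance:
#' bivariate tensor smooths for position (x, y) and kinematics (v, w),
#' cyclic smooths for the egocentric dispenser bearings alpha and beta, an
#' alpha x beta interaction, and smooths of the previous and next bin's
#' spike count to absorb autocorrelation. With `interactions = TRUE` all
#' second-order interaction tensors between the covariate blocks
#' (position x kinematics, position x angle, kinematics x angle) are added,
#' rank-limited by `k_int`.
#'
#' The position and kinematics main effects use full tensor products
#' (including their marginal bases) so that the bivariate tuning surface is
#' unconstrained; interaction terms use `ti()` so they exclude the main
#' effects they interact.
#'
#' @param k_pos marginal basis sizes for the position smooth (7 knots over
#'   a ~3 m room resolve fields down to ~0.4 m).
#' @param k_vel marginal basis sizes for the kinematics smooth.
#' @param k_angle basis size for each cyclic angular smooth.
#' @param k_lag basis size for the lag smooths.
#' @param k_int basis budget for interaction tensors: `c(bivariate-marginal,
#'   angle-marginal)`.
#' @param interactions include the second-order interaction tensors.
#' @return an object of class `tuning_model_spec`.
#' @export
tuning_model_spec <- function(k_pos = c(7, 7), k_vel = c(4, 4),
                              k_angle = 6, k_lag = 4,
                              k_int = c(9, 4), interactions = FALSE) {
  structure(list(k_pos = k_pos, k_vel = k_vel, k_angle = k_angle,
                 k_lag = k_lag, k_int = k_int, interactions = interactions),
            class = "tuning_model_spec")
}

# model frame for one neuron: pre-docking bins with lag/lead counts
model_frame <- function(session, neuron) {
  if (is.character(neuron)) neuron <- match(neuron, rownames(session$spikes))
  cov <- session$covariates
  y <- session$spikes[neuron, ]
  nb <- length(y)
  df <- data.frame(y = y, x = cov$x, yy = cov$y, v = cov$v, w = cov$w,
                   alpha = cov$alpha, beta = cov$beta,
                   lag1 = c(NA, y[-nb]), lead1 = c(y[-1], NA))
  df <- df[predocking_bins(session), ]
  df[stats::complete.cases(df), ]
}

model_terms <- function(spec, data) {
  main <- c(
    position = sprintf("te(x, yy, k = c(%d, %d))", spec$k_pos[1], spec$k_pos[2]),
    velocity = sprintf("te(v, w, k = c(%d, %d))", spec$k_vel[1], spec$k_vel[2]),
    alpha = sprintf("s(alpha, bs = 'cc', k = %d)", spec$k_angle),
    beta = sprintf("s(beta, bs = 'cc', k = %d)", spec$k_angle))
  inter <- sprintf("ti(alpha, beta, bs = c('cc', 'cc'), k = c(%d, %d))",
                   spec$k_int[2], spec$k_int[2])
  if (spec$interactions) {
    inter <- c(inter,
      sprintf("ti(x, yy, v, w, k = c(%d, %d), d = c(2, 2))",
              spec$k_int[1], spec$k_int[1]),
      sprintf("ti(x, yy, alpha, k = c(%d, %d), d = c(2, 1), bs = c('tp', 'cc'))",
              spec$k_int[1], spec$k_int[2]),
      sprintf("ti(x, yy, beta, k = c(%d, %d), d = c(2, 1), bs = c('tp', 'cc'))",
              spec$k_int[1], spec$k_int[2]),
      sprintf("ti(v, w, alpha, k = c(%d, %d), d = c(2, 1), bs = c('tp', 'cc'))",
              spec$k_int[1], spec$k_int[2]),
      sprintf("ti(v, w, beta, k = c(%d, %d), d = c(2, 1), bs = c('tp', 'cc'))",
              spec$k_int[1], spec$k_int[2]))
  }
  lags <- character(0)
  for (lv in c("lag1", "lead1")) {
    nu <- length(unique(data[[lv]]))
    if (nu > spec$k_lag) {
      lags <- c(lags, sprintf("s(%s, k = %d)", lv, spec$k_lag))
    } else if (nu > 1) {
      lags <- c(lags, lv)  # too few distinct counts for a smooth
    } else {
      warning("dropping constant lag covariate ", lv)
    }
  }
  # drop degenerate covariates (e.g. a session with no rotation)
  degen <- vapply(list(v = data$v, w = data$w, alpha = data$alpha,
                       beta = data$beta),
                  function(u) stats::sd(u) < 1e-8, TRUE)
  if (any(degen)) {
    warning("degenerate covariates dropped from model: ",
            paste(names(degen)[degen], collapse = ", "))
    if (degen[["v"]] || degen[["w"]]) main <- main[names(main) != "velocity"]
    if (degen[["alpha"]]) main <- main[names(main) != "alpha"]
    if (degen[["beta"]]) main <- main[names(main) != "beta"]
    inter <- inter[!(degen[["alpha"]] | degen[["beta"]])]
  }
  list(main = main, inter = inter, lags = lags)
}

build_formula <- function(terms, drop = character(0)) {
  main <- terms$main[setdiff(names(terms$main), drop)]
  rhs <- paste(c(main, terms$inter, terms$lags), collapse = " + ")
  stats::as.formula(paste("y ~", rhs))
}

angle_knots <- list(alpha = c(-180, 180), beta = c(-180, 180))

#' Fit the full additive tuning model for one neuron
#'
#' Quasi-Poisson penalized-spline fit on pre-docking bins, smoothing
#' parameters selected by fast REML (`mgcv::bam` with discretized
#' covariates, which is deterministic and an order of magnitude faster than
#' a dense GCV fit at identical recovered structure). Bins at trial edges
#' whose lag/lead counts are undefined are dropped.
#'
#' @param session a [session_data()].
#' @param neuron neuron index or rowname.
#' @param spec a [tuning_model_spec()].
#' @return an object of class `tuning_model_fit`: the `mgcv::gam` fit plus
#'   the model frame, term table and spec.
#' @export
fit_full_model <- function(session, neuron, spec = tuning_model_spec()) {
  data <- model_frame(session, neuron)
  terms <- model_terms(spec, data)
  fml <- build_formula(terms)
  # covariate discretization cannot represent the full interaction nesting
  disc <- !spec$interactions
  fit <- mgcv::bam(fml, family = stats::quasipoisson(link = "log"),
                   data = data, knots = angle_knots, method = "fREML",
                   discrete = disc)
  if (!fit$converged) stop("full model did not converge for neuron ", neuron,
                           " (deviance ", round(stats::deviance(fit), 2), ")")
  structure(list(fit = fit, data = data, terms = terms, spec = spec,
                 neuron = neuron, geometry = session$geometry,
                 discrete = disc),
            class = "tuning_model_fit")
}

#' @export
print.tuning_model_fit <- function(x, ...) {
  cat(sprintf("tuning_model_fit: neuron %s, deviance %.1f, edf %.1f, phi %.2f\n",
              as.character(x$neuron), stats::deviance(x$fit),
              sum(x$fit$edf), x$fit$sig2))
  invisible(x)
}

# smoothing parameters of the full fit restricted to the kept terms
sp_for_partial <- function(fit, dropped_labels) {
  sp <- fit$sp
  keep <- !vapply(names(sp), function(nm) {
    any(vapply(dropped_labels, function(lb) {
      nm == lb || (startsWith(nm, lb) &&
                     grepl("^[0-9]+$", substring(nm, nchar(lb) + 1L)))
    }, TRUE))
  }, TRUE)
  sp[keep]
}

#' McFadden's pseudo R-squared from nested deviances
#'
#' `TD = 1 - DF/DP` for a full-model deviance `DF` nested in a partial
#' model with deviance `DP`; clamped to 0 when the penalized refit yields
#' `DP < DF`.
#'
#' @param df_full,df_partial deviances of the full and partial models.
#' @return tuning depth in \[0, 1\].
#' @export
mcfadden_td <- function(df_full, df_partial) {
  if (df_partial <= 0) stop("partial deviance must be positive")
  max(0, 1 - df_full / df_partial)
}

#' Tuning depth of a covariate group by nested-model deviance
#'
#' The partial model removes only the group's main-effect terms (position:
#' the bivariate position smooth; orientation: both angular smooths),
#' keeping every interaction, and is refit with the full model's smoothing
#' parameters held fixed so the comparison is between nested mean
#' structures. Tuning depth is McFadden's pseudo R-squared
#' `TD = 1 - DF/DP`; an F-test `((DP - DF)/ddf) / phi` with the full-model
#' dispersion assesses whether the group contributes.
#'
#' @param full a [fit_full_model()] result.
#' @param group `"position"` or `"orientation"`.
#' @return list: `td`, `p`, `df_full`, `df_partial` (deviances), `ddf`,
#'   `fstat`, `clamped` (TRUE when the penalized refit gave DP < DF).
#' @export
tuning_depth <- function(full, group = c("position", "orientation")) {
  group <- match.arg(group)
  drop <- if (group == "position") "position" else c("alpha", "beta")
  drop <- intersect(drop, names(full$terms$main))
  if (!length(drop)) {
    return(list(td = 0, p = 1, df_full = stats::deviance(full$fit),
                df_partial = stats::deviance(full$fit), ddf = 0,
                fstat = 0, clamped = FALSE))
  }
  labels <- vapply(full$fit$smooth, function(s) s$label, "")
  drop_labels <- labels[vapply(full$fit$smooth, function(s) {
    vars <- s$term
    if (group == "position") identical(sort(vars), sort(c("x", "yy"))) &&
      startsWith(s$label, "te(") else
        (identical(vars, "alpha") || identical(vars, "beta")) &&
      startsWith(s$label, "s(")
  }, TRUE)]
  fml <- build_formula(full$terms, drop = drop)
  sp <- sp_for_partial(full$fit, drop_labels)
  partial <- mgcv::bam(fml, family = stats::quasipoisson(link = "log"),
                       data = full$data, knots = angle_knots, sp = sp,
                       discrete = isTRUE(full$discrete))
  df_f <- stats::deviance(full$fit)
  df_p <- stats::deviance(partial)
  clamped <- df_p < df_f
  td <- mcfadden_td(df_f, df_p)
  ddf <- stats::df.residual(partial) - stats::df.residual(full$fit)
  phi <- full$fit$sig2
  if (ddf <= 0 || clamped) {
    fstat <- 0
    p <- 1
  } else {
    # a fully shrunk smooth can leave ddf near zero, which would inflate F
    # out of a vanishing deviance difference; floor at one denominator df
    ddf <- max(ddf, 1)
    fstat <- ((df_p - df_f) / ddf) / phi
    p <- stats::pf(fstat, ddf, stats::df.residual(full$fit),
                   lower.tail = FALSE)
  }
  list(td = td, p = p, df_full = df_f, df_partial = df_p, ddf = ddf,
       fstat = fstat, clamped = clamped)
}

#' Fit tuning models and tuning depths for a set of neurons
#'
#' @param session a [session_data()].
#' @param neurons neuron indices or rownames (default: all).
#' @param spec a [tuning_model_spec()].
#' @param keep_fits retain the fitted models (memory-heavy).
#' @return an object of class `tuning_assessment`: data.frame `table` with
#'   one row per neuron (`td_position`, `p_position`, `td_orientation`,
#'   `p_orientation`, `edf`, `phi`) plus `fits` when requested.
#' @export
assess_tuning <- function(session, neurons = NULL,
                          spec = tuning_model_spec(), keep_fits = FALSE) {
  if (is.null(neurons)) neurons <- seq_len(nrow(session$spikes))
  fits <- if (keep_fits) vector("list", length(neurons)) else NULL
  rows <- vector("list", length(neurons))
  for (j in seq_along(neurons)) {
    full <- fit_full_model(session, neurons[j], spec)
    tp <- tuning_depth(full, "position")
    to <- tuning_depth(full, "orientation")
    rows[[j]] <- data.frame(
      neuron = if (is.character(neurons[j])) neurons[j] else
        rownames(session$spikes)[neurons[j]],
      td_position = tp$td, p_position = tp$p,
      td_orientation = to$td, p_orientation = to$p,
      edf = sum(full$fit$edf), phi = full$fit$sig2)
    if (keep_fits) fits[[j]] <- full
  }
  tab <- do.call(rbind, rows)
  tab <- classify_preference(tab)
  structure(list(table = tab, fits = fits, spec = spec),
            class = "tuning_assessment")
}

#' Classify neurons as position- or orientation-preferring
#'
#' A neuron is assessed when at least one covariate group is significant
#' (F-test p < `p_cut`); its preference is the group with the larger TD
#' (ties by smaller p, then position). Highly tuned neurons are those whose
#' preferred TD strictly exceeds the median preferred TD of the assessed
#' neurons in the session.
#'
#' @param tab data.frame with columns `td_position`, `p_position`,
#'   `td_orientation`, `p_orientation`.
#' @param p_cut significance cutoff for the group F-tests.
#' @return `tab` with added `preference` (`"position"`, `"orientation"` or
#'   `NA`), `preferred_td` and `highly_tuned` columns.
#' @export
classify_preference <- function(tab, p_cut = 0.005) {
  pref <- rep(NA_character_, nrow(tab))
  assessed <- pmin(tab$p_position, tab$p_orientation) < p_cut
  for (i in which(assessed)) {
    if (tab$td_position[i] > tab$td_orientation[i]) pref[i] <- "position"
    else if (tab$td_position[i] < tab$td_orientation[i]) pref[i] <- "orientation"
    else if (tab$p_position[i] < tab$p_orientation[i]) pref[i] <- "position"
    else if (tab$p_position[i] > tab$p_orientation[i]) pref[i] <- "orientation"
    else pref[i] <- "position"  # documented arbitrary tie-break
  }
  preferred_td <- ifelse(is.na(pref), NA_real_,
                         ifelse(pref == "position", tab$td_position,
                                tab$td_orientation))
  med <- stats::median(preferred_td, na.rm = TRUE)
  tab$preference <- pref
  tab$preferred_td <- preferred_td
  tab$highly_tuned <- !is.na(preferred_td) & preferred_td > med
  tab
}

#' Fitted position tuning surface on the 5 cm grid
#'
#' Evaluates the bivariate position term of the fitted model at the centers
#' of the 5 cm bins covering the drivable area (other covariates do not
#' enter a term-wise prediction). Bins never visited in the fitting data
#' are NA: spline extrapolation outside the sampled region is meaningless
#' and would corrupt argmax-based summaries.
#'
#' @param full a [fit_full_model()] result.
#' @param bin_size grid resolution in meters.
#' @return list: `surface` (ny x nx matrix, NA where unsupported),
#'   `xcenters`, `ycenters`.
#' @export
extract_position_surface <- function(full, bin_size = 0.05) {
  grid <- position_grid(full$geometry, bin_size)
  xc <- grid$xedges[-1] - bin_size / 2
  yc <- grid$yedges[-1] - bin_size / 2
  nd <- expand.grid(yy = yc, x = xc)
  nd$v <- 0; nd$w <- 0; nd$alpha <- 0; nd$beta <- 0; nd$lag1 <- 0; nd$lead1 <- 0
  lab <- grep("^te\\(x", vapply(full$fit$smooth, function(s) s$label, ""),
              value = TRUE)
  if (!length(lab)) stop("model has no position term")
  pr <- stats::predict(full$fit, newdata = nd, type = "terms", terms = lab)
  surface <- matrix(rowSums(as.matrix(pr)), length(yc), length(xc))
  ix <- grid_bin_index(full$data$x, grid$xedges)
  iy <- grid_bin_index(full$data$yy, grid$yedges)
  visited <- matrix(FALSE, length(yc), length(xc))
  visited[cbind(iy, ix)] <- TRUE
  # dilate the support by two bins (0.1 m): interpolation across small
  # gaps in coverage is fine, extrapolation beyond it is not
  for (pass in 1:2) {
    idx <- which(visited, arr.ind = TRUE)
    for (di in -1:1) for (dj in -1:1) {
      ii <- pmin(pmax(idx[, 1] + di, 1L), nrow(visited))
      jj <- pmin(pmax(idx[, 2] + dj, 1L), ncol(visited))
      visited[cbind(ii, jj)] <- TRUE
    }
  }
  surface[!visited] <- NA_real_
  list(surface = surface, xcenters = xc, ycenters = yc)
}

#' Fitted angular tuning curve on a 1 degree grid
#'
#' @param full a [fit_full_model()] result.
#' @param var `"alpha"` or `"beta"`.
#' @return list: `angle` (degrees, -180..179), `value`.
#' @export
extract_angle_curve <- function(full, var = c("alpha", "beta")) {
  var <- match.arg(var)
  ang <- seq(-180, 179, by = 1)
  nd <- data.frame(x = 0, yy = 0, v = 0, w = 0, alpha = 0, beta = 0,
                   lag1 = 0, lead1 = 0)[rep(1, length(ang)), ]
  nd[[var]] <- ang
  lab <- sprintf("s(%s)", var)
  labels <- vapply(full$fit$smooth, function(s) s$label, "")
  if (!lab %in% labels) stop("model has no ", var, " term")
  pr <- stats::predict(full$fit, newdata = nd, type = "terms", terms = lab)
  list(angle = ang, value = as.numeric(pr))
}
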