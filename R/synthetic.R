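#' Planted tuning specification for one synthetic neuron
#'
#' The per-bin log firing rate of a synthetic neuron is
#' `baseline + position_gain * G(x, y) + alpha_gain * V(alpha) +
#'  beta_gain * V(beta) + log(reach_gain) * 1[zone == reach] +
#'  lag_coef * (previous count - mean count)`,
#' where `G` is a Gaussian place field normalized to peak 1 and `V` is a
#' von Mises bump `exp(kappa * (cos(angle - mu) - 1))` also peaking at 1, so
#' each gain is the peak log-rate increase contributed by that covariate.
#' Counts are Poisson given the rate (doubly stochastic when `lag_coef > 0`).
#'
#' @param baseline_log_rate log expected spikes per 100 ms bin.
#' @param position_gain,field_center,field_sd Gaussian place-field parameters
#'   (gain >= 0; center in meters; isotropic sd in meters).
#' @param alpha_gain,alpha_mu,alpha_kappa von Mises tuning to the head-frame
#'   dispenser bearing alpha (mu in degrees).
#' @param beta_gain,beta_mu,beta_kappa likewise for the chair-frame bearing.
#' @param reach_gain multiplicative rate factor inside the reach zone (>= 1).
#' @param lag_coef autoregressive coefficient on the previous realized count,
#'   in \[0, 0.9\].
#' @param area cortical area label.
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(baseline_log_rate = log(0.5),
                        position_gain = 0, field_center = c(0, 0),
                        field_sd = 0.4,
                        alpha_gain = 0, alpha_mu = 0, alpha_kappa = 3,
                        beta_gain = 0, beta_mu = 0, beta_kappa = 3,
                        reach_gain = 1, lag_coef = 0, area = "M1") {
  stopifnot(position_gain >= 0, alpha_gain >= 0, beta_gain >= 0,
            reach_gain >= 1, lag_coef >= 0, lag_coef <= 0.9, field_sd > 0)
  structure(list(baseline_log_rate = baseline_log_rate,
                 position_gain = position_gain,
                 field_center = as.numeric(field_center),
                 field_sd = field_sd,
                 alpha_gain = alpha_gain, alpha_mu = alpha_mu,
                 alpha_kappa = alpha_kappa,
                 beta_gain = beta_gain, beta_mu = beta_mu,
                 beta_kappa = beta_kappa,
                 reach_gain = reach_gain, lag_coef = lag_coef, area = area),
            class = "neuron_spec")
}

#' Von Mises bump normalized to peak 1
#'
#' @param angle,mu degrees; @param kappa concentration.
#' @return values in (0, 1\].
#' @export
von_mises_bump <- function(angle, mu, kappa) {
  exp(kappa * (cos((angle - mu) * pi / 180) - 1))
}

#' Build a mixed population with planted tuning classes
#'
#' Classes are `position` (place field only), `orientation` (von Mises
#' tuning to alpha or beta only), `mixed` (both) and `untuned` (baseline
#' only). Requested counts are realized exactly. A fraction of neurons in
#' every class additionally receives reach-gain modulation.
#'
#' @param n_position,n_orientation,n_mixed,n_untuned class counts.
#' @param geometry a [room_geometry()]; field centers are drawn inside the
#'   drivable area, outside the docking zone, with a wall margin.
#' @param position_gain,alpha_gain,field_sd,kappa default planted strengths.
#' @param reach_fraction fraction of neurons given `reach_gain`.
#' @param reach_gain reach-zone rate factor for those neurons.
#' @param lag_coef autoregressive coefficient applied to all neurons.
#' @param baseline_log_rate baseline log rate per bin.
#' @param seed RNG seed for the parameter draws.
#' @return an object of class `ground_truth`: list with `neurons` (list of
#'   [neuron_spec()]), `class` (character per neuron) and the seed.
#' @export
make_population <- function(n_position = 20, n_orientation = 20,
                            n_mixed = 0, n_untuned = 20,
                            geometry = room_geometry(),
                            position_gain = 1.5, alpha_gain = 1.2,
                            field_sd = 0.4, kappa = 3,
                            reach_fraction = 0, reach_gain = 2,
                            lag_coef = 0, baseline_log_rate = log(0.5),
                            seed = 1) {
  set.seed(seed)
  classes <- rep(c("position", "orientation", "mixed", "untuned"),
                 c(n_position, n_orientation, n_mixed, n_untuned))
  n <- length(classes)
  half <- drivable_half(geometry)
  margin <- 0.25
  draw_center <- function() {
    repeat {
      c0 <- c(stats::runif(1, -half[1] + margin, half[1] - margin),
              stats::runif(1, -half[2] + margin, half[2] - margin))
      r0 <- sqrt(sum((c0 - geometry$dispenser_xy)^2))
      if (r0 > geometry$docking_radius + 0.1) return(c0)
    }
  }
  areas <- sample(c("S1", "M1", "PMd"), n, replace = TRUE)
  has_reach <- stats::runif(n) < reach_fraction
  neurons <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    pos_g <- if (cls %in% c("position", "mixed")) position_gain else 0
    use_alpha <- stats::runif(1) < 0.5
    a_g <- if (cls == "orientation" && use_alpha) alpha_gain else
      if (cls == "mixed") alpha_gain else 0
    b_g <- if (cls == "orientation" && !use_alpha) alpha_gain else 0
    neurons[[i]] <- neuron_spec(
      baseline_log_rate = baseline_log_rate,
      position_gain = pos_g,
      field_center = if (pos_g > 0) draw_center() else c(0, 0),
      field_sd = field_sd,
      alpha_gain = a_g, alpha_mu = stats::runif(1, -180, 180),
      alpha_kappa = kappa,
      beta_gain = b_g, beta_mu = stats::runif(1, -180, 180),
      beta_kappa = kappa,
      reach_gain = if (has_reach[i]) reach_gain else 1,
      lag_coef = lag_coef, area = areas[i])
  }
  structure(list(neurons = neurons, class = classes, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$neurons), "neurons (",
      paste(names(table(x$class)), table(x$class), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Simulate wheelchair navigation trajectories
#'
#' Each trial starts at one of the three start points (cycled in order) with
#' a random initial heading, wanders through one or two random waypoints
#' under a noisy proportional-steering controller, then heads for the
#' dispenser. On entering the docking zone a deterministic autopilot turns
#' toward the dispenser, drives in, and dwells near it (the reach period)
#' before the trial ends. Commanded velocities are clipped to +/-`v_max` and
#' +/-`w_max` and positions to the drivable bounds.
#'
#' @param geometry a [room_geometry()].
#' @param n_trials number of trials (>= 1).
#' @param seed RNG seed.
#' @param v_max,w_max command limits (0.28 m/s, 46 deg/s).
#' @param n_waypoints random waypoints visited before the dispenser run.
#' @param steer_gain proportional heading gain (per second).
#' @param steer_noise_sd innovation sd of the AR(1) turning noise (deg/s).
#' @param speed_noise_sd innovation sd of the AR(1) speed noise (m/s).
#' @param side_bias probability that a waypoint is drawn on the start side
#'   of the room (behavioral side preference knob).
#' @param reach_dwell_s dwell time near the dispenser at trial end.
#' @param max_duration_s per-trial cap; longer trials are truncated and
#'   flagged in the `truncated` attribute.
#' @return data.frame of poses (`t`, `x`, `y`, `chair_heading`,
#'   `head_heading`, `trial_id`) at 10 Hz.
#' @export
simulate_trajectories <- function(geometry, n_trials, seed = 1,
                                  v_max = 0.28, w_max = 46,
                                  n_waypoints = 2,
                                  steer_gain = 2.5,
                                  steer_noise_sd = 14,
                                  speed_noise_sd = 0.05,
                                  side_bias = 0.5,
                                  reach_dwell_s = 2,
                                  max_duration_s = 120) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  dt <- 0.1
  half <- drivable_half(geometry)
  margin <- 0.15
  disp <- geometry$dispenser_xy
  trials <- vector("list", n_trials)
  truncated <- logical(n_trials)
  for (trial in seq_len(n_trials)) {
    start <- geometry$start_xy[(trial - 1L) %% 3L + 1L, ]
    start_side <- sign(start[2] + 1e-9)
    draw_waypoint <- function() {
      side <- if (stats::runif(1) < side_bias) start_side else -start_side
      c(stats::runif(1, -half[1] + margin, half[1] - margin),
        side * stats::runif(1, 0, half[2] - margin))
    }
    targets <- c(lapply(seq_len(n_waypoints), function(i) draw_waypoint()),
                 list(disp))
    pos <- start
    h <- stats::runif(1, -180, 180)
    head_off <- stats::runif(1, -75, 75)
    w_noise <- 0
    v_noise <- 0
    ti <- 1L
    max_steps <- round(max_duration_s / dt)
    xs <- ys <- chs <- hhs <- numeric(0)
    phase <- "drive"
    dwell_left <- round(reach_dwell_s / dt)
    step <- 0L
    repeat {
      step <- step + 1L
      if (step > max_steps) { truncated[trial] <- TRUE; break }
      r <- sqrt(sum((pos - disp)^2))
      if (phase == "drive" && r <= geometry$docking_radius) phase <- "dock"
      target <- targets[[ti]]
      if (phase == "drive") {
        if (ti <= n_waypoints &&
            sqrt(sum((pos - target)^2)) < 0.35) {
          ti <- ti + 1L
          target <- targets[[ti]]
        }
        err <- wrap_angle(bearing_deg(pos, target) - h)
        w_noise <- 0.8 * w_noise + stats::rnorm(1, 0, steer_noise_sd)
        v_noise <- 0.9 * v_noise + stats::rnorm(1, 0, speed_noise_sd)
        w_cmd <- max(-w_max, min(w_max, steer_gain * err + w_noise))
        v_cmd <- max(-v_max, min(v_max, 0.18 + v_noise))
      } else if (phase == "dock") {
        err <- wrap_angle(bearing_deg(pos, disp) - h)
        w_cmd <- max(-w_max, min(w_max, 3 * err))
        v_cmd <- if (abs(err) < 20) min(0.2, v_max) else 0
        if (r <= geometry$reach_radius * 0.8) phase <- "dwell"
      }
      if (phase == "dwell") {
        w_cmd <- 0
        v_cmd <- 0
        dwell_left <- dwell_left - 1L
      }
      h <- h + w_cmd * dt
      pos <- pos + heading_unit(h)[1, ] * v_cmd * dt
      pos <- as.numeric(clip_to_drivable(matrix(pos, ncol = 2), geometry))
      head_off <- max(-90, min(90, 0.97 * head_off + stats::rnorm(1, 0, 12)))
      xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      chs <- c(chs, wrap_angle(h)); hhs <- c(hhs, wrap_angle(h + head_off))
      if (phase == "dwell" && dwell_left <= 0L) break
    }
    trials[[trial]] <- data.frame(x = xs, y = ys, chair_heading = chs,
                                  head_heading = hhs, trial_id = trial)
  }
  out <- do.call(rbind, trials)
  out <- data.frame(t = seq_len(nrow(out)) * dt - dt, out)
  attr(out, "truncated") <- truncated
  out
}

#' Generate Poisson spike counts with planted tuning
#'
#' @param covariates a `covariate_frame`.
#' @param ground_truth a [make_population()] result.
#' @param seed RNG seed.
#' @param rate_cap maximum allowed expected count per bin (error guard).
#' @return neurons x bins integer matrix with `area` attribute.
#' @export
generate_spikes <- function(covariates, ground_truth, seed = 1,
                            rate_cap = 50) {
  set.seed(seed)
  nb <- nrow(covariates)
  nn <- length(ground_truth$neurons)
  counts <- matrix(0L, nn, nb)
  in_reach <- covariates$zone == "reach"
  for (i in seq_len(nn)) {
    sp <- ground_truth$neurons[[i]]
    lograte <- rep(sp$baseline_log_rate, nb)
    if (sp$position_gain > 0) {
      d2 <- (covariates$x - sp$field_center[1])^2 +
        (covariates$y - sp$field_center[2])^2
      lograte <- lograte + sp$position_gain * exp(-d2 / (2 * sp$field_sd^2))
    }
    if (sp$alpha_gain > 0) {
      lograte <- lograte +
        sp$alpha_gain * von_mises_bump(covariates$alpha, sp$alpha_mu,
                                       sp$alpha_kappa)
    }
    if (sp$beta_gain > 0) {
      lograte <- lograte +
        sp$beta_gain * von_mises_bump(covariates$beta, sp$beta_mu,
                                      sp$beta_kappa)
    }
    if (sp$reach_gain > 1) lograte <- lograte + log(sp$reach_gain) * in_reach
    rate <- exp(lograte)
    if (any(rate > rate_cap)) {
      stop("rate cap exceeded for neuron ", i, " (max rate ",
           round(max(rate), 1), " spikes/bin)")
    }
    if (sp$lag_coef > 0) {
      mbar <- mean(rate)
      y <- integer(nb)
      prev <- mbar
      for (tt in seq_len(nb)) {
        lam <- rate[tt] * exp(sp$lag_coef * (prev - mbar))
        if (lam > rate_cap) {
          stop("rate cap exceeded (lag runaway) for neuron ", i)
        }
        y[tt] <- stats::rpois(1, lam)
        prev <- y[tt]
      }
      counts[i, ] <- y
    } else {
      counts[i, ] <- stats::rpois(nb, rate)
    }
  }
  rownames(counts) <- sprintf("n%03d", seq_len(nn))
  attr(counts, "area") <- vapply(ground_truth$neurons, `[[`, "", "area")
  counts
}

#' Simulate one complete session
#'
#' @param ground_truth a [make_population()] result.
#' @param n_trials number of navigation trials.
#' @param seed RNG seed (trajectory and spikes derive sub-seeds from it).
#' @param geometry a [room_geometry()].
#' @param session_id stored in metadata.
#' @param ... passed to [simulate_trajectories()].
#' @return a [session_data()].
#' @export
simulate_session <- function(ground_truth, n_trials = 30, seed = 1,
                             geometry = room_geometry(),
                             session_id = "synthetic", ...) {
  poses <- simulate_trajectories(geometry, n_trials, seed = seed, ...)
  cov <- compute_covariates(poses, geometry)
  spikes <- generate_spikes(cov, ground_truth, seed = seed + 1000L)
  session_data(geometry, cov, spikes,
               metadata = list(session_id = session_id, seed = seed,
                               class = ground_truth$class))
}

#' Simulate multiple sessions from one population
#'
#' In the `stable` condition the same planted parameters generate every
#' session (independent trajectories); in the `remap` condition the place
#' field centers of all position-tuned neurons and the preferred directions
#' of all direction-tuned neurons are re-drawn per session, a negative
#' control for cross-session consistency. Remapped field centers are drawn
#' over the whole room rather than the recoverable interior; see the
#' methods vignette for why a restricted redraw would bias the control.
#'
#' @param ground_truth a [make_population()] result.
#' @param n_sessions number of sessions.
#' @param seeds integer vector of per-session seeds (default `seed0 + 0:n`).
#' @param condition `"stable"` or `"remap"`.
#' @param n_trials trials per session.
#' @param geometry a [room_geometry()].
#' @param ... passed to [simulate_session()].
#' @return list of [session_data()]; each carries its (possibly remapped)
#'   ground truth in `metadata$ground_truth`.
#' @export
generate_multi_session <- function(ground_truth, n_sessions,
                                   seeds = NULL, condition = "stable",
                                   n_trials = 30,
                                   geometry = room_geometry(), ...) {
  condition <- match.arg(condition, c("stable", "remap"))
  if (is.null(seeds)) seeds <- ground_truth$seed * 100L + seq_len(n_sessions)
  stopifnot(length(seeds) == n_sessions)
  half <- drivable_half(geometry)
  out <- vector("list", n_sessions)
  prev <- ground_truth
  for (s in seq_len(n_sessions)) {
    gt <- ground_truth
    if (condition == "remap") {
      set.seed(seeds[s] + 5000L)
      for (i in seq_along(gt$neurons)) {
        if (gt$neurons[[i]]$position_gain > 0) {
          old <- prev$neurons[[i]]$field_center
          # independent redraw over the whole room: restricting remapped
          # centers to the well-sampled interior (as make_population does
          # for recoverability) would give all sessions a shared expected
          # tuning profile and bias the negative control positive; only
          # exact coincidence is rejected so centers provably differ
          rhalf <- geometry$room_size / 2
          repeat {
            c0 <- c(stats::runif(1, -rhalf[1], rhalf[1]),
                    stats::runif(1, -rhalf[2], rhalf[2]))
            if (sqrt(sum((c0 - old)^2)) > 1e-6) break
          }
          gt$neurons[[i]]$field_center <- c0
        }
        if (gt$neurons[[i]]$alpha_gain > 0) {
          gt$neurons[[i]]$alpha_mu <- stats::runif(1, -180, 180)
        }
        if (gt$neurons[[i]]$beta_gain > 0) {
          gt$neurons[[i]]$beta_mu <- stats::runif(1, -180, 180)
        }
      }
      prev <- gt
    }
    out[[s]] <- simulate_session(gt, n_trials = n_trials, seed = seeds[s],
                                 geometry = geometry,
                                 session_id = sprintf("s%02d", s), ...)
    out[[s]]$metadata$ground_truth <- gt
    out[[s]]$metadata$condition <- condition
  }
  out
}
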