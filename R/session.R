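#' Compute navigation covariates from a pose track
#'
#' Converts a time-ordered pose track (wheelchair position, chair heading and
#' head heading) into the canonical 10 Hz covariate frame used by every
#' analysis: position `x, y`, translational velocity `v` (m/s, signed along
#' the chair heading), rotational velocity `w` (deg/s, clockwise positive),
#' distance to the dispenser `r`, room-frame bearing of the chair from the
#' dispenser `theta`, and the egocentric dispenser bearings `alpha` (relative
#' to the head heading) and `beta` (relative to the chair heading). Each bin
#' also carries a zone label (`navigation`, `docking`, `reach`) assigned from
#' `r` and the zone radii, and the trial id.
#'
#' Poses sampled faster than 10 Hz are down-sampled by decimation; the pose
#' timestamps must be uniformly spaced with no gaps.
#'
#' @param poses data.frame with columns `t` (s), `x`, `y` (m),
#'   `chair_heading`, `head_heading` (deg in \[-180, 180)) and optionally
#'   `trial_id`.
#' @param geometry a [room_geometry()].
#' @return a data.frame of class `covariate_frame`, one row per 100 ms bin.
#' @export
compute_covariates <- function(poses, geometry) {
  stopifnot(is.data.frame(poses),
            all(c("t", "x", "y", "chair_heading", "head_heading") %in%
                  names(poses)))
  if (is.null(poses$trial_id)) poses$trial_id <- 1L
  n <- nrow(poses)
  if (n < 3) stop("need at least 3 poses")
  dt <- diff(poses$t)
  if (any(dt <= 0)) stop("pose timestamps must be strictly increasing")
  step <- stats::median(dt)
  if (any(abs(dt - step) > step * 0.5)) {
    stop("pose track has gaps; interpolate or split before calling")
  }
  target <- 0.1
  if (step < target - 1e-9) {
    k <- round(target / step)
    if (abs(k * step - target) > 1e-6) {
      stop("pose rate must be an integer multiple of 10 Hz for decimation")
    }
    poses <- poses[seq(1, n, by = k), , drop = FALSE]
    n <- nrow(poses)
  } else if (step > target + 1e-9) {
    stop("pose track is slower than 10 Hz")
  }

  x <- poses$x
  y <- poses$y
  ch <- poses$chair_heading
  hh <- poses$head_heading

  # central differences; one-sided at the ends; never across trial edges
  cdiff <- function(u) {
    m <- length(u)
    d <- numeric(m)
    if (m == 1) return(d)
    d[1] <- u[2] - u[1]
    d[m] <- u[m] - u[m - 1]
    if (m > 2) {
      mid <- 2:(m - 1)
      d[mid] <- (u[mid + 1] - u[mid - 1]) / 2
    }
    d
  }
  uh <- heading_unit(ch)
  v <- w <- numeric(n)
  for (ix in split(seq_len(n), poses$trial_id)) {
    # chair heading unwrapped before differencing so w is continuous
    chu <- ch[ix][1] + c(0, cumsum(wrap_angle(diff(ch[ix]))))
    v[ix] <- (cdiff(x[ix]) * uh[ix, 1] + cdiff(y[ix]) * uh[ix, 2]) / target
    w[ix] <- cdiff(chu) / target
  }

  dxy <- cbind(geometry$dispenser_xy[1] - x, geometry$dispenser_xy[2] - y)
  r <- sqrt(rowSums(dxy^2))
  theta <- bearing_deg(matrix(rep(geometry$dispenser_xy, each = n), ncol = 2),
                       cbind(x, y))
  to_disp <- bearing_deg(cbind(x, y),
                         matrix(rep(geometry$dispenser_xy, each = n), ncol = 2))
  alpha <- wrap_angle(to_disp - hh)
  beta <- wrap_angle(to_disp - ch)

  out <- data.frame(t = poses$t, x = x, y = y,
                    chair_heading = wrap_angle(ch),
                    head_heading = wrap_angle(hh),
                    v = v, w = w, r = r, theta = theta,
                    alpha = alpha, beta = beta,
                    zone = zone_label(r, geometry),
                    trial_id = poses$trial_id)
  class(out) <- c("covariate_frame", "data.frame")
  out
}

#' Z-score spike counts per neuron
#'
#' Each neuron's 100 ms spike counts are standardized over the whole session
#' using the population (divide-by-n) standard deviation; optionally a
#' 3-point centered moving average is applied afterwards. Neurons with zero
#' variance (e.g. silent units) yield all-zero traces and are flagged.
#'
#' @param counts neurons x bins integer matrix.
#' @param smooth logical; apply the 3-point moving average after z-scoring.
#' @return real matrix of the same shape, with attribute `zero_variance`
#'   (logical per neuron).
#' @export
zscore_counts <- function(counts, smooth = FALSE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  mu <- rowMeans(counts)
  sdev <- sqrt(rowMeans((counts - mu)^2))
  zero <- sdev == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance neuron(s); emitting all-zero z-scores")
    sdev[zero] <- 1
  }
  z <- (counts - mu) / sdev
  z[zero, ] <- 0
  if (smooth) z <- t(apply(z, 1, moving_average3))
  attr(z, "zero_variance") <- zero
  z
}

#' 3-point centered moving average
#'
#' Endpoints average the two available points.
#'
#' @param x numeric vector.
#' @return smoothed vector of the same length.
#' @export
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1):n])
  out
}

#' Bundle covariates and spikes into a session
#'
#' @param geometry a [room_geometry()].
#' @param covariates a `covariate_frame` from [compute_covariates()].
#' @param spikes neurons x bins integer matrix with rownames as neuron ids;
#'   may carry an `area` attribute (character per neuron).
#' @param metadata named list (session id, seed, ...).
#' @return an object of class `session_data`.
#' @export
session_data <- function(geometry, covariates, spikes, metadata = list()) {
  stopifnot(inherits(geometry, "room_geometry"),
            inherits(covariates, "covariate_frame"),
            is.matrix(spikes))
  if (ncol(spikes) != nrow(covariates)) {
    stop("spikes and covariates must share the same bin axis")
  }
  if (any(spikes < 0) || any(spikes != round(spikes))) {
    stop("spike counts must be nonnegative integers")
  }
  if (is.null(rownames(spikes))) {
    rownames(spikes) <- sprintf("n%03d", seq_len(nrow(spikes)))
  }
  structure(list(geometry = geometry, covariates = covariates,
                 spikes = spikes, metadata = metadata),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("session_data: %d neurons x %d bins (%.1f s at 10 Hz), %d trials\n",
              nrow(x$spikes), ncol(x$spikes), ncol(x$spikes) * 0.1,
              length(unique(x$covariates$trial_id))))
  zt <- table(x$covariates$zone)
  cat("  zones:", paste(names(zt), zt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Indices of pre-docking (open-field navigation) bins
#'
#' Most tuning analyses use only the bins before the autopilot takes over,
#' i.e. bins outside the docking zone.
#'
#' @param session a [session_data()].
#' @return integer bin indices.
#' @export
predocking_bins <- function(session) {
  which(session$covariates$zone == "navigation")
}

#' Write a session to plain-text files
#'
#' Writes `<prefix>_covariates.csv`, `<prefix>_counts.tsv` (dense integer
#' matrix, neurons in rows) and `<prefix>_geometry.json`. Integer columns
#' round-trip exactly; reals to better than 1e-12.
#'
#' @param session a [session_data()].
#' @param prefix file path prefix.
#' @return invisibly, the three file paths.
#' @export
write_session <- function(session, prefix) {
  cov_path <- paste0(prefix, "_covariates.csv")
  cnt_path <- paste0(prefix, "_counts.tsv")
  geo_path <- paste0(prefix, "_geometry.json")
  cov <- session$covariates
  utils::write.csv(format(as.data.frame(cov), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   cov_path, row.names = FALSE, quote = FALSE)
  utils::write.table(session$spikes, cnt_path, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  geo <- session$geometry
  # only atomic metadata is serialized; rich objects (e.g. an attached
  # ground truth) live in memory or in their own files
  md <- Filter(is.atomic, session$metadata)
  jsonlite::write_json(list(room_size = geo$room_size,
                            drivable_size = geo$drivable_size,
                            dispenser_xy = geo$dispenser_xy,
                            start_xy = geo$start_xy,
                            docking_radius = geo$docking_radius,
                            reach_radius = geo$reach_radius,
                            area = attr(session$spikes, "area"),
                            metadata = md),
                       geo_path, digits = NA, auto_unbox = TRUE)
  invisible(c(cov_path, cnt_path, geo_path))
}

#' Read a session written by [write_session()]
#'
#' @param prefix file path prefix used when writing.
#' @return a [session_data()].
#' @export
read_session <- function(prefix) {
  geo_json <- jsonlite::read_json(paste0(prefix, "_geometry.json"),
                                  simplifyVector = TRUE)
  geometry <- room_geometry(room_size = geo_json$room_size,
                            drivable_size = geo_json$drivable_size,
                            dispenser_xy = geo_json$dispenser_xy,
                            start_xy = matrix(geo_json$start_xy, ncol = 2),
                            docking_radius = geo_json$docking_radius,
                            reach_radius = geo_json$reach_radius)
  cov <- utils::read.csv(paste0(prefix, "_covariates.csv"),
                         stringsAsFactors = FALSE)
  cov$trial_id <- as.integer(cov$trial_id)
  class(cov) <- c("covariate_frame", "data.frame")
  cnt <- utils::read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                           row.names = 1, header = FALSE)
  cnt <- as.matrix(cnt)
  colnames(cnt) <- NULL
  storage.mode(cnt) <- "integer"
  if (!is.null(geo_json$area)) attr(cnt, "area") <- geo_json$area
  md <- geo_json$metadata
  if (is.null(md)) md <- list()
  session_data(geometry, cov, cnt, as.list(md))
}
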