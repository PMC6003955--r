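#' Place field of a fitted position surface
#'
#' The place field is the set of room locations (5 cm bins, docking-zone
#' bins masked out) where the fitted position tuning surface strictly
#' exceeds its median over all included locations. A constant (degenerate)
#' surface yields an empty field with a flag.
#'
#' @param surface a list from [extract_position_surface()].
#' @param geometry a [room_geometry()]; used to mask the docking zone.
#' @return list of class `place_field`: `field` (logical ny x nx matrix, NA
#'   where masked), `degenerate` flag.
#' @export
extract_place_field <- function(surface, geometry) {
  xc <- surface$xcenters
  yc <- surface$ycenters
  r <- sqrt(outer(yc, xc, function(yy, xx) {
    (xx - geometry$dispenser_xy[1])^2 + (yy - geometry$dispenser_xy[2])^2
  }))
  mask <- r <= geometry$docking_radius
  vals <- surface$surface
  vals[mask] <- NA
  med <- stats::median(vals, na.rm = TRUE)
  degenerate <- isTRUE(all(abs(vals - med) < 1e-12, na.rm = TRUE))
  field <- vals > med
  structure(list(field = field, degenerate = degenerate,
                 xcenters = xc, ycenters = yc), class = "place_field")
}

#' Ensemble place-field heatmap with a uniformity test
#'
#' Per session, the boolean place fields of position-preferring neurons are
#' averaged (normalized by the number of contributing cells); the session
#' maps are then averaged unweighted. A one-sample Kolmogorov-Smirnov test
#' compares the heatmap's value distribution against the uniform
#' distribution on \[0, max\].
#'
#' @param fields_by_session list (one element per session) of lists of
#'   [extract_place_field()] results.
#' @return list: `heatmap` (ny x nx, values in \[0, 1\]), `ks_p`,
#'   `n_sessions`.
#' @export
ensemble_place_field_heatmap <- function(fields_by_session) {
  session_maps <- list()
  for (s in seq_along(fields_by_session)) {
    flds <- Filter(function(f) !f$degenerate, fields_by_session[[s]])
    if (!length(flds)) {
      warning("session ", s, " has no position-preferring cells; excluded")
      next
    }
    stack <- lapply(flds, function(f) {
      m <- f$field + 0
      m
    })
    session_maps[[length(session_maps) + 1L]] <-
      Reduce(`+`, stack) / length(stack)
  }
  if (!length(session_maps)) stop("no sessions with position-preferring cells")
  heatmap <- Reduce(`+`, session_maps) / length(session_maps)
  vals <- heatmap[!is.na(heatmap)]
  ks <- suppressWarnings(
    stats::ks.test(vals, "punif", 0, max(vals)))
  list(heatmap = heatmap, ks_p = ks$p.value,
       n_sessions = length(session_maps))
}

#' Preferred direction of an angular tuning curve
#'
#' The argmax of the curve on its 1 degree grid; ties are broken by the
#' smallest angle. A constant curve has no preferred direction and returns
#' NA with a flag.
#'
#' @param curve list from [extract_angle_curve()].
#' @return list: `direction` (degrees or NA), `degenerate`.
#' @export
preferred_direction <- function(curve) {
  v <- curve$value
  if (max(v) - min(v) < 1e-12) {
    return(list(direction = NA_real_, degenerate = TRUE))
  }
  list(direction = curve$angle[which.max(v)], degenerate = FALSE)
}

#' Circular histogram of preferred directions across sessions
#'
#' Per session, directions are binned into eight 45 degree bins and
#' normalized to proportions of that session's orientation-preferring cells;
#' session histograms are then averaged. A KS test against the uniform
#' distribution on the circle assesses non-uniformity of the pooled
#' directions.
#'
#' @param directions_by_session list of numeric vectors of preferred
#'   directions (degrees), one per session; NAs are dropped.
#' @return list: `proportion` (8 bins), `edges`, `ks_p`.
#' @export
direction_histogram <- function(directions_by_session) {
  edges <- seq(-180, 180, by = 45)
  hists <- list()
  pooled <- numeric(0)
  for (d in directions_by_session) {
    d <- d[!is.na(d)]
    if (!length(d)) next
    h <- tabulate(findInterval(wrap_angle(d), edges, rightmost.closed = TRUE),
                  nbins = 8) / length(d)
    hists[[length(hists) + 1L]] <- h
    pooled <- c(pooled, d)
  }
  if (!length(hists)) stop("no preferred directions supplied")
  ks <- suppressWarnings(stats::ks.test(pooled, "punif", -180, 180))
  list(proportion = Reduce(`+`, hists) / length(hists), edges = edges,
       ks_p = ks$p.value)
}
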