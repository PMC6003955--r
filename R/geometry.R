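#' Angle wrapping to [-180, 180)
#'
#' All angles in this package are expressed in degrees on the half-open
#' interval \[-180, 180), with positive angles clockwise when the room is
#' viewed from above (matching the sign convention for rotational velocity:
#' positive for clockwise turns).
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into \[-180, 180).
#' @export
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

#' Bearing of one point from another, in room coordinates
#'
#' Returns the clockwise-positive angle of the vector `to - from`. A bearing
#' of 0 points along positive x; +90 points along negative y (clockwise).
#'
#' @param from,to two-column matrices (or length-2 vectors) of x, y in meters.
#' @return bearings in degrees in \[-180, 180).
#' @export
bearing_deg <- function(from, to) {
  from <- matrix(from, ncol = 2)
  to <- matrix(to, ncol = 2)
  dx <- to[, 1] - from[, 1]
  dy <- to[, 2] - from[, 2]
  wrap_angle(atan2(-dy, dx) * 180 / pi)
}

#' Unit vector of a heading
#'
#' @param h heading in degrees (clockwise-positive convention).
#' @return two-column matrix of (ux, uy).
#' @keywords internal
heading_unit <- function(h) {
  hr <- h * pi / 180
  cbind(cos(hr), -sin(hr))
}

#' Room geometry for a navigation session
#'
#' Describes the experimental room: outer room size, the smaller drivable
#' area, the reward-dispenser location, the three trial start points, and the
#' radii of the docking zone (inside which an autopilot parks the wheelchair)
#' and the reach zone (inside which the subject reaches for the reward).
#'
#' The default geometry is a 3.5 x 2.5 m room with a 3.1 x 2.4 m drivable
#' area, starts at (0.86, 0.65), (1.0, 0) and (0.86, -0.65) m, and the
#' dispenser at the midpoint of the wall at negative x. The origin is the
#' room center; x runs along the 3.5 m dimension. The dispenser-side
#' coordinate frame is a package convention (see the methods vignette).
#'
#' @param room_size length-2 numeric, room (length, width) in meters.
#' @param drivable_size length-2 numeric, drivable (length, width) in meters.
#' @param dispenser_xy length-2 numeric, dispenser position in meters.
#' @param start_xy 3 x 2 matrix of start positions in meters.
#' @param docking_radius radius of the docking zone in meters.
#' @param reach_radius radius of the reach zone in meters.
#' @return an object of class `room_geometry`.
#' @export
room_geometry <- function(room_size = c(3.5, 2.5),
                          drivable_size = c(3.1, 2.4),
                          dispenser_xy = c(-1.75, 0),
                          start_xy = rbind(c(0.86, 0.65),
                                           c(1.0, 0.0),
                                           c(0.86, -0.65)),
                          docking_radius = 0.9,
                          reach_radius = 0.55) {
  stopifnot(length(room_size) == 2, length(drivable_size) == 2,
            length(dispenser_xy) == 2, is.matrix(start_xy),
            ncol(start_xy) == 2, docking_radius > 0, reach_radius > 0)
  if (any(drivable_size > room_size)) {
    stop("drivable area must fit inside the room")
  }
  half <- drivable_size / 2
  inside <- abs(start_xy[, 1]) <= half[1] & abs(start_xy[, 2]) <= half[2]
  if (!all(inside)) stop("all start points must lie inside the drivable area")
  structure(list(room_size = as.numeric(room_size),
                 drivable_size = as.numeric(drivable_size),
                 dispenser_xy = as.numeric(dispenser_xy),
                 start_xy = unname(start_xy),
                 docking_radius = docking_radius,
                 reach_radius = reach_radius),
            class = "room_geometry")
}

#' @export
print.room_geometry <- function(x, ...) {
  cat(sprintf("room_geometry: room %.2f x %.2f m, drivable %.2f x %.2f m\n",
              x$room_size[1], x$room_size[2],
              x$drivable_size[1], x$drivable_size[2]))
  cat(sprintf("  dispenser (%.2f, %.2f); docking r = %.2f m, reach r = %.2f m\n",
              x$dispenser_xy[1], x$dispenser_xy[2],
              x$docking_radius, x$reach_radius))
  invisible(x)
}

#' Zone label from distance to the dispenser
#'
#' Zones are nested when `reach_radius <= docking_radius`: the reach zone sits
#' inside the docking zone, and everything else is open-field navigation.
#'
#' @param r distance to the dispenser in meters.
#' @param geometry a [room_geometry()].
#' @return character vector in `{"navigation", "docking", "reach"}`.
#' @export
zone_label <- function(r, geometry) {
  z <- rep("navigation", length(r))
  z[r <= geometry$docking_radius] <- "docking"
  z[r <= geometry$reach_radius] <- "reach"
  z
}

drivable_half <- function(geometry) geometry$drivable_size / 2

clip_to_drivable <- function(xy, geometry) {
  half <- drivable_half(geometry)
  xy[, 1] <- pmin(pmax(xy[, 1], -half[1]), half[1])
  xy[, 2] <- pmin(pmax(xy[, 2], -half[2]), half[2])
  xy
}
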