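#' 5 cm grid over the drivable area
#'
#' Bins are half-open and anchored at the drivable-area corner.
#'
#' @param geometry a [room_geometry()].
#' @param bin_size bin edge length in meters.
#' @return list with `xedges`, `yedges`, `nx`, `ny`.
#' @keywords internal
position_grid <- function(geometry, bin_size = 0.05) {
  half <- drivable_half(geometry)
  xedges <- seq(-half[1], half[1] + bin_size - 1e-12, by = bin_size)
  yedges <- seq(-half[2], half[2] + bin_size - 1e-12, by = bin_size)
  list(xedges = xedges, yedges = yedges,
       nx = length(xedges) - 1L, ny = length(yedges) - 1L)
}

grid_bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  i[i < 1L | i >= length(edges)] <- NA_integer_
  i
}

#' Occupancy-binned position tuning diagram for one neuron
#'
#' Spike counts are z-scored over the session, smoothed with a 3-point
#' moving average, and averaged within each visited 5 cm x 5 cm spatial bin.
#' The raw map (NA where unvisited) is retained; a display copy is produced
#' by neighbor fill-in followed by truncated-Gaussian smoothing
#' (7 x 7 kernel, sigma = 3 bins). The diagram can be conditioned on an
#' angular interval of `alpha` or `beta` (e.g. head pointing to one side of
#' the dispenser).
#'
#' @param session a [session_data()].
#' @param neuron neuron index or rowname.
#' @param condition optional list `list(var = "alpha", range = c(45, 135))`;
#'   the interval is half-open and may wrap across +/-180.
#' @param bin_size spatial bin size (m).
#' @param kernel_size,sigma display-smoothing parameters (bins).
#' @return an object of class `tuning_diagram`: list with `raw`, `display`,
#'   `occupancy` (ny x nx matrices, x in columns), grid info, and a
#'   `low_data` flag when the condition selects fewer than 50 bins.
#' @export
position_tuning_diagram <- function(session, neuron, condition = NULL,
                                    bin_size = 0.05, kernel_size = 7,
                                    sigma = 3) {
  z <- zscore_counts(session$spikes, smooth = TRUE)
  if (is.character(neuron)) neuron <- match(neuron, rownames(session$spikes))
  zi <- z[neuron, ]
  cov <- session$covariates
  keep <- rep(TRUE, nrow(cov))
  if (!is.null(condition)) {
    stopifnot(condition$var %in% c("alpha", "beta"), length(condition$range) == 2)
    ang <- cov[[condition$var]]
    lo <- condition$range[1]; hi <- condition$range[2]
    keep <- if (lo <= hi) ang >= lo & ang < hi else ang >= lo | ang < hi
  }
  grid <- position_grid(session$geometry, bin_size)
  ix <- grid_bin_index(cov$x, grid$xedges)
  iy <- grid_bin_index(cov$y, grid$yedges)
  ok <- keep & !is.na(ix) & !is.na(iy)
  cell <- (ix[ok] - 1L) * grid$ny + iy[ok]
  occ <- matrix(0L, grid$ny, grid$nx)
  raw <- matrix(NA_real_, grid$ny, grid$nx)
  tab <- tabulate(cell, nbins = grid$ny * grid$nx)
  sums <- rep(0, grid$ny * grid$nx)
  agg <- rowsum(zi[ok], cell)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  occ[] <- tab
  raw[occ > 0] <- sums[occ > 0] / tab[occ > 0]
  display <- fill_and_smooth(raw, kernel_size, sigma)
  structure(list(raw = raw, display = display, occupancy = occ,
                 xedges = grid$xedges, yedges = grid$yedges,
                 neuron = neuron, condition = condition,
                 low_data = sum(occ > 0) < 50,
                 kernel_size = kernel_size, sigma = sigma),
            class = "tuning_diagram")
}

#' Fill unoccupied bins and Gaussian-smooth a spatial map
#'
#' Missing bins are imputed by iterative nearest-neighbor averaging (each
#' pass fills every NA bin with the mean of its available 8-neighbors) until
#' none remain, then the map is convolved with a truncated Gaussian kernel
#' whose weights are renormalized at the edges, so constant maps are
#' preserved exactly.
#'
#' @param grid numeric matrix, NA = missing.
#' @param kernel_size odd kernel width in bins.
#' @param sigma Gaussian sd in bins.
#' @return smoothed matrix without NAs.
#' @export
fill_and_smooth <- function(grid, kernel_size = 7, sigma = 3) {
  if (all(is.na(grid))) stop("cannot fill an empty grid")
  g <- grid
  nr <- nrow(g); nc <- ncol(g)
  while (anyNA(g)) {
    miss <- which(is.na(g), arr.ind = TRUE)
    vals <- numeric(nrow(miss))
    okfill <- logical(nrow(miss))
    for (k in seq_len(nrow(miss))) {
      i <- miss[k, 1]; j <- miss[k, 2]
      nb <- g[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      nbv <- nb[!is.na(nb)]
      if (length(nbv)) { vals[k] <- mean(nbv); okfill[k] <- TRUE }
    }
    if (!any(okfill)) stop("fill-in failed to progress")
    g[miss[okfill, , drop = FALSE]] <- vals[okfill]
  }
  half <- (kernel_size - 1L) / 2L
  off <- seq(-half, half)
  k1 <- exp(-off^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  out <- matrix(0, nr, nc)
  wsum <- matrix(0, nr, nc)
  for (a in seq_along(off)) {
    for (b in seq_along(off)) {
      di <- off[a]; dj <- off[b]
      si <- max(1, 1 - di):min(nr, nr - di)
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      out[si, sj] <- out[si, sj] + kern[a, b] * g[si + di, sj + dj]
      wsum[si, sj] <- wsum[si, sj] + kern[a, b]
    }
  }
  out / wsum
}

#' @export
print.tuning_diagram <- function(x, ...) {
  cat(sprintf("tuning_diagram: %d x %d bins, %d occupied%s\n",
              nrow(x$raw), ncol(x$raw), sum(x$occupancy > 0),
              if (x$low_data) " (low data)" else ""))
  if (!is.null(x$condition)) {
    cat(sprintf("  condition: %s in [%g, %g)\n", x$condition$var,
                x$condition$range[1], x$condition$range[2]))
  }
  invisible(x)
}

#' Export a tuning diagram (and its occupancy) as CSV matrices
#'
#' @param diagram a [position_tuning_diagram()] result.
#' @param prefix file path prefix.
#' @return invisibly, the written paths.
#' @export
write_tuning_diagram <- function(diagram, prefix) {
  p1 <- paste0(prefix, "_map.csv")
  p2 <- paste0(prefix, "_occupancy.csv")
  utils::write.table(diagram$display, p1, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(diagram$occupancy, p2, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(p1, p2))
}
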