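#' Trivariate (x, y, alpha) tuning histograms for a session
#'
#' For each neuron, bins the session's z-scored, 3-point-smoothed activity
#' into a 3D histogram over x and y at 0.1 m resolution and the head-frame
#' dispenser bearing alpha in four 90 degree bins, averaging within cells.
#' Cells with zero occupancy are NA, never zero-filled.
#'
#' @param session a [session_data()].
#' @param neurons neuron indices (default all).
#' @param bins optional integer bin subset (e.g. one half of the session);
#'   it is always intersected with the pre-docking bins, matching the
#'   treatment of every other tuning analysis.
#' @return list: `tuning` (neurons x cells matrix, NA where unoccupied),
#'   `occupancy` (cell occupancy counts).
#' @export
trivariate_tuning <- function(session, neurons = NULL, bins = NULL) {
  if (is.null(neurons)) neurons <- seq_len(nrow(session$spikes))
  if (is.null(bins)) bins <- seq_len(ncol(session$spikes))
  bins <- intersect(bins, predocking_bins(session))
  z <- zscore_counts(session$spikes, smooth = TRUE)
  cell <- trivariate_cell_ids(session)
  nc <- attr(cell, "n_cells")
  h <- cell_histogram(z[neurons, bins, drop = FALSE], cell[bins], nc)
  list(tuning = h$tuning, occupancy = h$occupancy, neurons = neurons)
}

# mean of each neuron's trace within each cell; one rowsum over all neurons
cell_histogram <- function(z, cb, nc) {
  occ <- tabulate(cb, nbins = nc)
  agg <- rowsum(t(z), cb)
  idx <- as.integer(rownames(agg))
  tuning <- matrix(NA_real_, nrow(z), nc)
  tuning[, idx] <- t(agg / occ[idx])
  list(tuning = tuning, occupancy = occ)
}

# cell id per session bin on the (0.1 m x, 0.1 m y, 4 x 90 deg alpha) lattice
trivariate_cell_ids <- function(session) {
  geo <- session$geometry
  half <- drivable_half(geo)
  xe <- seq(-half[1], half[1] + 0.1, by = 0.1)
  ye <- seq(-half[2], half[2] + 0.1, by = 0.1)
  cov <- session$covariates
  ix <- pmin(pmax(findInterval(cov$x, xe), 1L), length(xe) - 1L)
  iy <- pmin(pmax(findInterval(cov$y, ye), 1L), length(ye) - 1L)
  ia <- findInterval(wrap_angle(cov$alpha), seq(-180, 180, by = 90),
                     rightmost.closed = TRUE)
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  id <- ((ix - 1L) * ny + (iy - 1L)) * 4L + ia
  attr(id, "n_cells") <- nx * ny * 4L
  id
}

#' Select neurons with stable high tuning across sessions
#'
#' @param highly_tuned logical matrix, neurons x sessions.
#' @param resorted logical per neuron (TRUE = unit was re-sorted at some
#'   point and is excluded).
#' @param min_fraction minimum fraction of sessions with high tuning.
#' @return integer indices of eligible neurons.
#' @export
select_stable_candidates <- function(highly_tuned, resorted = NULL,
                                     min_fraction = 0.7) {
  stopifnot(is.matrix(highly_tuned))
  if (is.null(resorted)) resorted <- rep(FALSE, nrow(highly_tuned))
  frac <- rowMeans(highly_tuned)
  which(frac >= min_fraction & !resorted)
}

#' Pairwise consistency index between two trivariate tunings
#'
#' Per neuron, the Pearson correlation of the two histograms over jointly
#' occupied cells; the index is the mean over neurons. Neurons with fewer
#' than `min_cells` jointly occupied cells are skipped with a warning.
#'
#' @param tuning_a,tuning_b [trivariate_tuning()] results with the same
#'   neuron set.
#' @param min_cells minimum jointly occupied cells per neuron.
#' @return list: `index`, `per_neuron` correlations (NA where skipped).
#' @export
consistency_index <- function(tuning_a, tuning_b, min_cells = 20) {
  stopifnot(nrow(tuning_a$tuning) == nrow(tuning_b$tuning))
  nn <- nrow(tuning_a$tuning)
  rs <- rep(NA_real_, nn)
  for (j in seq_len(nn)) {
    a <- tuning_a$tuning[j, ]
    b <- tuning_b$tuning[j, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_cells) {
      warning("neuron ", j, " skipped: only ", sum(ok),
              " jointly occupied cells")
      next
    }
    rs[j] <- stats::cor(a[ok], b[ok])
  }
  list(index = mean(rs, na.rm = TRUE), per_neuron = rs)
}

#' Within-session consistency index
#'
#' Splits the session into two equal contiguous halves and correlates the
#' half-session trivariate tunings as in [consistency_index()].
#'
#' @param session a [session_data()].
#' @param neurons neuron indices.
#' @param min_cells minimum jointly occupied cells per neuron.
#' @return as [consistency_index()].
#' @export
within_session_index <- function(session, neurons = NULL, min_cells = 20) {
  nb <- ncol(session$spikes)
  h1 <- seq_len(nb %/% 2)
  h2 <- (nb %/% 2 + 1L):nb
  consistency_index(trivariate_tuning(session, neurons, h1),
                    trivariate_tuning(session, neurons, h2),
                    min_cells = min_cells)
}

#' Permutation significance of consistency indices
#'
#' The null shifts each session's spike trains by a random circular offset
#' of 10 to 50 s relative to the covariates and recomputes every pairwise
#' (between-session) and within-session index. P-values use the add-one
#' convention. A two-sided Wilcoxon rank-sum test compares the observed
#' within-session against between-session indices.
#'
#' @param sessions list of [session_data()] with a shared neuron set.
#' @param neurons neuron indices used in the indices.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param min_cells minimum jointly occupied cells per neuron.
#' @return list: `between` (data.frame of session pairs with `index` and
#'   `p`), `within` (per session), `ranksum_p`, `null_between` (matrix of
#'   permuted between-session indices).
#' @export
consistency_permutation <- function(sessions, neurons = NULL, n_perm = 1000,
                                    seed = 1, min_cells = 20) {
  set.seed(seed)
  ns <- length(sessions)
  if (is.null(neurons)) neurons <- seq_len(nrow(sessions[[1]]$spikes))
  # precompute per-session z matrices, cell id tracks and navigation masks
  zs <- lapply(sessions, function(s) zscore_counts(s$spikes, smooth = TRUE))
  cells <- lapply(sessions, trivariate_cell_ids)
  navs <- lapply(sessions, function(s) s$covariates$zone == "navigation")
  nc <- attr(cells[[1]], "n_cells")

  hist_from <- function(si, window, shift = 0L) {
    cell <- cells[[si]]
    nav <- navs[[si]]
    nb <- length(cell)
    if (shift != 0L) {
      # shift spikes relative to covariates = rotate the covariate-derived
      # cell ids and the pre-docking mask together
      idx <- ((seq_len(nb) - 1L + shift) %% nb) + 1L
      cell <- cell[idx]
      nav <- nav[idx]
    }
    bins <- window[nav[window]]
    cell_histogram(zs[[si]][neurons, bins, drop = FALSE], cell[bins], nc)
  }

  pair_index <- function(ta, tb) {
    suppressWarnings(consistency_index(ta, tb, min_cells = min_cells)$index)
  }

  full_bins <- lapply(sessions, function(s) seq_len(ncol(s$spikes)))
  halves <- lapply(sessions, function(s) {
    nb <- ncol(s$spikes)
    list(seq_len(nb %/% 2), (nb %/% 2 + 1L):nb)
  })

  obs_full <- lapply(seq_len(ns), function(i) hist_from(i, full_bins[[i]]))
  pairs <- if (ns >= 2) utils::combn(ns, 2) else matrix(integer(0), 2, 0)
  between <- data.frame(a = pairs[1, ], b = pairs[2, ])
  between$index <- vapply(seq_len(ncol(pairs)), function(k) {
    pair_index(obs_full[[pairs[1, k]]], obs_full[[pairs[2, k]]])
  }, 0)
  within <- vapply(seq_len(ns), function(i) {
    pair_index(hist_from(i, halves[[i]][[1]]),
               hist_from(i, halves[[i]][[2]]))
  }, 0)

  null_between <- matrix(NA_real_, n_perm, ncol(pairs))
  null_within <- matrix(NA_real_, n_perm, ns)
  for (p in seq_len(n_perm)) {
    shifts <- sample(100:500, ns, replace = TRUE) *
      sample(c(-1L, 1L), ns, replace = TRUE)
    perm_full <- lapply(seq_len(ns), function(i) {
      hist_from(i, full_bins[[i]], shift = shifts[i])
    })
    null_between[p, ] <- vapply(seq_len(ncol(pairs)), function(k) {
      pair_index(perm_full[[pairs[1, k]]], perm_full[[pairs[2, k]]])
    }, 0)
    null_within[p, ] <- vapply(seq_len(ns), function(i) {
      pair_index(hist_from(i, halves[[i]][[1]], shift = shifts[i]),
                 hist_from(i, halves[[i]][[2]], shift = shifts[i]))
    }, 0)
  }
  between$p <- vapply(seq_len(ncol(pairs)), function(k) {
    (1 + sum(null_between[, k] >= between$index[k])) / (1 + n_perm)
  }, 0)
  within_p <- vapply(seq_len(ns), function(i) {
    (1 + sum(null_within[, i] >= within[i])) / (1 + n_perm)
  }, 0)
  ranksum_p <- if (ncol(pairs) >= 1 && ns >= 1) {
    suppressWarnings(stats::wilcox.test(within, between$index)$p.value)
  } else NA_real_
  list(between = between,
       within = data.frame(session = seq_len(ns), index = within,
                           p = within_p),
       ranksum_p = ranksum_p, null_between = null_between,
       null_within = null_within)
}
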