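#' Plug-in mutual information of a joint count table
#'
#' Computes `sum P(s,r) log2( P(s,r) / (P(s)P(r)) )` over cells with
#' positive probability, in bits.
#'
#' @param joint nonnegative integer matrix (stimuli x responses).
#' @return mutual information in bits.
#' @export
plugin_mi <- function(joint) {
  stopifnot(is.matrix(joint), all(joint >= 0))
  n <- sum(joint)
  if (n < 1) stop("joint table must contain at least one observation")
  p <- joint / n
  ps <- rowSums(p)
  pr <- colSums(p)
  pp <- outer(ps, pr)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / pp[pos]))
}

#' First-order analytic bias of plug-in mutual information
#'
#' `C1 = (Ns - 1)(NR - 1) / (2 N ln 2)` bits, where `Ns` is the number of
#' distinct stimuli, `NR` the number of distinct responses and `N` the
#' sample count.
#'
#' @param n sample count.
#' @param ns number of distinct stimulus bins.
#' @param nr number of distinct responses.
#' @return bias in bits.
#' @export
bias_correction <- function(n, ns, nr) {
  stopifnot(n >= 1, ns >= 1, nr >= 1)
  (ns - 1) * (nr - 1) / (2 * n * log(2))
}

#' Discretize a stimulus track for information analysis
#'
#' Position uses a 0.4 m x 0.4 m grid over the room; angles use eight 45
#' degree bins tiling \[-180, 180).
#'
#' @param session a [session_data()].
#' @param kind `"position"`, `"alpha"` or `"beta"`.
#' @return integer stimulus-bin id per session bin (full session, no
#'   occupancy filtering), with attribute `n_bins` giving the total size
#'   of the discretization.
#' @keywords internal
stimulus_ids <- function(session, kind) {
  cov <- session$covariates
  if (kind == "position") {
    half <- session$geometry$room_size / 2
    xe <- seq(-half[1], half[1] + 0.4, by = 0.4)
    ye <- seq(-half[2], half[2] + 0.4, by = 0.4)
    ix <- findInterval(cov$x, xe)
    iy <- findInterval(cov$y, ye)
    id <- (ix - 1L) * (length(ye) - 1L) + iy
    attr(id, "n_bins") <- (length(xe) - 1L) * (length(ye) - 1L)
    id
  } else {
    id <- findInterval(wrap_angle(cov[[kind]]), seq(-180, 180, by = 45),
                       rightmost.closed = TRUE)
    attr(id, "n_bins") <- 8L
    id
  }
}

# MI from aligned integer stimulus/response ids (internal fast path)
mi_from_ids <- function(sid, rid, ns, nr) {
  joint <- tabulate((sid - 1L) * nr + rid, nbins = ns * nr)
  dim(joint) <- c(nr, ns)
  plugin_mi(t(joint))
}

#' Bias-corrected mutual information for one neuron
#'
#' Builds the joint table of occupied stimulus bins versus distinct observed
#' spike counts over pre-docking bins, subtracts the analytic bias `C1`, and
#' clamps: the corrected value is set to 0 when it is negative or when
#' `C1 > 1` (stimulus space too finely sampled for the data).
#'
#' By default `Ns` in `C1` is the full size of the stimulus discretization
#' (all 0.4 m grid cells of the room, or all eight angle bins); with
#' `ns_convention = "occupied"` only stimulus bins with occupancy enter
#' `Ns`. The occupied convention under-corrects on sessions with many
#' thinly sampled cells, leaving small spurious positives for untuned
#' neurons (see the methods vignette).
#'
#' @param session a [session_data()].
#' @param neuron neuron index or rowname.
#' @param stimulus_kind `"position"`, `"alpha"` or `"beta"`.
#' @param ns_convention `"grid"` (default) or `"occupied"`.
#' @return list of class `mi_result`: `mi_raw`, `c1`, `mi_corrected`, `ns`,
#'   `nr`, `n`.
#' @export
corrected_mi <- function(session, neuron, stimulus_kind = "position",
                         ns_convention = c("grid", "occupied")) {
  ns_convention <- match.arg(ns_convention)
  if (is.character(neuron)) neuron <- match(neuron, rownames(session$spikes))
  bins <- predocking_bins(session)
  sid_full <- stimulus_ids(session, stimulus_kind)
  counts <- session$spikes[neuron, ]
  ns_total <- if (ns_convention == "grid") attr(sid_full, "n_bins") else NULL
  res <- corrected_mi_ids(sid_full[bins], counts[bins], ns_total)
  structure(c(res, list(neuron = neuron, stimulus_kind = stimulus_kind)),
            class = "mi_result")
}

# core of corrected_mi on pre-extracted vectors; ns_total (when given) is
# the full discretization size used for C1
corrected_mi_ids <- function(sid, counts, ns_total = NULL) {
  su <- sort(unique(sid))
  if (length(su) < 2) stop("stimulus space not sampled (fewer than 2 bins)")
  s <- match(sid, su)
  ru <- sort(unique(counts))
  r <- match(counts, ru)
  ns <- length(su); nr <- length(ru); n <- length(s)
  mi_raw <- mi_from_ids(s, r, ns, nr)
  c1 <- bias_correction(n, if (is.null(ns_total)) ns else ns_total, nr)
  mi_corr <- if (c1 > 1) 0 else max(0, mi_raw - c1)
  list(mi_raw = mi_raw, c1 = c1, mi_corrected = mi_corr,
       ns = ns, nr = nr, n = n)
}

#' Circular-shift permutation test for mutual information
#'
#' Each permutation circularly shifts the covariate track by a random
#' interval between 10 and 50 s (direction randomized) relative to the
#' spikes, preserving the autocorrelation of both, and recomputes the
#' bias-corrected MI. The p-value uses the add-one convention
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @inheritParams corrected_mi
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: `p_perm`, `observed`, `null` (permuted MI values).
#' @export
circular_shift_permutation <- function(session, neuron,
                                       stimulus_kind = "position",
                                       n_perm = 1000, seed = 1,
                                       ns_convention = c("grid", "occupied")) {
  ns_convention <- match.arg(ns_convention)
  nb <- ncol(session$spikes)
  if (nb * 0.1 <= 100) stop("session must be longer than 100 s")
  if (is.character(neuron)) neuron <- match(neuron, rownames(session$spikes))
  set.seed(seed)
  sid_full <- stimulus_ids(session, stimulus_kind)
  ns_total <- if (ns_convention == "grid") attr(sid_full, "n_bins") else NULL
  nav_full <- session$covariates$zone == "navigation"
  counts <- session$spikes[neuron, ]
  obs <- corrected_mi_ids(sid_full[nav_full], counts[nav_full],
                          ns_total)$mi_corrected
  shifts <- sample(100:500, n_perm, replace = TRUE) *
    sample(c(-1L, 1L), n_perm, replace = TRUE)
  null <- vapply(shifts, function(sh) {
    idx <- ((seq_len(nb) - 1L + sh) %% nb) + 1L
    keep <- nav_full[idx]
    corrected_mi_ids(sid_full[idx][keep], counts[keep],
                     ns_total)$mi_corrected
  }, 0)
  list(p_perm = (1 + sum(null >= obs)) / (1 + n_perm),
       observed = obs, null = null)
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p_values numeric vector of p-values.
#' @param alpha significance level on the adjusted values.
#' @return list: `q` (BH-adjusted values) and `significant` flags.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Mutual-information screening of a whole session
#'
#' For every neuron x stimulus kind, computes the bias-corrected MI, a
#' circular-shift permutation p-value, and BH-FDR-adjusted q-values over all
#' tests of the session (one FDR family per session).
#'
#' @param session a [session_data()].
#' @param kinds stimulus kinds to test.
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @param alpha FDR level.
#' @return data.frame, one row per neuron x kind: `neuron`, `kind`,
#'   `mi_raw`, `c1`, `mi_corrected`, `ns`, `nr`, `n`, `p_perm`, `q_fdr`,
#'   `significant`.
#' @export
mi_screen <- function(session, kinds = c("position", "alpha", "beta"),
                      n_perm = 1000, seed = 1, alpha = 0.05,
                      ns_convention = c("grid", "occupied")) {
  ns_convention <- match.arg(ns_convention)
  nb <- ncol(session$spikes)
  nn <- nrow(session$spikes)
  nav_full <- session$covariates$zone == "navigation"
  set.seed(seed)
  rows <- list()
  for (kind in kinds) {
    sid_full <- stimulus_ids(session, kind)
    ns_total <- if (ns_convention == "grid") attr(sid_full, "n_bins") else
      NULL
    # shared shift draws per kind: shifted stimulus ids computed once per perm
    shifts <- sample(100:500, n_perm, replace = TRUE) *
      sample(c(-1L, 1L), n_perm, replace = TRUE)
    perm_sid <- lapply(shifts, function(sh) {
      idx <- ((seq_len(nb) - 1L + sh) %% nb) + 1L
      list(sid = sid_full[idx][nav_full[idx]], keep = nav_full[idx])
    })
    for (i in seq_len(nn)) {
      counts <- session$spikes[i, ]
      obs <- corrected_mi_ids(sid_full[nav_full], counts[nav_full], ns_total)
      null <- vapply(perm_sid, function(ps) {
        corrected_mi_ids(ps$sid, counts[ps$keep], ns_total)$mi_corrected
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = rownames(session$spikes)[i], kind = kind,
        mi_raw = obs$mi_raw, c1 = obs$c1, mi_corrected = obs$mi_corrected,
        ns = obs$ns, nr = obs$nr, n = obs$n,
        p_perm = (1 + sum(null >= obs$mi_corrected)) / (1 + n_perm))
    }
  }
  out <- do.call(rbind, rows)
  fdr <- fdr_correct(out$p_perm, alpha)
  out$q_fdr <- fdr$q
  out$significant <- fdr$significant
  attr(out, "fdr_family") <- "per session, all neuron x kind tests"
  out
}
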