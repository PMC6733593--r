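# pointwise one-sample t statistics for a subjects x timepoints matrix
pointwise_t <- function(x, mu = 0) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  t <- (m - mu) / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

# maximal runs of TRUE in a logical vector, as (start, end) index pairs
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# clusters of suprathreshold t values of consistent sign; mass = summed t
find_clusters <- function(t, threshold) {
  out <- NULL
  for (sgn in c(1, -1)) {
    runs <- runs_of(sgn * t > threshold)
    if (nrow(runs))
      out <- rbind(out, cbind(runs,
                              mass = apply(runs, 1L, function(r)
                                sum(t[r[1L]:r[2L]]))))
  }
  out
}

#' Cluster-based permutation test over adjacent timepoints
#'
#' Tests a subjects x timepoints matrix against a reference value
#' (one-sample mode, e.g. AUC vs 0.5) or two matched matrices against each
#' other (paired mode) with a pointwise two-sided t-test; contiguous
#' suprathreshold samples of consistent sign form clusters scored by their
#' summed t (cluster mass). The null distribution of the maximum absolute
#' cluster mass is built by random per-subject sign flips of the (difference)
#' series; each cluster's p-value is the proportion of permutation maxima at
#' least as large as its observed mass, with the observed statistic included
#' in the null set so p >= 1/(n_perm + 1).
#'
#' @param x subjects x timepoints matrix
#' @param y optional second matrix for a paired test (same shape); the test
#'   is then on \code{x - y} against 0
#' @param mu reference value for the one-sample test (default 0; use 0.5 for
#'   AUC series)
#' @param n_perm number of permutations (default 5000)
#' @param alpha cluster significance level (default 0.05)
#' @param cluster_alpha pointwise cluster-forming alpha (default 0.05,
#'   two-sided)
#' @param times_ms optional time axis used to label clusters in ms
#' @param seed permutation seed
#' @return object of class \code{cluster_result}: data.frame \code{clusters}
#'   (start/end index, start/end ms, mass, p_value, significant), the
#'   pointwise \code{t} series, \code{threshold}, \code{alpha},
#'   \code{n_perm}
#' @export
cluster_permutation_test <- function(x, y = NULL, mu = 0, n_perm = 5000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     times_ms = NULL, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  x <- as.matrix(x)
  if (!is.null(y)) {
    stopifnot(all(dim(x) == dim(y)))
    x <- x - y
    mu <- 0
  }
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  d <- x - mu
  threshold <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  t_obs <- pointwise_t(d)
  cl <- find_clusters(t_obs, threshold)

  res <- data.frame(start = integer(0), end = integer(0),
                    start_ms = numeric(0), end_ms = numeric(0),
                    mass = numeric(0), p_value = numeric(0),
                    significant = logical(0))
  if (!is.null(cl)) {
    # permutation null of the maximum |mass|, vectorized over timepoints:
    # sign flips leave per-subject squares unchanged, so only the mean term
    # needs recomputation per permutation
    ss <- colSums(d^2)
    max_mass <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      m <- colSums(d * sgn) / n
      s <- sqrt((ss - n * m^2) / (n - 1))
      tp <- m / (s / sqrt(n))
      tp[!is.finite(tp)] <- 0
      cp <- find_clusters(tp, threshold)
      if (is.null(cp)) 0 else max(abs(cp[, "mass"]))
    }, numeric(1)))
    pvals <- vapply(cl[, "mass"], function(m)
      (1 + sum(max_mass >= abs(m))) / (n_perm + 1), numeric(1))
    res <- data.frame(
      start = cl[, "start"], end = cl[, "end"],
      start_ms = if (is.null(times_ms)) NA_real_ else times_ms[cl[, "start"]],
      end_ms = if (is.null(times_ms)) NA_real_ else times_ms[cl[, "end"]],
      mass = cl[, "mass"], p_value = pvals,
      significant = pvals <= alpha)
    res <- res[order(res$start), , drop = FALSE]
  }
  structure(list(clusters = res, t = t_obs, threshold = threshold,
                 alpha = alpha, n_perm = n_perm, times_ms = times_ms),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), alpha = ",
      x$alpha, ", ", x$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

# 3-point moving average (endpoints average the available neighbors)
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- mean(v[1:2]); out[n] <- mean(v[(n - 1):n])
  out
}

# fractional-peak onset of one series within a window; returns sample index
# into the full series, or NA when the series never rises above chance
fractional_onset <- function(series, times_ms, window_ms, fraction, chance) {
  idx <- window_index(times_ms, window_ms)
  sm <- smooth3(series)[idx]
  pk <- which.max(sm)
  if (pk == 1L || pk == length(idx))
    warning("peak at window edge; onset may be unreliable", call. = FALSE)
  peak <- sm[pk]
  if (peak <= chance) return(NA_integer_)
  thr <- chance + fraction * (peak - chance)
  hit <- which(sm >= thr)
  idx[hit[1L]]
}

#' Jackknife fractional-peak onset latency
#'
#' Computes leave-one-out group averages of a score time course (one subject
#' left out per average), smooths each with a 3-point moving average, finds
#' the peak within the search window, and returns the first sample at which
#' the smoothed score reaches \code{fraction} of the peak's elevation above
#' \code{chance}. Using the elevation above chance (rather than the raw
#' score) keeps the 50-percent criterion meaningful for AUC series that never
#' fall below ~0.5.
#'
#' @param x subjects x timepoints score matrix (e.g. per-subject AUC)
#' @param times_ms time axis
#' @param window_ms peak/onset search window (default \code{c(150, 700)} ms)
#' @param fraction fractional-peak criterion in (0, 1) (default 0.5)
#' @param chance chance reference (0.5 for AUC, 0 for difference waves)
#' @return object of class \code{jackknife_onsets}: \code{onset_ms} (one
#'   leave-one-out onset per subject; NA when a subsample never exceeds
#'   chance), \code{mean_onset_ms}, plus the estimation settings
#' @export
jackknife_onset_latency <- function(x, times_ms, window_ms = c(150, 700),
                                    fraction = 0.5, chance = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects for the jackknife",
                   call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  onset_idx <- vapply(seq_len(n), function(i) {
    loo <- colMeans(x[-i, , drop = FALSE])
    on <- fractional_onset(loo, times_ms, window_ms, fraction, chance)
    if (is.na(on)) NA_integer_ else as.integer(on)
  }, integer(1))
  onset_ms <- ifelse(is.na(onset_idx), NA_real_, times_ms[onset_idx])
  structure(list(onset_ms = onset_ms, onset_index = onset_idx,
                 mean_onset_ms = mean(onset_ms, na.rm = TRUE),
                 window_ms = window_ms, fraction = fraction,
                 chance = chance),
            class = "jackknife_onsets")
}

#' Jackknife-corrected paired t-test on leave-one-out onsets
#'
#' The leave-one-out averaging artificially shrinks the variability of the
#' onset estimates; the corrected statistic divides the naive paired t by the
#' degrees of freedom (n - 1), restoring a valid test.
#'
#' @param onsets_a,onsets_b leave-one-out onset vectors (ms) from the same
#'   cohort, e.g. the \code{onset_ms} fields of two
#'   \code{\link{jackknife_onset_latency}} results
#' @return object of class \code{latency_contrast}: mean onsets,
#'   \code{difference_ms}, \code{t_corrected}, \code{df}, \code{p_value}
#' @export
jackknife_corrected_t <- function(onsets_a, onsets_b) {
  if (inherits(onsets_a, "jackknife_onsets")) onsets_a <- onsets_a$onset_ms
  if (inherits(onsets_b, "jackknife_onsets")) onsets_b <- onsets_b$onset_ms
  stopifnot(length(onsets_a) == length(onsets_b))
  ok <- !is.na(onsets_a) & !is.na(onsets_b)
  d <- onsets_a[ok] - onsets_b[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 paired leave-one-out onsets",
                   call. = FALSE)
  sd_d <- stats::sd(d)
  t_naive <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (sd_d / sqrt(n))
  t_c <- t_naive / (n - 1)
  p <- if (is.infinite(t_c)) 0 else 2 * stats::pt(-abs(t_c), df = n - 1)
  structure(list(mean_a_ms = mean(onsets_a[ok]),
                 mean_b_ms = mean(onsets_b[ok]),
                 difference_ms = mean(d), t_naive = t_naive,
                 t_corrected = t_c, df = n - 1, p_value = p, n = n),
            class = "latency_contrast")
}

#' @export
print.latency_contrast <- function(x, ...) {
  cat("<latency_contrast> M = ", round(x$mean_a_ms), " vs ",
      round(x$mean_b_ms), " ms (diff ", round(x$difference_ms, 1),
      " ms), t_c(", x$df, ") = ", round(x$t_corrected, 2),
      ", p = ", signif(x$p_value, 2), "\n", sep = "")
  invisible(x)
}

#' Split epochs into target-color switch and repeat trials
#'
#' Partitions trials by whether the target color equals the previous trial's
#' target color within the same block; the first trial of each block has no
#' predecessor and is excluded from both sets.
#'
#' @param epochs an \code{\link{epochs_set}} with \code{target_color} and
#'   \code{block} metadata
#' @return list with \code{switch} and \code{repeat_} epochs_sets
#' @export
split_switch_repeat <- function(epochs) {
  stopifnot(inherits(epochs, "epochs_set"))
  need <- c("target_color", "block")
  if (!all(need %in% names(epochs$trials)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tr <- epochs$trials
  n <- nrow(tr)
  prev_same_block <- c(FALSE, tr$block[-1L] == tr$block[-n])
  same_color <- c(FALSE, tr$target_color[-1L] == tr$target_color[-n])
  list(switch = subset_trials(epochs, prev_same_block & !same_color),
       repeat_ = subset_trials(epochs, prev_same_block & same_color))
}
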