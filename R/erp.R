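#' Contralateral-minus-ipsilateral difference wave (N2pc)
#'
#' Computes the lateralized ERP difference at a posterior electrode pair:
#' for left-target trials the contralateral electrode is the right-hemisphere
#' member of the pair (e.g. PO8) and the ipsilateral one the left-hemisphere
#' member (PO7), and vice versa for right-target trials. The per-trial
#' contra-minus-ipsi difference is averaged over all trials with a lateral
#' target, collapsing over the vertical target position. An enhanced
#' negativity in the 200-350 ms window is the N2pc signature of attentional
#' selection.
#'
#' @param epochs an \code{\link{epochs_set}} with \code{h_class} metadata
#' @param pair electrode pair as c(left-hemisphere, right-hemisphere) labels;
#'   default \code{c("PO7", "PO8")}
#' @return object of class \code{difference_wave}: \code{wave} (microvolts
#'   per sample), \code{times_ms}, \code{pair}, \code{n_trials}
#' @export
lateralized_difference <- function(epochs, pair = c("PO7", "PO8")) {
  stopifnot(inherits(epochs, "epochs_set"))
  idx <- match(pair, epochs$channel_names)
  if (anyNA(idx))
    stop("electrode(s) not found: ", paste(pair[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (!"h_class" %in% names(epochs$trials))
    stop("h_class metadata required", call. = FALSE)
  left_ch <- epochs$data[, idx[1L], , drop = FALSE][, 1L, ]
  right_ch <- epochs$data[, idx[2L], , drop = FALSE][, 1L, ]
  is_left <- epochs$trials$h_class == "left"
  # contra - ipsi: left target -> right-hemisphere minus left-hemisphere
  diff <- right_ch - left_ch
  diff[!is_left, ] <- -diff[!is_left, , drop = FALSE]
  structure(list(wave = colMeans(diff), times_ms = epochs$times_ms,
                 pair = pair, n_trials = nrow(diff)),
            class = "difference_wave")
}

#' N2pc amplitude and onset latency over a cohort
#'
#' Group-level quantification of the lateralized difference waves: peak
#' amplitude of the group mean in the component window, jackknife
#' fractional-peak onset latencies (shared machinery with the decoding
#' latency analysis, chance reference 0), and a cluster permutation test of
#' the waves against zero.
#'
#' @param waves subjects x timepoints matrix of difference waves, or a list
#'   of \code{\link{difference_wave}} objects
#' @param times_ms time axis (taken from the waves when a list is given)
#' @param window_ms component window, default \code{c(200, 350)} ms (typical
#'   N2pc range)
#' @param fraction fractional-peak criterion (default 0.5)
#' @param n_perm permutations for the cluster test (default 5000)
#' @param polarity "negative" (default; the N2pc is a negativity, so peak =
#'   most negative point and the wave is sign-flipped for onset estimation)
#'   or "positive"
#' @param seed permutation seed
#' @return list with \code{peak_amplitude_uv}, \code{peak_time_ms},
#'   \code{onsets} (a \code{\link{jackknife_onset_latency}} result) and
#'   \code{cluster_test}
#' @export
n2pc_metrics <- function(waves, times_ms = NULL, window_ms = c(200, 350),
                         fraction = 0.5, n_perm = 5000,
                         polarity = c("negative", "positive"), seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.list(waves) && inherits(waves[[1L]], "difference_wave")) {
    times_ms <- waves[[1L]]$times_ms
    waves <- do.call(rbind, lapply(waves, `[[`, "wave"))
  }
  waves <- as.matrix(waves)
  stopifnot(!is.null(times_ms), ncol(waves) == length(times_ms))
  sgn <- if (polarity == "negative") -1 else 1
  idx <- window_index(times_ms, window_ms)
  gm <- colMeans(waves)
  pk <- idx[which.max(sgn * gm[idx])]
  onsets <- jackknife_onset_latency(sgn * waves, times_ms,
                                    window_ms = window_ms,
                                    fraction = fraction, chance = 0)
  ct <- cluster_permutation_test(waves, mu = 0, n_perm = n_perm,
                                 times_ms = times_ms, seed = seed)
  list(peak_amplitude_uv = gm[pk], peak_time_ms = times_ms[pk],
       onsets = onsets, cluster_test = ct)
}
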