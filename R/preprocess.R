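#' Trial rejection masks
#'
#' A rejection mask records, per trial, whether the trial is kept and the
#' reason code of the first rule that rejected it. Reason codes, in rule
#' order: \code{ok}, \code{rt_fast}, \code{rt_slow}, \code{incorrect},
#' \code{eog_step}, \code{emg}, \code{visual} (the last is reserved for a
#' manual-inspection stage and never set automatically).
#'
#' @param keep logical vector of keep flags
#' @param reason character vector of reason codes (\code{"ok"} for kept
#'   trials)
#' @return data.frame of class \code{rejection_mask} with columns
#'   \code{trial}, \code{keep}, \code{reason}
#' @export
rejection_mask <- function(keep, reason) {
  stopifnot(length(keep) == length(reason), all(keep == (reason == "ok")))
  valid <- c("ok", "rt_fast", "rt_slow", "incorrect", "eog_step", "emg",
             "visual")
  stopifnot(all(reason %in% valid))
  structure(data.frame(trial = seq_along(keep), keep = keep,
                       reason = reason, stringsAsFactors = FALSE),
            class = c("rejection_mask", "data.frame"))
}

#' Combine rejection masks with first-rule-wins precedence
#'
#' @param ... rejection masks over the same trials, in rule order
#' @return a single \code{rejection_mask}; a trial's reason is that of the
#'   first mask that rejected it
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  n <- nrow(masks[[1L]])
  reason <- rep("ok", n)
  for (m in masks) {
    stopifnot(nrow(m) == n)
    new <- reason == "ok" & !m$keep
    reason[new] <- m$reason[new]
  }
  rejection_mask(reason == "ok", reason)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the pre-stimulus
#' baseline window from every sample.
#'
#' @param epochs an \code{\link{epochs_set}}
#' @param window_ms baseline window, default \code{c(-100, 0)} ms
#' @return baseline-corrected \code{epochs_set}
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epochs_set"))
  idx <- window_index(epochs$times_ms, window_ms)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl) # recycles over samples
  epochs
}

#' Reject trials on behavioral criteria
#'
#' Flags trials with an incorrect response, anticipatory responses
#' (RT < \code{rt_min_ms}), and slow outliers
#' (RT > block mean + 3 block SD). Block mean and SD are computed once per
#' block over that block's correct trials, before any exclusion (single pass,
#' no iteration).
#'
#' @param trials data.frame with columns \code{rt_ms}, \code{correct},
#'   \code{block}
#' @param rt_min_ms anticipation threshold, default 200 ms
#' @param rt_sd_mult slow-outlier multiplier, default 3
#' @return a \code{\link{rejection_mask}}
#' @export
reject_by_response <- function(trials, rt_min_ms = 200, rt_sd_mult = 3) {
  need <- c("rt_ms", "correct", "block")
  if (!all(need %in% names(trials)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(trials)
  cut_hi <- stats::ave(ifelse(trials$correct, trials$rt_ms, NA_real_),
                       trials$block, FUN = function(r) {
                         mean(r, na.rm = TRUE) +
                           rt_sd_mult * stats::sd(r, na.rm = TRUE)
                       })
  reason <- rep("ok", n)
  reason[trials$rt_ms < rt_min_ms] <- "rt_fast"
  slow <- reason == "ok" & !is.na(cut_hi) & trials$rt_ms > cut_hi
  reason[slow] <- "rt_slow"
  reason[reason == "ok" & !trials$correct] <- "incorrect"
  rejection_mask(reason == "ok", reason)
}

#' Detect horizontal eye movements with a sliding step detector
#'
#' Scans each trial's horizontal-EOG trace over \code{scan_window_ms} with a
#' sliding window of \code{window_ms}, advanced in steps of \code{step_ms}. A
#' trial is flagged when the absolute difference between the mean of the
#' second and first half of any window reaches \code{threshold_uv}. The
#' statistic uses within-window differences only, so it is invariant to
#' adding a constant to the whole trace.
#'
#' @param heog numeric matrix, trials x samples, microvolts
#' @param times_ms time axis matching the columns of \code{heog}
#' @param threshold_uv step amplitude threshold (default 30)
#' @param window_ms window length (default 100)
#' @param step_ms step size (default 50)
#' @param scan_window_ms scan extent (default 0-500 ms post stimulus)
#' @return a \code{\link{rejection_mask}} with reason \code{eog_step}
#' @export
detect_eog_steps <- function(heog, times_ms, threshold_uv = 30,
                             window_ms = 100, step_ms = 50,
                             scan_window_ms = c(0, 500)) {
  stopifnot(is.matrix(heog), ncol(heog) == length(times_ms))
  if (scan_window_ms[1] < min(times_ms) || scan_window_ms[2] > max(times_ms))
    stop("scan window lies outside the epoch", call. = FALSE)
  sr <- 1000 / (times_ms[2] - times_ms[1])
  wlen <- max(2L, round(window_ms / 1000 * sr))
  half <- wlen %/% 2L
  step <- max(1L, round(step_ms / 1000 * sr))
  lo <- which.min(abs(times_ms - scan_window_ms[1]))
  hi <- which.min(abs(times_ms - scan_window_ms[2]))
  starts <- seq(lo, max(lo, hi - wlen + 1L), by = step)
  flagged <- rep(FALSE, nrow(heog))
  for (s0 in starts) {
    a <- rowMeans(heog[, s0:(s0 + half - 1L), drop = FALSE])
    b <- rowMeans(heog[, (s0 + half):(s0 + wlen - 1L), drop = FALSE])
    flagged <- flagged | abs(b - a) >= threshold_uv
  }
  rejection_mask(!flagged, ifelse(flagged, "eog_step", "ok"))
}

#' Reject high-frequency (EMG) artifact trials
#'
#' Band-pass filters every trial in the muscle-activity band, summarizes each
#' trial by its total band power across channels, z-scores the summary across
#' trials, and flags trials exceeding the subject-specific cutoff
#' \code{max(z_min, z_mult * sd(z))} (the z-scores have unit SD by
#' construction, so the default rule reduces to a cutoff of 3 unless raised
#' via \code{z_mult}). The chosen cutoff is returned as an attribute.
#'
#' @param epochs an \code{\link{epochs_set}}; sample rate must exceed twice
#'   the upper band edge
#' @param band_hz band-pass edges in Hz (default \code{c(110, 140)})
#' @param z_min minimum cutoff (default 3)
#' @param z_mult multiplier on the SD of the z-scores (default 3)
#' @return a \code{\link{rejection_mask}} with reason \code{emg} and
#'   attributes \code{cutoff} and \code{z} (per-trial z-scores)
#' @export
reject_emg <- function(epochs, band_hz = c(110, 140), z_min = 3, z_mult = 3) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (epochs$sample_rate <= 2 * band_hz[2])
    stop("sample rate ", epochs$sample_rate,
         " Hz too low for band ", band_hz[1], "-", band_hz[2], " Hz",
         call. = FALSE)
  n <- dim(epochs$data)[1L]
  if (all(epochs$data == 0))
    return(rejection_mask(rep(TRUE, n), rep("ok", n)))
  bf <- signal::butter(4, band_hz / (epochs$sample_rate / 2), type = "pass")
  pow <- vapply(seq_len(n), function(i) {
    tr <- epochs$data[i, , ] # channels x samples
    sum(apply(tr, 1L, function(ch)
      sum(signal::filtfilt(bf, ch)^2)))
  }, numeric(1))
  z <- as.vector(scale(pow))
  if (all(!is.finite(z))) z <- rep(0, n) # zero-variance power
  cutoff <- max(z_min, z_mult * stats::sd(z))
  flagged <- is.finite(z) & z > cutoff
  m <- rejection_mask(!flagged, ifelse(flagged, "emg", "ok"))
  attr(m, "cutoff") <- cutoff
  attr(m, "z") <- z
  m
}

#' Blink-component removal hook
#'
#' Pass-through stage standing where an ICA-based blink correction would run
#' on real recordings. A custom cleaning function can be supplied; by default
#' the epochs are returned unchanged.
#'
#' @param epochs an \code{\link{epochs_set}}
#' @param fun optional function \code{epochs -> epochs}
#' @return the (possibly cleaned) \code{epochs_set}
#' @export
remove_blink_components <- function(epochs, fun = NULL) {
  if (is.null(fun)) epochs else fun(epochs)
}

#' Run the full preprocessing chain
#'
#' Baseline correction, then trial screening in the fixed order
#' response -> horizontal-EOG step detection -> EMG band-power rejection,
#' with first-rule-wins reason codes. EOG screening runs only when a channel
#' named \code{heog_channel} is present.
#'
#' @param epochs an \code{\link{epochs_set}}
#' @param baseline_ms baseline window (default \code{c(-100, 0)})
#' @param heog_channel name of the horizontal-EOG channel (default "HEOG")
#' @param emg TRUE to apply EMG rejection (default TRUE)
#' @return list with \code{epochs} (kept, baseline-corrected trials) and
#'   \code{mask} (the combined \code{\link{rejection_mask}} over all input
#'   trials)
#' @export
preprocess_epochs <- function(epochs, baseline_ms = c(-100, 0),
                              heog_channel = "HEOG", emg = TRUE) {
  epochs <- baseline_correct(epochs, baseline_ms)
  masks <- list(reject_by_response(epochs$trials))
  if (heog_channel %in% epochs$channel_names) {
    ch <- match(heog_channel, epochs$channel_names)
    masks <- c(masks, list(detect_eog_steps(epochs$data[, ch, ],
                                            epochs$times_ms)))
  }
  if (emg) masks <- c(masks, list(reject_emg(epochs)))
  mask <- do.call(combine_masks, masks)
  list(epochs = subset_trials(epochs, mask$keep), mask = mask)
}

#' Write a rejection mask as a CSV sidecar
#'
#' @param mask a \code{\link{rejection_mask}}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}
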