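#' Half-sine ERP kernel
#'
#' Builds the canonical simulated attention ERP: half a cycle of a sine wave
#' rising from zero at \code{onset_ms}, peaking at the window midpoint with
#' value \code{amplitude}, and returning to zero at \code{offset_ms}. Samples
#' outside the window are exactly zero.
#'
#' @param amplitude peak amplitude in microvolts (default 1)
#' @param onset_ms,offset_ms kernel window, ms post-stimulus (default 200-600)
#' @param sample_rate sampling rate in Hz
#' @param times_ms epoch time axis the kernel is evaluated on
#' @return an object of class \code{erp_kernel} with fields \code{amplitude},
#'   \code{onset_ms}, \code{offset_ms}, \code{sample_rate}, \code{waveform}
#' @examples
#' k <- make_erp_kernel(1, 200, 600, 512, seq(-300, 800, by = 1000 / 512))
#' max(k$waveform)  # 1 at the 400 ms midpoint (up to sampling grid)
#' @export
make_erp_kernel <- function(amplitude = 1, onset_ms = 200, offset_ms = 600,
                            sample_rate = 512,
                            times_ms = seq(-300, 800, by = 1000 / sample_rate)) {
  if (offset_ms <= onset_ms)
    stop("offset_ms must exceed onset_ms", call. = FALSE)
  if (onset_ms < min(times_ms) || offset_ms > max(times_ms))
    stop("kernel window [", onset_ms, ", ", offset_ms,
         "] ms lies outside the epoch grid", call. = FALSE)
  w <- numeric(length(times_ms))
  inside <- times_ms >= onset_ms & times_ms <= offset_ms
  w[inside] <- amplitude *
    sin(pi * (times_ms[inside] - onset_ms) / (offset_ms - onset_ms))
  structure(list(amplitude = amplitude, onset_ms = onset_ms,
                 offset_ms = offset_ms, sample_rate = sample_rate,
                 times_ms = times_ms, waveform = w),
            class = "erp_kernel")
}

#' Orthogonal split of the signal channels
#'
#' The simulator writes the ERP onto eight signal channels. The horizontal
#' target is lateralized over one split of those channels
#' (contralateral +, ipsilateral -, relative to the first class level "left"),
#' the vertical target over an orthogonal split, so the two spatial patterns
#' are orthogonal channel-space vectors and carry independent information.
#'
#' @param channel_names full montage labels (default \code{\link{montage64}})
#' @param signal_channels labels of the eight channels carrying signal; the
#'   default places the horizontal split on the right/left posterior pairs so
#'   that the conventional N2pc electrodes PO7/PO8 are signal-bearing
#' @return an object of class \code{channel_split} with integer index fields
#'   \code{signal_channels}, \code{h_contra}, \code{h_ipsi}, \code{v_contra},
#'   \code{v_ipsi}
#' @export
make_channel_split <- function(channel_names = montage64(),
                               signal_channels = c("PO8", "P8", "PO4", "O2",
                                                   "PO7", "P7", "PO3", "O1")) {
  idx <- match(signal_channels, channel_names)
  if (anyNA(idx))
    stop("signal channels not in montage: ",
         paste(signal_channels[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(idx) != 8L) stop("exactly 8 signal channels required",
                              call. = FALSE)
  # horizontal: first four vs last four; vertical: orthogonal interleave
  split <- structure(
    list(signal_channels = idx,
         h_contra = idx[1:4], h_ipsi = idx[5:8],
         v_contra = idx[c(1, 2, 5, 6)], v_ipsi = idx[c(3, 4, 7, 8)]),
    class = "channel_split")
  stopifnot(length(intersect(split$h_contra, split$v_contra)) ==
              length(intersect(split$h_contra, split$v_ipsi)))
  split
}

# signed channel pattern (+1 contra / -1 ipsi) over the full montage
split_pattern <- function(split, dimension, n_channels) {
  p <- numeric(n_channels)
  if (dimension == "horizontal") {
    p[split$h_contra] <- 1; p[split$h_ipsi] <- -1
  } else {
    p[split$v_contra] <- 1; p[split$v_ipsi] <- -1
  }
  p
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-EEG generator. The defaults are
#' the study conditions of the simulation this package validates: 512 trials,
#' 64 channels at 512 Hz, epochs -300..800 ms, a 1 microvolt half-sine ERP
#' over 200-600 ms on 8 signal channels, and uniform noise whose maximum
#' amplitude is \code{amplitude / snr}.
#'
#' @param n_trials trials per dataset (even; default 512)
#' @param n_channels total channels (default 64); channels beyond the signal
#'   split carry noise only
#' @param correlation_mode injected inter-target dependency: "positive" (ERP
#'   on both targets or neither, half of trials each), "negative" (ERP on
#'   exactly one target, never both), or "null" (independent coin flips)
#' @param snr peak ERP amplitude divided by maximum noise amplitude (> 0)
#' @param amplitude kernel peak, microvolts (default 1)
#' @param onset_ms,offset_ms kernel window (default 200-600 ms)
#' @param sample_rate Hz (default 512)
#' @param epoch_window_ms epoch extent relative to stimulus (default
#'   c(-300, 800))
#' @param noise_amplitude maximum noise magnitude in microvolts; defaults to
#'   \code{amplitude / snr}. Supply explicitly to simulate noise-only data
#'   (\code{amplitude = 0}).
#' @param noise one of "uniform" (default; hard bound at
#'   \code{noise_amplitude}) or "gaussian" (sd = \code{noise_amplitude / 3})
#' @param channel_names montage labels, length \code{n_channels}
#' @param split a \code{channel_split}; default built from
#'   \code{channel_names}
#' @param accuracy,rt_meanlog,rt_sdlog,rt_shift_ms behavioral metadata model:
#'   response correctness is Bernoulli(\code{accuracy}) and RTs are shifted
#'   lognormal, giving realistic input for the response-based trial rejection
#' @param block_size trials per block for the metadata (default 32)
#' @param condition condition label stored in the metadata
#' @param seed integer seed; all randomness in \code{generate_dataset} derives
#'   from it
#' @return an object of class \code{simulation_config}
#' @export
simulation_config <- function(n_trials = 512, n_channels = 64,
                              correlation_mode = c("negative", "positive",
                                                   "null"),
                              snr = 4, amplitude = 1,
                              onset_ms = 200, offset_ms = 600,
                              sample_rate = 512,
                              epoch_window_ms = c(-300, 800),
                              noise_amplitude = NULL,
                              noise = c("uniform", "gaussian"),
                              channel_names = NULL, split = NULL,
                              accuracy = 0.95, rt_meanlog = log(650),
                              rt_sdlog = 0.2, rt_shift_ms = 50,
                              block_size = 32,
                              condition = "2TMP-2TGT", seed = 1L) {
  correlation_mode <- match.arg(correlation_mode)
  noise <- match.arg(noise)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (n_trials %% 2L != 0L) stop("n_trials must be even", call. = FALSE)
  if (n_channels < 8L)
    stop("n_channels must be at least 8 to host the signal split",
         call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 64L) montage64() else
      sprintf("CH%02d", seq_len(n_channels))
  }
  stopifnot(length(channel_names) == n_channels)
  if (is.null(split)) {
    split <- if (all(c("PO7", "PO8") %in% channel_names))
      make_channel_split(channel_names) else
      make_channel_split(channel_names, channel_names[1:8])
  }
  if (is.null(noise_amplitude)) noise_amplitude <- amplitude / snr
  if (epoch_window_ms[1] > onset_ms || epoch_window_ms[2] < offset_ms)
    stop("epoch window must contain the kernel window", call. = FALSE)
  structure(
    list(n_trials = n_trials, n_channels = n_channels,
         correlation_mode = correlation_mode, snr = snr,
         amplitude = amplitude, onset_ms = onset_ms, offset_ms = offset_ms,
         sample_rate = sample_rate, epoch_window_ms = epoch_window_ms,
         noise_amplitude = noise_amplitude, noise = noise,
         channel_names = channel_names, split = split,
         accuracy = accuracy, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         rt_shift_ms = rt_shift_ms, block_size = block_size,
         condition = condition, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Draw per-trial ERP presence flags with a known correlation structure
#'
#' @param correlation_mode "positive", "negative" or "null"; positive gives
#'   exactly half the trials an ERP on both targets and half on neither,
#'   negative gives exactly half an ERP on the horizontal target only and half
#'   on the vertical target only (never both), null draws presence of each
#'   target independently with probability 1/2
#' @param n_trials even trial count (divisible by 4 recommended for null-mode
#'   balance)
#' @param seed integer seed
#' @return data.frame with logical columns \code{erp_present_h},
#'   \code{erp_present_v}
#' @export
draw_presence <- function(correlation_mode, n_trials, seed = 1L) {
  if (n_trials %% 2L != 0L) stop("n_trials must be even", call. = FALSE)
  with_seed(seed, {
    half <- n_trials / 2L
    ord <- sample.int(n_trials)
    switch(correlation_mode,
      positive = {
        h <- rep(c(TRUE, FALSE), each = half)[ord]
        data.frame(erp_present_h = h, erp_present_v = h)
      },
      negative = {
        h <- rep(c(TRUE, FALSE), each = half)[ord]
        data.frame(erp_present_h = h, erp_present_v = !h)
      },
      null = data.frame(
        erp_present_h = stats::runif(n_trials) < 0.5,
        erp_present_v = stats::runif(n_trials) < 0.5),
      stop("unknown correlation_mode: ", correlation_mode, call. = FALSE))
  })
}

# balanced random class labels: exactly n/2 of each level, shuffled
balanced_classes <- function(levels2, n) {
  sample(rep(levels2, length.out = n))
}

#' Generate one synthetic epoched-EEG dataset
#'
#' Simulates one subject's epochs: balanced left/right and top/bottom target
#' positions, the half-sine ERP written with + sign on the contralateral and
#' - sign on the ipsilateral half of the signal channels on ERP-present trials
#' (sign convention fixed per class; swapping the class flips both signs), and
#' i.i.d. noise on every trial, channel and sample. Noise is uniform on
#' [-noise_amplitude, +noise_amplitude] so that the peak-ERP to maximum-noise
#' ratio is exactly the configured SNR, or Gaussian with
#' sd = noise_amplitude/3 when \code{noise = "gaussian"}. Non-signal channels
#' contain noise only. Class labels on ERP-absent trials are still assigned
#' (balanced at random) and carry chance-level information only.
#'
#' @param config a \code{\link{simulation_config}}
#' @return an \code{\link{epochs_set}} with simulation ground truth
#'   (\code{erp_present_h}, \code{erp_present_v}) in the metadata
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_trials; p <- config$n_channels
  times <- seq(config$epoch_window_ms[1], config$epoch_window_ms[2],
               by = 1000 / config$sample_rate)
  s <- length(times)
  kernel <- make_erp_kernel(config$amplitude, config$onset_ms,
                            config$offset_ms, config$sample_rate, times)
  presence <- draw_presence(config$correlation_mode, n,
                            derive_seed(config$seed, "presence"))

  meta <- with_seed(derive_seed(config$seed, "labels"), {
    data.frame(
      condition = config$condition,
      h_class = balanced_classes(c("left", "right"), n),
      v_class = balanced_classes(c("top", "bottom"), n),
      erp_present_h = presence$erp_present_h,
      erp_present_v = presence$erp_present_v,
      block = rep(seq_len(ceiling(n / config$block_size)),
                  each = config$block_size)[seq_len(n)],
      target_color = sample(c("red", "green", "blue", "yellow"), n,
                            replace = TRUE),
      correct = stats::runif(n) < config$accuracy,
      rt_ms = config$rt_shift_ms +
        stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog))
  })

  x <- with_seed(derive_seed(config$seed, "noise"), {
    b <- config$noise_amplitude
    if (config$noise == "uniform")
      array(stats::runif(n * p * s, -b, b), dim = c(n, p, s))
    else
      array(stats::rnorm(n * p * s, 0, b / 3), dim = c(n, p, s))
  })

  # signed trial coefficient: +1 first class, -1 second, 0 when ERP absent
  coef_h <- ifelse(meta$erp_present_h,
                   ifelse(meta$h_class == "left", 1, -1), 0)
  coef_v <- ifelse(meta$erp_present_v,
                   ifelse(meta$v_class == "top", 1, -1), 0)
  add_pattern <- function(x, coefs, contra, ipsi) {
    contrib <- outer(coefs, kernel$waveform) # trials x samples
    for (ch in contra) x[, ch, ] <- x[, ch, ] + contrib
    for (ch in ipsi) x[, ch, ] <- x[, ch, ] - contrib
    x
  }
  x <- add_pattern(x, coef_h, config$split$h_contra, config$split$h_ipsi)
  x <- add_pattern(x, coef_v, config$split$v_contra, config$split$v_ipsi)

  epochs_set(x, config$sample_rate, times, config$channel_names, meta)
}

#' Generate a cohort of independent simulated subjects
#'
#' Each subject receives a distinct child seed derived deterministically from
#' \code{seed}, so the cohort is reproducible as a whole and per subject.
#'
#' @param config a \code{\link{simulation_config}} (its own seed is ignored)
#' @param n_subjects number of subjects (>= 2)
#' @param seed master cohort seed
#' @return list of \code{\link{epochs_set}} objects, length \code{n_subjects}
#' @export
generate_cohort <- function(config, n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 2L)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "subject", i)
    generate_dataset(cfg)
  })
}
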