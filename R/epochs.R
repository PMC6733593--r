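#' Epoched multichannel EEG container
#'
#' An \code{epochs_set} holds a trials x channels x samples tensor (microvolts)
#' together with its time axis and per-trial metadata, the common currency of
#' every stage of the pipeline (simulation, preprocessing, decoding, ERP
#' analysis).
#'
#' @param data numeric array, trials x channels x samples, in microvolts
#' @param sample_rate sampling rate in Hz
#' @param times_ms numeric vector of per-sample timestamps (ms relative to
#'   stimulus onset); must be strictly increasing and uniformly spaced at
#'   \code{1000 / sample_rate}
#' @param channel_names character vector of channel labels
#' @param trials data.frame of per-trial metadata; typical columns are
#'   \code{condition}, \code{h_class} ("left"/"right"), \code{v_class}
#'   ("top"/"bottom"), \code{erp_present_h}, \code{erp_present_v} (simulation
#'   only), \code{block}, \code{target_color}, \code{correct}, \code{rt_ms}
#' @return an object of class \code{epochs_set}
#' @export
epochs_set <- function(data, sample_rate, times_ms, channel_names, trials) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (nrow(trials) != dim(data)[1L])
    stop("metadata rows (", nrow(trials), ") must equal number of trials (",
         dim(data)[1L], ")", call. = FALSE)
  if (length(channel_names) != dim(data)[2L])
    stop("channel_names length must equal number of channels", call. = FALSE)
  if (length(times_ms) != dim(data)[3L])
    stop("times_ms length must equal number of samples", call. = FALSE)
  dt <- diff(times_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / sample_rate)) > 1e-6)
    stop("times_ms must be strictly increasing and uniformly spaced at ",
         "1000/sample_rate ms", call. = FALSE)
  structure(
    list(data = data, sample_rate = sample_rate, times_ms = times_ms,
         channel_names = as.character(channel_names),
         trials = as.data.frame(trials)),
    class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epochs_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  cat("  time: ", round(min(x$times_ms)), " .. ", round(max(x$times_ms)),
      " ms\n", sep = "")
  cat("  metadata: ", paste(names(x$trials), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.epochs_set <- function(x) dim(x$data)

#' Subset an epochs_set by trial
#'
#' @param epochs an \code{epochs_set}
#' @param keep logical or integer index of trials to keep
#' @return an \code{epochs_set} with the selected trials
#' @export
subset_trials <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epochs_set"))
  epochs_set(epochs$data[keep, , , drop = FALSE], epochs$sample_rate,
             epochs$times_ms, epochs$channel_names,
             epochs$trials[keep, , drop = FALSE])
}

#' Write / read an epochs_set
#'
#' Epochs serialize to an RDS file with a plain-text CSV sidecar carrying the
#' per-trial metadata (\code{<path>.trials.csv}), so the trial table remains
#' inspectable without R. The round-trip is bit-exact.
#'
#' @param epochs an \code{epochs_set}
#' @param path file path (conventionally \code{*.rds})
#' @return \code{write_epochs} returns \code{path} invisibly;
#'   \code{read_epochs} returns the restored \code{epochs_set}.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  saveRDS(epochs, path)
  utils::write.csv(epochs$trials, paste0(path, ".trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epochs_set"))
  x
}

#' Standard 64-channel montage labels
#'
#' The 10-20 labels of the usual 64-channel BioSemi layout, so that
#' conventional electrode names (e.g. "PO7"/"PO8" for the N2pc pair) resolve
#' on simulated data.
#'
#' @return character vector of 64 channel labels
#' @export
montage64 <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}
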