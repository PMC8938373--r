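# Deterministic signal conditioning: continuous recording container,
# re-referencing, zero-phase filtering, resampling, epoching with
# baseline correction.

#' Continuous multichannel recording
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param labels channel labels (length = nrow(data)).
#' @param events data.frame with at least `sample` (1-based stimulus
#'   onset sample, strictly increasing); further columns are carried as
#'   trial metadata.
#' @param montage optional `montage`.
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sample_rate, labels,
                                 events = NULL, montage = NULL) {
  data <- as.matrix(data)
  stopifnot(sample_rate > 0, nrow(data) == length(labels))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(events)) events <- data.frame(sample = integer(0))
  stopifnot(is.data.frame(events), "sample" %in% names(events))
  if (is.unsorted(events$sample, strictly = TRUE))
    stop("event samples must be strictly increasing")
  rownames(data) <- labels
  structure(list(data = data, sample_rate = sample_rate,
                 labels = labels, events = events, montage = montage),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$sample_rate, " Hz; ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts the per-sample mean of the reference channels (typically the
#' averaged mastoids) from every scalp EEG channel. EOG and the reference
#' channels themselves are left untouched; reference channels are
#' retained in the recording.
#'
#' @param recording a `continuous_recording`.
#' @param reference_channels labels of the reference channels.
#' @param scalp_channels labels to re-reference; default: all channels of
#'   type "eeg" in the montage, or all channels not in
#'   `reference_channels` if no montage is attached.
#' @return re-referenced `continuous_recording`.
#' @export
rereference <- function(recording, reference_channels = c("M1", "M2"),
                        scalp_channels = NULL) {
  miss <- setdiff(reference_channels, recording$labels)
  if (length(miss)) stop("missing reference channel(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(scalp_channels)) {
    if (!is.null(recording$montage)) {
      ch <- recording$montage$channels
      scalp_channels <- intersect(ch$label[ch$type == "eeg"],
                                  recording$labels)
    } else {
      scalp_channels <- setdiff(recording$labels, reference_channels)
    }
  }
  ref <- colMeans(recording$data[reference_channels, , drop = FALSE])
  idx <- match(scalp_channels, recording$labels)
  recording$data[idx, ] <- sweep(recording$data[idx, , drop = FALSE], 2, ref)
  recording
}

# zero-phase Butterworth filtering; order > 2 is applied as a cascade of
# order-2 sections for numerical stability at very low relative cutoffs
#' @keywords internal
.zp_filter <- function(x, rate, type, cutoff, order = 4) {
  w <- cutoff / (rate / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff must lie strictly between 0 and Nyquist (",
         rate / 2, " Hz): got ", paste(cutoff, collapse = "-"))
  n_sections <- max(1L, as.integer(round(order / 2)))
  bf <- signal::butter(2, w, type = type)
  for (s in seq_len(n_sections)) {
    x <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  }
  x
}

#' Filter and resample a continuous recording
#'
#' Applies zero-phase (forward-backward) Butterworth filtering --
#' high-pass, low-pass, and band-stop notch -- and polyphase resampling
#' to a target rate. By default filtering runs at the native rate before
#' resampling so every cutoff (including a low-pass above the target
#' Nyquist) is applied where it is valid; the stage order is
#' configurable. Event sample indices are remapped to the new rate.
#'
#' @param recording a `continuous_recording`.
#' @param highpass high-pass cutoff in Hz, or NULL to skip.
#' @param lowpass low-pass cutoff in Hz, or NULL to skip.
#' @param notch_band length-2 band-stop edges in Hz, or NULL to skip.
#' @param target_rate output rate in Hz, or NULL to keep the native rate.
#' @param order Butterworth order (applied as cascaded order-2 sections).
#' @param stage_order character vector over `"filter"`, `"resample"`.
#' @return filtered `continuous_recording`.
#' @export
filter_resample <- function(recording, highpass = 0.1, lowpass = 120,
                            notch_band = c(48, 52), target_rate = 200,
                            order = 4, stage_order = c("filter", "resample")) {
  if (!is.null(highpass) && !is.null(lowpass) && highpass >= lowpass)
    stop("highpass cutoff must be below lowpass cutoff")
  do_filter <- function(rec) {
    x <- rec$data
    if (!is.null(highpass)) x <- .zp_filter(x, rec$sample_rate, "high", highpass, order)
    if (!is.null(lowpass))  x <- .zp_filter(x, rec$sample_rate, "low", lowpass, order)
    if (!is.null(notch_band)) {
      stopifnot(length(notch_band) == 2, notch_band[1] < notch_band[2])
      x <- .zp_filter(x, rec$sample_rate, "stop", notch_band, order)
    }
    rownames(x) <- rec$labels
    rec$data <- x
    rec
  }
  do_resample <- function(rec) {
    if (is.null(target_rate) || target_rate == rec$sample_rate) return(rec)
    stopifnot(target_rate > 0, target_rate < rec$sample_rate)
    fr <- .as_fraction(target_rate / rec$sample_rate)
    x <- t(apply(rec$data, 1, function(row)
      signal::resample(row, fr[1], fr[2])))
    rownames(x) <- rec$labels
    rec$data <- x
    if (nrow(rec$events))
      rec$events$sample <- pmin(ncol(x), pmax(1L, as.integer(
        round((rec$events$sample - 1) * target_rate / rec$sample_rate) + 1L)))
    rec$sample_rate <- target_rate
    rec
  }
  for (stage in stage_order) {
    recording <- switch(stage, filter = do_filter(recording),
                        resample = do_resample(recording),
                        stop("unknown stage: ", stage))
  }
  recording
}

#' @keywords internal
.as_fraction <- function(r, max_den = 1024) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("rate ratio has no small rational representation")
}

#' Epoch set: trials x channels x time with metadata
#'
#' @keywords internal
new_epoch_set <- function(data, times, sample_rate, labels, meta,
                          valid = NULL, dropped = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(labels),
            dim(data)[3] == length(times), nrow(meta) == dim(data)[1])
  if (is.null(valid)) valid <- rep(TRUE, dim(data)[1])
  structure(list(data = data, times = times, sample_rate = sample_rate,
                 labels = labels, meta = meta, valid = valid,
                 dropped = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trials (", sum(x$valid),
      " valid) x ", dim(x$data)[2], " channels x ", dim(x$data)[3],
      " samples; ", min(x$times), "..", max(x$times), " ms @ ",
      x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Cut epochs around events with baseline correction
#'
#' Cuts a half-open window `[window[1], window[2])` ms around each event
#' on the sample grid (time 0 = the stimulus-onset sample), optionally
#' crops, subtracts the per-epoch per-channel mean over the baseline
#' interval, and optionally applies a zero-phase low-pass to the epoched
#' data. Events whose window runs off the recording edge are dropped and
#' logged in `$dropped`.
#'
#' Processing order follows crop -> baseline -> low-pass.
#'
#' @param recording a `continuous_recording` with events.
#' @param window epoch window in ms relative to stimulus onset.
#' @param baseline baseline interval in ms, or NULL to skip.
#' @param crop optional crop interval in ms applied before baseline.
#' @param lowpass_post optional low-pass cutoff (Hz) applied per epoch.
#' @return an `epoch_set`.
#' @export
epoch_baseline <- function(recording, window = c(-600, 1400),
                           baseline = c(-100, 0), crop = NULL,
                           lowpass_post = NULL) {
  stopifnot(window[1] < 0, window[2] > 0)
  if (!nrow(recording$events)) stop("recording has no events")
  rate <- recording$sample_rate
  off1 <- as.integer(round(window[1] * rate / 1000))
  off2 <- as.integer(round(window[2] * rate / 1000)) - 1L
  n_samp <- off2 - off1 + 1L
  ev <- recording$events
  ok <- ev$sample + off1 >= 1 & ev$sample + off2 <= ncol(recording$data)
  dropped <- ev[!ok, , drop = FALSE]
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no events with a complete epoch window")

  n_ch <- nrow(recording$data)
  data <- array(NA_real_, dim = c(nrow(ev), n_ch, n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample[i] + off1):(ev$sample[i] + off2)
    data[i, , ] <- recording$data[, idx]
  }
  times <- (off1:off2) / rate * 1000

  if (!is.null(crop)) {
    keep <- times >= crop[1] & times < crop[2]
    data <- data[, , keep, drop = FALSE]
    times <- times[keep]
  }
  if (!is.null(baseline)) {
    bidx <- which(times >= baseline[1] & times < baseline[2] + 1e-9)
    if (!length(bidx)) stop("baseline interval contains no samples")
    bl <- apply(data[, , bidx, drop = FALSE], c(1, 2), mean)
    data <- sweep(data, c(1, 2), bl)
  }
  if (!is.null(lowpass_post)) {
    bf <- signal::butter(2, lowpass_post / (rate / 2), type = "low")
    for (i in seq_len(dim(data)[1]))
      for (j in seq_len(dim(data)[2]))
        data[i, j, ] <- signal::filtfilt(bf, data[i, j, ])
  }
  meta <- ev
  meta$sample <- NULL
  if (!ncol(meta)) meta <- data.frame(trial = seq_len(nrow(ev)))
  new_epoch_set(data, times, rate, recording$labels, meta,
                dropped = dropped)
}
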