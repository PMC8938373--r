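# Trial selection and balancing, condition averaging, and P300
# measurement: window-mean amplitude, fractional-area latency, ROI means.

#' Flag valid trials by amplitude threshold and correctness
#'
#' Marks an epoch invalid when any sample on any EEG channel exceeds the
#' rejection threshold in absolute value, or when the trial was answered
#' incorrectly (metadata column `correct`, when present).
#'
#' @param epochs an `epoch_set`.
#' @param amplitude_threshold rejection threshold in microvolts.
#' @param eeg_channels labels to screen; defaults to all channels.
#' @return the `epoch_set` with `$valid` updated and a `rejection`
#'   attribute recording per-reason counts.
#' @export
select_valid_trials <- function(epochs, amplitude_threshold = 120,
                                eeg_channels = NULL) {
  ch <- if (is.null(eeg_channels)) seq_along(epochs$labels)
        else match(eeg_channels, epochs$labels)
  if (anyNA(ch)) stop("unknown EEG channel label(s)")
  amp_bad <- apply(abs(epochs$data[, ch, , drop = FALSE]) >
                     amplitude_threshold, 1, any)
  incorrect <- if ("correct" %in% names(epochs$meta))
    !epochs$meta$correct else rep(FALSE, dim(epochs$data)[1])
  epochs$valid <- epochs$valid & !amp_bad & !incorrect
  attr(epochs, "rejection") <- list(amplitude = sum(amp_bad),
                                    incorrect = sum(incorrect),
                                    retained = sum(epochs$valid))
  epochs
}

#' Balance non-target trial counts against targets
#'
#' Correct non-target trials outnumber correct target trials, so per
#' block each valid target (in temporal order) selects the not yet
#' selected valid non-target with the smallest trial-index distance
#' (ties go to the earlier trial); unselected non-targets are flagged
#' invalid. Requires metadata columns `is_target` and (if multiple
#' blocks) `block`.
#'
#' @param epochs an `epoch_set` with validity flags set.
#' @return the `epoch_set` with non-selected non-targets invalidated.
#' @export
balance_nontargets <- function(epochs) {
  meta <- epochs$meta
  stopifnot("is_target" %in% names(meta))
  block <- if ("block" %in% names(meta)) meta$block else rep(1L, nrow(meta))
  pos <- if ("position" %in% names(meta)) meta$position else seq_len(nrow(meta))
  keep_nt <- rep(FALSE, nrow(meta))
  any_target <- FALSE
  for (b in unique(block)) {
    in_b <- which(block == b)
    tgt <- in_b[meta$is_target[in_b] & epochs$valid[in_b]]
    nt <- in_b[!meta$is_target[in_b] & epochs$valid[in_b]]
    if (!length(tgt)) next
    any_target <- TRUE
    avail <- nt
    for (t_i in tgt[order(pos[tgt])]) {
      if (!length(avail)) break
      d <- abs(pos[avail] - pos[t_i])
      pick <- avail[order(d, pos[avail])][1]
      keep_nt[pick] <- TRUE
      avail <- setdiff(avail, pick)
    }
  }
  if (!any_target) warning("no valid target trials; empty selection")
  drop <- !epochs$meta$is_target & !keep_nt
  epochs$valid <- epochs$valid & !(drop)
  epochs
}

#' Condition-averaged waveform
#'
#' @param epochs an `epoch_set`.
#' @param condition optional logical/integer index over trials (e.g.
#'   `epochs$meta$is_target`); combined with the validity flags.
#' @param label condition label carried on the result.
#' @return object of class `evoked`: `data` (channels x samples, uV),
#'   `times`, `labels`, `n_trials`, `condition`.
#' @export
average_evoked <- function(epochs, condition = NULL, label = "all") {
  sel <- epochs$valid
  if (!is.null(condition)) {
    if (is.logical(condition)) sel <- sel & condition
    else sel <- sel & seq_len(dim(epochs$data)[1]) %in% condition
  }
  if (!any(sel)) stop("no valid trials in condition '", label, "'")
  dat <- epochs$data[sel, , , drop = FALSE]
  avg <- apply(dat, c(2, 3), mean)
  rownames(avg) <- epochs$labels
  structure(list(data = avg, times = epochs$times, labels = epochs$labels,
                 n_trials = sum(sel), condition = label),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat("<evoked> '", x$condition, "': ", nrow(x$data), " channels x ",
      length(x$times), " samples, n = ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

#' @keywords internal
.check_axes <- function(a, b) {
  if (!isTRUE(all.equal(a$times, b$times)) ||
      !identical(a$labels, b$labels))
    stop("evoked objects have mismatching time axes or channels")
}

#' Grand average across subjects
#'
#' @param evoked_list list of `evoked` with identical axes.
#' @return `evoked` with the unweighted mean waveform; `n_trials` is the
#'   number of contributing averages.
#' @export
grand_average <- function(evoked_list) {
  stopifnot(length(evoked_list) >= 1)
  for (e in evoked_list[-1]) .check_axes(evoked_list[[1]], e)
  dat <- Reduce(`+`, lapply(evoked_list, `[[`, "data")) / length(evoked_list)
  out <- evoked_list[[1]]
  out$data <- dat
  out$n_trials <- length(evoked_list)
  out$condition <- paste0("grand(", evoked_list[[1]]$condition, ")")
  out
}

#' Difference wave a - b
#'
#' @param a,b `evoked` objects on identical axes.
#' @return `evoked` of the sample-wise difference.
#' @export
difference_wave <- function(a, b) {
  .check_axes(a, b)
  a$data <- a$data - b$data
  a$n_trials <- min(a$n_trials, b$n_trials)
  a$condition <- paste0(a$condition, "-", b$condition)
  a
}

#' @keywords internal
.site_rows <- function(evoked, site, roi_map = NULL) {
  if (site %in% evoked$labels) return(match(site, evoked$labels))
  if (!is.null(roi_map) && site %in% names(roi_map)) {
    idx <- match(roi_map[[site]], evoked$labels)
    if (anyNA(idx)) stop("ROI '", site, "' has channels missing from data")
    return(idx)
  }
  stop("unknown site: ", site)
}

#' Window-mean amplitude at a channel or ROI
#'
#' Mean voltage over the analysis window (inclusive endpoints on the
#' sample grid); for an ROI, the mean over its 7 channels then over time.
#'
#' @param evoked an `evoked`.
#' @param site channel label or ROI name.
#' @param window length-2 window in ms.
#' @param roi_map named list of ROI channel sets (e.g.
#'   `make_montage()$roi_map`) when `site` is an ROI.
#' @return mean amplitude in microvolts.
#' @export
window_amplitude <- function(evoked, site = "Pz", window = c(300, 700),
                             roi_map = NULL) {
  rows <- .site_rows(evoked, site, roi_map)
  tidx <- which(evoked$times >= window[1] - 1e-9 &
                  evoked$times <= window[2] + 1e-9)
  if (!length(tidx)) stop("window contains no samples")
  mean(evoked$data[rows, tidx])
}

#' Fractional-area latency
#'
#' The time at which a given fraction (default 50\%) of the area under
#' the waveform within the analysis window has accumulated. Negative
#' values are rectified to zero by default (the P300 is a positivity;
#' signed area can make the crossing non-monotone); cumulative area is
#' computed trapezoidally on the sample grid and the crossing located by
#' linear interpolation.
#'
#' @param waveform numeric vector (one channel), or an `evoked` with
#'   `site` given.
#' @param times time axis in ms (taken from the `evoked` if given).
#' @param window analysis window in ms, inclusive endpoints.
#' @param fraction area fraction in (0,1).
#' @param rectify rectify negative values to 0 (default) or use signed
#'   area.
#' @param site channel label when `waveform` is an `evoked`.
#' @return latency in ms, or NA (with a warning) if the windowed
#'   rectified area is zero.
#' @export
fractional_area_latency <- function(waveform, times = NULL,
                                    window = c(300, 700), fraction = 0.5,
                                    rectify = TRUE, site = "Pz") {
  stopifnot(fraction > 0, fraction < 1)
  if (inherits(waveform, "evoked")) {
    times <- waveform$times
    waveform <- waveform$data[.site_rows(waveform, site), ]
  }
  stopifnot(length(waveform) == length(times))
  sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(sel) < 2) stop("window contains fewer than 2 samples")
  w <- waveform[sel]
  tt <- times[sel]
  if (rectify) w <- pmax(w, 0)
  # trapezoidal cumulative area
  seg <- diff(tt) * (utils::head(w, -1) + utils::tail(w, -1)) / 2
  total <- sum(seg)
  if (total <= 0) {
    warning("zero rectified area in window; latency undefined")
    return(NA_real_)
  }
  cum <- c(0, cumsum(seg))
  target <- fraction * total
  k <- which(cum >= target)[1]
  if (k == 1) return(tt[1])
  # linear interpolation within segment k-1
  over <- target - cum[k - 1]
  tt[k - 1] + diff(tt)[k - 1] * over / seg[k - 1]
}

#' Measure P300 amplitude and latency for one subject
#'
#' Computes window-mean amplitude in the full (300-700 ms), early
#' (300-500 ms) and late (500-700 ms) windows at a channel and the four
#' ROIs, plus 50\% fractional-area latency at the channel in the full
#' window, for an evoked response.
#'
#' @param evoked an `evoked`.
#' @param channel canonical measurement channel (default Pz).
#' @param roi_map ROI definition (default: the standard montage's).
#' @param windows named list of measurement windows in ms.
#' @return data.frame with columns `site`, `window`, `amplitude_uV`,
#'   `latency_ms` (latency only at the channel, full window),
#'   `n_trials`.
#' @export
p300_measures <- function(evoked, channel = "Pz", roi_map = NULL,
                          windows = list(full = c(300, 700),
                                         early = c(300, 500),
                                         late = c(500, 700))) {
  if (is.null(roi_map)) roi_map <- .roi_lists
  sites <- c(channel, names(roi_map))
  out <- list()
  for (win_name in names(windows)) {
    for (site in sites) {
      amp <- window_amplitude(evoked, site, windows[[win_name]], roi_map)
      lat <- if (site == channel && win_name == "full")
        fractional_area_latency(evoked, window = windows[[win_name]],
                                site = channel)
      else NA_real_
      out[[length(out) + 1]] <- data.frame(
        site = site, window = win_name, amplitude_uV = amp,
        latency_ms = lat, n_trials = evoked$n_trials)
    }
  }
  res <- do.call(rbind, out)
  res$condition <- evoked$condition
  # conditions averaging fewer than 10 valid trials are unreliable
  res$low_trial <- evoked$n_trials < 10
  res
}
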