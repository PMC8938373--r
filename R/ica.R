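# ICA-based ocular artifact removal: FastICA decomposition, blink
# detection and template, z-scored component-artifact correlations,
# suspect flagging, removal and interpolation matrices composed into a
# single cleaning montage.

#' @keywords internal
.sym_decorrelate <- function(W) {
  s <- La.svd(W)
  s$u %*% s$vt
}

#' Fit ICA to epoched EEG data
#'
#' Concatenates epochs, reduces the EEG channels to `n_components`
#' principal components, and runs symmetric fixed-point ICA (tanh
#' nonlinearity) on the whitened data. Components are ordered by
#' explained variance and sign-fixed (largest mixing weight positive),
#' so the fit is deterministic under a fixed seed.
#'
#' @param epochs an `epoch_set` or a channels x samples matrix.
#' @param n_components number of components to extract (default 32).
#' @param seed integer seed for the unmixing initialisation.
#' @param channels labels of the EEG channels to decompose; default: all
#'   labels except VEOG/HEOG/M1/M2.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `ica_model`: `unmixing` (components x
#'   channels), `mixing` (channels x components), `sources` (components
#'   x samples), `channels`, `n_components`, `seed`.
#' @export
fit_ica <- function(epochs, n_components = 32, seed = 1L,
                    channels = NULL, max_iter = 200, tol = 1e-6) {
  if (inherits(epochs, "epoch_set")) {
    labs <- epochs$labels
    if (is.null(channels))
      channels <- setdiff(labs, c("VEOG", "HEOG", "M1", "M2"))
    idx <- match(channels, labs)
    if (anyNA(idx)) stop("unknown channel label(s)")
    d <- epochs$data[, idx, , drop = FALSE]
    X <- matrix(aperm(d, c(2, 3, 1)), nrow = length(idx))
  } else {
    X <- as.matrix(epochs)
    channels <- if (is.null(channels)) rownames(X) else channels
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(X)))
  }
  n_ch <- nrow(X)
  if (n_components > n_ch)
    stop("requested ", n_components, " components from ", n_ch, " channels")
  X <- X - rowMeans(X)
  n_t <- ncol(X)

  cv <- tcrossprod(X) / n_t
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_components) {
    warning("rank ", sum(pos), " below requested ", n_components,
            " components; reducing")
    n_components <- sum(pos)
  }
  K <- diag(1 / sqrt(eg$values[1:n_components]), n_components) %*%
    t(eg$vectors[, 1:n_components, drop = FALSE])
  Z <- K %*% X

  local_seed(seed, "ica")
  W <- .sym_decorrelate(matrix(stats::rnorm(n_components^2), n_components))
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W_new <- G %*% t(Z) / n_t - diag(rowMeans(1 - G^2)) %*% W
    W_new <- .sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) break
  }

  unmixing <- W %*% K
  mixing <- eg$vectors[, 1:n_components, drop = FALSE] %*%
    diag(sqrt(eg$values[1:n_components]), n_components) %*% t(W)

  # order by explained variance (sources are unit variance)
  ev <- colSums(mixing^2)
  ord <- order(ev, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude mixing weight positive
  for (k in seq_len(n_components)) {
    s <- sign(mixing[which.max(abs(mixing[, k])), k])
    mixing[, k] <- mixing[, k] * s
    unmixing[k, ] <- unmixing[k, ] * s
  }
  rownames(mixing) <- channels
  colnames(unmixing) <- channels

  structure(list(unmixing = unmixing, mixing = mixing,
                 sources = unmixing %*% X, channels = channels,
                 n_components = n_components, seed = seed),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model> ", x$n_components, " components from ",
      length(x$channels), " channels", sep = "")
  if (!is.null(x$suspects))
    cat("; suspects: ", paste(which(x$suspects), collapse = ","), sep = "")
  if (!is.null(x$removed))
    cat("; removed: ", paste(x$removed, collapse = ","), sep = "")
  cat("\n")
  invisible(x)
}

#' Extract one channel of an epoch set as a concatenated time series
#'
#' Uses the same trial-by-trial concatenation order as [fit_ica()], so
#' the result is time-aligned with the fitted component sources (e.g.
#' for passing epoched VEOG/HEOG to [score_components()]).
#'
#' @param epochs an `epoch_set`.
#' @param label channel label.
#' @return numeric vector of length trials x samples.
#' @export
concat_epoch_channel <- function(epochs, label) {
  i <- match(label, epochs$labels)
  if (is.na(i)) stop("unknown channel label: ", label)
  as.vector(t(epochs$data[, i, ]))
}

#' Detect blinks and build the blink topography
#'
#' Band-passes VEOG (1-15 Hz), marks threshold crossings at median +
#' `threshold_mads` * MAD with a refractory gap, then averages
#' blink-locked epochs (-100..300 ms) on all EEG channels and takes the
#' 50-250 ms window mean as the blink topography.
#'
#' @param recording a `continuous_recording` containing VEOG.
#' @param veog,eeg_channels channel labels.
#' @param band VEOG conditioning band (Hz).
#' @param threshold_mads threshold in MAD units above the median.
#' @param refractory_ms minimum gap between blink events.
#' @param min_peak_frac events below this fraction of the largest peak
#'   are discarded (suppresses filter-ringing side lobes).
#' @param epoch_win,topo_win blink epoch and topography windows (ms).
#' @return list of class `blink_detection`: `events` (sample indices),
#'   `times_ms`, `topography` (named vector over EEG channels, or NULL),
#'   `available` (FALSE when no blinks were found).
#' @export
detect_blinks <- function(recording, veog = "VEOG", eeg_channels = NULL,
                          band = c(1, 15), threshold_mads = 5,
                          refractory_ms = 300, min_peak_frac = 0.2,
                          epoch_win = c(-100, 300),
                          topo_win = c(50, 250)) {
  if (!veog %in% recording$labels) stop("VEOG channel not present")
  rate <- recording$sample_rate
  v <- recording$data[veog, ]
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  vf <- signal::filtfilt(bf, v)
  thr <- stats::median(vf) + threshold_mads * stats::mad(vf)
  above <- vf > thr
  if (!any(above)) {
    return(structure(list(events = integer(0), times_ms = numeric(0),
                          topography = NULL, available = FALSE),
                     class = "blink_detection"))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peaks <- integer(0)
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    peaks <- c(peaks, seg[which.max(vf[seg])])
  }
  # amplitude-ordered non-maximum suppression within the refractory gap,
  # then a relative floor: the zero-phase 1 Hz high-pass rings around a
  # large monophasic blink, and those ripples (a few % of the peak) must
  # not count as events
  refr <- refractory_ms / 1000 * rate
  keep <- logical(length(peaks))
  taken <- numeric(0)
  for (i in order(vf[peaks], decreasing = TRUE)) {
    if (!length(taken) || all(abs(peaks[i] - taken) >= refr)) {
      keep[i] <- TRUE
      taken <- c(taken, peaks[i])
    }
  }
  peaks <- sort(peaks[keep])
  peaks <- peaks[vf[peaks] >= min_peak_frac * max(vf[peaks])]

  if (is.null(eeg_channels)) {
    eeg_channels <- if (!is.null(recording$montage)) {
      ch <- recording$montage$channels
      intersect(ch$label[ch$type == "eeg"], recording$labels)
    } else setdiff(recording$labels, c("VEOG", "HEOG", "M1", "M2"))
  }
  o1 <- as.integer(round(epoch_win[1] / 1000 * rate))
  o2 <- as.integer(round(epoch_win[2] / 1000 * rate)) - 1L
  ok <- peaks + o1 >= 1 & peaks + o2 <= ncol(recording$data)
  topo <- NULL
  if (any(ok)) {
    eidx <- match(eeg_channels, recording$labels)
    acc <- matrix(0, length(eidx), o2 - o1 + 1)
    for (p in peaks[ok]) acc <- acc + recording$data[eidx, (p + o1):(p + o2)]
    acc <- acc / sum(ok)
    tms <- (o1:o2) / rate * 1000
    tsel <- tms >= topo_win[1] & tms <= topo_win[2]
    topo <- rowMeans(acc[, tsel, drop = FALSE])
    names(topo) <- eeg_channels
  }
  structure(list(events = peaks, times_ms = (peaks - 1) / rate * 1000,
                 topography = topo, available = TRUE),
            class = "blink_detection")
}

#' Score ICA components against ocular artifact signatures
#'
#' Computes three correlation sets per component -- temporal correlation
#' with VEOG, temporal correlation with HEOG (all signals band-passed
#' 1-20 Hz first), and spatial correlation of the mixing column with the
#' blink topography -- and z-scores each set across components
#' (subtracting the set mean, dividing by the set SD), so a score
#' indexes how unusual a component's correlation is relative to the
#' others. Components with any |z| > `z_threshold` are suspects; a
#' suspect is recommended for removal only if its raw |correlation| also
#' exceeds `min_abs_cor` (an automatic stand-in for visual
#' confirmation).
#'
#' @param ica a fitted `ica_model`.
#' @param veog,heog EOG signals time-aligned with the ICA sources.
#' @param blink_topography named vector from [detect_blinks()], or NULL
#'   to skip spatial scoring.
#' @param rate sample rate of the sources (Hz).
#' @param band correlation conditioning band (Hz).
#' @param z_threshold suspect threshold on |z| (default 2).
#' @param min_abs_cor removal gate on the raw |correlation|.
#' @return the `ica_model` with `scores` (data.frame: component,
#'   cor_veog, cor_heog, cor_blink, z_veog, z_heog, z_blink), `suspects`
#'   (logical), `removal_recommended` (integer ids).
#' @export
score_components <- function(ica, veog, heog, blink_topography = NULL,
                             rate, band = c(1, 20), z_threshold = 2,
                             min_abs_cor = 0.2) {
  stopifnot(inherits(ica, "ica_model"))
  if (is.null(veog) || is.null(heog)) stop("missing EOG channel data")
  stopifnot(length(veog) == ncol(ica$sources),
            length(heog) == ncol(ica$sources))
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  vf <- signal::filtfilt(bf, veog)
  hf <- signal::filtfilt(bf, heog)
  k <- ica$n_components
  cv <- ch <- cb <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    src <- signal::filtfilt(bf, ica$sources[i, ])
    cv[i] <- stats::cor(src, vf)
    ch[i] <- stats::cor(src, hf)
  }
  if (!is.null(blink_topography)) {
    bt <- blink_topography[ica$channels]
    if (anyNA(bt)) stop("blink topography missing channels of the ICA fit")
    for (i in seq_len(k)) cb[i] <- stats::cor(ica$mixing[, i], bt)
  }
  zscore <- function(r) {
    if (all(is.na(r))) return(r)
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-12) {
      warning("degenerate correlation set (zero spread); z set to 0")
      return(rep(0, length(r)))
    }
    (r - mean(r)) / s
  }
  zv <- zscore(cv); zh <- zscore(ch); zb <- zscore(cb)
  scores <- data.frame(component = seq_len(k), cor_veog = cv,
                       cor_heog = ch, cor_blink = cb,
                       z_veog = zv, z_heog = zh, z_blink = zb)
  zmat <- abs(cbind(zv, zh, zb))
  suspects <- apply(zmat, 1, function(r) any(r > z_threshold, na.rm = TRUE))
  suspects[is.na(suspects)] <- FALSE
  rawmax <- apply(abs(cbind(cv, ch, cb)), 1, max, na.rm = TRUE)
  ica$scores <- scores
  ica$suspects <- suspects
  ica$removal_recommended <- which(suspects & rawmax > min_abs_cor)
  ica
}

#' Detect bad channels by robust variance
#'
#' Each channel's scale is summarised by its (squared) MAD over the
#' epoched data -- robust to sparse large excursions such as blinks --
#' and channels whose log scale deviates from the median across channels
#' by more than `threshold` robust z units (MAD-scaled) are flagged;
#' channels in `force` are always included.
#'
#' @param epochs an `epoch_set` or channels x samples matrix.
#' @param threshold robust z threshold (default 4).
#' @param force channels to always flag (e.g. a persistently bad
#'   electrode).
#' @param channels restrict detection to these labels.
#' @return character vector of bad channel labels.
#' @export
detect_bad_channels <- function(epochs, threshold = 4,
                                force = character(0), channels = NULL) {
  if (inherits(epochs, "epoch_set")) {
    labs <- epochs$labels
    X <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = length(labs))
  } else {
    X <- as.matrix(epochs)
    labs <- rownames(X)
  }
  if (!is.null(channels)) {
    idx <- match(channels, labs)
    X <- X[idx, , drop = FALSE]
    labs <- channels
  }
  v <- log(apply(X, 1, stats::mad)^2 + 1e-20)
  z <- (v - stats::median(v)) / stats::mad(v)
  bad <- labs[z > threshold]
  union(bad, intersect(force, labs))
}

#' Build the cleaning montage (component removal + channel interpolation)
#'
#' The removal matrix projects the chosen components' spatial subspace
#' out of the channel data (I - A_rem W_rem, idempotent because the
#' unmixing-mixing product is the identity on the retained subspace).
#' The interpolation matrix replaces each bad channel by an
#' inverse-geodesic-distance weighted average of its 6 nearest good
#' channels (weights normalised to sum 1); good channels pass through
#' unchanged. The composed matrix (interpolation x removal) is applied
#' to the epoched data in a single step.
#'
#' @param ica a fitted (scored) `ica_model`.
#' @param removed_components integer component ids to remove; defaults to
#'   `ica$removal_recommended`. An empty set gives an identity removal.
#' @param montage a `montage` for channel geometry.
#' @param bad_channels labels to interpolate.
#' @param n_neighbors interpolation neighbourhood size.
#' @return object of class `cleaning_montage`: `removal`,
#'   `interpolation`, `composed` (channels x channels), `channels`,
#'   `bad_channels`, `provenance`.
#' @export
build_cleaning_montage <- function(ica, removed_components = NULL,
                                   montage = NULL,
                                   bad_channels = character(0),
                                   n_neighbors = 6) {
  stopifnot(inherits(ica, "ica_model"))
  if (is.null(removed_components))
    removed_components <- ica$removal_recommended
  removed_components <- as.integer(removed_components)
  if (length(removed_components) &&
      (min(removed_components) < 1 ||
       max(removed_components) > ica$n_components))
    stop("removed components outside the fitted set")
  if (!is.null(ica$suspects) && length(removed_components) &&
      !all(removed_components %in% which(ica$suspects)))
    message("operator override: removing component(s) ",
            paste(setdiff(removed_components, which(ica$suspects)),
                  collapse = ", "), " not in the suspect set")
  chs <- ica$channels
  n <- length(chs)
  bad_channels <- intersect(bad_channels, chs)
  if (length(bad_channels) == n) stop("all channels are bad")

  removal <- diag(n)
  if (length(removed_components)) {
    A <- ica$mixing[, removed_components, drop = FALSE]
    W <- ica$unmixing[removed_components, , drop = FALSE]
    removal <- diag(n) - A %*% W
  }

  interp <- diag(n)
  if (length(bad_channels)) {
    if (is.null(montage)) stop("montage required to interpolate channels")
    d <- channel_distances(montage)
    good <- setdiff(chs, bad_channels)
    for (bc in bad_channels) {
      i <- match(bc, chs)
      dd <- d[bc, good]
      nb <- names(sort(dd))[seq_len(min(n_neighbors, length(good)))]
      w <- 1 / d[bc, nb]
      w <- w / sum(w)
      interp[i, ] <- 0
      interp[i, match(nb, chs)] <- w
    }
  }
  dimnames(removal) <- dimnames(interp) <- list(chs, chs)
  structure(list(removal = removal, interpolation = interp,
                 composed = interp %*% removal, channels = chs,
                 bad_channels = bad_channels,
                 provenance = list(removed_components = removed_components,
                                   n_bad = length(bad_channels))),
            class = "cleaning_montage")
}

#' @export
print.cleaning_montage <- function(x, ...) {
  cat("<cleaning_montage> ", length(x$provenance$removed_components),
      " component(s) removed; ", length(x$bad_channels),
      " channel(s) interpolated\n", sep = "")
  invisible(x)
}

#' Apply a cleaning montage to epoched data
#'
#' Multiplies each epoch by the composed cleaning matrix on the channels
#' covered by the montage; other channels (EOG, mastoids) pass through.
#'
#' @param epochs an `epoch_set`.
#' @param cleaning a `cleaning_montage`.
#' @return the cleaned `epoch_set`.
#' @export
apply_cleaning <- function(epochs, cleaning) {
  idx <- match(cleaning$channels, epochs$labels)
  if (anyNA(idx)) stop("cleaning montage channels missing from epochs")
  M <- cleaning$composed
  for (i in seq_len(dim(epochs$data)[1]))
    epochs$data[i, idx, ] <- M %*% epochs$data[i, idx, ]
  attr(epochs, "cleaning") <- cleaning$provenance
  epochs
}
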