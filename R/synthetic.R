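# Synthetic cohort and EEG generator with known ground truth: two groups
# of adolescents, behavioral scores, capacity-limited n-back observers,
# and continuous recordings containing a parietal P300 with configurable
# group/load effects plus ocular artifacts and bad channels.

#' Default cohort and ERP effect configuration
#'
#' Group means and SDs for the behavioral scores, working-memory
#' capacity parameters for the staircase observers, and the ground-truth
#' P300 structure: 1-back vs 2-back target amplitude at the parietal
#' maximum (window means of 14.0 vs 11.5 uV over 300-700 ms) and an
#' earlier P300 in the clinical group (about 20 ms at 1-back, 55 ms at
#' 2-back). `group_scale` scales every group difference (0 gives two
#' exchangeable groups for null calibration).
#'
#' @param group_scale multiplier on all group differences.
#' @param amp_load_effect_uV 1-back minus 2-back target amplitude.
#' @param lat_group_shift_2back_ms,lat_group_shift_1back_ms latency
#'   reduction in the clinical (nf1) group per load level.
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(group_scale = 1, amp_load_effect_uV = 2.5,
                           lat_group_shift_2back_ms = 55,
                           lat_group_shift_1back_ms = 20) {
  # per-score group means (clinical, control) and SDs
  scores <- data.frame(
    score = c("conners_inattention", "conners_hyperactivity",
              "vineland_abc", "digit_span_fwd", "digit_span_bwd",
              "teach_sky_search", "teach_score", "teach_creature",
              "teach_sky_dt"),
    mean_nf1 = c(73.63, 69.88, 83.06, 6.75, 5.88, 10.50, 9.13, 8.62, 7.88),
    sd_nf1   = c(12.92, 18.53, 16.58, 3.02, 1.31, 3.14, 3.81, 3.28, 1.63),
    mean_control = c(48.81, 49.31, 103.56, 10.56, 9.00, 10.81, 11.44,
                     11.31, 8.19),
    sd_control   = c(8.16, 8.90, 15.35, 2.33, 2.31, 2.04, 2.31, 2.98, 1.94),
    stringsAsFactors = FALSE
  )
  if (group_scale != 1) {
    mid <- (scores$mean_nf1 + scores$mean_control) / 2
    scores$mean_nf1 <- mid + (scores$mean_nf1 - mid) * group_scale
    scores$mean_control <- mid + (scores$mean_control - mid) * group_scale
  }
  structure(list(
    scores = scores,
    capacity = list(mean_control = 3.1, mean_nf1 = 3.1 - 0.9 * group_scale,
                    sd = 0.6, age_slope = 0.15),
    corsi = list(mean_control = 5.5, mean_nf1 = 5.5 - 0.7 * group_scale,
                 sd = 0.9, age_slope = 0.12),
    erp = list(
      amp_1back_uV = 14.0,
      amp_2back_uV = 14.0 - amp_load_effect_uV,
      amp_subject_sd_uV = 2.5,
      amp_cond_sd_uV = 1.0,
      amp_group_diff_uV = 0 * group_scale,
      lat_1back_control_ms = 510,
      lat_2back_control_ms = 532,
      lat_group_shift_1back_ms = lat_group_shift_1back_ms * group_scale,
      lat_group_shift_2back_ms = lat_group_shift_2back_ms * group_scale,
      lat_subject_sd_ms = 25,
      lat_cond_sd_ms = 10,
      nontarget_scale = 0.35,
      p300_sigma_ms = 70,
      center = "Pz"),
    group_scale = group_scale
  ), class = "cohort_effects")
}

#' Simulate a two-group cohort with ERP ground truth
#'
#' Draws an age- and sex-matched cohort (ages 11-17), behavioral scores
#' from the configured group Gaussians, runs the adaptive n-back
#' staircase with capacity-limited observers for the visual and auditory
#' modalities, scores a simulated Corsi session, and lays down the
#' per-subject, per-load ground-truth P300 amplitude and latency that
#' the recording simulator injects.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effects a [cohort_effects()] configuration.
#' @param seed integer master seed; all draws derive from it.
#' @return list of class `cohort`: `subjects` (one row per subject:
#'   group, age, sex, scores, mean n-back, Corsi span), `truth` (one row
#'   per subject x load level: target amplitude uV, latency ms), and
#'   `artifacts` (per-subject blink rate and bad channels).
#' @export
simulate_cohort <- function(n_per_group = 16, effects = cohort_effects(),
                            seed = 1L) {
  stopifnot(n_per_group >= 2)
  if (!inherits(effects, "cohort_effects"))
    stop("malformed effect_config: use cohort_effects()")
  local_seed(seed, "cohort")
  n <- 2L * n_per_group
  group <- rep(c("nf1", "control"), each = n_per_group)

  # matched pairs: same base age, same sex pattern in both groups
  base_age <- stats::runif(n_per_group, 11, 17)
  age <- round(c(base_age + stats::runif(n_per_group, -0.25, 0.25),
                 base_age + stats::runif(n_per_group, -0.25, 0.25)), 2)
  age <- pmin(17, pmax(11, age))
  n_male <- round(9 / 16 * n_per_group)
  sex_pat <- sample(rep(c("M", "F"), c(n_male, n_per_group - n_male)))
  sex <- c(sex_pat, sex_pat)

  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n)), group = group,
    age = age, sex = sex, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(effects$scores))) {
    sc <- effects$scores[i, ]
    mu <- ifelse(group == "nf1", sc$mean_nf1, sc$mean_control)
    sdv <- ifelse(group == "nf1", sc$sd_nf1, sc$sd_control)
    subjects[[sc$score]] <- round(stats::rnorm(n, mu, sdv), 2)
  }

  # behavioral adaptive n-back via capacity-limited observers
  cap_cfg <- effects$capacity
  for (modality in c("visual", "auditory")) {
    vals <- numeric(n)
    for (i in seq_len(n)) {
      cap_mu <- if (group[i] == "nf1") cap_cfg$mean_nf1 else cap_cfg$mean_control
      s_i <- derive_seed(seed, paste0("capacity/", modality, "/", i))
      set.seed(s_i)
      cap <- stats::rnorm(1, cap_mu + cap_cfg$age_slope * (age[i] - 14),
                          cap_cfg$sd)
      obs <- make_capacity_observer(cap, seed = s_i)
      sess <- run_staircase(obs, staircase_rules(),
                            seed = derive_seed(seed, paste0("stair/", modality, "/", i)))
      vals[i] <- sess$mean_nback
    }
    subjects[[paste0("mean_nback_", modality)]] <- vals
  }

  # Corsi block-tapping session driven by a span ability
  corsi_cfg <- effects$corsi
  corsi <- numeric(n)
  for (i in seq_len(n)) {
    mu <- if (group[i] == "nf1") corsi_cfg$mean_nf1 else corsi_cfg$mean_control
    local_seed(seed, paste0("corsi/", i))
    ability <- stats::rnorm(1, mu + corsi_cfg$age_slope * (age[i] - 14),
                            corsi_cfg$sd)
    lens <- rep(2:9, each = 2)
    outc <- data.frame(length = lens,
                       correct = stats::runif(length(lens)) <
                         stats::plogis(1.6 * (ability - lens)))
    corsi[i] <- corsi_score(outc)$span
  }
  subjects$corsi_span <- corsi

  # ERP ground truth per subject x load
  e <- effects$erp
  truth <- list()
  local_seed(seed, "truth")
  for (i in seq_len(n)) {
    amp_re <- stats::rnorm(1, 0, e$amp_subject_sd_uV)
    lat_re <- stats::rnorm(1, 0, e$lat_subject_sd_ms)
    is_nf1 <- group[i] == "nf1"
    for (load in 1:2) {
      amp <- (if (load == 1) e$amp_1back_uV else e$amp_2back_uV) +
        amp_re + (if (is_nf1) e$amp_group_diff_uV else 0) +
        stats::rnorm(1, 0, e$amp_cond_sd_uV)
      lat <- (if (load == 1) e$lat_1back_control_ms else e$lat_2back_control_ms) -
        (if (is_nf1) {
          if (load == 1) e$lat_group_shift_1back_ms else e$lat_group_shift_2back_ms
        } else 0) + lat_re + stats::rnorm(1, 0, e$lat_cond_sd_ms)
      truth[[length(truth) + 1]] <- data.frame(
        subject = subjects$subject[i], group = group[i], load = load,
        amp_uV = amp, lat_ms = lat)
    }
  }
  truth <- do.call(rbind, truth)

  local_seed(seed, "artifacts")
  artifacts <- data.frame(
    subject = subjects$subject,
    blink_rate_per_min = pmax(4, stats::rnorm(n, 12, 3)),
    stringsAsFactors = FALSE)
  extra_bad <- sample(c("F6", "C5", "PO8", "FT7"), n, replace = TRUE)
  artifacts$bad_channels <- ifelse(stats::runif(n) < 0.5,
                                   paste("TP7", extra_bad, sep = ";"), "TP7")

  structure(list(subjects = subjects, truth = truth,
                 artifacts = artifacts, effects = effects, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects (",
      paste(names(table(x$subjects$group)), table(x$subjects$group),
            sep = "=", collapse = ", "), "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Noise and artifact configuration for the recording simulator
#'
#' @param background_rms_uV RMS of the 1/f background per channel.
#' @param shared_noise_frac fraction of background variance carried by
#'   spatially smooth shared components (volume conduction); the rest is
#'   independent sensor noise.
#' @param alpha_uV amplitude of the 10 Hz posterior alpha component.
#' @param blink_amp_uV blink amplitude at VEOG.
#' @param blink_frontal_uV blink field amplitude at the frontal pole.
#' @param saccade_rate_per_min,saccade_amp_uV HEOG saccade steps.
#' @param bad_channel_factor noise multiplier on bad channels.
#' @param include_artifacts master switch for blinks/saccades/bad
#'   channels.
#' @param p300_fwhm_rad spatial width of the P300 field (geodesic FWHM).
#' @export
noise_config <- function(background_rms_uV = 12, alpha_uV = 4,
                         blink_amp_uV = 200, blink_frontal_uV = 80,
                         saccade_rate_per_min = 6, saccade_amp_uV = 40,
                         bad_channel_factor = 10, include_artifacts = TRUE,
                         p300_fwhm_rad = 0.9, shared_noise_frac = 0.7) {
  structure(list(background_rms_uV = background_rms_uV,
                 alpha_uV = alpha_uV, blink_amp_uV = blink_amp_uV,
                 blink_frontal_uV = blink_frontal_uV,
                 saccade_rate_per_min = saccade_rate_per_min,
                 saccade_amp_uV = saccade_amp_uV,
                 bad_channel_factor = bad_channel_factor,
                 include_artifacts = isTRUE(include_artifacts),
                 p300_fwhm_rad = p300_fwhm_rad,
                 shared_noise_frac = shared_noise_frac),
            class = "noise_config")
}

# 1/f-spectrum noise via spectral shaping of white noise
#' @keywords internal
.pink_noise <- function(n, rate, rms) {
  if (rms <= 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))  # composite length keeps the FFT fast
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(1e-3, seq_len(m - 1)) * rate / m
  f <- pmin(f, rate - f)            # mirror for the upper half
  shape <- 1 / sqrt(pmax(f, 0.5))   # flat below 0.5 Hz
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / m
  x * rms / stats::sd(x)
}

#' @keywords internal
.gauss_pulse <- function(t_ms, center_ms, sigma_ms) {
  exp(-(t_ms - center_ms)^2 / (2 * sigma_ms^2))
}

#' Pulse peak equivalent of a window-mean amplitude
#'
#' Ground-truth P300 amplitudes are expressed as window-mean amplitude
#' over the canonical analysis window (the quantity the measurement
#' layer reports); the simulators convert them to the peak of the
#' Gaussian pulse whose mean over the window equals that value.
#'
#' @param amp_window_uV window-mean amplitude in microvolts.
#' @param lat_ms pulse centre latency.
#' @param sigma_ms pulse width.
#' @param window analysis window in ms.
#' @return pulse peak amplitude in microvolts.
#' @export
p300_peak_amplitude <- function(amp_window_uV, lat_ms, sigma_ms = 70,
                                window = c(300, 700)) {
  coverage <- stats::pnorm((window[2] - lat_ms) / sigma_ms) -
    stats::pnorm((window[1] - lat_ms) / sigma_ms)
  amp_window_uV * diff(window) /
    (sigma_ms * sqrt(2 * pi) * pmax(coverage, 1e-6))
}

#' Simulate a continuous EEG recording for one subject
#'
#' Builds a 512 Hz (configurable) multichannel recording: 1/f plus
#' posterior-alpha background, a parietal-maximal P300 pulse at each
#' stimulus onset (Gaussian in time, Gaussian in geodesic distance over
#' the scalp, larger for targets and for lower load, latency per the
#' cohort ground truth), Poisson blinks with a frontal field mirrored in
#' VEOG, saccade steps in HEOG, and high-variance noise on the
#' configured bad channels. Simulated responses from a capacity-limited
#' observer give per-trial correctness. Events are embedded at stimulus
#' onsets.
#'
#' @param cohort a `cohort`.
#' @param subject subject id from the cohort.
#' @param sequences list of `trial_sequence` (eeg mode); default: the
#'   fixed 1-back, 2-back, 2-back, 1-back session. NULL simulates a
#'   task-free recording of `duration_s` seconds.
#' @param montage a `montage`.
#' @param noise a [noise_config()].
#' @param rate sample rate in Hz.
#' @param duration_s recording length when `sequences` is NULL.
#' @param seed integer seed (defaults to the cohort seed).
#' @return a `continuous_recording` with a `ground_truth` attribute.
#' @export
simulate_recording <- function(cohort, subject, sequences = NULL,
                               montage = make_montage(),
                               noise = noise_config(), rate = 512,
                               duration_s = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!subject %in% cohort$subjects$subject) stop("unknown subject id")
  if (is.null(seed)) seed <- cohort$seed
  sub_i <- match(subject, cohort$subjects$subject)
  e <- cohort$effects$erp

  task_free <- is.null(sequences) && !is.null(duration_s)
  if (is.null(sequences) && !task_free) {
    sequences <- lapply(seq_along(c(1, 2, 2, 1)), function(b)
      generate_sequence(c(1, 2, 2, 1)[b], "eeg",
                        seed = derive_seed(seed, paste0(subject, "/seq", b))))
  }

  gap_s <- 4
  if (task_free) {
    n_samp <- as.integer(round(duration_s * rate))
    events <- data.frame(sample = integer(0))
  } else {
    # lay blocks end to end with a gap
    block_offsets_ms <- numeric(length(sequences))
    cursor <- gap_s * 1000
    ev_list <- list()
    for (b in seq_along(sequences)) {
      sq <- sequences[[b]]
      block_offsets_ms[b] <- cursor
      lvl <- attr(sq, "level")
      # observer responses -> correctness per trial
      local_seed(seed, paste0(subject, "/resp", b))
      p_hit <- if (lvl == 1) 0.90 else 0.78
      pressed <- ifelse(sq$is_target, stats::runif(nrow(sq)) < p_hit,
                        stats::runif(nrow(sq)) < 0.03)
      correct <- ifelse(sq$is_target, pressed, !pressed)
      ev_list[[b]] <- data.frame(
        sample = as.integer(round((cursor + sq$onset_ms) / 1000 * rate)) + 1L,
        block = b, level = lvl, position = sq$position,
        is_target = sq$is_target, correct = correct)
      cursor <- cursor + max(sq$onset_ms) + 2500 + gap_s * 1000
    }
    events <- do.call(rbind, ev_list)
    n_samp <- as.integer(round(cursor / 1000 * rate))
  }

  labels <- montage$channels$label
  n_ch <- length(labels)
  eeg_idx <- which(montage$channels$type == "eeg")
  x <- matrix(0, n_ch, n_samp)
  t_ms <- (seq_len(n_samp) - 1) / rate * 1000

  # background: spatially smooth shared 1/f components (volume-conducted
  # activity is correlated across the scalp) plus independent per-channel
  # sensor noise, and a shared posterior alpha rhythm
  local_seed(seed, paste0(subject, "/background"))
  if (noise$background_rms_uV > 0) {
    eegl <- labels[eeg_idx]
    k_bg <- 12L
    shared_rms <- noise$background_rms_uV * sqrt(noise$shared_noise_frac)
    indep_rms <- noise$background_rms_uV * sqrt(1 - noise$shared_noise_frac)
    centers <- sample(eegl, k_bg, replace = TRUE)
    P <- vapply(centers, function(cc)
      spatial_weights(montage, cc, fwhm_rad = 1.4)[eegl],
      numeric(length(eegl)))
    P <- sweep(P, 2, sqrt(colMeans(P^2)), "/")
    TS <- t(vapply(seq_len(k_bg), function(kk)
      .pink_noise(n_samp, rate, shared_rms / sqrt(k_bg)), numeric(n_samp)))
    x[eeg_idx, ] <- x[eeg_idx, ] + P %*% TS
    for (c_i in eeg_idx)
      x[c_i, ] <- x[c_i, ] + .pink_noise(n_samp, rate, indep_rms)
    for (c_i in setdiff(seq_len(n_ch), eeg_idx))
      x[c_i, ] <- .pink_noise(n_samp, rate, noise$background_rms_uV)
  }
  if (noise$alpha_uV > 0) {
    alpha_w <- spatial_weights(montage, "Oz", fwhm_rad = 1.0)
    ph <- stats::runif(1, 0, 2 * pi)
    am <- 1 + 0.3 * sin(2 * pi * 0.1 * t_ms / 1000)  # slow waxing/waning
    alpha <- noise$alpha_uV * am * sin(2 * pi * 10 * t_ms / 1000 + ph)
    x[eeg_idx, ] <- x[eeg_idx, ] + outer(alpha_w[labels[eeg_idx]], alpha)
  }

  # stimulus-locked P300 pulses: the spatial pattern is fixed, so
  # accumulate one scalar time series and add it as a single rank-1 term
  if (!task_free) {
    w <- spatial_weights(montage, e$center, fwhm_rad = noise$p300_fwhm_rad)
    tr <- cohort$truth
    p300_ts <- numeric(n_samp)
    for (b in seq_along(sequences)) {
      lvl <- attr(sequences[[b]], "level")
      row <- tr[tr$subject == subject & tr$load == lvl, ]
      ev_b <- events[events$block == b, ]
      peak <- p300_peak_amplitude(row$amp_uV, row$lat_ms, e$p300_sigma_ms)
      for (k in seq_len(nrow(ev_b))) {
        amp <- peak * if (ev_b$is_target[k]) 1 else e$nontarget_scale
        onset_ms <- (ev_b$sample[k] - 1) / rate * 1000
        lo <- max(1L, as.integer(round((onset_ms + row$lat_ms -
                                          8 * e$p300_sigma_ms) / 1000 * rate)))
        hi <- min(n_samp, as.integer(round((onset_ms + row$lat_ms +
                                              8 * e$p300_sigma_ms) / 1000 * rate)))
        if (hi <= lo) next
        p300_ts[lo:hi] <- p300_ts[lo:hi] +
          amp * .gauss_pulse(t_ms[lo:hi], onset_ms + row$lat_ms,
                             e$p300_sigma_ms)
      }
    }
    x[eeg_idx, ] <- x[eeg_idx, ] + outer(w[labels[eeg_idx]], p300_ts)
  }

  blink_times_ms <- numeric(0)
  if (noise$include_artifacts) {
    art <- cohort$artifacts[sub_i, ]
    # blinks: Poisson count, uniform times, 500 ms refractory
    local_seed(seed, paste0(subject, "/blinks"))
    dur_min <- n_samp / rate / 60
    n_blink <- stats::rpois(1, art$blink_rate_per_min * dur_min)
    if (n_blink > 0) {
      tt <- sort(stats::runif(n_blink, 500, n_samp / rate * 1000 - 500))
      keep <- c(TRUE, diff(tt) > 500)
      blink_times_ms <- tt[keep]
      bw <- spatial_weights(montage, "Fpz", fwhm_rad = 0.8)
      veog_i <- match("VEOG", labels)
      blink_ts <- numeric(n_samp)
      for (bt in blink_times_ms) {
        lo <- max(1L, as.integer(round((bt - 250) / 1000 * rate)))
        hi <- min(n_samp, as.integer(round((bt + 250) / 1000 * rate)))
        blink_ts[lo:hi] <- blink_ts[lo:hi] + .gauss_pulse(t_ms[lo:hi], bt, 55)
      }
      x[eeg_idx, ] <- x[eeg_idx, ] +
        outer(noise$blink_frontal_uV * bw[labels[eeg_idx]], blink_ts)
      x[veog_i, ] <- x[veog_i, ] + noise$blink_amp_uV * blink_ts
    }
    # saccade steps in HEOG
    local_seed(seed, paste0(subject, "/saccades"))
    n_sac <- stats::rpois(1, noise$saccade_rate_per_min * dur_min)
    heog_i <- match("HEOG", labels)
    if (n_sac > 0) {
      st <- sort(stats::runif(n_sac, 0, n_samp / rate * 1000 - 400))
      for (s_t in st) {
        lo <- as.integer(round(s_t / 1000 * rate)) + 1L
        hi <- min(n_samp, lo + as.integer(round(stats::runif(1, 0.15, 0.4) * rate)))
        x[heog_i, lo:hi] <- x[heog_i, lo:hi] +
          sample(c(-1, 1), 1) * noise$saccade_amp_uV
      }
    }
    # bad channels: high-variance noise replaces the signal
    bad <- strsplit(art$bad_channels, ";")[[1]]
    local_seed(seed, paste0(subject, "/badchan"))
    for (bc in intersect(bad, labels)) {
      i <- match(bc, labels)
      x[i, ] <- stats::rnorm(n_samp, 0,
                             max(1, noise$background_rms_uV) *
                               noise$bad_channel_factor)
    }
  }

  rec <- continuous_recording(x, rate, labels, events, montage)
  attr(rec, "ground_truth") <- list(
    subject = subject,
    truth = cohort$truth[cohort$truth$subject == subject, ],
    blink_times_ms = blink_times_ms,
    bad_channels = if (noise$include_artifacts)
      strsplit(cohort$artifacts$bad_channels[sub_i], ";")[[1]]
    else character(0),
    seed = seed)
  rec
}

#' Simulate single-channel P300 epochs at the measurement site
#'
#' Fast path for parameter-recovery studies: draws `n_trials`
#' single-trial epochs at the P300 maximum (Pz) as ground-truth pulse
#' plus 1/f noise, already on the epoch time axis, skipping the
#' continuous-recording and cleaning stages that the full pipeline
#' tests separately.
#'
#' @param amp_uV window-mean (300-700 ms) ground-truth amplitude; the
#'   pulse peak is derived via [p300_peak_amplitude()].
#' @param lat_ms,sigma_ms pulse centre and width.
#' @param n_trials number of single trials.
#' @param noise_rms_uV single-trial background RMS.
#' @param rate sample rate (Hz).
#' @param window epoch window in ms.
#' @param seed integer seed.
#' @return an `epoch_set` with one channel "Pz".
#' @export
simulate_erp_epochs <- function(amp_uV, lat_ms, sigma_ms = 70,
                                n_trials = 40, noise_rms_uV = 12,
                                rate = 200, window = c(-100, 900),
                                seed = 1L) {
  local_seed(seed, "erp_epochs")
  times <- seq(window[1], window[2] - 1000 / rate, by = 1000 / rate)
  n_s <- length(times)
  sig <- p300_peak_amplitude(amp_uV, lat_ms, sigma_ms) *
    .gauss_pulse(times, lat_ms, sigma_ms)
  dat <- array(0, dim = c(n_trials, 1, n_s))
  for (i in seq_len(n_trials))
    dat[i, 1, ] <- sig + .pink_noise(n_s, rate, noise_rms_uV)
  bl <- times < 0
  for (i in seq_len(n_trials))
    dat[i, 1, ] <- dat[i, 1, ] - mean(dat[i, 1, bl])
  new_epoch_set(dat, times, rate, "Pz",
                data.frame(trial = seq_len(n_trials),
                           is_target = TRUE, correct = TRUE))
}
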