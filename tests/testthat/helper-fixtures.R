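# Shared fixtures, built in code at test time.

fixture_montage <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_montage()
    m
  }
})

# a tiny deterministic recording: flat channels with a known pulse
toy_recording <- function(n_ch = 4, n_samp = 1000, rate = 200,
                          labels = paste0("ch", seq_len(n_ch)),
                          events = data.frame(sample = c(300, 600))) {
  continuous_recording(matrix(0, n_ch, n_samp), rate, labels, events)
}

# deterministic observer with a fixed accuracy profile by level
profile_observer <- function(acc_by_level) {
  function(level, sequence) {
    acc <- if (level <= length(acc_by_level)) acc_by_level[level]
           else acc_by_level[length(acc_by_level)]
    tg <- which(sequence$is_target)
    r <- rep(FALSE, nrow(sequence))
    if (length(tg)) r[tg[seq_len(round(acc * length(tg)))]] <- TRUE
    r
  }
}

# mean |blink-locked average| over given channel rows: average the
# event-locked segments first so background noise cancels, then take
# the mean absolute amplitude in a +/-100 ms window
blink_locked_amp <- function(dat, events, rows, win = -20:20) {
  acc <- 0
  n_used <- 0
  for (b in events) {
    s <- b + win
    if (min(s) < 1 || max(s) > ncol(dat)) next
    acc <- acc + dat[rows, s, drop = FALSE]
    n_used <- n_used + 1
  }
  mean(abs(acc / n_used))
}

# epoch set built directly from an array, for measurement-layer tests
toy_epochs <- function(data, rate = 200, t0_frac = 0.1,
                       labels = NULL, meta = NULL) {
  d <- dim(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(d[2]))
  n_pre <- round(d[3] * t0_frac)
  times <- (seq_len(d[3]) - n_pre - 1) / rate * 1000
  if (is.null(meta)) meta <- data.frame(trial = seq_len(d[1]))
  nbackerp:::new_epoch_set(data, times, rate, labels, meta)
}
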