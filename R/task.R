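# Behavioral adaptive n-back staircase, EEG-task sequence generation with
# placement constraints, block scoring, and Corsi span scoring.

#' Staircase rules for the adaptive n-back task
#'
#' Block accuracy at or above `up_threshold` raises the next block's load
#' level by one; at or below `down_threshold` lowers it by one; otherwise
#' the level is unchanged. The session ends after two consecutive blocks
#' played at an unchanged level, or at `max_blocks`.
#'
#' @param up_threshold proportion correct at/above which the level increases.
#' @param down_threshold proportion at/below which the level decreases.
#' @param start_level,min_level,max_level level bounds (max_level is a
#'   safety cap on top of the adaptive rule).
#' @param max_blocks safety cap on administered blocks.
#' @param targets_per_block targets among the critical screens.
#' @param critical_screens scored screens per block (lead-in screens are
#'   added on top, one per load level).
#' @return list of class `staircase_rules`.
#' @export
staircase_rules <- function(up_threshold = 0.90, down_threshold = 0.70,
                            start_level = 1L, min_level = 1L,
                            max_level = 9L, max_blocks = 20L,
                            targets_per_block = 6L, critical_screens = 20L) {
  stopifnot(down_threshold > 0, down_threshold < up_threshold,
            up_threshold <= 1, min_level <= start_level,
            start_level <= max_level, max_blocks >= 1,
            targets_per_block < critical_screens)
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 start_level = as.integer(start_level),
                 min_level = as.integer(min_level),
                 max_level = as.integer(max_level),
                 max_blocks = as.integer(max_blocks),
                 targets_per_block = as.integer(targets_per_block),
                 critical_screens = as.integer(critical_screens)),
            class = "staircase_rules")
}

# default alphabets: the eight consonants of the auditory task; the
# 4-locus visuospatial variant is represented abstractly as 4 symbols
.default_alphabet <- c("c", "g", "h", "k", "p", "q", "t", "w")

#' EEG n-back sequence configuration
#'
#' @param n_trials trials per block.
#' @param n_targets targets per block.
#' @param max_consecutive_targets cap on the number of adjacent
#'   target-target pairs in a block.
#' @param alphabet stimulus symbols.
#' @param soa_ms stimulus onset asynchrony before jitter.
#' @param jitter_step_ms,jitter_max_ms onset jitter grid: multiples of
#'   `jitter_step_ms` not exceeding `jitter_max_ms` in magnitude.
#' @param cross_level forbid stimuli that would be targets at the other
#'   load level (1-back repeats in 2-back blocks and vice versa).
#' @export
eeg_sequence_config <- function(n_trials = 100L, n_targets = 25L,
                                max_consecutive_targets = 6L,
                                alphabet = .default_alphabet,
                                soa_ms = 2500, jitter_step_ms = 17,
                                jitter_max_ms = 100, cross_level = TRUE) {
  stopifnot(n_targets < n_trials, length(alphabet) >= 3)
  structure(list(n_trials = as.integer(n_trials),
                 n_targets = as.integer(n_targets),
                 max_consecutive_targets = as.integer(max_consecutive_targets),
                 alphabet = alphabet, soa_ms = soa_ms,
                 jitter_step_ms = jitter_step_ms,
                 jitter_max_ms = jitter_max_ms,
                 cross_level = isTRUE(cross_level)),
            class = "eeg_sequence_config")
}

#' Generate an n-back trial sequence
#'
#' Behavioral mode emits `level` lead-in screens plus the critical
#' screens, with exactly `targets_per_block` targets among the critical
#' screens. EEG mode emits a fixed-length block (default 100 trials, 25
#' targets) with the cross-level placement constraint: in a 1-back block
#' no stimulus repeats the one two back, and in a 2-back block no
#' stimulus repeats the immediately preceding one, so a trial is a target
#' at exactly its own load level. Adjacent target pairs are capped. Onset
#' jitter is drawn from the `k * 17 ms` grid within +/-100 ms.
#'
#' @param level n-back load level (>= 1).
#' @param mode `"behavioral"` or `"eeg"`.
#' @param config a `staircase_rules` (behavioral) or
#'   `eeg_sequence_config` (eeg).
#' @param seed integer seed; sequences are reproducible.
#' @return data.frame of class `trial_sequence` with columns `position`,
#'   `symbol`, `is_target`, `onset_ms`; attributes `level`, `mode`,
#'   `n_leadin`, `alphabet`.
#' @export
generate_sequence <- function(level, mode = c("behavioral", "eeg"),
                              config = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(level >= 1)
  level <- as.integer(level)
  if (mode == "behavioral") {
    if (is.null(config)) config <- staircase_rules()
    n_crit <- config$critical_screens
    n_targ <- config$targets_per_block
    n_total <- level + n_crit
    alphabet <- .default_alphabet[1:4]
    cross <- FALSE
    max_consec <- n_targ
    soa <- 3500; jstep <- 0; jmax <- 0
  } else {
    if (is.null(config)) config <- eeg_sequence_config()
    if (!inherits(config, "eeg_sequence_config"))
      stop("eeg mode requires an eeg_sequence_config")
    n_total <- config$n_trials
    n_targ <- config$n_targets
    alphabet <- config$alphabet
    cross <- config$cross_level
    max_consec <- config$max_consecutive_targets
    soa <- config$soa_ms
    jstep <- config$jitter_step_ms; jmax <- config$jitter_max_ms
  }

  local_seed(seed, "sequence")
  other <- if (level == 1L) 2L else if (level == 2L) 1L else NA_integer_

  # in a 1-back block the cross-level rule forbids consecutive targets
  # outright (two adjacent 1-back targets give three equal symbols in a
  # row, i.e. a 2-back match), so placement there must be non-adjacent
  no_adjacent <- cross && level == 1L
  for (attempt in 1:200) {
    # choose target positions among eligible trials (position > level),
    # respecting the adjacency cap; behavioral targets fall in the
    # critical screens only (which positions > level guarantees)
    eligible <- (level + 1L):n_total
    if (no_adjacent) {
      # bijection between k non-adjacent picks from m slots and k
      # unrestricted picks from m - k + 1
      m <- length(eligible)
      base <- sort(sample(m - n_targ + 1L, n_targ))
      targ_pos <- eligible[base + seq_len(n_targ) - 1L]
    } else {
      repeat {
        targ_pos <- sort(sample(eligible, n_targ))
        if (sum(diff(targ_pos) == 1L) <= max_consec) break
      }
    }
    is_target <- rep(FALSE, n_total)
    is_target[targ_pos] <- TRUE

    sym <- character(n_total)
    ok <- TRUE
    for (i in seq_len(n_total)) {
      if (is_target[i]) {
        s <- sym[i - level]
        # a forced target must not collide with the cross-level constraint
        if (cross && !is.na(other) && i > other && s == sym[i - other]) {
          ok <- FALSE; break
        }
        sym[i] <- s
      } else {
        forbid <- character(0)
        if (i > level) forbid <- c(forbid, sym[i - level])
        if (cross && !is.na(other) && i > other)
          forbid <- c(forbid, sym[i - other])
        choices <- setdiff(alphabet, forbid)
        if (!length(choices)) { ok <- FALSE; break }
        sym[i] <- sample(choices, 1L)
      }
    }
    if (ok) break
    if (attempt == 200) stop("infeasible sequence constraint set: level ",
                             level, ", alphabet size ", length(alphabet))
  }

  jitter <- if (jstep > 0) {
    kmax <- floor(jmax / jstep)
    sample(seq(-kmax, kmax), n_total, replace = TRUE) * jstep
  } else rep(0, n_total)
  onset <- (seq_len(n_total) - 1L) * soa + jitter

  out <- data.frame(position = seq_len(n_total), symbol = sym,
                    is_target = is_target, onset_ms = onset,
                    stringsAsFactors = FALSE)
  attr(out, "level") <- level
  attr(out, "mode") <- mode
  attr(out, "n_leadin") <- if (mode == "behavioral") level else 0L
  attr(out, "alphabet") <- alphabet
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' Score a block of responses
#'
#' `responses` is a logical vector (pressed or not) aligned to trials, or
#' a data.frame with `pressed` and `rt_ms`. Accuracy for the staircase
#' rule is hits/targets (no responses are required for non-targets);
#' hits-minus-false-alarms is the EEG task's performance measure in
#' percentage points.
#'
#' @param sequence a `trial_sequence`.
#' @param responses logical vector or data.frame aligned to trials.
#' @return list: `hits`, `false_alarms`, `n_targets`, `n_nontargets`,
#'   `accuracy`, `hits_minus_fa_pct`, `mean_rt_ms` (NA if no correct
#'   target response).
#' @export
score_block <- function(sequence, responses) {
  if (is.data.frame(responses)) {
    pressed <- responses$pressed
    rt <- responses$rt_ms
  } else {
    pressed <- as.logical(responses)
    rt <- rep(NA_real_, length(pressed))
  }
  if (length(pressed) != nrow(sequence))
    stop("responses length (", length(pressed),
         ") does not match sequence length (", nrow(sequence), ")")
  tgt <- sequence$is_target
  hits <- sum(pressed & tgt)
  fa <- sum(pressed & !tgt)
  n_t <- sum(tgt); n_nt <- sum(!tgt)
  acc <- if (n_t > 0) hits / n_t else NA_real_
  hmf <- 100 * hits / n_t - 100 * fa / n_nt
  rts <- rt[pressed & tgt]
  rts <- rts[is.finite(rts)]
  list(hits = hits, false_alarms = fa, n_targets = n_t,
       n_nontargets = n_nt, accuracy = acc, hits_minus_fa_pct = hmf,
       mean_rt_ms = if (length(rts)) mean(rts) else NA_real_)
}

#' Run the adaptive n-back staircase
#'
#' The observer is a function `function(level, sequence)` returning a
#' response data.frame (`pressed`, `rt_ms`) or logical vector for the
#' block. Level transitions follow the up/down thresholds with floor and
#' cap; the session terminates once two consecutive level transitions
#' leave the level unchanged (i.e. after the third block at a stable
#' level), or at `max_blocks`.
#'
#' @param observer response-generating function.
#' @param rules a `staircase_rules`.
#' @param seed integer seed for sequence generation.
#' @return list of class `staircase_session`: `blocks` (data.frame with
#'   level, accuracy, hits, false_alarms, mean_rt_ms), `mean_nback`,
#'   `mean_rt_ms`, `termination` ("stable_level" or "max_blocks").
#' @export
run_staircase <- function(observer, rules = staircase_rules(), seed = 1L) {
  level <- rules$start_level
  prev_level <- NA_integer_
  unchanged <- 0L
  rec <- list()
  termination <- "max_blocks"
  for (b in seq_len(rules$max_blocks)) {
    seq_b <- generate_sequence(level, "behavioral", rules,
                               seed = derive_seed(seed, paste0("block", b)))
    resp <- observer(level, seq_b)
    sc <- score_block(seq_b, resp)
    rec[[b]] <- data.frame(block = b, level = level, accuracy = sc$accuracy,
                           hits = sc$hits, false_alarms = sc$false_alarms,
                           mean_rt_ms = sc$mean_rt_ms)
    # a block played at the level of the previous block is "unchanged";
    # the counter resets whenever the level moves
    if (!is.na(prev_level) && level == prev_level)
      unchanged <- unchanged + 1L
    else unchanged <- 0L
    prev_level <- level
    if (unchanged >= 2L) { termination <- "stable_level"; break }
    nxt <- level
    if (sc$accuracy >= rules$up_threshold) nxt <- level + 1L
    else if (sc$accuracy <= rules$down_threshold) nxt <- level - 1L
    level <- max(rules$min_level, min(rules$max_level, nxt))
  }
  blocks <- do.call(rbind, rec)
  structure(list(blocks = blocks,
                 mean_nback = mean(blocks$level),
                 mean_rt_ms = mean(blocks$mean_rt_ms, na.rm = TRUE),
                 termination = termination),
            class = "staircase_session")
}

#' @export
print.staircase_session <- function(x, ...) {
  cat("<staircase_session> ", nrow(x$blocks), " blocks, levels ",
      paste(x$blocks$level, collapse = ","), "; mean n-back ",
      round(x$mean_nback, 2), " (", x$termination, ")\n", sep = "")
  invisible(x)
}

#' Capacity-limited n-back observer
#'
#' Simulates a participant whose hit probability decays once the load
#' level exceeds their working-memory capacity; used to drive the
#' staircase in the cohort generator.
#'
#' @param capacity level at which performance starts to break down.
#' @param slope decay of hit probability per level above capacity.
#' @param fa_rate per-trial false-alarm probability on non-targets.
#' @param rt_mean_ms,rt_sd_ms response-time distribution for presses.
#' @param seed integer seed.
#' @return observer function for [run_staircase()].
#' @export
make_capacity_observer <- function(capacity, slope = 0.35, fa_rate = 0.02,
                                   rt_mean_ms = 600, rt_sd_ms = 120,
                                   seed = 1L) {
  counter <- 0L
  function(level, sequence) {
    counter <<- counter + 1L
    local_seed(seed, paste0("observer", counter))
    p_hit <- min(0.98, max(0.05, 0.98 - slope * max(0, level - capacity)))
    n <- nrow(sequence)
    press <- ifelse(sequence$is_target,
                    stats::runif(n) < p_hit,
                    stats::runif(n) < fa_rate)
    rt <- stats::rnorm(n, rt_mean_ms + 40 * (level - 1), rt_sd_ms)
    data.frame(pressed = press, rt_ms = pmax(150, rt))
  }
}

#' Score a Corsi block-tapping session
#'
#' Applies the two-failure termination rule to an ordered list of
#' outcomes and returns the mean of the two longest correctly repeated
#' sequence lengths.
#'
#' @param trial_outcomes data.frame with `length` and `correct`, in
#'   administration order.
#' @return list: `span` (mean of the two longest correct lengths; the
#'   single length if only one; 0 if none), `flag` ("ok", "single-span",
#'   "no-span"), `n_administered` after termination.
#' @export
corsi_score <- function(trial_outcomes) {
  stopifnot(all(c("length", "correct") %in% names(trial_outcomes)))
  fails <- cumsum(!trial_outcomes$correct)
  stop_at <- which(fails >= 2L)[1]
  if (!is.na(stop_at)) trial_outcomes <- trial_outcomes[seq_len(stop_at), ]
  correct_lens <- trial_outcomes$length[trial_outcomes$correct]
  if (length(correct_lens) == 0) {
    list(span = 0, flag = "no-span", n_administered = nrow(trial_outcomes))
  } else if (length(correct_lens) == 1) {
    list(span = correct_lens, flag = "single-span",
         n_administered = nrow(trial_outcomes))
  } else {
    two <- sort(correct_lens, decreasing = TRUE)[1:2]
    list(span = mean(two), flag = "ok",
         n_administered = nrow(trial_outcomes))
  }
}
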