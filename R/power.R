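# Parameter-recovery power studies: can the measurement + statistics
# layers detect the effects the generator injects at study scale?

#' Parameter-recovery power study
#'
#' For each replicate, simulates a cohort at study scale, draws
#' single-trial P300 epochs at the measurement channel for every
#' subject and load level from the cohort's ground truth, averages
#' them, measures window-mean amplitude and 50\% fractional-area
#' latency, and submits both to the 2 x 2 group x load mixed ANCOVA
#' with age as covariate. Reports per replicate the p-values for the
#' group effect on latency (injected group latency shift), the load
#' effect on amplitude (injected load amplitude effect), and the
#' group x load latency interaction together with its direction.
#'
#' @param n_reps number of replicates.
#' @param n_per_group subjects per group.
#' @param effects a [cohort_effects()] configuration.
#' @param n_trials single trials averaged per subject x condition.
#' @param noise_rms_uV single-trial background RMS at the channel.
#' @param alpha significance criterion.
#' @param seed integer master seed.
#' @return data.frame with one row per replicate: `p_group_latency`,
#'   `p_load_amplitude`, `p_interaction_latency`,
#'   `interaction_direction_ok`; attribute `power` holds the three
#'   rejection proportions.
#' @export
power_recovery <- function(n_reps = 50, n_per_group = 16,
                           effects = cohort_effects(), n_trials = 40,
                           noise_rms_uV = 12, alpha = 0.05, seed = 1L) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(n_per_group, effects,
                              seed = derive_seed(seed, paste0("rep", r)))
    tr <- cohort$truth
    meas <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      ep <- simulate_erp_epochs(
        tr$amp_uV[i], tr$lat_ms[i],
        sigma_ms = effects$erp$p300_sigma_ms, n_trials = n_trials,
        noise_rms_uV = noise_rms_uV,
        seed = derive_seed(seed, paste0("rep", r, "/", tr$subject[i],
                                        "/", tr$load[i])))
      ev <- average_evoked(ep, label = "target")
      meas[[i]] <- data.frame(
        subject = tr$subject[i], group = tr$group[i], load = tr$load[i],
        amplitude_uV = window_amplitude(ev, "Pz", c(300, 700)),
        latency_ms = fractional_area_latency(ev, window = c(300, 700)))
    }
    d <- do.call(rbind, meas)
    d <- merge(d, cohort$subjects[, c("subject", "age")], by = "subject")
    d$nback <- factor(paste0(d$load, "back"))

    fit_lat <- mixed_ancova(d, "latency_ms", "group", "nback",
                            covariate = "age", alpha = alpha)
    fit_amp <- mixed_ancova(d, "amplitude_uV", "group", "nback",
                            covariate = "age", alpha = alpha)
    tl <- fit_lat$table
    ta <- fit_amp$table
    # injected direction: the load latency difference (1-back minus
    # 2-back) is more positive in the clinical group than in controls
    ld <- stats::aggregate(latency_ms ~ group + nback, d, mean)
    diff_by_group <- vapply(c("control", "nf1"), function(g)
      ld$latency_ms[ld$group == g & ld$nback == "1back"] -
        ld$latency_ms[ld$group == g & ld$nback == "2back"], numeric(1))
    rows[[r]] <- data.frame(
      rep = r,
      p_group_latency = tl$p[tl$effect == "group"],
      p_load_amplitude = ta$p[ta$effect == "nback"],
      p_interaction_latency = tl$p[tl$effect == "group:nback"],
      interaction_direction_ok =
        diff_by_group["control"] < diff_by_group["nf1"])
  }
  out <- do.call(rbind, rows)
  attr(out, "power") <- c(
    group_latency = mean(out$p_group_latency < alpha),
    load_amplitude = mean(out$p_load_amplitude < alpha),
    interaction_latency = mean(out$p_interaction_latency < alpha &
                                 out$interaction_direction_ok))
  out
}
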