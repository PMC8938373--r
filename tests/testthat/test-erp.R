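test_that("amplitude/correctness rejection flags exactly the violating epochs", {
  set.seed(5)
  d <- array(rnorm(10 * 2 * 50, sd = 10), dim = c(10, 2, 50))
  d[2, 1, 10] <- 121           # amplitude violation
  d[5, 2, 3] <- -150           # amplitude violation
  meta <- data.frame(trial = 1:10, correct = rep(TRUE, 10))
  meta$correct[7] <- FALSE     # incorrect trial
  ep <- toy_epochs(d, meta = meta)
  out <- select_valid_trials(ep, 120)
  expect_equal(which(!out$valid), c(2, 5, 7))
  expect_equal(sum(out$valid), 7)

  # boundary: values within the threshold are retained
  d2 <- array(119, dim = c(1, 2, 50))
  ep2 <- toy_epochs(d2, meta = data.frame(trial = 1, correct = TRUE))
  expect_true(all(select_valid_trials(ep2, 120)$valid))

  # rejection is monotone in the threshold
  n_low <- sum(select_valid_trials(ep, 50)$valid)
  n_high <- sum(select_valid_trials(ep, 200)$valid)
  expect_lte(n_low, sum(out$valid))
  expect_lte(sum(out$valid), n_high)
})

test_that("non-target balancing picks temporally proximal trials with earlier-tie rule", {
  # targets at positions 10 and 50; non-targets at 8, 12, 49
  pos <- c(10, 50, 8, 12, 49)
  is_t <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- array(0, dim = c(5, 1, 10))
  ep <- toy_epochs(d, meta = data.frame(position = pos, is_target = is_t,
                                        block = 1))
  out <- balance_nontargets(ep)
  expect_true(all(out$valid[1:2]))
  # tie at distance 2 for target 10 (8 vs 12): earlier wins; 49 pairs 50
  expect_equal(out$valid[3:5], c(TRUE, FALSE, TRUE))

  # selected count never exceeds target count and matches a brute-force
  # greedy re-implementation
  set.seed(11)
  n <- 95
  is_t2 <- rep(FALSE, n); is_t2[sample(n, 25)] <- TRUE
  ep2 <- toy_epochs(array(0, dim = c(n, 1, 4)),
                    meta = data.frame(position = 1:n, is_target = is_t2,
                                      block = 1))
  out2 <- balance_nontargets(ep2)
  expect_equal(sum(out2$valid & !is_t2), 25)
  # oracle: independent greedy pass
  sel <- logical(n); avail <- which(!is_t2)
  for (t_i in which(is_t2)) {
    k <- avail[order(abs(avail - t_i), avail)][1]
    sel[k] <- TRUE; avail <- setdiff(avail, k)
  }
  expect_equal(which(out2$valid & !is_t2), which(sel))

  ep3 <- toy_epochs(array(0, dim = c(3, 1, 4)),
                    meta = data.frame(position = 1:3,
                                      is_target = rep(FALSE, 3), block = 1))
  expect_warning(balance_nontargets(ep3), "no valid target")
})

test_that("averaging, grand averages and difference waves are arithmetic means", {
  d <- array(0, dim = c(2, 1, 20))
  d[1, 1, ] <- 2; d[2, 1, ] <- 2
  ep <- toy_epochs(d)
  av <- average_evoked(ep, label = "x")
  expect_equal(unname(av$data[1, ]), rep(2, 20))
  expect_equal(av$n_trials, 2)

  a <- av; b <- av; b$data[] <- 4; b$condition <- "y"
  g <- grand_average(list(a, b))
  expect_equal(unname(g$data[1, ]), rep(3, 20))

  dw <- difference_wave(av, av)
  expect_true(all(dw$data == 0))

  ep$valid <- c(FALSE, FALSE)
  expect_error(average_evoked(ep), "no valid trials")
})

test_that("window amplitude equals the brute-force sample mean, incl. ROIs", {
  set.seed(9)
  m <- fixture_montage()
  labs <- c("Pz", m$roi_map[["left parietal"]])
  d <- array(rnorm(1 * 8 * 200), dim = c(1, 8, 200))
  ep <- toy_epochs(d, labels = labs)
  ev <- average_evoked(ep, label = "t")
  w <- c(300, 700)
  tidx <- ev$times >= w[1] & ev$times <= w[2]
  expect_equal(window_amplitude(ev, "Pz", w), mean(ev$data["Pz", tidx]))
  expect_equal(window_amplitude(ev, "left parietal", w, m$roi_map),
               mean(ev$data[m$roi_map[["left parietal"]], tidx]))
  # constant and ramp identities
  ev2 <- ev; ev2$data[] <- 5
  expect_equal(window_amplitude(ev2, "Pz", w), 5)
  ev3 <- ev
  ev3$data["Pz", ] <- seq(0, 10, length.out = 200)
  tsel <- which(tidx)
  expect_equal(window_amplitude(ev3, "Pz", w),
               mean(ev3$data["Pz", tsel]))
  expect_error(window_amplitude(ev, "Qz", w), "unknown site")
})

test_that("fractional area latency: symmetry, uniform pulse, numeric oracle", {
  times <- seq(0, 1000, by = 5)
  gauss <- exp(-(times - 500)^2 / (2 * 60^2))
  expect_equal(fractional_area_latency(gauss, times, c(300, 700)), 500,
               tolerance = 2.5)
  rect <- as.numeric(times >= 300 & times <= 500)
  expect_equal(fractional_area_latency(rect, times, c(300, 700)), 400,
               tolerance = 2.5)
  # arbitrary positive waveform vs dense-grid cumulative oracle
  set.seed(4)
  w <- abs(stats::filter(rnorm(201), rep(1 / 10, 10), circular = TRUE))
  w <- as.numeric(w)
  fal <- fractional_area_latency(w, times, c(300, 700))
  dense_t <- seq(300, 700, by = 0.01)
  dense_w <- approx(times, w, dense_t)$y
  cum <- cumsum((dense_w[-1] + dense_w[-length(dense_w)]) / 2 * 0.01)
  oracle <- dense_t[which(cum >= 0.5 * cum[length(cum)])[1]]
  expect_equal(fal, oracle, tolerance = 0.5)
})

test_that("fractional area latency is shift-equivariant and scale-invariant", {
  times <- seq(0, 1000, by = 5)
  base <- exp(-(times - 450)^2 / (2 * 50^2))
  f0 <- fractional_area_latency(base, times, c(300, 700))
  for (shift in c(-50, 25, 80)) {
    shifted <- exp(-(times - 450 - shift)^2 / (2 * 50^2))
    expect_equal(fractional_area_latency(shifted, times, c(300, 700)),
                 f0 + shift, tolerance = 1.0)
  }
  for (scale in c(0.2, 3, 40)) {
    expect_equal(fractional_area_latency(scale * base, times, c(300, 700)),
                 f0, tolerance = 1e-9)
  }
  # all-negative waveform has zero rectified area
  expect_warning(
    fal <- fractional_area_latency(-base - 1, times, c(300, 700)),
    "zero rectified area")
  expect_true(is.na(fal))
})

test_that("p300_measures reports amplitude at all sites and latency at Pz", {
  m <- fixture_montage()
  labs <- c("Pz", unlist(m$roi_map, use.names = FALSE))
  set.seed(2)
  d <- array(rnorm(2 * length(labs) * 220, sd = 1), dim = c(2, length(labs), 220))
  ep <- toy_epochs(d, labels = labs)
  ev <- average_evoked(ep, label = "target")
  res <- p300_measures(ev, roi_map = m$roi_map)
  expect_equal(nrow(res), 15)  # 5 sites x 3 windows
  expect_setequal(unique(res$window), c("full", "early", "late"))
  expect_equal(sum(!is.na(res$latency_ms)), 1)
  lat_row <- res[!is.na(res$latency_ms), ]
  expect_equal(lat_row$site, "Pz")
  expect_true(lat_row$latency_ms >= 300 && lat_row$latency_ms <= 700)
})
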