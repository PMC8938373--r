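test_that("ICA recovers known independent sources up to sign and permutation", {
  set.seed(1)
  n <- 6000
  s1 <- sign(sin(2 * pi * seq_len(n) / 400))         # square wave
  s2 <- ((seq_len(n) %% 213) / 213 - 0.5) * 2        # sawtooth
  s3 <- stats::runif(n, -1, 1)                       # uniform noise
  S <- rbind(s1, s2, s3)
  A <- matrix(c(1, 0.5, 0.2, -0.3, 1, 0.4, 0.2, -0.6, 1,
                0.7, 0.1, -0.2, 0.3, 0.8, 0.1, -0.1, 0.2, 0.9), 6, 3,
              byrow = TRUE)
  X <- A %*% S
  rownames(X) <- paste0("ch", 1:6)
  ica <- fit_ica(X, n_components = 3, seed = 2)
  cmat <- abs(stats::cor(t(ica$sources), t(S)))
  # every true source is matched by some component with |r| > 0.99
  expect_true(all(apply(cmat, 2, max) > 0.99))
})

test_that("ICA is deterministic, validates sizes, and inverts on the retained subspace", {
  set.seed(3)
  X <- matrix(rnorm(8 * 4000), 8)
  rownames(X) <- paste0("ch", 1:8)
  i1 <- fit_ica(X, 4, seed = 7)
  i2 <- fit_ica(X, 4, seed = 7)
  expect_identical(i1$unmixing, i2$unmixing)
  expect_equal(i1$unmixing %*% i1$mixing, diag(4), tolerance = 1e-6)
  expect_error(fit_ica(X, 70), "70 components from 8 channels")
  # rank deficiency reduces with a warning
  Xr <- rbind(X[1:3, ], X[1, ] + X[2, ])
  rownames(Xr) <- paste0("c", 1:4)
  expect_warning(ir <- fit_ica(Xr, 4, seed = 1), "rank")
  expect_lt(ir$n_components, 4)
})

test_that("blink detector recovers injected blinks and their frontal topography", {
  m <- fixture_montage()
  rate <- 200
  n <- rate * 120
  labs <- m$channels$label
  x <- matrix(stats::rnorm(length(labs) * n, sd = 2), length(labs), n)
  rownames(x) <- labs
  set.seed(6)
  truth_ms <- sort(stats::runif(10, 2000, n / rate * 1000 - 2000))
  truth_ms <- truth_ms[c(TRUE, diff(truth_ms) > 1000)]
  t_ms <- (seq_len(n) - 1) / rate * 1000
  bw <- spatial_weights(m, "Fpz", fwhm_rad = 0.8)
  eeg_i <- which(m$channels$type == "eeg")
  for (bt in truth_ms) {
    pulse <- 100 * exp(-(t_ms - bt)^2 / (2 * 55^2))
    keep <- pulse > 0.01
    x[eeg_i, keep] <- x[eeg_i, keep] + outer(bw[labs[eeg_i]], pulse[keep])
    x[match("VEOG", labs), keep] <- x[match("VEOG", labs), keep] +
      250 * pulse[keep] / 100
  }
  rec <- continuous_recording(x, rate, labs, montage = m)
  det <- detect_blinks(rec)
  expect_true(det$available)
  expect_equal(length(det$events), length(truth_ms))
  expect_true(all(abs(det$times_ms - truth_ms) <= 20))
  # topography maximal frontally
  expect_equal(names(which.max(det$topography)), "Fpz")
  expect_gt(mean(det$topography[c("Fp1", "Fp2", "AF7", "AF8")]),
            mean(det$topography[c("Pz", "POz", "Oz", "CPz")]))

  flat <- continuous_recording(matrix(0, 2, 1000), rate, c("Pz", "VEOG"))
  det0 <- detect_blinks(flat)
  expect_false(det0$available)
  expect_equal(length(det0$events), 0)
  expect_null(det0$topography)
})

test_that("component scoring z-scores each correlation set and flags the EOG copy", {
  set.seed(4)
  n <- 6000
  k <- 32
  veog <- as.numeric(stats::filter(rnorm(n), rep(1 / 15, 15),
                                   circular = TRUE))
  S <- rbind(veog, matrix(rnorm((k - 1) * n), k - 1))
  A <- diag(k) + matrix(runif(k * k, -0.1, 0.1), k)
  X <- A %*% S
  rownames(X) <- paste0("ch", 1:k)
  ica <- fit_ica(X, k, seed = 5)
  heog <- rnorm(n)
  scored <- score_components(ica, veog, heog, NULL, rate = 200)
  sc <- scored$scores
  # z-scores of each set have mean 0, sd 1
  expect_equal(mean(sc$z_veog), 0, tolerance = 1e-9)
  expect_equal(stats::sd(sc$z_veog), 1, tolerance = 1e-9)
  expect_equal(sum(sc$z_veog), 0, tolerance = 1e-9)
  # the component matching VEOG is a suspect with |z| > 2
  best <- which.max(abs(sc$cor_veog))
  expect_gt(abs(sc$z_veog[best]), 2)
  expect_true(scored$suspects[best])
  expect_true(best %in% scored$removal_recommended)
})

test_that("degenerate (equal) correlation sets give z = 0 and no suspects", {
  ica <- structure(list(
    sources = rbind(rep(c(1, -1), 50), rep(c(1, -1), 50)),
    mixing = matrix(1, 2, 2), unmixing = matrix(1, 2, 2),
    channels = c("a", "b"), n_components = 2L, seed = 1L),
    class = "ica_model")
  veog <- rep(c(1, -1), 50)
  w <- capture_warnings(out <- score_components(ica, veog, veog, NULL,
                                                rate = 100))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(out$scores$z_veog == 0))
  expect_false(any(out$suspects))
})

test_that("bad channel detection: injection recovery, false positives, force list", {
  set.seed(10)
  X <- matrix(rnorm(32 * 3000), 32)
  rownames(X) <- paste0("ch", 1:32)
  X[17, ] <- rnorm(3000, sd = 10)
  expect_equal(detect_bad_channels(X), "ch17")
  # homogeneous noise: low false-positive rate
  fp <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    H <- matrix(rnorm(32 * 1500), 32)
    rownames(H) <- paste0("ch", 1:32)
    fp <- fp + (length(detect_bad_channels(H)) > 0)
  }
  expect_lt(fp / 60, 0.05)
  expect_true("TP7" %in% detect_bad_channels(X, force = "TP7",
                                             channels = rownames(X)) |
                !"TP7" %in% rownames(X))
  Y <- X; rownames(Y)[1] <- "TP7"
  expect_true("TP7" %in% detect_bad_channels(Y, force = "TP7"))
})

test_that("cleaning montage: identity case, idempotent projector, interpolation", {
  set.seed(12)
  X <- matrix(rnorm(8 * 5000), 8)
  rownames(X) <- paste0("ch", 1:8)
  ica <- fit_ica(X, 8, seed = 1)
  cm0 <- build_cleaning_montage(ica, removed_components = integer(0))
  expect_equal(cm0$composed, diag(8), ignore_attr = TRUE)

  cm1 <- build_cleaning_montage(ica, removed_components = c(1, 3))
  P <- cm1$removal
  expect_lt(max(abs(P %*% P - P)), 1e-9)
  expect_error(build_cleaning_montage(ica, removed_components = 9),
               "outside the fitted set")

  # interpolation reconstructs a smooth spatial field within 10%
  m <- fixture_montage()
  eeg <- m$channels[m$channels$type == "eeg", ]
  field <- 10 * exp(-((eeg$x - 0.2)^2 + (eeg$y + 0.5)^2 + (eeg$z - 0.8)^2))
  names(field) <- eeg$label
  ica64 <- structure(list(mixing = matrix(0, 64, 1),
                          unmixing = matrix(0, 1, 64),
                          channels = eeg$label, n_components = 1L),
                     class = "ica_model")
  cmi <- build_cleaning_montage(ica64, removed_components = integer(0),
                                montage = m, bad_channels = "CP1")
  # rows of the interpolation matrix sum to 1
  expect_equal(unname(rowSums(cmi$interpolation)), rep(1, 64))
  recon <- (cmi$composed %*% field)["CP1", ]
  expect_lt(abs(recon - field["CP1"]) / abs(field["CP1"]), 0.10)
})

test_that("removing the blink component suppresses frontal blink activity, spares Pz P300", {
  m <- fixture_montage()
  co <- simulate_cohort(2, seed = 5)
  seqs <- list(generate_sequence(1, "eeg",
                                 eeg_sequence_config(n_trials = 40,
                                                     n_targets = 10),
                                 seed = 1))
  rec <- simulate_recording(co, "S01", seqs, m, noise_config(), rate = 512)
  rec <- filter_resample(rereference(rec))
  ep <- epoch_baseline(rec, c(-600, 1400), c(-100, 0))
  eeg <- m$channels$label[m$channels$type == "eeg"]
  ica <- fit_ica(rec$data[eeg, ], 32, seed = 3)
  bl <- detect_blinks(rec)
  ica <- score_components(ica, rec$data["VEOG", ], rec$data["HEOG", ],
                          bl$topography, rate = rec$sample_rate)
  expect_gt(length(ica$removal_recommended), 0)
  cm <- build_cleaning_montage(ica, montage = m)
  clean <- apply_cleaning(ep, cm)

  # Pz P300 window amplitude changes < 5 %
  evb <- average_evoked(ep, ep$meta$is_target, "t")
  eva <- average_evoked(clean, clean$meta$is_target, "t")
  ab <- window_amplitude(evb, "Pz", c(300, 700))
  aa <- window_amplitude(eva, "Pz", c(300, 700))
  expect_lt(abs(aa - ab) / abs(ab), 0.05)

  # blink-locked frontal average (noise cancels across events) drops > 90 %
  idx <- match(ica$channels, rec$labels)
  cleaned <- cm$composed %*% rec$data[idx, ]
  front <- match(c("Fpz", "Fp1", "Fp2"), ica$channels)
  before <- blink_locked_amp(rec$data[idx, ], bl$events, front)
  after <- blink_locked_amp(cleaned, bl$events, front)
  expect_lt(after / before, 0.10)

  # cleaning with empty removal and no bad channels leaves data unchanged
  cm0 <- build_cleaning_montage(ica, removed_components = integer(0),
                                montage = m)
  same <- apply_cleaning(ep, cm0)
  expect_equal(same$data, ep$data, tolerance = 1e-12)
})
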