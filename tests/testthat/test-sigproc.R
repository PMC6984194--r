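# Filtering, epoching, artifact rejection, CSP, log-variance features.

make_recording <- function(x, fs = 500) {
  eeg_recording(matrix(x, ncol = 1), fs = fs, channels = "C3")
}

test_that("band-pass attenuates stop band and preserves pass band", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  amp_after <- function(f_hz, mode) {
    rec <- bandpass(make_recording(sin(2 * pi * f_hz * t), fs), mode = mode)
    x <- rec$data[1000:4000, 1]          # skip transients
    sqrt(2 * mean(x^2))
  }
  for (mode in c("zero_phase", "causal")) {
    expect_lt(amp_after(4, mode), 0.1)           # >= 90% reduction
    expect_equal(amp_after(15, mode), 1, tolerance = 0.05)
  }
  expect_validation_error(bandpass(make_recording(t, fs), low = 8, high = 300))
})

test_that("filtered white noise concentrates its power inside the band", {
  set.seed(1)
  fs <- 500
  rec <- bandpass(make_recording(rnorm(20 * fs), fs))
  x <- rec$data[(2 * fs):(18 * fs), 1]
  expect_gt(band_power(x, fs, 8, 28) / band_power(x, fs, 0, 250), 0.9)
})

test_that("epoching yields one MI epoch per onset and two rest epochs per run", {
  sim <- generate_training_recording(sim_config(n_runs = 6, seed = 2))
  ep <- epoch_training(sim$recording, sim$events)
  expect_s3_class(ep, "epoch_set")
  expect_equal(sum(ep$labels == "flexion"), 6)
  expect_equal(sum(ep$labels == "extension"), 6)
  expect_equal(sum(ep$labels == "rest_open"), 6)
  expect_equal(sum(ep$labels == "rest_closed"), 6)
  expect_equal(dim(ep$data)[1], 750)      # 1.5 s at 500 Hz

  # empty event list -> empty epoch set
  empty <- epoch_training(sim$recording, event_table())
  expect_equal(smrbci:::n_trials(empty), 0)

  # run truncated mid-extension: the out-of-bounds epoch is dropped
  short <- eeg_recording(sim$recording$data[1:(12.5 * 500), , drop = FALSE],
                         fs = 500, channels = sim$recording$channels)
  expect_warning(ep2 <- epoch_training(short, sim$events), "dropped")
  expect_equal(sum(ep2$labels == "extension"), 0)
  expect_equal(sum(ep2$labels == "flexion"), 1)
})

test_that("artifact rejection removes exactly the contaminated epoch", {
  set.seed(3)
  ep <- noise_epochs(n_trials = 20)
  clean <- reject_artifacts(ep)
  expect_equal(smrbci:::n_trials(clean), 20)

  spiked <- ep
  spiked$data[, , 7] <- spiked$data[, , 7] * 10
  out <- reject_artifacts(spiked)
  expect_equal(attr(out, "rejection")$trial, 7)
  expect_equal(smrbci:::n_trials(out), 19)

  # infinite threshold is the identity
  same <- reject_artifacts(spiked, z_thresh = Inf)
  expect_equal(smrbci:::n_trials(same), 20)
})

test_that("CSP on identical class covariances gives eigenvalues of one half", {
  set.seed(4)
  ep <- noise_epochs(n_trials = 20)
  a <- smrbci:::subset_epochs(ep, 1:20)
  csp <- fit_csp(a, a)
  expect_equal(csp$eigenvalues, rep(0.5, 4), tolerance = 1e-10)
})

test_that("two-channel toy CSP recovers the high-variance channel", {
  set.seed(5)
  n <- 50; len <- 200
  mk <- function(sd1) {
    data <- array(0, dim = c(len, 2, n))
    data[, 1, ] <- rnorm(len * n, sd = sd1)
    data[, 2, ] <- rnorm(len * n)
    epoch_set(data, rep("a", n), fs = 100, channels = c("ch1", "ch2"))
  }
  csp <- fit_csp(mk(sqrt(10)), mk(1))
  top <- csp$filters[, 1] / sqrt(sum(csp$filters[, 1]^2))
  expect_gte(abs(top[1]), 0.99)
  # closed form on trace-normalized covariances: (10/11) / (10/11 + 1/2)
  expect_equal(csp$eigenvalues[1], (10 / 11) / (10 / 11 + 1 / 2),
               tolerance = 0.05)
})

test_that("CSP simultaneously diagonalizes both class covariances", {
  set.seed(6)
  ep <- noise_epochs(n_trials = 40, ch = 6)
  a <- smrbci:::subset_epochs(ep, 1:20)
  b <- smrbci:::subset_epochs(ep, 21:40)
  csp <- fit_csp(a, b)
  off_diag_norm <- function(epochs) {
    s <- smrbci:::class_covariance(epochs)
    m <- t(csp$filters) %*% s %*% csp$filters
    sqrt(sum((m - diag(diag(m)))^2))
  }
  expect_lt(off_diag_norm(a), 1e-8)
  expect_lt(off_diag_norm(b), 1e-8)
})

test_that("swapping the class order mirrors the eigenvalue spectrum", {
  set.seed(7)
  ep <- noise_epochs(n_trials = 40, ch = 5)
  ep$data[, 2, 1:20] <- ep$data[, 2, 1:20] * 2
  a <- smrbci:::subset_epochs(ep, 1:20)
  b <- smrbci:::subset_epochs(ep, 21:40)
  ab <- fit_csp(a, b)
  ba <- fit_csp(b, a)
  expect_equal(ab$eigenvalues, rev(1 - ba$eigenvalues), tolerance = 1e-8)
  # same component set, reversed order (compare up to sign)
  align <- abs(colSums(ab$filters * ba$filters[, rev(seq_len(5))]))
  expect_equal(align, rep(1, 5), tolerance = 1e-6)
})

test_that("feature pipeline is invariant to channel permutation", {
  set.seed(8)
  ep <- noise_epochs(n_trials = 40, ch = 5)
  ep$data[, 3, 1:20] <- ep$data[, 3, 1:20] * 3
  a_idx <- 1:20; b_idx <- 21:40
  feats <- function(e) {
    csp <- fit_csp(smrbci:::subset_epochs(e, a_idx),
                   smrbci:::subset_epochs(e, b_idx))
    logvar_features(e, csp, components = seq_len(5))
  }
  perm <- c(4, 2, 5, 1, 3)
  ep_p <- ep
  ep_p$data <- ep$data[, perm, ]
  ep_p$channels <- ep$channels[perm]
  expect_equal(unname(feats(ep)), unname(feats(ep_p)), tolerance = 1e-6)
})

test_that("planted topography is recovered by the ERD-contrast pattern", {
  sim <- strong_training_sim(seed = 9)
  ep <- epoch_training(bandpass(sim$recording), sim$events)
  csp <- fit_csp(smrbci:::subset_epochs(ep, which(ep$labels == "flexion")),
                 smrbci:::subset_epochs(ep, which(ep$labels == "rest_open")))
  topo <- rep(0, 24)
  names(topo) <- montage_24()
  topo[names(sim$truth$topographies$flexion)] <- sim$truth$topographies$flexion
  # ERD suppresses flexion-class variance: the planted source sits at the
  # variance-minimizing end of the spectrum
  pat <- csp$patterns[, 24]
  expect_gte(abs(cor(pat, topo)), 0.9)
})

test_that("log-variance features behave like log of projected variance", {
  set.seed(10)
  ep <- noise_epochs(n_trials = 10, ch = 3, len = 5000)
  csp <- fit_csp(smrbci:::subset_epochs(ep, 1:5),
                 smrbci:::subset_epochs(ep, 6:10))
  f <- logvar_features(ep, csp, components = 1:3)
  expect_true(all(is.finite(f)))
  expect_equal(mean(f), 0, tolerance = 0.1)   # unit-variance projections

  doubled <- ep
  doubled$data[, , 1] <- doubled$data[, , 1] * 2
  f2 <- logvar_features(doubled, csp, components = 1:3)
  expect_equal(unname(f2[1, ] - f[1, ]), rep(log(4), 3), tolerance = 1e-10)
})

test_that("plausibility selection keeps sensorimotor patterns", {
  sim <- strong_training_sim(seed = 11)
  ep <- epoch_training(bandpass(sim$recording), sim$events)
  csp <- fit_csp(smrbci:::subset_epochs(ep, which(ep$labels == "flexion")),
                 smrbci:::subset_epochs(ep, which(ep$labels == "rest_open")))
  sel <- select_plausible_components(csp)
  expect_true(24 %in% sel$selected)     # the planted ERD component survives
  expect_true(length(sel$selected) >= 1)

  # hand-built patterns: all mass on C3 kept, all mass on O1 dropped
  toy <- csp
  toy$patterns[] <- 0
  toy$patterns[match("C3", toy$channels), toy$selected] <- 1
  toy$patterns[, 24] <- 0
  toy$patterns[match("O1", toy$channels), 24] <- 1
  out <- select_plausible_components(toy)
  expect_false(24 %in% out$selected)
})

test_that("top log-variance feature separates MI from rest with high AUC", {
  cfg <- sim_config(n_runs = 20, erd_depth = 0.3, seed = 12)
  sim <- generate_training_recording(cfg)
  ep <- epoch_training(bandpass(sim$recording), sim$events)
  idx <- which(ep$labels %in% c("flexion", "rest_open"))
  sub <- smrbci:::subset_epochs(ep, idx)
  csp <- fit_csp(smrbci:::subset_epochs(sub, which(sub$labels == "flexion")),
                 smrbci:::subset_epochs(sub, which(sub$labels == "rest_open")))
  f <- logvar_features(sub, csp, components = 24)
  auc <- smrbci:::auc_stat(f[sub$labels == "rest_open", 1],
                           f[sub$labels == "flexion", 1])
  expect_gte(auc, 0.85)
})
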