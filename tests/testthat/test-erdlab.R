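# Morlet time-frequency analysis, percent power change, ERD latency,
# CSP quality rubric.

# analytic segments object: one or more rows of a deterministic signal
analytic_segments <- function(signals, fs = 500, tmin = -2, tmax = 3,
                              labels = NULL) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  structure(list(data = signals,
                 labels = labels %||% rep("flexion", nrow(signals)),
                 fs = fs,
                 times = seq(tmin, tmax, by = 1 / fs)[seq_len(ncol(signals))]),
            class = "component_segments")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the Morlet transform is frequency selective", {
  fs <- 500
  t <- seq(-2, 3, by = 1 / fs)
  tf <- morlet_tf(analytic_segments(sin(2 * pi * 20 * t), fs))
  ridge <- mean(tf$power[tf$freqs == 20, , 1])
  off <- mean(tf$power[tf$freqs == 35, , 1])
  expect_gt(ridge, 10 * off)

  zero <- morlet_tf(analytic_segments(rep(0, length(t)), fs))
  expect_true(all(zero$power == 0))

  expect_validation_error(
    morlet_tf(analytic_segments(matrix(rnorm(100), 1), fs = 500,
                                tmin = 0, tmax = 0.2)))
})

test_that("Morlet power tracks the squared envelope of an AM tone", {
  fs <- 500
  t <- seq(-2, 3, by = 1 / fs)
  env <- 1 + 0.5 * sin(2 * pi * 0.7 * t)
  tf <- morlet_tf(analytic_segments(env * sin(2 * pi * 15 * t), fs))
  inner <- tf$times > -0.5 & tf$times < 2
  got <- tf$power[tf$freqs == 15, inner, 1]
  want <- (1 + 0.5 * sin(2 * pi * 0.7 * tf$times[inner]))^2
  expect_gt(cor(got, want), 0.95)
})

test_that("percent power change has an exactly zero-mean baseline", {
  fs <- 500
  t <- seq(-2, 3, by = 1 / fs)
  set.seed(50)
  sig <- rbind(rnorm(length(t)) * sin(2 * pi * 12 * t),
               rnorm(length(t)) + sin(2 * pi * 18 * t))
  tf <- percent_power_change(morlet_tf(analytic_segments(sig, fs)))
  base <- tf$times >= -0.5 & tf$times <= 0
  for (tr in 1:2) {
    bm <- rowMeans(tf$per_trial[, base, tr])
    expect_lt(max(abs(bm)), 1e-9)
  }
})

test_that("halving the amplitude reads as a 75% power drop", {
  fs <- 500
  t <- seq(-2, 3, by = 1 / fs)
  amp <- ifelse(t < 0, 1, 0.5)
  tf <- percent_power_change(morlet_tf(analytic_segments(
    amp * sin(2 * pi * 15 * t), fs)))
  plateau <- tf$times > 0.8 & tf$times < 1.8
  got <- mean(tf$per_trial[tf$freqs == 15, plateau, 1])
  expect_lt(abs(got - (-75)), 2)
  # constant signal: no change anywhere
  flat <- percent_power_change(morlet_tf(analytic_segments(
    sin(2 * pi * 15 * t), fs)))
  expect_lt(max(abs(flat$per_trial[tf$freqs == 15, , 1])), 1)
})

test_that("the band statistic recovers injected depth and is monotone", {
  seeds <- 1:3
  vals <- sapply(seeds, function(s) {
    sapply(c(0.2, 0.3, 0.5), function(d) {
      cfg <- sim_config(n_runs = 20, erd_depth = d, erd_latency = 0.3,
                        seed = 60 + s)
      sim <- generate_training_recording(cfg)
      topo <- rep(0, 24)
      names(topo) <- montage_24()
      topo[names(sim$truth$topographies$flexion)] <-
        sim$truth$topographies$flexion
      tf <- suppressWarnings(percent_power_change(morlet_tf(
        csp_component_segments(sim$recording, sim$events, topo))))
      mean_smr_change(tf, trials = tf$labels == "flexion")
    })
  })
  mid <- rowMeans(vals)
  expect_lt(abs(mid[2] - (-30)), 5)          # d = 0.3 reads near -30%
  expect_true(all(diff(mid) < 0))            # deeper ERD, more negative
})

test_that("ERD latency follows the threshold / percentile definition", {
  times <- seq(-0.5, 2, by = 0.01)
  step_trace <- function(depth, onset) {
    ifelse(times >= onset, depth, 0)
  }
  traces <- do.call(rbind, replicate(10, step_trace(-50, 0.6),
                                     simplify = FALSE))
  la <- erd_latency(traces, times = times)
  expect_equal(la$latency, 0.6, tolerance = 0.011)
  expect_equal(la$n_crossing, 10)

  shallow <- do.call(rbind, replicate(5, step_trace(-20, 0.6),
                                      simplify = FALSE))
  expect_true(is.na(erd_latency(shallow, times = times)$latency))

  # late-onset outliers barely move the 20th percentile
  mixed <- rbind(traces, step_trace(-50, 1.8), step_trace(-50, 1.9))
  la2 <- erd_latency(mixed, times = times)
  onsets <- la2$onsets
  expect_lt(abs(la2$latency - 0.6), 0.05)
  expect_gt(mean(onsets) - 0.6, 0.15)
})

test_that("latency is invariant to affine rescaling of raw power", {
  fs <- 500
  t <- seq(-2, 3, by = 1 / fs)
  amp <- ifelse(t >= 0.5, sqrt(0.4), 1)
  seg <- analytic_segments(amp * sin(2 * pi * 15 * t) +
                             0.05 * sin(2 * pi * 22 * t), fs)
  tf1 <- morlet_tf(seg)
  seg$data <- seg$data * 7.3
  tf2 <- morlet_tf(seg)
  l1 <- erd_latency(percent_power_change(tf1))
  l2 <- erd_latency(percent_power_change(tf2))
  expect_equal(l1$latency, l2$latency)
  expect_equal(l1$onsets, l2$onsets)
})

test_that("CSP quality rubric scores strong data high and noise low", {
  sim <- strong_training_sim(seed = 70)
  ep <- epoch_training(bandpass(sim$recording), sim$events)
  bank <- train_classifier_bank(ep, shrinkage = 0.2)
  rep_strong <- csp_quality_score(bank$of$csp, bank$ce$csp, ep)
  expect_equal(rep_strong$total, 12L)
  expect_true(rep_strong$plausible)
  expect_identical(rep_strong$plausible, rep_strong$total >= 10)

  # null data, with the criteria evaluated on held-out epochs so that
  # in-sample CSP overfitting cannot masquerade as discriminability
  sim0 <- generate_training_recording(
    sim_config(n_runs = 15, erd_depth = 0, seed = 71))
  ep0 <- epoch_training(bandpass(sim0$recording), sim0$events)
  bank0 <- train_classifier_bank(ep0, shrinkage = 0.2)
  sim1 <- generate_training_recording(
    sim_config(n_runs = 15, erd_depth = 0, seed = 72))
  ep1 <- epoch_training(bandpass(sim1$recording), sim1$events)
  rep_null <- csp_quality_score(bank0$of$csp, bank0$ce$csp, ep1,
                                components = c(24, 24))
  crit <- rep_null$criteria
  disc <- crit[crit$criterion %in% c("power_discriminability",
                                     "single_trial_discriminability",
                                     "lateralized_erd"), ]
  expect_false(any(disc$flexion | disc$extension))
  expect_lte(rep_null$total, 6L)
  expect_false(rep_null$plausible)
})
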