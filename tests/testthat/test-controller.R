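# Six-state ensemble controller: gating, transitions, traces, monotonicity.

test_that("state gating activates the documented classifier subsets", {
  expect_equal(active_classifiers("REMAINING_OPENED"), "Y_OF")
  expect_equal(active_classifiers("REMAINING_CLOSED"), "Y_CE")
  expect_equal(active_classifiers("JUST_CLOSED"), c("Y_CE", "Y_EF"))
  expect_equal(active_classifiers("JUST_OPENED"), c("Y_OF", "Y_EF"))
  expect_equal(active_classifiers("CURRENTLY_FLEXING"), character())
  expect_equal(active_classifiers("CURRENTLY_EXTENDING"), character())
})

test_that("single steps follow the transition rules", {
  cfg <- controller_config()
  # threshold crossing from the open resting state emits a flexion
  s <- controller_step("REMAINING_OPENED", 0.75, 0, 0.5, 0, cfg)
  expect_equal(s$state, "CURRENTLY_FLEXING")
  expect_equal(s$movement, "movement_flexion")
  # inclusive comparison: exact threshold triggers
  expect_equal(controller_step("REMAINING_OPENED", 0.7, 0, 0.5, 0,
                               cfg)$state, "CURRENTLY_FLEXING")
  # sub-threshold probabilities change nothing before the timeout
  for (st in hand_states()) {
    s <- controller_step(st, 0, 0, 0.5, 0.05, cfg)
    expect_equal(s$state, st)
  }
  # JUST_CLOSED timeout falls back to REMAINING_CLOSED
  s <- controller_step("JUST_CLOSED", 0, 0, 0.5, 2.0, cfg)
  expect_equal(s$state, "REMAINING_CLOSED")
  expect_true(is.na(s$movement))
  # the JUST_CLOSED shortcut needs both classifiers; p_extension_EF is the
  # complement of the flexion probability
  expect_equal(controller_step("JUST_CLOSED", 0, 0.8, 0.2, 0.5,
                               cfg)$state, "CURRENTLY_EXTENDING")
  expect_equal(controller_step("JUST_CLOSED", 0, 0.8, 0.5, 0.5,
                               cfg)$state, "JUST_CLOSED")
  # threshold wins over a simultaneous timeout
  s <- controller_step("JUST_CLOSED", 0, 0.8, 0.2, 2.0, cfg)
  expect_equal(s$state, "CURRENTLY_EXTENDING")
  expect_equal(s$movement, "movement_extension")
  # movements are uninterruptible before movement_duration
  expect_equal(controller_step("CURRENTLY_FLEXING", 1, 1, 1, 1.95,
                               cfg)$state, "CURRENTLY_FLEXING")
  expect_equal(controller_step("CURRENTLY_FLEXING", 0, 0, 0.5, 2,
                               cfg)$state, "JUST_CLOSED")
  expect_validation_error(controller_step("REMAINING_OPENED", 1.2, 0, 0, 0))
})

test_that("an all-zero stream leaves the controller in its initial state", {
  stream <- generate_probability_stream(list(c(60, 0, 0, 0)))
  trace <- run_controller(stream)
  expect_equal(unique(trace$states$state), "REMAINING_OPENED")
  expect_equal(nrow(trace$movements), 0)
})

test_that("a saturated stream cycles with the hand-computed period", {
  # p_of = p_ce = 1, p_ef = 0.5: flexion triggers instantly from open;
  # extension from closed. Cycle: flex (tick 1), 40 ticks moving, JUST
  # CLOSED for 40 ticks (EF blocks the shortcut), then extension, ...
  stream <- generate_probability_stream(list(c(30, 0.5, 1, 1)))
  trace <- run_controller(stream)
  mv <- trace$movements
  expect_equal(mv$label[1:4],
               c("movement_flexion", "movement_extension",
                 "movement_flexion", "movement_extension"))
  # flexion at the first tick; extension after 2 s moving, the 2 s JUST
  # CLOSED timeout, and the one REMAINING_CLOSED decision tick
  expect_equal(mv$time[1], 0)
  expect_equal(mv$time[2] - mv$time[1], 2 + 2 + 0.05)
  expect_equal(diff(mv$time), rep(4.05, length(mv$time) - 1))
})

test_that("a single threshold crossing emits exactly one movement", {
  stream <- generate_probability_stream(list(c(0.5, 0, 0, 0),
                                             c(0.05, 0, 0.9, 0),
                                             c(0.95, 0, 0, 0)))
  trace <- run_controller(stream)
  expect_equal(nrow(trace$movements), 1)
  expect_equal(trace$movements$time, 0.5)
  expect_equal(trace$movements$label, "movement_flexion")
})

test_that("run_controller matches the independent tick oracle bitwise", {
  set.seed(20)
  cfg <- controller_config()
  scripts <- list(
    list(c(10, 0, 0, 0)),
    list(c(5, 0.5, 1, 1)),
    list(c(2, 0, 0.9, 0), c(3, 0.9, 0, 0.9), c(2, 0.1, 0, 0.95)),
    list(c(1, 0.7, 0.7, 0.7)),
    list(c(4, 0.3, 0.69, 0.7), c(4, 0.7, 0.71, 0.1))
  )
  streams <- lapply(scripts, generate_probability_stream)
  # plus random piecewise streams
  for (k in 1:6) {
    seg <- lapply(seq_len(8), function(i) c(runif(1, 0.3, 1.5), runif(3)))
    streams[[length(streams) + 1]] <- generate_probability_stream(seg)
  }
  for (stream in streams) {
    got <- run_controller(stream, cfg)
    want <- oracle_controller(stream, cfg)
    expect_identical(got$states$state, want$states)
    expect_equal(got$movements, want$movements)
  }
})

test_that("raising a threshold never increases the movement count", {
  set.seed(21)
  seg <- lapply(seq_len(30), function(i) c(runif(1, 0.2, 1), runif(3)))
  stream <- generate_probability_stream(seg)
  base <- controller_config(theta_of = 0.6, theta_ce = 0.6, theta_ef = 0.6)
  n_base <- nrow(run_controller(stream, base)$movements)
  for (cl in c("of", "ce", "ef")) {
    for (th in c(0.7, 0.85, 0.95)) {
      cfg <- adjust_threshold(base, cl, th)
      expect_lte(nrow(run_controller(stream, cfg)$movements), n_base)
    }
  }
})

test_that("threshold adjustment validates and logs", {
  cfg <- controller_config()
  cfg2 <- adjust_threshold(cfg, "of", 0.8)
  expect_equal(cfg2$theta_of, 0.8)
  expect_equal(cfg2$adjustments$old, 0.7)
  expect_validation_error(adjust_threshold(cfg, "of", 1.0))
  expect_validation_error(adjust_threshold(cfg, "ce", 0))
  # no-op adjustment leaves traces identical
  stream <- generate_probability_stream(list(c(5, 0.5, 0.9, 0.2)))
  same <- adjust_threshold(cfg, "of", 0.7)
  expect_identical(run_controller(stream, cfg)$states,
                   run_controller(stream, same)$states)
})

test_that("only graph edges occur and movements are uninterruptible", {
  set.seed(22)
  allowed <- list(
    REMAINING_OPENED = c("REMAINING_OPENED", "CURRENTLY_FLEXING"),
    CURRENTLY_FLEXING = c("CURRENTLY_FLEXING", "JUST_CLOSED"),
    JUST_CLOSED = c("JUST_CLOSED", "CURRENTLY_EXTENDING", "REMAINING_CLOSED"),
    REMAINING_CLOSED = c("REMAINING_CLOSED", "CURRENTLY_EXTENDING"),
    CURRENTLY_EXTENDING = c("CURRENTLY_EXTENDING", "JUST_OPENED"),
    JUST_OPENED = c("JUST_OPENED", "CURRENTLY_FLEXING", "REMAINING_OPENED"))
  n <- 20000
  stream <- tibble::tibble(time = (seq_len(n) - 1) * 0.05,
                           p_ef = runif(n), p_of = runif(n), p_ce = runif(n))
  trace <- run_controller(stream)
  states <- c("REMAINING_OPENED", trace$states$state)
  for (i in seq_len(n)) {
    expect_true(states[i + 1] %in% allowed[[states[i]]])
  }
  # movement states persist exactly movement_duration (40 ticks)
  r <- rle(trace$states$state)
  moving <- r$lengths[r$values %in% c("CURRENTLY_FLEXING",
                                      "CURRENTLY_EXTENDING")]
  expect_true(all(moving[-length(moving)] == 41 | moving[-length(moving)] == 40))
})

test_that("online pipeline equals run_controller on its own stream", {
  sim <- strong_training_sim(seed = 30, n_runs = 12)
  ep <- epoch_training(bandpass(sim$recording), sim$events)
  bank <- train_classifier_bank(ep, shrinkage = 0.2)
  fb <- generate_feedback_scenario(
    sim_config(n_runs = 12, erd_depth = 0.6, erd_latency = 0.2, seed = 31),
    user_model(), "follow_commands", duration = 40,
    commands = tibble::tibble(time = 10, label = "command_close"))
  trace <- run_online_pipeline(fb$recording, bank)
  replay <- run_controller(trace$probabilities, controller_config())
  expect_identical(trace$states, replay$states)
  expect_identical(trace$movements, replay$movements)
  # determinism end to end
  trace2 <- run_online_pipeline(fb$recording, bank)
  expect_identical(trace$states, trace2$states)
  # channel mismatch is rejected
  bad <- fb$recording
  bad$channels <- rev(bad$channels)
  expect_validation_error(run_online_pipeline(bad, bank))
})

test_that("a compliant user drives commanded movements; a null effect does not", {
  answered <- numeric(0)
  for (seed in c(5, 6, 8)) {
    cfg <- sim_config(n_runs = 30, erd_depth = 0.6, erd_latency = 0.2,
                      seed = seed)
    sim <- generate_training_recording(cfg)
    ep <- epoch_training(bandpass(sim$recording), sim$events)
    bank <- train_classifier_bank(ep, shrinkage = 0.2)
    ctrl <- calibrate_thresholds(sim$recording, sim$events, bank)
    fb <- generate_feedback_scenario(cfg, user_model(), "follow_commands",
                                     duration = 120)
    trace <- run_online_pipeline(fb$recording, bank, ctrl)
    cmds <- fb$events
    until <- c(cmds$time[-1], 120)
    answered <- c(answered, vapply(seq_len(nrow(cmds)), function(i) {
      any(trace$movements$time > cmds$time[i] &
            trace$movements$time <= until[i])
    }, logical(1)))
  }
  expect_gte(mean(answered), 0.8)
})
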