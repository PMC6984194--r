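# The six-state ensemble controller: turns streaming pairwise classifier
# probabilities into robotic-hand movements.
#
# State graph (a 6-cycle with two shortcut edges out of the JUST states):
#
#   REMAINING_OPENED --p_of >= th_of--> CURRENTLY_FLEXING (emit flexion)
#   CURRENTLY_FLEXING --2 s elapsed--> JUST_CLOSED
#   JUST_CLOSED --p_ce >= th_ce AND (1-p_ef) >= th_ef--> CURRENTLY_EXTENDING
#   JUST_CLOSED --2 s timeout--> REMAINING_CLOSED
#   REMAINING_CLOSED --p_ce >= th_ce--> CURRENTLY_EXTENDING (emit extension)
#   CURRENTLY_EXTENDING --2 s elapsed--> JUST_OPENED
#   JUST_OPENED --p_of >= th_of AND p_ef >= th_ef--> CURRENTLY_FLEXING
#   JUST_OPENED --2 s timeout--> REMAINING_OPENED
#
# All decisions happen on the 50 ms update grid; elapsed time in a state is
# counted in whole ticks. Threshold comparisons are inclusive (>=) and, in
# the JUST states, a threshold crossing wins over a simultaneous timeout.

#' Hand states of the ensemble controller
#'
#' @return Character vector of the six state names.
#' @export
hand_states <- function() {
  c("REMAINING_OPENED", "CURRENTLY_FLEXING", "JUST_CLOSED",
    "REMAINING_CLOSED", "CURRENTLY_EXTENDING", "JUST_OPENED")
}

#' Controller configuration
#'
#' @param theta_of,theta_ce,theta_ef Decision thresholds in (0, 1) for the
#'   open-vs-flexion, closed-vs-extension and extension-vs-flexion
#'   classifiers (default 0.7).
#' @param movement_duration Seconds a flexion/extension movement takes
#'   (default 2).
#' @param just_state_timeout Seconds before a JUST state falls back to the
#'   corresponding REMAINING state (default 2).
#' @param update_interval Tick spacing in seconds (default 0.05).
#' @param window Sliding analysis window in seconds (default 1.5).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(theta_of = 0.7, theta_ce = 0.7, theta_ef = 0.7,
                              movement_duration = 2, just_state_timeout = 2,
                              update_interval = 0.05, window = 1.5) {
  for (nm in c("theta_of", "theta_ce", "theta_ef")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v <= 0 || v >= 1) {
      abort_validation(sprintf("`%s` must lie strictly inside (0, 1)", nm))
    }
  }
  check_scalar(movement_duration, "movement_duration", lower = 1e-9)
  check_scalar(just_state_timeout, "just_state_timeout", lower = 1e-9)
  check_scalar(update_interval, "update_interval", lower = 1e-9)
  check_scalar(window, "window", lower = 1e-9)
  structure(list(theta_of = theta_of, theta_ce = theta_ce,
                 theta_ef = theta_ef,
                 movement_duration = movement_duration,
                 just_state_timeout = just_state_timeout,
                 update_interval = update_interval, window = window),
            class = "controller_config")
}

#' Adjust a classifier threshold
#'
#' Records the acquaintance-phase threshold adaptation (e.g. raising the
#' open-vs-flexion threshold from 0.7 to 0.8 when the hand opens more often
#' than intended). The change is appended to the config's audit log.
#'
#' @param config A [controller_config()].
#' @param classifier One of `"of"`, `"ce"`, `"ef"`.
#' @param new_theta New threshold, strictly inside (0, 1).
#' @return The updated [controller_config()] with an `adjustments` log.
#' @export
adjust_threshold <- function(config, classifier = c("of", "ce", "ef"),
                             new_theta) {
  classifier <- match.arg(classifier)
  check_scalar(new_theta, "new_theta")
  if (new_theta <= 0 || new_theta >= 1) {
    abort_validation("`new_theta` must lie strictly inside (0, 1)")
  }
  field <- paste0("theta_", classifier)
  log_entry <- tibble(classifier = classifier, old = config[[field]],
                      new = new_theta, stamp = format(Sys.time(), tz = "UTC"))
  config[[field]] <- new_theta
  config$adjustments <- bind_rows(config$adjustments, log_entry)
  config
}

#' Classifiers active in a hand state
#'
#' @param state One of [hand_states()].
#' @return Character subset of `c("Y_OF", "Y_CE", "Y_EF")`; empty during
#'   movements.
#' @export
active_classifiers <- function(state) {
  switch(match.arg(state, hand_states()),
         REMAINING_OPENED = "Y_OF",
         REMAINING_CLOSED = "Y_CE",
         JUST_CLOSED = c("Y_CE", "Y_EF"),
         JUST_OPENED = c("Y_OF", "Y_EF"),
         CURRENTLY_FLEXING = character(),
         CURRENTLY_EXTENDING = character())
}

#' Single controller transition
#'
#' One 50 ms decision given the current state, the active classifier
#' probabilities and the time already spent in the state. `p_flexion_ef` is
#' the flexion probability of the flexion-vs-extension classifier; its
#' extension probability is the complement.
#'
#' @param state Current state, one of [hand_states()].
#' @param p_flexion_of,p_extension_ce,p_flexion_ef Probabilities in `[0, 1]`.
#' @param elapsed Seconds spent in `state` so far (>= 0).
#' @param config A [controller_config()].
#' @return List with `state` (new state) and `movement` (`"movement_flexion"`,
#'   `"movement_extension"` or `NA`).
#' @export
controller_step <- function(state, p_flexion_of, p_extension_ce, p_flexion_ef,
                            elapsed, config = controller_config()) {
  check_probability(p_flexion_of, "p_flexion_of")
  check_probability(p_extension_ce, "p_extension_ce")
  check_probability(p_flexion_ef, "p_flexion_ef")
  if (elapsed < 0) abort_validation("`elapsed` must be >= 0")
  p_extension_ef <- 1 - p_flexion_ef
  new <- state
  movement <- NA_character_
  if (state == "REMAINING_OPENED") {
    if (p_flexion_of >= config$theta_of) {
      new <- "CURRENTLY_FLEXING"; movement <- "movement_flexion"
    }
  } else if (state == "CURRENTLY_FLEXING") {
    if (elapsed >= config$movement_duration) new <- "JUST_CLOSED"
  } else if (state == "JUST_CLOSED") {
    if (p_extension_ce >= config$theta_ce && p_extension_ef >= config$theta_ef) {
      new <- "CURRENTLY_EXTENDING"; movement <- "movement_extension"
    } else if (elapsed >= config$just_state_timeout) {
      new <- "REMAINING_CLOSED"
    }
  } else if (state == "REMAINING_CLOSED") {
    if (p_extension_ce >= config$theta_ce) {
      new <- "CURRENTLY_EXTENDING"; movement <- "movement_extension"
    }
  } else if (state == "CURRENTLY_EXTENDING") {
    if (elapsed >= config$movement_duration) new <- "JUST_OPENED"
  } else if (state == "JUST_OPENED") {
    if (p_flexion_of >= config$theta_of && p_flexion_ef >= config$theta_ef) {
      new <- "CURRENTLY_FLEXING"; movement <- "movement_flexion"
    } else if (elapsed >= config$just_state_timeout) {
      new <- "REMAINING_OPENED"
    }
  } else {
    abort_validation("unknown hand state")
  }
  list(state = new, movement = movement)
}

#' Run the controller over a probability stream
#'
#' Deterministic fold of [controller_step()] over a tick-sampled stream
#' (see [generate_probability_stream()]). Movements coincide exactly with
#' entries into the `CURRENTLY_*` states.
#'
#' @param stream Tibble `time`, `p_ef`, `p_of`, `p_ce`, sampled every
#'   `config$update_interval`, timestamps sorted.
#' @param config A [controller_config()].
#' @param initial_state Starting state (default `REMAINING_OPENED`).
#' @return An object of class `controller_trace`: list with `states`
#'   (tibble `time`, `state` — state after each tick), `movements` (tibble
#'   `time`, `label`) and `probabilities` (the consumed stream).
#' @export
run_controller <- function(stream, config = controller_config(),
                           initial_state = "REMAINING_OPENED") {
  initial_state <- match.arg(initial_state, hand_states())
  nt <- nrow(stream)
  if (nt > 1 && is.unsorted(stream$time)) {
    abort_validation("stream timestamps must be sorted")
  }
  for (col in c("p_ef", "p_of", "p_ce")) check_probability(stream[[col]], col)
  dt <- config$update_interval
  state <- initial_state
  entered_tick <- 0L
  states <- character(nt)
  mv_time <- numeric(0)
  mv_lab <- character(0)
  p_of <- stream$p_of; p_ce <- stream$p_ce; p_ef <- stream$p_ef
  th_of <- config$theta_of; th_ce <- config$theta_ce; th_ef <- config$theta_ef
  move_ticks <- config$movement_duration / dt
  just_ticks <- config$just_state_timeout / dt
  for (i in seq_len(nt)) {
    elapsed <- (i - 1L) - entered_tick
    new <- state
    movement <- NA_character_
    if (state == "REMAINING_OPENED") {
      if (p_of[i] >= th_of) { new <- "CURRENTLY_FLEXING"; movement <- "movement_flexion" }
    } else if (state == "CURRENTLY_FLEXING") {
      if (elapsed >= move_ticks) new <- "JUST_CLOSED"
    } else if (state == "JUST_CLOSED") {
      if (p_ce[i] >= th_ce && (1 - p_ef[i]) >= th_ef) {
        new <- "CURRENTLY_EXTENDING"; movement <- "movement_extension"
      } else if (elapsed >= just_ticks) new <- "REMAINING_CLOSED"
    } else if (state == "REMAINING_CLOSED") {
      if (p_ce[i] >= th_ce) { new <- "CURRENTLY_EXTENDING"; movement <- "movement_extension" }
    } else if (state == "CURRENTLY_EXTENDING") {
      if (elapsed >= move_ticks) new <- "JUST_OPENED"
    } else { # JUST_OPENED
      if (p_of[i] >= th_of && p_ef[i] >= th_ef) {
        new <- "CURRENTLY_FLEXING"; movement <- "movement_flexion"
      } else if (elapsed >= just_ticks) new <- "REMAINING_OPENED"
    }
    if (new != state) entered_tick <- i - 1L
    state <- new
    states[i] <- state
    if (!is.na(movement)) {
      mv_time <- c(mv_time, stream$time[i])
      mv_lab <- c(mv_lab, movement)
    }
  }
  structure(list(
    states = tibble(time = stream$time, state = states),
    movements = tibble(time = mv_time, label = mv_lab),
    probabilities = stream,
    initial_state = initial_state,
    config = config),
    class = "controller_trace")
}

#' @export
print.controller_trace <- function(x, ...) {
  cat(sprintf("<controller_trace> %d ticks, %d movements\n",
              nrow(x$states), nrow(x$movements)))
  if (nrow(x$movements) > 0) print(table(x$movements$label))
  invisible(x)
}

# Windowed variances of projected signals via cumulative sums: O(1)/tick.
window_logvar <- function(proj, starts, len) {
  cs <- rbind(0, apply(proj, 2, cumsum))
  cs2 <- rbind(0, apply(proj^2, 2, cumsum))
  s <- cs[starts + len, , drop = FALSE] - cs[starts, , drop = FALSE]
  s2 <- cs2[starts + len, , drop = FALSE] - cs2[starts, , drop = FALSE]
  v <- (s2 - s^2 / len) / (len - 1)
  log(pmax(v, .Machine$double.eps))
}

#' Extract the sliding-window probability stream from a recording
#'
#' Every `update_interval`, the most recent `window` of the causally
#' band-pass filtered recording is projected through each classifier's CSP
#' filters, log-variance featurized and scored by all three classifiers —
#' the same processing chain as classifier training.
#'
#' @param recording An [eeg_recording()] at the training montage.
#' @param bank A [train_classifier_bank()] bank.
#' @param config A [controller_config()].
#' @param band Band edges used during training (default 8-28 Hz).
#' @return A tibble `time`, `p_ef`, `p_of`, `p_ce` (one row per tick;
#'   `time` is the trailing edge of each window).
#' @export
decode_probability_stream <- function(recording, bank,
                                      config = controller_config(),
                                      band = c(8, 28)) {
  if (!identical(recording$channels, bank$of$csp$channels)) {
    abort_validation("recording channels do not match the training montage")
  }
  fs <- recording$fs
  len <- round(config$window * fs)
  if (n_samples(recording) < len) {
    abort_validation("recording shorter than one analysis window")
  }
  filtered <- bandpass(recording, band[1], band[2], mode = "causal")
  hop <- round(config$update_interval * fs)
  starts <- seq(1L, n_samples(recording) - len + 1L, by = hop)
  times <- (starts + len - 1L) / fs
  prob_for <- function(fit) {
    proj <- filtered$data %*% fit$csp$filters[, fit$csp$selected, drop = FALSE]
    feats <- window_logvar(proj, starts, len)
    colnames(feats) <- paste0("csp", fit$csp$selected)
    predict(fit$clf, feats)
  }
  tibble(time = times,
         p_ef = prob_for(bank$ef),
         p_of = prob_for(bank$of),
         p_ce = prob_for(bank$ce))
}

#' Run the full online decoding + controller pipeline on a recording
#'
#' Extracts the probability stream with [decode_probability_stream()] and
#' folds the six-state controller over it; the trace equals
#' [run_controller()] on the extracted stream by construction, and the
#' stream is returned inside the trace for audit.
#'
#' @inheritParams decode_probability_stream
#' @param initial_state Starting hand state.
#' @return A `controller_trace` (see [run_controller()]).
#' @export
run_online_pipeline <- function(recording, bank, config = controller_config(),
                                initial_state = "REMAINING_OPENED",
                                band = c(8, 28)) {
  stream <- decode_probability_stream(recording, bank, config, band)
  run_controller(stream, config, initial_state = initial_state)
}

#' Calibrate controller thresholds on rest-period probabilities
#'
#' Automatic stand-in for the acquaintance-phase threshold adjustment: each
#' classifier's threshold is set just above the `quantile` of its output
#' during known rest, so that spontaneous rest activity rarely triggers a
#' movement while imagery-driven excursions still can. Thresholds are
#' clamped to `[lower, upper]`.
#'
#' @param recording A training [eeg_recording()].
#' @param events Its event table (rest onsets define the rest windows).
#' @param bank A [train_classifier_bank()] bank.
#' @param config Base [controller_config()].
#' @param quantile_level Rest-probability quantile (default 0.99).
#' @param margin Added above the quantile (default 0.02).
#' @param lower,upper Clamping bounds for the thresholds.
#' @return The config with `theta_of`, `theta_ce`, `theta_ef` replaced
#'   (via [adjust_threshold()], so the changes are logged).
#' @export
calibrate_thresholds <- function(recording, events, bank,
                                 config = controller_config(),
                                 quantile_level = 0.99, margin = 0.02,
                                 lower = 0.55, upper = 0.92) {
  stream <- decode_probability_stream(recording, bank, config)
  rests <- events[events$label == "rest_onset", ]
  # windows fully inside a rest period: trailing edge in [start+window, start+5]
  in_rest <- rep(FALSE, nrow(stream))
  for (i in seq_len(nrow(rests))) {
    in_rest <- in_rest | (stream$time >= rests$time[i] + config$window &
                            stream$time <= rests$time[i] + 5)
  }
  if (!any(in_rest)) abort_validation("no rest-period windows available")
  clamp01 <- function(x) min(max(x, lower), upper)
  config <- adjust_threshold(config, "of", clamp01(
    quantile(stream$p_of[in_rest], quantile_level) + margin))
  config <- adjust_threshold(config, "ce", clamp01(
    quantile(stream$p_ce[in_rest], quantile_level) + margin))
  config <- adjust_threshold(config, "ef", clamp01(
    quantile(pmax(stream$p_ef[in_rest], 1 - stream$p_ef[in_rest]),
             quantile_level) + margin))
  config
}
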