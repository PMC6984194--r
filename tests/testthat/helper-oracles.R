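# Shared fixtures and independent oracles.

# Independent tick-by-tick simulation of the six-state hand machine,
# written as an explicit transition table over (state, condition) rather
# than the package's fold — used to cross-check run_controller() bitwise.
oracle_controller <- function(stream, config = controller_config(),
                              initial_state = "REMAINING_OPENED") {
  dt <- config$update_interval
  mv_ticks <- config$movement_duration / dt
  to_ticks <- config$just_state_timeout / dt
  state <- initial_state
  entry <- 1                        # tick index at which the state was entered
  out_state <- character(nrow(stream))
  movements <- list()
  for (i in seq_len(nrow(stream))) {
    since <- i - entry              # whole ticks spent in the current state
    ef <- stream$p_ef[i]; of <- stream$p_of[i]; ce <- stream$p_ce[i]
    trans <- NULL
    if (state == "REMAINING_OPENED" && of >= config$theta_of) {
      trans <- c("CURRENTLY_FLEXING", "movement_flexion")
    } else if (state == "CURRENTLY_FLEXING" && since >= mv_ticks) {
      trans <- c("JUST_CLOSED", NA)
    } else if (state == "JUST_CLOSED") {
      if (ce >= config$theta_ce && (1 - ef) >= config$theta_ef) {
        trans <- c("CURRENTLY_EXTENDING", "movement_extension")
      } else if (since >= to_ticks) trans <- c("REMAINING_CLOSED", NA)
    } else if (state == "REMAINING_CLOSED" && ce >= config$theta_ce) {
      trans <- c("CURRENTLY_EXTENDING", "movement_extension")
    } else if (state == "CURRENTLY_EXTENDING" && since >= mv_ticks) {
      trans <- c("JUST_OPENED", NA)
    } else if (state == "JUST_OPENED") {
      if (of >= config$theta_of && ef >= config$theta_ef) {
        trans <- c("CURRENTLY_FLEXING", "movement_flexion")
      } else if (since >= to_ticks) trans <- c("REMAINING_OPENED", NA)
    }
    if (!is.null(trans)) {
      state <- trans[1]
      entry <- i
      if (!is.na(trans[2])) {
        movements[[length(movements) + 1]] <-
          list(time = stream$time[i], label = trans[2])
      }
    }
    out_state[i] <- state
  }
  list(states = out_state,
       movements = if (length(movements) == 0) {
         tibble::tibble(time = numeric(), label = character())
       } else {
         tibble::tibble(time = sapply(movements, `[[`, "time"),
                        label = sapply(movements, `[[`, "label"))
       })
}

# Small noise epoch set built directly (no EEG generator): n_trials trials
# of ch-channel white noise, labelled alternately, with run metadata.
noise_epochs <- function(n_trials = 40, ch = 4, len = 100, fs = 100,
                         labels = rep(c("flexion", "rest_open"),
                                      n_trials / 2)) {
  data <- array(rnorm(len * ch * n_trials), dim = c(len, ch, n_trials))
  epoch_set(data, labels, fs = fs,
            meta = tibble::tibble(onset_time = seq_len(n_trials),
                                  run = rep(seq_len(n_trials / 2), each = 2)),
            channels = paste0("ch", seq_len(ch)))
}

# Band power (per sample, so comparable across segment lengths) of a
# signal in [low, high] Hz via the periodogram.
band_power <- function(x, fs, low, high) {
  x <- x - mean(x)
  sp <- Mod(fft(x))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  sum(sp[f >= low & f <= high]) / length(x)^2
}

# Training simulation small enough for unit tests but with a strong,
# early-onset effect, so decoding is close to separable.
strong_training_sim <- function(seed = 5, n_runs = 40) {
  generate_training_recording(
    sim_config(n_runs = n_runs, erd_depth = 0.75, erd_latency = 0.1,
               seed = seed))
}

expect_validation_error <- function(expr) {
  testthat::expect_error(expr, class = "smrbci_validation_error")
}
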