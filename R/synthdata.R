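# Synthetic sensorimotor-rhythm EEG.
#
# Signal model: per-channel white noise + 1/f background, plus two
# band-limited oscillatory sources (one per motor-imagery class) projected
# through fixed spatial topographies over central / centro-parietal
# channels. Each source is a superposition of constant-amplitude sinusoids
# spread across 9-26 Hz with a slow (~4 s time constant) multiplicative
# amplitude drift, so its band power is stable on the sub-second scale a
# single-trial ERD-onset analysis needs. Event-related desynchronization is
# a multiplicative amplitude envelope sqrt(1 - d) applied to the class's own
# source from (MI onset + latency) until shortly after MI offset, which
# produces an exact fractional band-power drop of d.

default_topographies <- function() {
  flexion <- c(C3 = 1, CP1 = 0.8, CP5 = 0.6, FC1 = 0.4)
  extension <- c(CZ = 1, CPz = 0.85, CP2 = 0.7, FC2 = 0.4)
  list(flexion = flexion, extension = extension)
}

#' Simulation configuration
#'
#' Parameters of the synthetic EEG generator. Defaults reproduce the fixed
#' study conditions: 24 channels at 500 Hz, 50 training runs of ~13.6 s
#' (5 s rest, LED, 1.5 s flexion imagery, 5 s rest, LED, 1.5 s extension
#' imagery), a 30% sensorimotor-band power drop during imagery and a
#' 0.51 s ERD onset latency (control-group preset; the stroke preset uses
#' 0.63 s).
#'
#' @param n_channels Number of channels; must match the montage length.
#' @param fs Sampling rate in Hz (> 100, i.e. twice the 50 Hz analysis top).
#' @param n_runs Number of training runs.
#' @param erd_depth Fraction of 10-25 Hz source power removed during MI;
#'   scalar or named vector `c(flexion = , extension = )`, each in \[0, 1\].
#' @param erd_latency Seconds from MI onset to ERD onset (>= 0).
#' @param erd_tail Seconds the desynchronization persists past MI offset.
#' @param noise List with `white_sd` and `pink_sd` (per-channel background).
#' @param source_rms RMS amplitude of each oscillatory source at its
#'   strongest channel, in the same units as the noise.
#' @param amp_mod_sd Relative SD of the slow amplitude drift of each source.
#' @param montage Channel labels (default [montage_24()]).
#' @param topographies List with named weight vectors `flexion` and
#'   `extension` over montage channels.
#' @param group `"control"` or `"stroke"`; presets `erd_latency` when it is
#'   not given explicitly (0.51 s vs 0.63 s).
#' @param seed Integer seed fixing all randomness, or `NULL`.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 24, fs = 500, n_runs = 50,
                       erd_depth = 0.30, erd_latency = NULL, erd_tail = 0.5,
                       noise = list(white_sd = 1, pink_sd = 2),
                       source_rms = 4, amp_mod_sd = 0.05,
                       montage = montage_24(),
                       topographies = default_topographies(),
                       group = c("control", "stroke"),
                       seed = NULL) {
  group <- match.arg(group)
  if (is.null(erd_latency)) {
    erd_latency <- if (group == "stroke") 0.63 else 0.51
  }
  check_scalar(n_channels, "n_channels", lower = 1, integerish = TRUE)
  if (length(montage) != n_channels) {
    abort_validation("field `montage` must have length n_channels")
  }
  check_scalar(fs, "fs", lower = 100 + 1e-9)
  check_scalar(n_runs, "n_runs", lower = 1, integerish = TRUE)
  if (!is.numeric(erd_depth) || anyNA(erd_depth) ||
      any(erd_depth < 0) || any(erd_depth > 1)) {
    abort_validation("field `erd_depth` must lie in [0, 1]")
  }
  if (!length(erd_depth) %in% c(1L, 2L)) {
    abort_validation("field `erd_depth` must be a scalar or length-2 vector")
  }
  check_scalar(erd_latency, "erd_latency", lower = 0)
  check_scalar(erd_tail, "erd_tail", lower = 0)
  check_scalar(noise$white_sd, "noise$white_sd", lower = 0)
  check_scalar(noise$pink_sd, "noise$pink_sd", lower = 0)
  check_scalar(source_rms, "source_rms", lower = 0)
  check_scalar(amp_mod_sd, "amp_mod_sd", lower = 0, upper = 0.5)
  for (cls in c("flexion", "extension")) {
    w <- topographies[[cls]]
    if (is.null(w) || is.null(names(w)) || !all(names(w) %in% montage)) {
      abort_validation(sprintf(
        "field `topographies$%s` must be named with montage channels", cls))
    }
  }
  check_scalar(seed, "seed", integerish = TRUE, allow_null = TRUE)
  structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    n_runs = as.integer(n_runs), erd_depth = erd_depth,
    erd_latency = erd_latency, erd_tail = erd_tail, noise = noise,
    source_rms = source_rms, amp_mod_sd = amp_mod_sd,
    montage = montage, topographies = topographies, group = group,
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

depth_for_class <- function(config, class) {
  d <- config$erd_depth
  if (length(d) == 1L) return(unname(d))
  if (!is.null(names(d)) && class %in% names(d)) return(unname(d[[class]]))
  unname(d[[if (class == "flexion") 1L else 2L]])
}

#' Simulated participant model
#'
#' Stands in for the participant during the feedback block: how quickly and
#' how reliably commanded mental states are adopted, and how often motor
#' imagery occurs spontaneously during rest.
#'
#' @param reaction_delay Seconds between a command and the mental-state
#'   switch (>= 0).
#' @param compliance Probability of adopting the commanded mental state.
#' @param spontaneous_mi_rate Uncommanded MI bouts per minute during rest.
#' @param mi_duration Duration of one MI bout in seconds.
#' @param attempt_interval Seconds between repeated attempts at a commanded
#'   movement (an instructed participant keeps trying until the movement is
#'   carried out).
#' @param max_attempts Maximum command-driven attempts per command.
#'
#' @return An object of class `user_model`.
#' @export
user_model <- function(reaction_delay = 0.5, compliance = 1,
                       spontaneous_mi_rate = 0, mi_duration = 3,
                       attempt_interval = 4.5, max_attempts = 3) {
  check_scalar(reaction_delay, "reaction_delay", lower = 0)
  check_scalar(compliance, "compliance", lower = 0, upper = 1)
  check_scalar(spontaneous_mi_rate, "spontaneous_mi_rate", lower = 0)
  check_scalar(mi_duration, "mi_duration", lower = 0.1)
  check_scalar(attempt_interval, "attempt_interval", lower = 0.5)
  check_scalar(max_attempts, "max_attempts", lower = 1, integerish = TRUE)
  structure(list(reaction_delay = reaction_delay, compliance = compliance,
                 spontaneous_mi_rate = spontaneous_mi_rate,
                 mi_duration = mi_duration,
                 attempt_interval = attempt_interval,
                 max_attempts = max_attempts),
            class = "user_model")
}

# --- low-level signal builders -----------------------------------------------

# 1/f-shaped noise via spectral shaping, unit variance.
pink_noise <- function(n, fs) {
  m <- stats::nextn(n, 2)
  z <- rnorm(m)
  zf <- fft(z)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, fs - f)                    # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))
  g[1] <- 0
  out <- Re(fft(zf * g, inverse = TRUE)) / m
  out <- out[seq_len(n)]
  out / sd(out)
}

# Constant-amplitude multi-sine oscillator with slow amplitude drift,
# normalized to unit RMS before the drift is applied.
smr_source <- function(n, fs, amp_mod_sd, freq_centers = c(10, 15, 20, 25)) {
  t <- (seq_len(n) - 1) / fs
  freqs <- freq_centers + runif(length(freq_centers), -1, 1)
  phases <- runif(length(freq_centers), 0, 2 * pi)
  x <- numeric(n)
  for (k in seq_along(freqs)) x <- x + sin(2 * pi * freqs[k] * t + phases[k])
  x <- x / sqrt(length(freqs) / 2)        # unit RMS
  if (amp_mod_sd > 0) {
    rho <- exp(-1 / (2 * fs))             # ~2 s drift time constant
    ar <- stats::filter(rnorm(n, sd = sqrt(1 - rho^2)), rho,
                        method = "recursive")
    x <- x * (1 + amp_mod_sd * as.numeric(ar))
  }
  x
}

# Assemble a recording from MI bout tables. `bouts` is a tibble with columns
# start, end, class; ERD applies to the class's own source from
# start + latency to end + tail.
build_recording <- function(config, n, bouts, seed) {
  fs <- config$fs
  with_rng_seed(seed, {
    data <- matrix(rnorm(n * config$n_channels, sd = config$noise$white_sd),
                   nrow = n, ncol = config$n_channels)
    if (config$noise$pink_sd > 0) {
      for (ch in seq_len(config$n_channels)) {
        data[, ch] <- data[, ch] + config$noise$pink_sd * pink_noise(n, fs)
      }
    }
    for (cls in c("flexion", "extension")) {
      src <- smr_source(n, fs, config$amp_mod_sd)
      env <- rep(1, n)
      cls_bouts <- bouts[bouts$class == cls, , drop = FALSE]
      d <- depth_for_class(config, cls)
      if (nrow(cls_bouts) > 0 && d > 0) {
        gain <- sqrt(1 - d)
        for (i in seq_len(nrow(cls_bouts))) {
          i0 <- round((cls_bouts$start[i] + config$erd_latency) * fs) + 1
          i1 <- round((cls_bouts$end[i] + config$erd_tail) * fs)
          if (i0 <= n && i1 >= i0) env[i0:min(i1, n)] <- gain
        }
      }
      src <- src * env * config$source_rms
      w <- config$topographies[[cls]]
      idx <- match(names(w), config$montage)
      for (k in seq_along(idx)) {
        data[, idx[k]] <- data[, idx[k]] + w[[k]] * src
      }
    }
    eeg_recording(data, fs = fs, channels = config$montage)
  })
}

# --- training block ----------------------------------------------------------

training_schedule <- function(config) {
  fs <- config$fs
  snap <- function(t) round(t * fs) / fs
  run_len <- 13.6
  ev <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    t0 <- (r - 1) * run_len
    ev[[r]] <- tibble(
      time = snap(t0 + c(0, 5, 5.3, 6.8, 11.8, 12.1)),
      label = c("rest_onset", "led_onset", "flexion_onset",
                "rest_onset", "led_onset", "extension_onset"),
      run = r)
  }
  list(events = bind_rows(ev), run_len = run_len)
}

#' Generate a synthetic training-block recording
#'
#' Emits, per run: 5 s rest, LED, 1.5 s flexion imagery, 5 s rest, LED,
#' 1.5 s extension imagery. Class-specific ERD (band-limited power reduction
#' of `erd_depth`, starting `erd_latency` after MI onset) is injected on the
#' class topography.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recording` ([eeg_recording()]), `events`
#'   (tibble `time`, `label`, `run`) and `truth` (the planted topographies,
#'   depth and latency, for evaluation oracles).
#' @export
generate_training_recording <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_validation("`config` must be a sim_config object")
  }
  sched <- training_schedule(config)
  n <- round(config$n_runs * sched$run_len * config$fs)
  onsets <- sched$events[sched$events$label %in%
                           c("flexion_onset", "extension_onset"), ]
  bouts <- tibble(start = onsets$time, end = onsets$time + 1.5,
                  class = sub("_onset$", "", onsets$label))
  recording <- build_recording(config, n, bouts, config$seed)
  list(recording = recording,
       events = sched$events,
       truth = list(topographies = config$topographies,
                    erd_depth = config$erd_depth,
                    erd_latency = config$erd_latency,
                    mi_bouts = bouts))
}

# --- feedback block ----------------------------------------------------------

# Command schedule consistent with the hand state under perfect execution:
# "close" when the hand is open, "open" when closed, with every fourth
# command a "grasp" (only issued from the closed state; a grasp ends closed).
default_command_schedule <- function(duration = 240) {
  times <- seq(10, duration - 20, by = 20)
  labels <- character(length(times))
  closed <- FALSE
  for (i in seq_along(times)) {
    if (i %% 4 == 0 && closed) {
      labels[i] <- "command_grasp"          # ends closed
    } else if (closed) {
      labels[i] <- "command_open"; closed <- FALSE
    } else {
      labels[i] <- "command_close"; closed <- TRUE
    }
  }
  tibble(time = times, label = labels)
}

# Latent MI bouts a (possibly non-compliant) user produces for a command
# set. The simulation is open loop, so a compliant user repeats attempts at
# `attempt_interval` spacing (up to `max_attempts`) within the command's
# time slot, mimicking a participant who keeps imagining until the hand
# finally moves.
command_bouts <- function(commands, user, duration) {
  bouts <- list()
  nxt <- c(commands$time[-1], duration)
  for (i in seq_len(nrow(commands))) {
    if (runif(1) > user$compliance) next
    t0 <- commands$time[i] + user$reaction_delay
    slot_end <- nxt[i]
    cls <- switch(commands$label[i],
                  command_close = "flexion",
                  command_open = "extension",
                  command_grasp = "grasp")
    starts <- seq(t0, by = user$attempt_interval,
                  length.out = user$max_attempts)
    if (cls == "grasp") {
      # open (extension) then immediately close (flexion); the flexion
      # attempt waits out the 2 s extension movement
      starts <- starts[seq_len(min(2, length(starts)))]
      for (s in starts) {
        if (s + user$mi_duration > slot_end) break
        bouts[[length(bouts) + 1]] <-
          tibble(start = s, end = s + user$mi_duration, class = "extension")
        t1 <- s + user$mi_duration + 2.5
        if (t1 + user$mi_duration <= slot_end) {
          bouts[[length(bouts) + 1]] <-
            tibble(start = t1, end = t1 + user$mi_duration, class = "flexion")
          break
        }
      }
    } else {
      starts <- starts[starts + user$mi_duration <= slot_end]
      for (s in starts) {
        bouts[[length(bouts) + 1]] <-
          tibble(start = s, end = s + user$mi_duration, class = cls)
      }
    }
  }
  out <- bind_rows(bouts)
  if (nrow(out) > 0) out <- out[out$end <= duration, , drop = FALSE]
  out
}

spontaneous_bouts <- function(windows, user) {
  bouts <- list()
  for (i in seq_len(nrow(windows))) {
    len <- windows$end[i] - windows$start[i]
    k <- rpois(1, user$spontaneous_mi_rate * len / 60)
    if (k == 0) next
    starts <- sort(runif(k, windows$start[i], windows$end[i] - user$mi_duration))
    bouts[[length(bouts) + 1]] <- tibble(
      start = starts, end = starts + user$mi_duration,
      class = sample(c("flexion", "extension"), k, replace = TRUE))
  }
  bind_rows(bouts)
}

#' Generate a synthetic self-paced feedback scenario
#'
#' Builds a recording whose latent mental-state trace follows the user
#' model for one of the three neurofeedback tasks: `rest_move` (phases of
#' free movement vs. rest, alternating eight times at 30 s), or
#' `follow_commands` / `announce_commands` (timestamped open/close/grasp
#' commands).
#'
#' @param config A [sim_config()].
#' @param user A [user_model()].
#' @param task One of `"rest_move"`, `"follow_commands"`,
#'   `"announce_commands"`.
#' @param commands Optional command tibble (`time`, `label`) for the command
#'   tasks; defaults to a schedule of alternating close/open with every
#'   fourth command a grasp, one command per 20 s.
#' @param duration Recording length in seconds for the command tasks.
#' @param phase_duration,n_phases Phase layout of the rest-vs-move task.
#' @param move_bout_interval Seconds between movement attempts in move phases.
#' @return A list with `recording`, `events` (phase / command markers),
#'   `intention` (ground-truth latent MI bouts: `start`, `end`, `class`) and
#'   `truth` (generator parameters).
#' @export
generate_feedback_scenario <- function(config, user = user_model(),
                                       task = c("rest_move", "follow_commands",
                                                "announce_commands"),
                                       commands = NULL, duration = 240,
                                       phase_duration = 30, n_phases = 8,
                                       move_bout_interval = 6) {
  task <- match.arg(task)
  if (!inherits(config, "sim_config")) {
    abort_validation("`config` must be a sim_config object")
  }
  if (!inherits(user, "user_model")) {
    abort_validation("`user` must be a user_model object")
  }
  seed <- child_seed(config$seed, 211L)
  if (task == "rest_move") {
    duration <- n_phases * phase_duration
    phase_start <- (seq_len(n_phases) - 1) * phase_duration
    phase_lab <- rep(c("phase_move", "phase_rest"), length.out = n_phases)
    events <- event_table(phase_start, phase_lab)
    bouts <- with_rng_seed(seed, {
      move <- tibble(start = phase_start[phase_lab == "phase_move"],
                     end = phase_start[phase_lab == "phase_move"] + phase_duration)
      attempts <- list()
      for (i in seq_len(nrow(move))) {
        starts <- seq(move$start[i] + 1, move$end[i] - user$mi_duration,
                      by = move_bout_interval)
        keep <- runif(length(starts)) <= user$compliance
        if (!any(keep)) next
        attempts[[length(attempts) + 1]] <- tibble(
          start = starts[keep], end = starts[keep] + user$mi_duration,
          class = rep(c("flexion", "extension"), length.out = length(starts))[keep])
      }
      rest <- tibble(start = phase_start[phase_lab == "phase_rest"],
                     end = phase_start[phase_lab == "phase_rest"] + phase_duration)
      bind_rows(bind_rows(attempts), spontaneous_bouts(rest, user))
    })
  } else {
    if (is.null(commands)) commands <- default_command_schedule(duration)
    if (nrow(commands) > 0 && max(commands$time) > duration - user$mi_duration) {
      abort_validation("command schedule extends past the recording end")
    }
    events <- event_table(commands$time, commands$label)
    bouts <- with_rng_seed(seed, {
      quiet <- tibble(start = c(0, commands$time + 10),
                      end = c(commands$time, duration))
      quiet <- quiet[quiet$end > quiet$start, , drop = FALSE]
      bind_rows(command_bouts(commands, user, duration),
                spontaneous_bouts(quiet, user))
    })
  }
  if (nrow(bouts) > 0) {
    bouts <- arrange(bouts, .data$start)
  } else {
    bouts <- tibble(start = numeric(), end = numeric(), class = character())
  }
  n <- round(duration * config$fs)
  recording <- build_recording(config, n, bouts, child_seed(config$seed, 97L))
  list(recording = recording, events = events, intention = bouts,
       truth = list(task = task, user = user, config_seed = config$seed))
}

# --- scripted probability streams --------------------------------------------

#' Generate a scripted classifier probability stream
#'
#' Produces the timestamped probability triples the six-state controller
#' consumes, piecewise constant per script segment, sampled at the
#' controller update rate. Lets controller tests bypass EEG decoding.
#'
#' @param script A data frame (or list of length-4 vectors) with columns
#'   `duration` (s), `p_ef`, `p_of`, `p_ce` — the flexion probability of the
#'   flexion-vs-extension classifier, the flexion probability of the
#'   open-vs-flexion classifier, and the extension probability of the
#'   closed-vs-extension classifier.
#' @param update_interval Tick spacing in seconds (default 0.05).
#' @return A tibble `time`, `p_ef`, `p_of`, `p_ce`; one row per tick.
#' @export
generate_probability_stream <- function(script, update_interval = 0.05) {
  check_scalar(update_interval, "update_interval", lower = 1e-6)
  if (is.list(script) && !is.data.frame(script)) {
    script <- do.call(rbind, lapply(script, function(s) {
      tibble(duration = s[[1]], p_ef = s[[2]], p_of = s[[3]], p_ce = s[[4]])
    }))
  }
  if (is.null(script) || nrow(script) == 0) {
    return(tibble(time = numeric(), p_ef = numeric(), p_of = numeric(),
                  p_ce = numeric()))
  }
  if (any(script$duration <= 0)) {
    abort_validation("script segment durations must be positive")
  }
  for (col in c("p_ef", "p_of", "p_ce")) check_probability(script[[col]], col)
  reps <- round(script$duration / update_interval)
  tibble(
    time = (seq_len(sum(reps)) - 1) * update_interval,
    p_ef = rep(script$p_ef, reps),
    p_of = rep(script$p_of, reps),
    p_ce = rep(script$p_ce, reps))
}
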