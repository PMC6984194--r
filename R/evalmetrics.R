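# Feedback-block performance evaluation: reconstructed 5 s trials and
# TP/FN/TN/FP scoring, rest-vs-move movement counts, and questionnaire
# construct scoring.

# Phase schedules may come as event tables (`time`) or as `start` columns.
normalize_phases <- function(phases) {
  if (!"start" %in% names(phases) && "time" %in% names(phases)) {
    phases <- rename(phases, start = "time")
  }
  phases
}

command_movement_map <- function() {
  c(command_close = "movement_flexion", command_open = "movement_extension")
}

#' When is a grasp command satisfied?
#'
#' A grasp means open (extension) then immediately close (flexion): it is
#' satisfied at the first flexion that directly follows an extension, with
#' both movements after the command and no other command in between.
#'
#' @param command_time Time of the grasp command in seconds.
#' @param movements Movement tibble (`time`, `label`), sorted.
#' @param until Time of the next command (or `Inf`).
#' @return Satisfaction time in seconds, or `NA` if unsatisfied.
#' @export
grasp_outcome <- function(command_time, movements, until = Inf) {
  mv <- movements[movements$time > command_time & movements$time < until, ,
                  drop = FALSE]
  if (nrow(mv) < 2) return(NA_real_)
  for (i in seq_len(nrow(mv) - 1)) {
    if (mv$label[i] == "movement_extension" &&
        mv$label[i + 1] == "movement_flexion") {
      return(mv$time[i + 1])
    }
  }
  NA_real_
}

satisfaction_time <- function(cmd_time, cmd_label, movements, until) {
  if (cmd_label == "command_grasp") {
    return(grasp_outcome(cmd_time, movements, until))
  }
  want <- command_movement_map()[[cmd_label]]
  hits <- movements$time[movements$label == want &
                           movements$time > cmd_time &
                           movements$time < until]
  if (length(hits) == 0) NA_real_ else hits[1]
}

#' Reconstruct 5 s trials from command and movement logs
#'
#' Rebuilds the trial structure of a self-paced session: from each command,
#' consecutive 5 s intended-movement trials run until the commanded
#' movement occurs (the trial containing it closes the series), after which
#' consecutive 5 s intended-rest trials run until the next command. An
#' intended-movement trial containing a movement is a true positive (TP),
#' one without is a false negative (FN); an intended-rest trial without a
#' movement is a true negative (TN), one with a movement a false positive
#' (FP). Movements before the first command count against an implicit
#' initial rest series; a new command truncates the running series (the
#' partial segment is dropped); trailing segments shorter than 5 s are
#' dropped.
#'
#' @param commands Command tibble (`time`, `label` in
#'   `command_open`/`command_close`/`command_grasp`), time-sorted.
#' @param movements Movement tibble (`time`, `label` in
#'   `movement_flexion`/`movement_extension`), time-sorted.
#' @param session_end Session length in seconds.
#' @param trial_length Trial length in seconds (default 5).
#' @param strict_direction If `TRUE` (default), only the commanded movement
#'   type satisfies an intended-movement series; a wrong-direction movement
#'   leaves the trial an FN and is logged as a wrong-polarity event.
#' @return An object of class `trial_ledger`: list with `trials` (tibble
#'   `start`, `end`, `intended`, `outcome`), `counts` (named TP/FN/TN/FP)
#'   and `wrong_polarity` (times of wrong-direction movements in intended-
#'   movement trials).
#' @export
reconstruct_trials <- function(commands, movements, session_end,
                               trial_length = 5, strict_direction = TRUE) {
  check_scalar(session_end, "session_end", lower = 0)
  if (nrow(commands) > 0 && is.unsorted(commands$time)) {
    abort_validation("`commands` must be time-sorted")
  }
  if (nrow(movements) > 0 && is.unsorted(movements$time)) {
    abort_validation("`movements` must be time-sorted")
  }
  any_movement_in <- function(a, b) {
    any(movements$time >= a & movements$time < b)
  }
  trials <- list()
  add_trial <- function(start, end, intended, outcome) {
    trials[[length(trials) + 1]] <<-
      tibble(start = start, end = end, intended = intended, outcome = outcome)
  }
  wrong_polarity <- numeric(0)
  # rest series on a 5 s grid from `from` until `until`; partials dropped
  emit_rest <- function(from, until) {
    s <- from
    while (s + trial_length <= until + 1e-9) {
      hit <- any_movement_in(s, s + trial_length)
      add_trial(s, s + trial_length, "rest", if (hit) "FP" else "TN")
      s <- s + trial_length
    }
  }
  cmd_times <- commands$time
  nxt <- c(cmd_times[-1], Inf)
  if (nrow(commands) == 0) {
    emit_rest(0, session_end)
  } else {
    emit_rest(0, cmd_times[1])
    for (i in seq_len(nrow(commands))) {
      t0 <- cmd_times[i]
      until <- min(nxt[i], session_end)
      sat <- satisfaction_time(t0, commands$label[i], movements, until)
      if (!strict_direction && is.na(sat)) {
        anyhit <- movements$time[movements$time > t0 & movements$time < until]
        if (length(anyhit) > 0) sat <- anyhit[1]
      }
      s <- t0
      while (s + trial_length <= until + 1e-9) {
        e <- s + trial_length
        if (!is.na(sat) && sat >= s && sat < e) {
          add_trial(s, e, "movement", "TP")
          # intended-rest series resumes at the end of the closing trial
          emit_rest(e, until)
          break
        } else if (!is.na(sat) && sat < s) {
          break  # handled by emit_rest above
        } else {
          if (strict_direction && any_movement_in(s, e)) {
            wrong_polarity <- c(wrong_polarity,
                                movements$time[movements$time >= s &
                                                 movements$time < e])
          }
          add_trial(s, e, "movement", "FN")
          s <- e
        }
      }
    }
  }
  trials <- if (length(trials) == 0) {
    tibble(start = numeric(), end = numeric(), intended = character(),
           outcome = character())
  } else bind_rows(trials)
  counts <- vapply(c("TP", "FN", "TN", "FP"),
                   function(o) sum(trials$outcome == o), integer(1))
  structure(list(trials = trials, counts = counts,
                 wrong_polarity = wrong_polarity),
            class = "trial_ledger")
}

#' @export
print.trial_ledger <- function(x, ...) {
  cat(sprintf("<trial_ledger> %d trials: TP %d, FN %d, TN %d, FP %d\n",
              nrow(x$trials), x$counts["TP"], x$counts["FN"],
              x$counts["TN"], x$counts["FP"]))
  invisible(x)
}

#' Feedback accuracy of a trial ledger
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`: 100 means every intended
#' movement produced a movement and every intended rest stayed still.
#'
#' @param ledger A [reconstruct_trials()] ledger (or a named TP/FN/TN/FP
#'   count vector).
#' @return Percent accuracy in `[0, 100]`.
#' @export
feedback_accuracy <- function(ledger) {
  counts <- if (inherits(ledger, "trial_ledger")) ledger$counts else ledger
  total <- sum(counts[c("TP", "FN", "TN", "FP")])
  if (is.na(total) || total == 0) {
    abort_validation("ledger contains no scored trials")
  }
  100 * sum(counts[c("TP", "TN")]) / total
}

#' Build a trial ledger for the rest-vs-move task
#'
#' Move phases consist solely of intended-movement 5 s trials, rest phases
#' solely of intended-rest trials; any movement type counts.
#'
#' @param trace A `controller_trace` (or a movement tibble).
#' @param phases Tibble `start`, `label` (`phase_move` / `phase_rest`).
#' @param phase_duration Phase length in seconds.
#' @param trial_length Trial length in seconds.
#' @return A `trial_ledger`.
#' @export
rest_move_ledger <- function(trace, phases, phase_duration = 30,
                             trial_length = 5) {
  movements <- if (inherits(trace, "controller_trace")) trace$movements else trace
  phases <- normalize_phases(phases)
  trials <- list()
  for (i in seq_len(nrow(phases))) {
    intended <- if (phases$label[i] == "phase_move") "movement" else "rest"
    starts <- seq(phases$start[i], by = trial_length,
                  length.out = floor(phase_duration / trial_length))
    for (s in starts) {
      hit <- any(movements$time >= s & movements$time < s + trial_length)
      outcome <- if (intended == "movement") {
        if (hit) "TP" else "FN"
      } else {
        if (hit) "FP" else "TN"
      }
      trials[[length(trials) + 1]] <-
        tibble(start = s, end = s + trial_length, intended = intended,
               outcome = outcome)
    }
  }
  trials <- bind_rows(trials)
  counts <- vapply(c("TP", "FN", "TN", "FP"),
                   function(o) sum(trials$outcome == o), integer(1))
  structure(list(trials = trials, counts = counts,
                 wrong_polarity = numeric(0)),
            class = "trial_ledger")
}

#' Movement counts per rest / move phase
#'
#' Counts hand movements in each phase of the rest-vs-move task (phase
#' intervals are left-closed, right-open: a movement exactly on a boundary
#' belongs to the phase that starts there).
#'
#' @param trace A `controller_trace` (or a movement tibble `time`, `label`).
#' @param phases Tibble `start`, `label` with alternating `phase_move` /
#'   `phase_rest` markers.
#' @param phase_duration Phase length in seconds (default 30).
#' @return A list with `per_phase` (tibble `start`, `label`, `movements`)
#'   and `means` (named mean counts for move and rest phases).
#' @export
rest_move_counts <- function(trace, phases, phase_duration = 30) {
  movements <- if (inherits(trace, "controller_trace")) trace$movements else trace
  phases <- normalize_phases(phases)
  if (nrow(phases) == 0) abort_validation("empty phase schedule")
  if (inherits(trace, "controller_trace") && nrow(trace$states) > 0) {
    span <- max(trace$states$time)
    if (max(phases$start) + phase_duration > span + phase_duration) {
      abort_validation("phase schedule extends past the trace")
    }
  }
  counts <- vapply(seq_len(nrow(phases)), function(i) {
    sum(movements$time >= phases$start[i] &
          movements$time < phases$start[i] + phase_duration)
  }, numeric(1))
  per_phase <- tibble(start = phases$start, label = phases$label,
                      movements = counts)
  means <- c(move = mean(counts[phases$label == "phase_move"]),
             rest = mean(counts[phases$label == "phase_rest"]))
  list(per_phase = per_phase, means = means)
}

questionnaire_items <- function() {
  tibble(
    construct = c(rep("SoO", 3), rep("SoO_control", 2), rep("SoA", 3),
                  "SoA_control", rep("ER", 3), rep("MIAB", 3)),
    item = c("soo_own_hand", "soo_position", "soo_part_of_body",
             "soo_ctrl_right_gone", "soo_ctrl_left_gone",
             "soa_closing", "soa_opening", "soa_withhold",
             "soa_ctrl_hand_controls_will",
             "er_clear_detailed", "er_vivid_real", "er_forgot_imagining",
             "miab_extension_linked", "miab_flexion_linked",
             "miab_position_fused"))
}

#' Score questionnaire constructs
#'
#' Averages the three 7-point Likert items (-3 "totally disagree" to +3
#' "totally agree") of each phenomenal construct — sense of ownership
#' (SoO), sense of agency (SoA), experiential realness (ER) and MI-action
#' binding (MIAB) — plus their control items (two for SoO, one for SoA). A
#' construct counts as induced when its mean is >= 1 (inclusive); control
#' constructs are scored but never flagged as induction evidence.
#'
#' @param ratings Named numeric vector (names as in the package item set,
#'   see internal item table) or a tibble `item`, `rating`; every item must
#'   be answered with an integer in `[-3, 3]`.
#' @return A tibble `construct`, `n_items`, `mean`, `induced`, `control`.
#' @export
score_questionnaire <- function(ratings) {
  items <- questionnaire_items()
  if (is.data.frame(ratings)) {
    ratings <- setNames(ratings$rating, ratings$item)
  }
  missing <- setdiff(items$item, names(ratings))
  if (length(missing) > 0) {
    abort_validation(paste0("missing rating(s): ",
                            paste(missing, collapse = ", ")))
  }
  vals <- ratings[items$item]
  bad <- !is.finite(vals) | vals < -3 | vals > 3 |
    abs(vals - round(vals)) > 1e-9
  if (any(bad)) {
    abort_validation(paste0("out-of-range or non-integer rating(s): ",
                            paste(items$item[bad], collapse = ", ")))
  }
  items$rating <- as.numeric(vals)
  out <- items %>%
    group_by(construct = .data$construct) %>%
    summarise(n_items = dplyr::n(), mean = mean(.data$rating),
              .groups = "drop") %>%
    mutate(control = grepl("_control$", .data$construct),
           induced = !.data$control & .data$mean >= 1)
  out[match(c("SoO", "SoA", "ER", "MIAB", "SoO_control", "SoA_control"),
            out$construct), ]
}
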