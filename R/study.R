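# End-to-end simulated cohort study: per-subject simulation, decoding,
# feedback, ERD analysis, questionnaire scoring, and group statistics.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Synthetic questionnaire ratings for one subject and block. Latent
# construct levels follow feasibility-scale defaults (induction criterion
# region ~1 for most constructs, agency reduced in controls); item ratings
# are the latent level plus unit noise, rounded and clamped to the 7-point
# scale. Purely synthetic stand-ins for participant self-reports.
simulate_questionnaire <- function(group, block) {
  latent <- c(
    SoO = 1.1, SoA = if (group == "stroke") 1.45 else 0.35,
    ER = 1.3, MIAB = if (group == "stroke") 1.3 else 0.3,
    SoO_control = -0.3, SoA_control = -0.2)
  items <- questionnaire_items()
  vals <- vapply(items$construct, function(cn) {
    clamp(round(latent[[cn]] + rnorm(1)), -3, 3)
  }, numeric(1))
  setNames(vals, items$item)
}

analyze_subject <- function(subject_id, group, seed, n_runs, erd_depth,
                            erd_latency, feedback_duration, l2_lambda,
                            cv_folds, shrinkage) {
  cfg <- sim_config(n_runs = n_runs, erd_depth = erd_depth,
                    erd_latency = erd_latency, group = group, seed = seed)
  train <- generate_training_recording(cfg)
  filt <- bandpass(train$recording)
  epochs <- reject_artifacts(epoch_training(filt, train$events))
  bank <- train_classifier_bank(epochs, l2_lambda = l2_lambda,
                                shrinkage = shrinkage)

  pairs <- list(ef = c("flexion", "extension"), of = c("flexion", "rest_open"),
                ce = c("extension", "rest_closed"))
  acc <- vapply(pairs, function(p) {
    as.numeric(blockwise_cv_accuracy(epochs, p, k = cv_folds,
                                     l2_lambda = l2_lambda,
                                     shrinkage = shrinkage))
  }, numeric(1))
  n_pair <- vapply(pairs, function(p) sum(epochs$labels %in% p), numeric(1))
  chance <- vapply(n_pair, function(n) binomial_chance_level(n), numeric(1))
  above <- acc > chance

  # offline ERD analysis: each MI class on its own contrast component
  comp_f <- choose_component(bank$of$csp, epochs, "flexion", "rest_open")
  comp_e <- choose_component(bank$ce$csp, epochs, "extension", "rest_closed")
  # extract the component with the pattern-matched spatial filter: the
  # estimated source topography is far more stable than the CSP filter
  # weights, so single-trial traces carry less cross-source interference
  match_filter <- function(csp, comp) {
    pat <- csp$patterns[, comp]
    pat / sum(pat^2)
  }
  tf_f <- percent_power_change(morlet_tf(csp_component_segments(
    train$recording, train$events, match_filter(bank$of$csp, comp_f))))
  tf_e <- percent_power_change(morlet_tf(csp_component_segments(
    train$recording, train$events, match_filter(bank$ce$csp, comp_e))))
  smr_flex <- mean_smr_change(tf_f, trials = tf_f$labels == "flexion")
  smr_ext <- mean_smr_change(tf_e, trials = tf_e$labels == "extension")
  lat_f <- erd_latency(band_power_traces(tf_f)[tf_f$labels == "flexion", ,
                                               drop = FALSE],
                       times = tf_f$times)
  lat_e <- erd_latency(band_power_traces(tf_e)[tf_e$labels == "extension", ,
                                               drop = FALSE],
                       times = tf_e$times)
  lat <- list(latency = mean(c(lat_f$latency, lat_e$latency), na.rm = TRUE))
  if (!is.finite(lat$latency)) lat$latency <- NA_real_

  quality <- csp_quality_score(bank$of$csp, bank$ce$csp, epochs)

  # feedback block: rest-vs-move task + follow-commands task, with
  # acquaintance-phase threshold calibration on the training data
  user <- user_model()
  ctrl_cfg <- calibrate_thresholds(train$recording, train$events, bank,
                                   controller_config())
  fb_rm <- generate_feedback_scenario(cfg, user, "rest_move")
  trace_rm <- run_online_pipeline(fb_rm$recording, bank, ctrl_cfg)
  phases <- fb_rm$events[fb_rm$events$label %in% c("phase_move", "phase_rest"), ]
  rm_counts <- rest_move_counts(trace_rm, phases)
  acc_rm <- feedback_accuracy(rest_move_ledger(trace_rm, phases))

  fb_fc <- generate_feedback_scenario(cfg, user, "follow_commands",
                                      duration = feedback_duration)
  trace_fc <- run_online_pipeline(fb_fc$recording, bank, ctrl_cfg)
  ledger_fc <- reconstruct_trials(fb_fc$events, trace_fc$movements,
                                  feedback_duration)
  acc_fc <- feedback_accuracy(ledger_fc)

  q_train <- with_rng_seed(child_seed(seed, 31L),
                           simulate_questionnaire(group, "training"))
  q_fb <- with_rng_seed(child_seed(seed, 32L),
                        simulate_questionnaire(group, "feedback"))
  sc_train <- score_questionnaire(q_train)
  sc_fb <- score_questionnaire(q_fb)
  construct_cols <- function(sc, suffix) {
    setNames(as.list(sc$mean[match(c("SoO", "SoA", "ER", "MIAB"),
                                   sc$construct)]),
             paste0(c("SoO", "SoA", "ER", "MIAB"), suffix))
  }

  c(list(subject = subject_id, group = group,
         erd_depth = erd_depth, erd_latency_true = erd_latency,
         acc_ef = acc[["ef"]], acc_of = acc[["of"]], acc_ce = acc[["ce"]],
         chance_ef = chance[["ef"]], chance_of = chance[["of"]],
         chance_ce = chance[["ce"]],
         n_above_chance = sum(above),
         smr_change_flexion = smr_flex, smr_change_extension = smr_ext,
         erd_latency_est = lat$latency,
         csp_quality = quality$total, csp_plausible = quality$plausible,
         movements_move = rm_counts$means[["move"]],
         movements_rest = rm_counts$means[["rest"]],
         accuracy_rest_move = acc_rm, accuracy_follow = acc_fc),
    construct_cols(sc_train, "_training"), construct_cols(sc_fb, "_feedback"))
}

#' Run the full simulated cohort study
#'
#' Simulates a cohort of stroke-group and control-group participants (the
#' stroke preset delays ERD onset), runs the complete per-subject pipeline
#' — training-block simulation, decoding, block-wise cross-validated
#' training accuracies with binomial chance levels, offline ERD
#' time-frequency analysis, CSP quality scoring, the online feedback block
#' with the six-state controller, trial reconstruction and feedback
#' accuracies, and synthetic questionnaire scoring — then the group-level
#' bootstrap statistics with Holm correction.
#'
#' @param n_per_group Subjects per group (default 9).
#' @param n_runs Training runs per subject.
#' @param feedback_duration Follow-commands task length in seconds.
#' @param erd_depth_mean,erd_depth_sd Cohort ERD depth distribution.
#' @param latency_sd Between-subject SD of the ERD latency (s).
#' @param cv_folds Cross-validation folds.
#' @param l2_lambda Classifier regularization.
#' @param shrinkage Covariance shrinkage used throughout the decoding
#'   pipeline (default 0.2; tempers CSP eigenvector overfitting at
#'   moderate trial counts).
#' @param B Bootstrap replicates for the group statistics.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Optional directory: per-subject CSV table and a JSON
#'   stats report are written there.
#' @return A list with `subjects` (one row per participant) and `stats`
#'   (one row per significance test, Holm-corrected within family).
#' @export
run_study <- function(n_per_group = 9, n_runs = 24, feedback_duration = 120,
                      erd_depth_mean = 0.30, erd_depth_sd = 0.05,
                      latency_sd = 0.06, cv_folds = 5, l2_lambda = 1,
                      shrinkage = 0.2, B = 1000, seed = 1, out_dir = NULL) {
  check_scalar(n_per_group, "n_per_group", lower = 2, integerish = TRUE)
  groups <- rep(c("stroke", "control"), each = n_per_group)
  n_sub <- length(groups)
  subject_params <- with_rng_seed(child_seed(seed, 1L), {
    tibble(
      subject = sprintf("S%02d", seq_len(n_sub)),
      group = groups,
      erd_depth = clamp(rnorm(n_sub, erd_depth_mean, erd_depth_sd), 0.1, 0.6),
      erd_latency = clamp(
        rnorm(n_sub, ifelse(groups == "stroke", 0.63, 0.51), latency_sd),
        0.2, 1.2))
  })
  rows <- lapply(seq_len(n_sub), function(i) {
    analyze_subject(subject_params$subject[i], subject_params$group[i],
                    seed = child_seed(seed, 100L + i),
                    n_runs = n_runs,
                    erd_depth = subject_params$erd_depth[i],
                    erd_latency = subject_params$erd_latency[i],
                    feedback_duration = feedback_duration,
                    l2_lambda = l2_lambda, cv_folds = cv_folds,
                    shrinkage = shrinkage)
  })
  subjects <- bind_rows(lapply(rows, as_tibble))
  subjects$accuracy_feedback_mean <-
    rowMeans(subjects[, c("accuracy_rest_move", "accuracy_follow")])

  stats <- cohort_statistics(subjects, B = B, seed = child_seed(seed, 7L))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(subjects, file.path(out_dir, "subjects.csv"),
                     progress = FALSE)
    readr::write_csv(stats, file.path(out_dir, "stats.csv"), progress = FALSE)
    jsonlite::write_json(list(seed = seed, n_per_group = n_per_group,
                              n_runs = n_runs, B = B, stats = stats),
                         file.path(out_dir, "stats.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(subjects = subjects, stats = stats)
}

anova_rows <- function(label, data, B, seed) {
  res <- bootstrap_mixed_anova(data, B = B, seed = seed)
  bind_rows(lapply(names(res), function(eff) {
    tibble(test = label, effect = eff, statistic = res[[eff]]$statistic,
           estimate = res[[eff]]$observed, p = res[[eff]]$p)
  }))
}

cohort_statistics <- function(subjects, B, seed) {
  long2 <- function(col1, col2, cond_names) {
    mixed_design(
      subject = rep(subjects$subject, 2),
      group = rep(subjects$group, 2),
      condition = rep(cond_names, each = nrow(subjects)),
      value = c(subjects[[col1]], subjects[[col2]]))
  }
  out <- list()
  k <- 0L
  nxt <- function() { k <<- k + 1L; child_seed(seed, k) }

  out$smr <- anova_rows("smr_change_group_x_class",
                        long2("smr_change_flexion", "smr_change_extension",
                              c("flexion", "extension")), B, nxt())
  for (cn in c("SoO", "SoA", "ER", "MIAB")) {
    out[[cn]] <- anova_rows(paste0(cn, "_group_x_block"),
                            long2(paste0(cn, "_training"),
                                  paste0(cn, "_feedback"),
                                  c("training", "feedback")), B, nxt())
  }
  out$moves <- anova_rows("movements_group_x_phase",
                          long2("movements_move", "movements_rest",
                                c("move", "rest")), B, nxt())

  stroke <- subjects$group == "stroke"
  lat_ok <- is.finite(subjects$erd_latency_est)
  tt_lat <- bootstrap_ttest(subjects$erd_latency_est[stroke & lat_ok],
                            subjects$erd_latency_est[!stroke & lat_ok],
                            B = B, seed = nxt())
  tt_q <- bootstrap_ttest(subjects$csp_quality[stroke],
                          subjects$csp_quality[!stroke], B = B, seed = nxt())
  out$tt <- tibble(
    test = c("erd_latency_group", "csp_quality_group"),
    effect = "group_difference", statistic = "t",
    estimate = c(tt_lat$observed, tt_q$observed),
    p = c(tt_lat$p, tt_q$p))

  # construct intercorrelations, groups and blocks pooled
  constructs <- c("SoO", "SoA", "ER", "MIAB")
  pooled <- lapply(constructs, function(cn) {
    c(subjects[[paste0(cn, "_training")]], subjects[[paste0(cn, "_feedback")]])
  })
  names(pooled) <- constructs
  pairs <- utils::combn(constructs, 2)
  out$cor <- bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    r <- bootstrap_correlation(pooled[[a]], pooled[[b]], B = B, seed = nxt())
    tibble(test = paste0("cor_", a, "_", b), effect = "correlation",
           statistic = "r", estimate = r$observed, p = r$p)
  }))

  stats <- bind_rows(out)
  stats$p_holm <- holm_correction(stats$p)$p_adjusted
  stats$reject_holm <- holm_correction(stats$p)$reject
  stats
}
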