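# Trial reconstruction, feedback accuracy, rest/move counts, questionnaire.

cmd <- function(time, label) tibble::tibble(time = time, label = label)
mov <- function(time, label) tibble::tibble(time = time, label = label)

test_that("hand-segmented toy sessions are reproduced exactly", {
  # one command satisfied at +3 s, then 20 s of quiet
  led <- reconstruct_trials(cmd(0, "command_close"),
                            mov(3, "movement_flexion"), session_end = 25)
  expect_equal(unname(led$counts), c(1L, 0L, 4L, 0L))

  # a command never satisfied within 15 s gives three failed trials
  led2 <- reconstruct_trials(cmd(0, "command_close"),
                             mov(numeric(), character()), session_end = 15)
  expect_equal(unname(led2$counts), c(0L, 3L, 0L, 0L))

  # empty logs, whole session of implicit rest
  led3 <- reconstruct_trials(cmd(numeric(), character()),
                             mov(numeric(), character()), session_end = 17)
  expect_equal(unname(led3$counts), c(0L, 0L, 3L, 0L))

  # movement before any command is a false positive in the initial rest
  led4 <- reconstruct_trials(cmd(12, "command_close"),
                             mov(2, "movement_flexion"), session_end = 12)
  expect_equal(unname(led4$counts), c(0L, 0L, 1L, 1L))
})

test_that("wrong-direction movements do not satisfy a command", {
  led <- reconstruct_trials(cmd(0, "command_close"),
                            mov(2, "movement_extension"), session_end = 10)
  expect_equal(unname(led$counts), c(0L, 2L, 0L, 0L))
  expect_equal(led$wrong_polarity, 2)
})

test_that("a later command supersedes the running series", {
  led <- reconstruct_trials(
    cmd(c(0, 8), c("command_close", "command_close")),
    mov(9, "movement_flexion"), session_end = 23)
  # first command: one FN trial [0,5); partial [5,8) dropped; second
  # command: TP at [8,13), then rest [13,18), [18,23)
  expect_equal(unname(led$counts), c(1L, 1L, 2L, 0L))
})

test_that("grasp satisfaction needs extension directly followed by flexion", {
  mv <- mov(c(2, 4.5), c("movement_extension", "movement_flexion"))
  expect_equal(grasp_outcome(0, mv), 4.5)
  expect_true(is.na(grasp_outcome(0, mov(4.5, "movement_flexion"))))
  # an intervening command voids the pair
  expect_true(is.na(grasp_outcome(0, mv, until = 3)))
  led <- reconstruct_trials(cmd(0, "command_grasp"), mv, session_end = 10)
  expect_equal(unname(led$counts), c(1L, 0L, 1L, 0L))
})

test_that("feedback accuracy is the percent of successful trials", {
  expect_equal(feedback_accuracy(c(TP = 3L, FN = 1L, TN = 4L, FP = 2L)), 70)
  expect_equal(feedback_accuracy(c(TP = 5L, FN = 0L, TN = 5L, FP = 0L)), 100)
  expect_equal(feedback_accuracy(c(TP = 0L, FN = 5L, TN = 0L, FP = 5L)), 0)
  expect_validation_error(feedback_accuracy(c(TP = 0L, FN = 0L, TN = 0L,
                                              FP = 0L)))
})

test_that("confusion counts conserve the number of whole trials", {
  set.seed(80)
  for (i in 1:20) {
    n_cmd <- sample(1:5, 1)
    commands <- cmd(sort(runif(n_cmd, 0, 80)),
                    sample(c("command_close", "command_open",
                             "command_grasp"), n_cmd, replace = TRUE))
    n_mov <- rpois(1, 6)
    movements <- mov(sort(runif(n_mov, 0, 90)),
                     sample(c("movement_flexion", "movement_extension"),
                            n_mov, replace = TRUE))
    led <- reconstruct_trials(commands, movements, session_end = 90)
    expect_equal(sum(led$counts), nrow(led$trials))
    expect_true(all(led$trials$end - led$trials$start == 5))
    acc <- feedback_accuracy(led)
    expect_gte(acc, 0)
    expect_lte(acc, 100)
  }
})

test_that("a perfect user scores exactly 100", {
  commands <- cmd(c(0, 20, 40), c("command_close", "command_open",
                                  "command_close"))
  movements <- mov(c(2, 22, 42), c("movement_flexion", "movement_extension",
                                   "movement_flexion"))
  led <- reconstruct_trials(commands, movements, session_end = 60)
  expect_equal(feedback_accuracy(led), 100)
  expect_equal(led$counts[["FN"]] + led$counts[["FP"]], 0L)
})

test_that("Poisson null movements match the closed-form rest accuracy", {
  # command-free sessions: every trial is an intended-rest trial, and the
  # expected accuracy is 100 * P(no movement in 5 s) = 100 * exp(-5 lambda)
  set.seed(81)
  lambda <- 0.1
  acc <- replicate(200, {
    n <- rpois(1, lambda * 100)
    movements <- mov(sort(runif(n, 0, 100)),
                     rep("movement_flexion", n))
    feedback_accuracy(reconstruct_trials(cmd(numeric(), character()),
                                         movements, session_end = 100))
  })
  expect_lt(abs(mean(acc) - 100 * exp(-5 * lambda)), 3)
})

test_that("rest/move phase counts respect left-closed boundaries", {
  phases <- tibble::tibble(start = seq(0, 210, by = 30),
                           label = rep(c("phase_move", "phase_rest"), 4))
  none <- rest_move_counts(mov(numeric(), character()), phases)
  expect_equal(unname(none$means), c(0, 0))

  mv <- mov(c(30, 59.99, 60), rep("movement_flexion", 3))
  rc <- rest_move_counts(mv, phases)
  # 30 and 59.99 fall in the rest phase [30, 60); 60 starts the next move
  expect_equal(rc$per_phase$movements[2], 2)
  expect_equal(rc$per_phase$movements[3], 1)
  expect_validation_error(rest_move_counts(mv, phases[0, ]))
})

test_that("rest-move trial ledger marks phases with the right outcomes", {
  phases <- tibble::tibble(start = c(0, 30), label = c("phase_move",
                                                       "phase_rest"))
  mv <- mov(c(2, 40), c("movement_flexion", "movement_extension"))
  led <- rest_move_ledger(mv, phases)
  expect_equal(nrow(led$trials), 12)
  expect_equal(led$counts[["TP"]], 1L)     # movement in first move trial
  expect_equal(led$counts[["FN"]], 5L)
  expect_equal(led$counts[["FP"]], 1L)     # movement at 40 s in rest
  expect_equal(led$counts[["TN"]], 5L)
})

test_that("questionnaire constructs honor the inclusive induction threshold", {
  items <- smrbci:::questionnaire_items()
  ratings <- setNames(rep(3, nrow(items)), items$item)
  sc <- score_questionnaire(ratings)
  expect_equal(sc$mean[sc$construct == "SoO"], 3)
  expect_true(all(sc$induced[!sc$control]))
  expect_false(any(sc$induced[sc$control]))   # controls are never induction evidence

  ratings[items$item[items$construct == "SoA"]] <- c(1, 1, 1)
  expect_true(score_questionnaire(ratings)$induced[
    score_questionnaire(ratings)$construct == "SoA"])
  ratings[items$item[items$construct == "SoA"]] <- c(0, 1, 1)
  sc3 <- score_questionnaire(ratings)
  expect_equal(sc3$mean[sc3$construct == "SoA"], 2 / 3, tolerance = 1e-9)
  expect_false(sc3$induced[sc3$construct == "SoA"])

  bad <- ratings
  bad[1] <- 5
  expect_error(score_questionnaire(bad), "out-of-range",
               class = "smrbci_validation_error")
  expect_error(score_questionnaire(ratings[-1]), "missing",
               class = "smrbci_validation_error")
})
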