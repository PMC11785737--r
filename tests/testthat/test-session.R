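test_that("feedback thresholds match the published 80/50 rule", {
  cfg <- session_config()
  expect_equal(feedback_for(0.85, cfg), "Great Job!")
  expect_equal(feedback_for(0.80, cfg), "Great Job!")   # inclusive at 80%
  expect_equal(feedback_for(0.50, cfg), "Good Job!")    # inclusive at 50%
  expect_equal(feedback_for(0.49, cfg), "Try Again!")
  expect_equal(feedback_for(1, cfg), "Great Job!")
  expect_equal(feedback_for(0, cfg), "Try Again!")
  expect_error(feedback_for(1.2, cfg), class = "fm_range_error")
  # monotone non-decreasing under Try Again! < Good Job! < Great Job!
  rank <- c("Try Again!" = 1, "Good Job!" = 2, "Great Job!" = 3)
  fb <- rank[vapply(seq(0, 1, by = 0.01), feedback_for, character(1),
                    config = cfg)]
  expect_true(all(diff(fb) >= 0))
})

test_that("the default window is 16 frames (5 s at 3.2 Hz)", {
  expect_equal(window_frames(session_config()), 16L)
  expect_equal(window_frames(session_config(window_seconds = 2,
                                            frame_rate_hz = 3)), 6L)
})

test_that("run_attempt averages frame correctness over the window", {
  neutral <- fixture_neutral()
  frames <- replicate(16, neutral, simplify = FALSE)
  all_ok <- run_attempt(frames, neutral, "happiness", oracle_classifier)
  expect_equal(all_ok$mean_accuracy, 1)
  expect_equal(all_ok$feedback, "Great Job!")

  half <- run_attempt(frames, neutral, "happiness", partial_classifier(8))
  expect_equal(half$mean_accuracy, 0.5)
  expect_equal(half$feedback, "Good Job!")

  seven <- run_attempt(frames, neutral, "happiness", partial_classifier(7))
  expect_equal(seven$mean_accuracy, 0.4375)   # 7/16 by direct count
  expect_equal(seven$feedback, "Try Again!")
})

test_that("invalid frames are skipped and all-invalid windows error", {
  neutral <- fixture_neutral()
  dead <- landmark_frame(matrix(0, 478, 3))
  frames <- c(replicate(8, neutral, simplify = FALSE),
              replicate(8, dead, simplify = FALSE))
  res <- run_attempt(frames, neutral, "fear", oracle_classifier)
  expect_equal(res$skipped_frames, 8)
  expect_length(res$frame_predictions, 8)   # denominator excludes skips
  expect_equal(res$mean_accuracy, 1)
  expect_error(
    run_attempt(replicate(4, dead, simplify = FALSE), neutral, "fear",
                oracle_classifier),
    class = "fm_face_not_recognized_error")
})

test_that("an oracle classifier completes the session without retries", {
  streams <- generate_session_streams(cohort_spec(seed = 21L), skill = 1)
  log <- run_session(streams$provider, oracle_classifier, streams$reference)
  expect_equal(unname(try_again_counts(log)), rep(0L, 7))
  expect_equal(unname(log$attempt_counts), rep(1L, 7))
  expect_equal(length(log$attempts), 7)
  expect_true(all(vapply(log$attempts, `[[`, character(1), "feedback")
                  == "Great Job!"))
})

test_that("a class that always fails is re-queued to the attempt cap", {
  streams <- generate_session_streams(cohort_spec(seed = 21L), skill = 1)
  log <- run_session(streams$provider, always_wrong_on("surprise"),
                     streams$reference)
  counts <- try_again_counts(log)
  expect_equal(unname(counts["surprise"]), 3L)
  expect_equal(unname(counts[names(counts) != "surprise"]), rep(0L, 6))
  expect_equal(unname(log$attempt_counts["surprise"]), 3L)
  # the re-queued attempts run after the initial lineup
  exprs <- vapply(log$attempts, `[[`, character(1), "expression")
  expect_equal(exprs, c(label_scheme()$seven_classes, "surprise", "surprise"))
})

test_that("an always-failing session totals sequence x max_attempts attempts", {
  streams <- generate_session_streams(cohort_spec(seed = 22L), skill = 1)
  log <- run_session(streams$provider, always_wrong_classifier,
                     streams$reference)
  expect_equal(length(log$attempts), 21)   # 7 expressions x 3 attempts
  expect_equal(unname(log$attempt_counts), rep(3L, 7))
  expect_equal(sum(try_again_counts(log)), 21L)
})

test_that("session log invariants hold and replays are reproducible", {
  streams <- generate_session_streams(cohort_spec(seed = 23L),
                                      skill = c(surprise = 0.3, fear = 0.4))
  cohort <- small_cohort_features()
  model <- train_model(cohort, train_config(epochs = 40L, seed = 23L))
  log1 <- run_session(streams$provider, model, streams$reference)
  log2 <- run_session(streams$provider, model, streams$reference)
  expect_identical(session_summary(log1), session_summary(log2))
  cfg <- log1$config
  expect_true(all(log1$attempt_counts <= cfg$max_attempts))
  # every non-final attempt has feedback "Try Again!"
  by_expr <- split(log1$attempts,
                   vapply(log1$attempts, `[[`, character(1), "expression"))
  for (attempts in by_expr) {
    ks <- vapply(attempts, `[[`, integer(1), "attempt_number")
    expect_equal(ks, seq_along(ks))   # consecutive from 1
    fb <- vapply(attempts, `[[`, character(1), "feedback")
    if (length(fb) > 1) {
      expect_true(all(fb[-length(fb)] == "Try Again!"))
    }
  }
})

test_that("session logs round-trip through JSONL and summarize to CSV", {
  streams <- generate_session_streams(cohort_spec(seed = 24L), skill = 1)
  log <- run_session(streams$provider, always_wrong_on("anger"),
                     streams$reference, subject_id = "s42")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_jsonl(log, path)
  back <- read_session_jsonl(path)
  expect_equal(back$subject_id, "s42")
  expect_equal(session_summary(back)[-1], session_summary(log)[-1])
  expect_equal(try_again_counts(back), try_again_counts(log))
  # merged logs are additive
  merged <- try_again_counts(list(log, log))
  expect_equal(merged, try_again_counts(log) * 2L)
})
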