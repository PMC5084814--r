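# Session validation, scoring, confusion matrices and group comparisons.

test_that("response validation applies the 100 ms / 4 s window rules", {
  ev <- make_events(list(
    list(trial = 1, timbre = "pure", target = "C4",
         presses = data.frame(note = "C4", latency = 2.0)),      # valid
    list(trial = 2, timbre = "pure", target = "D4",
         presses = data.frame(note = "C4", latency = 0.05)),     # late echo only
    list(trial = 3, timbre = "pure", target = "E4"),             # no press
    list(trial = 4, timbre = "pure", target = "F4",
         presses = data.frame(note = "F4", latency = 0.1)),      # exactly 100 ms
    list(trial = 5, timbre = "pure", target = "G4",
         presses = data.frame(note = "G4", latency = 4.5)),      # after window
    list(trial = 6, timbre = "pure", target = "A4",
         presses = data.frame(note = c("A3", "A4"), latency = c(1.0, 2.0)))))
  vs <- validate_session(ev)
  expect_identical(vs$trials$valid, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # trials 2 and 4: both first presses are at or before 100 ms
  expect_identical(vs$n_late_reassigned, 2L)
  expect_identical(vs$n_valid + vs$n_timeout, nrow(vs$trials))
  # multiple presses: first valid press wins
  expect_identical(vs$trials$response_midi[6], note_to_midi("A3"))
  # echo press is discarded, not promoted
  expect_true(is.na(vs$trials$response_midi[2]))
  # valid latencies always inside (0.1, 4]
  lat <- vs$trials$latency_s[vs$trials$valid]
  expect_true(all(lat > 0.1 & lat <= 4))
  expect_error(validate_session(transform(ev, latency_s = -latency_s)), "negative")
})

test_that("an echo press followed by a real press keeps the real press", {
  ev <- make_events(list(
    list(trial = 1, timbre = "pure", target = "C4",
         presses = data.frame(note = c("B3", "C4"), latency = c(0.07, 1.2)))))
  vs <- validate_session(ev)
  expect_true(vs$trials$valid[1])
  expect_identical(vs$trials$response_midi[1], note_to_midi("C4"))
  expect_identical(vs$n_late_reassigned, 1L)
})

test_that("scoring reproduces the defining identities", {
  perfect <- offset_session(0)
  sc <- score_session(perfect)
  all_row <- sc[sc$timbre == "all", ]
  expect_equal(all_row$mean_ae, 0)
  expect_equal(all_row$aps, 1)
  expect_equal(all_row$hit_rate, 1)
  expect_equal(all_row$octave_error_rate, 0)

  # every answer one octave below target
  oct_down <- score_session(offset_session(-12))
  row <- oct_down[oct_down$timbre == "all", ]
  expect_equal(row$mean_ae, 12)
  expect_equal(row$mean_ace, 0)
  expect_equal(row$octave_error_measure, 12)
  expect_equal(row$octave_error_rate, 1)
  expect_equal(row$hit_rate, 1)       # hit judged on corrected error
  expect_equal(row$aps, 1)
  # under the raw-error reading of "hit" the octave shift is a miss
  row_ae <- score_session(offset_session(-12), hit_on = "ae")
  expect_equal(row_ae[row_ae$timbre == "all", "hit_rate"], 0)
})

test_that("scores are invariant to trial order and APS follows mean ACE", {
  prof <- behavior_profile()
  ev <- simulate_behavior(prof, seed = 11)
  vs1 <- validate_session(ev)
  vs2 <- validate_session(ev[sample(nrow(ev)), ])
  expect_equal(as.data.frame(score_session(vs1)), as.data.frame(score_session(vs2)))
  sc <- score_session(vs1)
  expect_equal(sc$aps, 1 - sc$mean_ace / 6)
  expect_true(all(sc$mean_ace >= 0 & sc$mean_ace <= 6))
  expect_true(all(sc$octave_error_measure >= -1e-12))
})

test_that("scoring a session with no valid trials fails", {
  ev <- make_events(list(list(trial = 1, timbre = "pure", target = "C4")))
  expect_error(score_session(validate_session(ev)), "no valid trials")
})

test_that("confusion matrices conserve mass and fold octaves when corrected", {
  # perfect responder: identity diagonal
  cm <- confusion_matrix(list(offset_session(0)), timbre = "pure")
  expect_equal(sum(cm), 1)
  expect_equal(attr(cm, "prop_unanswered"), 0)
  on_diag <- sum(cm[cbind(rownames(cm), rownames(cm))])
  expect_equal(on_diag, 1)

  # pure octave-error responder: raw band at -12, corrected diagonal
  down <- offset_session(-12)
  raw <- confusion_matrix(list(down), timbre = "pure", corrected = FALSE)
  cor_ <- confusion_matrix(list(down), timbre = "pure", corrected = TRUE)
  tgt <- note_to_midi(rownames(raw))
  band <- sum(raw[cbind(seq_along(tgt), match(tgt - 12, note_to_midi(colnames(raw))))])
  expect_equal(band, 1)
  expect_equal(sum(cor_[cbind(rownames(cor_), rownames(cor_))]), 1)

  # with timeouts, answered mass + unanswered mass = 1
  prof <- behavior_profile(timeout_rate = 0.2, late_echo_rate = 0)
  sess <- lapply(1:3, function(s) validate_session(simulate_behavior(prof, seed = s)))
  cm2 <- confusion_matrix(sess, timbre = "all")
  expect_equal(sum(cm2) + attr(cm2, "prop_unanswered"), 1)
})

test_that("group comparisons match closed-form t and z statistics", {
  # identical groups: statistic 0, p = 1
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # Welch t against the closed form
  x <- c(0.52, 0.55, 0.49, 0.58, 0.51)
  y <- c(0.91, 0.88, 0.95, 0.97)
  g <- rep(c("non", "ap"), c(5, 4))
  got <- compare_groups(c(x, y), factor(g, levels = c("non", "ap")))
  se <- sqrt(var(x) / 5 + var(y) / 4)
  expect_equal(got$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  # pooled Student variant agrees with t.test(var.equal = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  got2 <- compare_groups(c(x, y), factor(g, levels = c("non", "ap")), var_equal = TRUE)
  expect_equal(got2$statistic, unname(ref$statistic))
  expect_equal(got2$df, 7)

  # two-proportion z: 5/9 vs 5/8
  zb <- compare_groups(rep(c(1, 0, 1, 0), c(5, 4, 5, 3)),
                       rep(c("g1", "g2"), c(9, 8)), kind = "z")
  p_pool <- 10 / 17
  se_z <- sqrt(p_pool * (1 - p_pool) * (1 / 9 + 1 / 8))
  expect_equal(zb$statistic, (5 / 9 - 5 / 8) / se_z, tolerance = 1e-12)
  expect_lt(abs(zb$statistic), 1)

  expect_error(compare_groups(rep(1, 6), rep(c("a", "b"), 3)), "zero variance")
})

test_that("session logs round-trip through CSV files", {
  ev <- simulate_behavior(behavior_profile(), seed = 3)
  path <- tempfile(fileext = ".csv")
  write.csv(ev, path, row.names = FALSE, na = "")
  vs_file <- read_sessions(path)[[1]]
  vs_mem <- validate_session(ev)
  expect_equal(vs_file$trials$response_midi, vs_mem$trials$response_midi)
  expect_equal(vs_file$n_valid, vs_mem$n_valid)
  unlink(path)
})
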