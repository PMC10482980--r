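test_that("simulated logs honor the schedule and the study structure", {
  d <- group_design("g1", cp_theta(0.6, 0.4, 0.2, 0.1, 0.1), 25)
  log <- simulate_trials(d, seed = 3)
  expect_equal(nrow(log), 25 * 26)
  per <- split(log, log$participant_id)
  for (p in per) {
    expect_equal(sum(p$phase == "training"), 6)
    expect_equal(sum(p$partner == "cooperate"), 13)
    expect_equal(sum(p$phase == "test" & p$partner == "defect"), 10)
    expect_equal(sum(p$phase == "test" & p$partner == "cooperate"), 10)
    expect_equal(sort(p$trial), 1:26)
  }
  expect_true(all(log$punish_invest >= 0 & log$punish_invest <= 9))
  expect_true(all((log$punish_invest > 0) ==
                    (log$punish_invest %in% 1:9)))
  # online variant bounds punishment at 3 and records punish-backs
  log2 <- simulate_trials(d, seed = 3, rules = cp_rules(max_punishment = 3),
                          partner_punishes_defection = TRUE)
  expect_true(all(log2$punish_invest <= 3))
  back <- log2$partner == "cooperate" & log2$participant == "defect"
  expect_true(all(log2$partner_punish_invest[back] %in% 1:3))
  expect_true(all(log2$partner_punish_invest[!back] == 0))
})

test_that("degenerate parameters produce degenerate logs", {
  d <- group_design("g", cp_theta(C = 1), 10)
  log <- simulate_trials(d, seed = 5)
  test <- log[log$phase == "test", ]
  expect_true(all(test$participant == "cooperate"))
  expect_true(all(test$punish_invest == 0))

  # no punishment process active -> zero punished trials anywhere
  d2 <- group_design("g", cp_theta(C = 0.5), 50)
  log2 <- simulate_trials(d2, seed = 5)
  expect_true(all(log2$punish_invest == 0))
})

test_that("simulation is reproducible and stable under growth", {
  d <- group_design("g", cp_theta(0.5, 0.4, 0.3, 0.2, 0.1), 30)
  a <- simulate_trials(d, seed = 17)
  b <- simulate_trials(d, seed = 17)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(a, fa); write_trial_log(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))

  # adding participants appends without reshuffling earlier ones
  bigger <- simulate_trials(
    group_design("g", cp_theta(0.5, 0.4, 0.3, 0.2, 0.1), 40), seed = 17)
  expect_equal(bigger[seq_len(nrow(a)), names(a)], a, ignore_attr = TRUE)

  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_trials(d, seed = 17)); after <- runif(3)
  expect_identical(before, after)
})

test_that("empirical category frequencies converge to the model probabilities", {
  th <- cp_theta(0.5, 0.5, 0.2, 0.1, 0.1)
  d <- group_design("g", th, 2000)
  tabs <- aggregate_trials(simulate_trials(d, seed = 23))
  tab <- tabs$g
  expect_equal(tab$n_defect_tree, 20000)
  expect_equal(tab$n_coop_tree, 20000)
  p <- category_probabilities(th)
  n_tree <- c(rep(20000, 4), rep(20000, 4))
  emp <- tab$counts / n_tree
  se <- sqrt(p * (1 - p) / n_tree)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
  # the spot check of the derivation: P(cooperate & punished | defect tree)
  expect_lt(abs(emp[1] - 0.5 * (0.5 + 0.5 * 0.1)), 3 * se[1])
})

test_that("parameter recovery is well-calibrated at a desk scale", {
  th <- cp_theta(0.6, 0.4, 0.2, 0.1, 0.1)
  rec <- parameter_recovery(th, n_participants = 150, n_replicates = 40,
                            seed = 2)
  expect_equal(rec$n_nonconverged, 0)
  expect_true(all(abs(rec$bias) < 0.05))
  expect_true(all(rec$coverage > 0.8))
  # consistency: more participants, lower error
  rec_big <- parameter_recovery(th, n_participants = 1500,
                                n_replicates = 10, seed = 2)
  expect_true(all(rec_big$rmse < rec$rmse))
})
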