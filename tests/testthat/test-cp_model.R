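test_that("category probabilities match the branch products in degenerate cases", {
  p <- category_probabilities(cp_theta(C = 1))
  expect_equal(unname(p[c("defect:cooperate:not_punished",
                          "cooperate:cooperate:not_punished")]), c(1, 1))
  expect_equal(sum(p), 2)

  p2 <- category_probabilities(cp_theta(C = 0.5, P_moral = 0.5, b = 0.5))
  expect_equal(unname(p2["defect:cooperate:punished"]),
               0.5 * (0.5 + 0.5 * 0.5))

  p3 <- category_probabilities(cp_theta(C = 0.5))
  expect_equal(unname(p3[c("cooperate:cooperate:punished",
                           "cooperate:defect:punished")]), c(0, 0))
})

test_that("each tree's probabilities sum to one over random parameters", {
  set.seed(101)
  for (i in 1:1000) {
    p <- category_probabilities(cp_theta(runif(1), runif(1), runif(1),
                                         runif(1), runif(1)))
    expect_lt(abs(sum(p[1:4]) - 1), 1e-12)
    expect_lt(abs(sum(p[5:8]) - 1), 1e-12)
  }
})

test_that("moral-punishment probability is monotone in P_moral and b, and the cooperate marginal is exactly C in both trees", {
  set.seed(7)
  for (i in 1:50) {
    th <- random_theta()
    pm_grid <- seq(0, 1, by = 0.1)
    probs_pm <- sapply(pm_grid, function(pm) {
      th2 <- unclass(th); th2["P_moral"] <- pm
      category_probabilities(th2)["defect:cooperate:punished"]
    })
    expect_true(all(diff(probs_pm) >= -1e-14))
    b_grid <- seq(0, 1, by = 0.1)
    probs_b <- sapply(b_grid, function(b) {
      th2 <- unclass(th); th2["b"] <- b
      category_probabilities(th2)["defect:cooperate:punished"]
    })
    expect_true(all(diff(probs_b) >= -1e-14))
    p <- category_probabilities(th)
    expect_equal(unname(sum(p[1:2])), unname(th["C"]))
    expect_equal(unname(sum(p[5:6])), unname(th["C"]))
  }
})

test_that("analytic probabilities agree with a Monte-Carlo branch process", {
  set.seed(42)
  th <- cp_theta(0.55, 0.45, 0.25, 0.15, 0.2)
  n <- 1e5
  emp <- branch_process_freqs(th, n)
  p <- category_probabilities(th)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
})

test_that("log-likelihood matches a term-by-term oracle and handles zeros", {
  empty <- cp_freq_table(rep(0, 8))
  th <- random_theta()
  expect_equal(cp_loglik(th, empty), 0)

  set.seed(3)
  tab <- random_table(th)
  p <- category_probabilities(th)
  manual <- 0
  for (j in 1:8) if (tab$counts[j] > 0)
    manual <- manual + tab$counts[j] * log(p[j])
  expect_lt(abs(cp_loglik(th, tab) - manual), 1e-10)

  # positive count in a zero-probability category -> -Inf
  th0 <- cp_theta(C = 1)          # all defect categories impossible
  tab0 <- cp_freq_table(c(0, 10, 1, 0, 0, 10, 0, 0))
  expect_identical(cp_loglik(th0, tab0), -Inf)
})

test_that("expected counts scale probabilities by tree totals", {
  expect_equal(unname(expected_counts(cp_theta(C = 1), 10, 10)),
               c(0, 10, 0, 0, 0, 10, 0, 0))
  th <- cp_theta(0.3, 0.6, 0.2, 0.4, 0.25)
  e <- expected_counts(th, 120, 80)
  p <- category_probabilities(th)
  expect_equal(unname(e), unname(c(p[1:4] * 120, p[5:8] * 80)))
  expect_equal(sum(e[1:4]), 120)
  expect_equal(sum(e[5:8]), 80)
  expect_equal(unname(expected_counts(th, 0, 0)), rep(0, 8))
})

test_that("frequency tables validate, print totals, and round-trip via CSV", {
  expect_error(cp_freq_table(c(-1, rep(1, 7))), "non-negative")
  expect_error(cp_freq_table(c(0.5, rep(1, 7))), "integers")
  tab <- dyadic_table()
  expect_equal(tab$n_defect_tree, 160)
  expect_equal(tab$n_coop_tree, 160)
  path <- withr::local_tempfile(fileext = ".csv")
  write_freq_table(tab, path)
  expect_equal(read_freq_table(path), tab)
})
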