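test_that("fitting a table of exact expected counts recovers the generating parameters with G^2 = 0", {
  th <- theta_dyadic()
  tab <- dyadic_table(160)
  fit <- fit_cp(cp_model_spec("g"), list(g = tab))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["g", ]), unname(unclass(th)),
               tolerance = 1e-6)
  expect_lt(abs(fit$g_squared), 1e-8)

  # two groups with different generating values, fitted jointly
  th2 <- cp_theta(0.75, 0.5, 0.5, 0.5, 0.5)
  tab2 <- cp_freq_table(expected_counts(th2, 320, 160))
  fit2 <- fit_cp(cp_model_spec(c("a", "b")), list(a = tab, b = tab2))
  expect_equal(unname(fit2$estimates["b", ]), unname(unclass(th2)),
               tolerance = 1e-6)
  expect_lt(abs(fit2$g_squared), 1e-8)
  expect_equal(fit2$df, 2L)
  expect_equal(fit2$n_total, 160 + 160 + 320 + 160)
})

test_that("degrees of freedom follow the structural count 6G - n_free", {
  set.seed(21)
  tabs <- list(a = random_table(random_theta(0.2, 0.8)),
               b = random_table(random_theta(0.2, 0.8)),
               c = random_table(random_theta(0.2, 0.8)))
  fit2 <- fit_cp(cp_model_spec(c("a", "b")), tabs[1:2])
  expect_equal(fit2$df, 2L)
  fit3 <- fit_cp(cp_model_spec(c("a", "b", "c")), tabs)
  expect_equal(fit3$df, 3L)
  # equating one parameter across the three groups frees 2 df
  con <- list(list(parameter = "b", groups = c("a", "b", "c")))
  fitc <- fit_cp(cp_model_spec(c("a", "b", "c"), constraints = con), tabs)
  expect_equal(fitc$df, 5L)
  expect_equal(fitc$n_free, 13L)
})

test_that("the optimizer beats a brute-force grid on a small table", {
  set.seed(5)
  tab <- random_table(random_theta(0.2, 0.8), n_defect = 10, n_coop = 10)
  fit <- fit_cp(cp_model_spec("g"), list(g = tab))
  expect_gte(fit$log_likelihood + 1e-8, grid_best_loglik(tab, step = 0.1))
})

test_that("fits are bit-identical under identical options and empty trees are rejected", {
  set.seed(9)
  tabs <- list(g = random_table(random_theta(0.2, 0.8)))
  f1 <- fit_cp(cp_model_spec("g"), tabs, cp_fit_options(seed = 7))
  f2 <- fit_cp(cp_model_spec("g"), tabs, cp_fit_options(seed = 7))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_identical(f1$se, f2$se)

  empty_coop <- cp_freq_table(c(5, 5, 5, 5, 0, 0, 0, 0))
  expect_error(fit_cp(cp_model_spec("g"), list(g = empty_coop)),
               "empty tree")
})

test_that("equating a parameter between identical groups costs nothing; constraints never decrease G^2", {
  tab <- dyadic_table(160)
  spec <- cp_model_spec(c("a", "b"))
  tabs <- list(a = tab, b = tab)
  for (par in c("C", "P_moral", "b")) {
    tt <- cp_nested_test(spec, tabs, par)
    expect_lt(tt$delta_g_squared, 1e-6)
    expect_equal(tt$p_value, 1, tolerance = 1e-6)
  }
  # nesting monotonicity on unequal random tables
  set.seed(31)
  for (i in 1:5) {
    tabs2 <- list(a = random_table(random_theta(0.2, 0.8)),
                  b = random_table(random_theta(0.2, 0.8)))
    base <- fit_cp(spec, tabs2)
    for (par in c("C", "P_moral", "P_hypocritical", "P_antisocial", "b")) {
      con <- cp_model_spec(c("a", "b"),
                           list(list(parameter = par, groups = c("a", "b"))))
      restricted <- fit_cp(con, tabs2)
      expect_gte(restricted$g_squared - base$g_squared, -1e-6)
    }
  }
})

test_that("nested tests report the structural df and reject implied constraints", {
  set.seed(77)
  tabs <- list(a = random_table(random_theta(0.2, 0.8)),
               b = random_table(random_theta(0.2, 0.8)),
               c = random_table(random_theta(0.2, 0.8)))
  spec3 <- cp_model_spec(c("a", "b", "c"))
  omnibus <- cp_nested_test(spec3, tabs, "P_antisocial")
  expect_equal(omnibus$df, 2L)
  pair <- cp_nested_test(spec3, tabs, "C", groups = c("a", "b"))
  expect_equal(pair$df, 1L)
  expect_equal(pair$n_total, omnibus$n_total)

  spec_con <- cp_model_spec(c("a", "b"),
                            list(list(parameter = "C",
                                      groups = c("a", "b"))))
  expect_error(cp_nested_test(spec_con, tabs[1:2], "C"), "implied")
})

test_that("effect size w reproduces every value reported for the two experiments", {
  expect_equal(round_half_up(effect_size_w(5.11, 4060), 2), 0.04)
  expect_equal(effect_size_w(5.11, 4060), sqrt(5.11 / 4060))
  expect_equal(effect_size_w(0, 12345), 0)
  expect_error(effect_size_w(1, 0), "positive")
  expect_error(effect_size_w(-1, 10), "non-negative")

  # two-group experiment: n = 203 participants x 20 decisions
  exp1 <- list(dg2 = c(0.37, 5.11, 0.51, 0.02, 3.64),
               w = c("0.01", "0.04", "0.01", "<0.01", "0.03"))
  # three-group experiment: n = 1681 participants x 20 decisions
  exp2 <- list(dg2 = c(25.73, 4.37, 8.52, 7.19, 4.32, 0.32, 14.01, 7.55,
                       1.00, 1.22, 1.60, 6.23, 13.81),
               w = c("0.03", "0.01", "0.02", "0.01", "0.01", "<0.01",
                     "0.02", "0.01", "0.01", "0.01", "0.01", "0.01",
                     "0.02"))
  render <- function(dg2, n) {
    w <- effect_size_w(dg2, n)
    r <- round_half_up(w, 2)
    if (r < 0.01 && w > 0) "<0.01" else sprintf("%.2f", r)
  }
  expect_equal(vapply(exp1$dg2, render, "", n = 203 * 20), exp1$w)
  expect_equal(vapply(exp2$dg2, render, "", n = 1681 * 20), exp2$w)
})

test_that("standard error of C matches the closed-form binomial expression", {
  # C is information-orthogonal to the punishment parameters, so its SE
  # equals sqrt(C(1-C)/n) with n the total number of decisions
  th <- cp_theta(0.55, 0.45, 0.25, 0.15, 0.2)
  tabs <- list(g = dyadic_table(160))
  se <- cp_standard_errors(cp_model_spec("g"), tabs, th)
  expect_lt(abs(se["g", "C"] - sqrt(0.55 * 0.45 / 320)), 1e-8)

  set.seed(12)
  fit <- fit_cp(cp_model_spec("g"),
                list(g = random_table(random_theta(0.3, 0.7), 400, 400)))
  C_hat <- fit$estimates["g", "C"]
  expect_lt(abs(fit$se["g", "C"] - sqrt(C_hat * (1 - C_hat) / 800)), 1e-8)
})

test_that("doubling all counts shrinks every standard error by sqrt(2)", {
  th <- cp_theta(0.55, 0.45, 0.25, 0.15, 0.2)
  tab1 <- dyadic_table(160)
  tab2 <- cp_freq_table(tab1$counts * 2)
  se1 <- cp_standard_errors(cp_model_spec("g"), list(g = tab1), th)
  se2 <- cp_standard_errors(cp_model_spec("g"), list(g = tab2), th)
  expect_equal(unname(se1["g", ] / se2["g", ]), rep(sqrt(2), 5),
               tolerance = 1e-6)
})

test_that("analytic expected information agrees with a numeric Hessian of the log-likelihood", {
  skip_if_not_installed("pracma")
  th0 <- theta_dyadic()
  tab <- dyadic_table(160)
  # at counts equal to expected counts the observed information equals the
  # expected information, so the numeric Hessian is an independent oracle
  H <- pracma::hessian(function(th) cp_loglik(th, tab), unclass(th0))
  se_numeric <- sqrt(diag(solve(-H)))
  se_analytic <- cp_standard_errors(cp_model_spec("g"), list(g = tab), th0)
  expect_equal(unname(se_analytic["g", ]), se_numeric, tolerance = 1e-4)
})

test_that("boundary estimates get undefined standard errors", {
  th <- cp_theta(0.5, 0.4, 0.2, 0, 0.1)
  tabs <- list(g = dyadic_table(160))
  se <- cp_standard_errors(cp_model_spec("g"), tabs, th)
  expect_true(is.na(se["g", "P_antisocial"]))
  expect_true(all(!is.na(se["g", c("C", "P_moral", "b")])))
})
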