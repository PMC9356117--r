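test_that("scenario table maps names to heterogeneity variances", {
  expected <- list("No" = c(0, 0), "RI+Low" = c(0.01, 0),
                   "RI+Moderate" = c(0.09, 0), "RI+High" = c(0.16, 0),
                   "RIS+Low" = c(0.01, 0.01), "RIS+Moderate" = c(0.09, 0.09),
                   "RIS+High" = c(0.16, 0.16))
  for (nm in names(expected)) {
    sc <- scenario_spec(nm)
    expect_equal(c(sc$sigma_d0_sq, sc$sigma_d1_sq), expected[[nm]])
  }
  expect_error(scenario_spec("Bogus"))
  sc <- scenario_spec("No", effect = 0.36)
  expect_equal(sc$beta2, 0.36)
  expect_equal(sc$times, seq(0, 1, by = 0.2))
  expect_equal(sc$n_per_arm, 100L)
})

test_that("simulated trials have the design dimensions", {
  trial <- simulate_trial(scenario_spec("No"), seed = 1)
  expect_equal(nrow(trial$current), 200L * 6L)
  expect_equal(length(unique(trial$current$subject)), 200L)
  expect_equal(nrow(trial$historical), 100L * 6L)
  expect_true(all(trial$historical$arm == "control"))
  expect_equal(sum(trial$current$arm == "treatment"), 100L * 6L)
  expect_equal(sort(unique(trial$current$time)), seq(0, 1, by = 0.2))
  # seeded determinism
  t2 <- simulate_trial(scenario_spec("No"), seed = 1)
  expect_identical(as.data.frame(trial$current), as.data.frame(t2$current))
})

test_that("baseline outcome variance matches its moment decomposition", {
  # across many independently simulated studies the variance of y at t = 0
  # is sigma_b0^2 + sigma_d0^2 + sigma_eps^2
  sc <- scenario_spec("RI+High", n_per_arm = 100)
  y0 <- unlist(lapply(1:20, function(r) {
    h <- simulate_trial(sc, seed = 500 + r)$historical
    h$y[h$time == 0]
  }))
  expected <- 0.25 + 0.16 + 1
  n <- length(y0)
  se_var <- expected * sqrt(2 / (n - 1))  # SE of a variance estimate
  expect_equal(length(y0), 2000L)
  expect_lt(abs(var(y0) - expected), 3 * se_var)
  # treatment enters only through beta2 * trt * time: at t = 0 the arms agree
  cur <- simulate_trial(scenario_spec("No", effect = 5), seed = 3)$current
  m_trt <- mean(cur$y[cur$time == 0 & cur$arm == "treatment"])
  m_ctl <- mean(cur$y[cur$time == 0 & cur$arm == "control"])
  expect_lt(abs(m_trt - m_ctl), 0.5)
  m1_trt <- mean(cur$y[cur$time == 1 & cur$arm == "treatment"])
  expect_gt(m1_trt - mean(cur$y[cur$time == 1 & cur$arm == "control"]), 3)
})

test_that("run_scenario produces a paired replicate table with MC-SEs", {
  sc <- scenario_spec("No", n_per_arm = 15)
  cfg <- quick_cfg(iterations = 400, burn_in = 200)
  oc <- run_scenario(c("none", "pool"), sc, R = 4, base_seed = 900,
                     config = cfg)
  expect_s3_class(oc, "oc_result")
  tab <- oc$table
  expect_equal(nrow(tab), 8L)
  # paired design: both methods see the same replicate seeds
  expect_identical(tab$seed[tab$method == "none"],
                   tab$seed[tab$method == "pool"])
  s <- oc$summary
  expect_true(all(s$rejection_rate >= 0 & s$rejection_rate <= 1))
  expect_equal(s$rejection_mcse,
               sqrt(s$rejection_rate * (1 - s$rejection_rate) / s$R))
  expect_error(run_scenario("none", sc, R = 1, base_seed = 1, config = cfg),
               "R >= 2")
})

test_that("calibrated power equals its closed-form oracle on synthetic tails", {
  set.seed(11)
  R <- 10000
  null_tab <- data.frame(method = "m", tail_prob = runif(R))
  alt_tab <- data.frame(method = "m", tail_prob = rbeta(R, 1, 9))
  cp <- calibrated_power(null_tab, alt_tab, target = 0.05)
  oracle <- 1 - (1 - 0.05)^9  # Pr(Beta(1, 9) < 0.05)
  # MC noise: SE of the null 5% quantile times the Beta(1,9) density there
  mc_se <- sqrt(0.05 * 0.95 / R) * 9 * 0.95^8
  expect_lt(abs(cp$calibrated_power - oracle), 3 * mc_se + sqrt(oracle * (1 - oracle) / R))
  # a method already calibrated at the target keeps its raw power
  raw <- mean(alt_tab$tail_prob < 0.05)
  expect_lt(abs(cp$calibrated_power - raw), 3 * mc_se)
  # degenerate separation
  cp2 <- calibrated_power(null_tab,
                          data.frame(method = "m", tail_prob = rep(0, 10)))
  expect_equal(cp2$calibrated_power, 1)
  expect_error(calibrated_power(null_tab[1:10, , drop = FALSE], alt_tab),
               "too few")
})

test_that("McNemar test matches exact and chi-square oracles", {
  expect_equal(mcnemar_paired(c(TRUE, FALSE), c(TRUE, FALSE))$p_value, 1)
  # discordant (12, 3): exact doubled binomial tail
  a <- c(rep(TRUE, 12), rep(FALSE, 3), rep(TRUE, 10))
  b <- c(rep(FALSE, 12), rep(TRUE, 3), rep(TRUE, 10))
  res <- mcnemar_paired(a, b)
  expect_equal(res$test, "exact")
  expect_equal(res$p_value, min(1, 2 * pbinom(3, 15, 0.5)), tolerance = 1e-12)
  # discordant (30, 10): continuity-corrected chi-square
  a2 <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 5))
  b2 <- c(rep(FALSE, 30), rep(TRUE, 10), rep(TRUE, 5))
  res2 <- mcnemar_paired(a2, b2)
  expect_equal(res2$test, "chisq")
  expect_equal(res2$statistic, (abs(30 - 10) - 1)^2 / 40, tolerance = 1e-12)
  expect_equal(res2$statistic, 9.025)
  # cross-check the chi-square branch against the standard implementation
  ref <- stats::mcnemar.test(table(factor(a2, c(FALSE, TRUE)),
                                   factor(b2, c(FALSE, TRUE))),
                             correct = TRUE)
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_value, ref$p.value)
})

test_that("alpha summaries reduce to order statistics", {
  tab <- data.frame(method = "mmpp", alpha_mean = rep(0.5, 6),
                    alpha_mode = rep(0.5, 6))
  s <- summarize_alpha(tab)
  expect_equal(s$median, 0.5)
  expect_equal(unname(diff(s$iqr)), 0)
  expect_false(s$boundary_mode)
  tab2 <- data.frame(method = "mmpp", alpha_mean = seq(0.1, 1, by = 0.1),
                     alpha_mode = rep(1, 10))
  s2 <- summarize_alpha(tab2)
  expect_equal(s2$median, 0.55)
  expect_true(s2$boundary_mode)
  expect_error(summarize_alpha(data.frame(method = "x",
                                          alpha_mean = NA_real_,
                                          alpha_mode = NA_real_)),
               "no power-parameter")
})
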