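test_that("no-borrowing posterior agrees with a frequentist REML oracle", {
  trial <- small_trial(seed = 3, n_per_arm = 60)
  cfg <- quick_cfg(seed = 10)
  fit <- fit_no_borrowing(trial$current, cfg)

  d <- as.data.frame(trial$current)
  d$trt_time <- as.numeric(d$arm == "treatment") * d$time
  reml <- lme4::lmer(y ~ time + trt_time + (1 + time | subject), data = d,
                     REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular =
                                                   "ignore"))
  reml_bT <- unname(lme4::fixef(reml)["trt_time"])
  post <- test_treatment_effect(fit)
  expect_lt(abs(post$mean - reml_bT), 3 * post$sd)
  expect_lt(abs(mean(fit$draws$time) - unname(lme4::fixef(reml)["time"])),
            3 * sd(fit$draws$time))
})

test_that("fits are deterministic given the seed", {
  trial <- small_trial(seed = 5, n_per_arm = 20)
  cfg <- quick_cfg(seed = 77, iterations = 300, burn_in = 150)
  f1 <- fit_pooling(trial$current, trial$historical, cfg)
  f2 <- fit_pooling(trial$current, trial$historical, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_pooling(trial$current, trial$historical,
                    quick_cfg(seed = 78, iterations = 300, burn_in = 150))
  expect_false(identical(f1$draws$trt_time, f3$draws$trt_time))
})

test_that("convergence diagnostics meet the contract at default-style settings", {
  trial <- small_trial(seed = 8, n_per_arm = 50)
  cfg <- quick_cfg(seed = 4, chains = 4, iterations = 1500, burn_in = 500)
  fit <- fit_marginal_mpp(trial$current, trial$historical, cfg)
  expect_true(all(fit$diagnostics$rhat < 1.05, na.rm = TRUE))
  key <- fit$diagnostics$parameter %in%
    c("intercept", "time", "trt_time", "sigma", "alpha")
  expect_true(all(fit$diagnostics$ess[key] >= 400))
})

test_that("degenerate inputs are rejected or degrade gracefully", {
  trial <- small_trial(seed = 2, n_per_arm = 10)
  single_arm <- trial$current[trial$current$arm == "control", ]
  expect_error(fit_no_borrowing(longitudinal_data(single_arm), quick_cfg()),
               "both arms")
  expect_error(fit_marginal_mpp(trial$current, NULL, quick_cfg()),
               "historical")
  cfg <- quick_cfg(iterations = 300, burn_in = 150)
  expect_warning(f <- fit_pooling(trial$current, NULL, cfg), "no borrowing")
  f0 <- fit_no_borrowing(trial$current, cfg)
  expect_identical(f$draws, f0$draws)
})

test_that("pooling gains information on the shared time effect", {
  # homogeneous data: pooled posterior SD of the time effect should not
  # exceed the no-borrowing posterior SD, on average over replicates
  sds <- vapply(1:20, function(r) {
    trial <- small_trial(seed = 100 + r, n_per_arm = 15)
    cfg <- quick_cfg(seed = r, iterations = 400, burn_in = 200)
    f0 <- fit_no_borrowing(trial$current, cfg)
    f1 <- fit_pooling(trial$current, trial$historical, cfg)
    c(sd(f0$draws$time), sd(f1$draws$time))
  }, numeric(2))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
  expect_gt(mean(sds[1, ] - sds[2, ]), 0.9 * 0)  # strict gain on average
})

test_that("the credible-interval test implements the decision rule", {
  mk <- function(x) {
    structure(list(draws = list(trt_time = matrix(x, ncol = 1)),
                   method = "none"), class = "borrow_fit")
  }
  t1 <- suppressWarnings(test_treatment_effect(mk(rep(0.5, 100))))
  expect_true(t1$significant)
  expect_equal(t1$ci, c(0.5, 0.5))
  t2 <- suppressWarnings(test_treatment_effect(mk(rep(c(-1, 1), 50))))
  expect_false(t2$significant)
  set.seed(1)
  t3 <- suppressWarnings(test_treatment_effect(mk(rnorm(4000, 0.36, 0.05))))
  expect_true(t3$significant)
  expect_lt(t3$tail_prob, 0.001)
  # warning when effective draws are scarce
  expect_warning(test_treatment_effect(mk(cumsum(rnorm(500)) + 50)),
                 "effective")
})

test_that("commensurate-prior limits bracket pooling and no borrowing", {
  trial <- small_trial(seed = 7, n_per_arm = 40)
  cfg <- function(fx = list(), seed = 5) {
    borrow_config(prior = prior_spec(fixed = fx), chains = 2,
                  iterations = 1000, burn_in = 500, seed = seed)
  }
  f_none <- fit_no_borrowing(trial$current, cfg())
  f_pool <- fit_pooling(trial$current, trial$historical, cfg())
  f_weak <- fit_commensurate(trial$current, trial$historical,
                             cfg(list(comm_sd = 20)))
  f_strong <- fit_commensurate(trial$current, trial$historical,
                               cfg(list(comm_sd = 0.001)))
  # weak link: treatment effect approximates no borrowing
  expect_lt(abs(mean(f_weak$draws$trt_time) - mean(f_none$draws$trt_time)),
            3 * combined_mcse(f_weak, f_none))
  # strong link: shared time effect approaches the pooled analysis, and its
  # posterior SD shrinks monotonically with the link SD
  expect_lt(abs(mean(f_strong$draws$time) - mean(f_pool$draws$time)),
            3 * combined_mcse(f_strong, f_pool, par = "time"))
  expect_lt(sd(f_strong$draws$time), sd(f_weak$draws$time))
})

test_that("commensurate prior recovers the treatment effect on homogeneous data", {
  trial <- simulate_trial(scenario_spec("No", effect = 0.36), seed = 12)
  fit <- fit_commensurate(trial$current, trial$historical, quick_cfg(seed = 6))
  tt <- test_treatment_effect(fit)
  expect_lt(abs(tt$mean - 0.36), 3 * tt$sd)
})

test_that("dynamic discounting: the power drops as historical data drift", {
  trial <- small_trial(seed = 9, n_per_arm = 50)
  alpha_means <- vapply(c(0, 0.3, 0.6), function(shift) {
    h <- trial$historical
    h$y <- h$y + shift * h$time  # shift the historical time effect
    fit <- fit_marginal_mpp(trial$current, longitudinal_data(h),
                            quick_cfg(seed = 31))
    mean(fit$draws$alpha)
  }, numeric(1))
  expect_true(all(diff(alpha_means) < 0))
})

test_that("bimodality detection flags two separated modes and not one", {
  set.seed(2)
  uni <- rbeta(4000, 8, 3)
  bi <- c(rbeta(2000, 60, 140), rbeta(2000, 140, 20))
  expect_false(lmmborrow:::detect_bimodality(uni))
  expect_true(lmmborrow:::detect_bimodality(bi))
})

test_that("alpha histogram mode handles interior and boundary cases", {
  set.seed(3)
  expect_equal(alpha_mode(rbeta(20000, 50, 50)), 0.5, tolerance = 0.03)
  expect_identical(alpha_mode(rbeta(5000, 40, 1)), 1)
  expect_identical(alpha_mode(rbeta(5000, 1, 40)), 0)
})

test_that("rhat and ess behave sensibly and match coda on iid draws", {
  set.seed(4)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(good), 1.01)
  expect_gt(ess_bulk(good), 3000)
  bad <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(rhat(bad), 1.5)
  ar <- matrix(0, 1000, 2)
  for (ch in 1:2) {
    for (i in 2:1000) ar[i, ch] <- 0.9 * ar[i - 1, ch] + rnorm(1)
  }
  ours <- ess_bulk(ar)
  codas <- coda::effectiveSize(coda::mcmc.list(coda::mcmc(ar[, 1]),
                                               coda::mcmc(ar[, 2])))
  expect_equal(ours, unname(codas), tolerance = 0.5)
  # AR(1) with phi = 0.9 has efficiency (1-phi)/(1+phi) ~ 5%
  expect_lt(ours, 0.25 * 2000)
})
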