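test_that("conditional log-likelihood matches the standard normal at its mean", {
  d <- manual_data("s1", "current", "control", time = 0, y = 0)
  des <- build_design(d, for_study = "current")
  p <- lmm_params(betaC = c(0, 0), betaT = 0, G = diag(0.3, 2), sigma2 = 1)
  ll <- conditional_loglik(p, list(c(0, 0)), des)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-9)
  expect_error(conditional_loglik(lmm_params(c(0, 0), 0, diag(2), 1e-9),
                                  list(c(0, 0)), des), NA)
})

test_that("conditional and marginal log-likelihoods are additive over subjects", {
  set.seed(2)
  d <- manual_data(subject = rep(c("a", "b"), each = 3), study = "current",
                   arm = rep(c("treatment", "control"), each = 3),
                   time = rep(c(0, 0.5, 1), 2), y = rnorm(6, 2))
  des <- build_design(d, for_study = "current")
  p <- lmm_params(betaC = c(2, 1), betaT = 0.4,
                  G = matrix(c(0.3, 0.1, 0.1, 0.2), 2), sigma2 = 1.3)
  b <- list(c(0.2, -0.1), c(-0.3, 0.4))
  ll_ab <- conditional_loglik(p, b, des)
  ll_a <- conditional_loglik(p, b[1], des[1])
  ll_b <- conditional_loglik(p, b[2], des[2])
  expect_equal(ll_ab, ll_a + ll_b, tolerance = 1e-12)
  expect_equal(marginal_loglik(p, des),
               marginal_loglik(p, des[1]) + marginal_loglik(p, des[2]),
               tolerance = 1e-12)
})

test_that("marginal likelihood equals MC average of the conditional (toy, 1e6 draws)", {
  set.seed(5)
  d <- manual_data(subject = rep("a", 3), study = "current", arm = "control",
                   time = c(0, 0.5, 1), y = c(2.2, 2.6, 3.4))
  des <- build_design(d, for_study = "current")
  G <- matrix(c(0.3, 0.05, 0.05, 0.2), 2)
  p <- lmm_params(betaC = c(2, 1), betaT = 0, G = G, sigma2 = 0.8)
  n_mc <- 1e6
  B <- matrix(rnorm(2 * n_mc), n_mc, 2) %*% chol(G)
  s <- des[[1]]
  mu0 <- drop(s$X %*% c(2, 1, 0))
  E <- matrix(s$y - mu0, n_mc, 3, byrow = TRUE) - B %*% t(s$Z)
  ll_cond <- -3 / 2 * log(2 * pi * 0.8) - rowSums(E^2) / (2 * 0.8)
  mx <- max(ll_cond)
  log_mc <- mx + log(mean(exp(ll_cond - mx)))
  expect_equal(exp(log_mc) / exp(marginal_loglik(p, des)), 1,
               tolerance = 0.01)
})

test_that("marginal likelihood matches a dense bivariate-normal oracle", {
  d <- manual_data(subject = rep("a", 2), study = "current",
                   arm = "treatment", time = c(0.2, 0.8), y = c(2.1, 3.3))
  des <- build_design(d, for_study = "current")
  G <- matrix(c(0.25, 0.08, 0.08, 0.3), 2)
  p <- lmm_params(betaC = c(2, 1), betaT = 0.36, G = G, sigma2 = 1.1)
  s <- des[[1]]
  V <- s$Z %*% G %*% t(s$Z) + diag(1.1, 2)
  mu <- drop(s$X %*% c(2, 1, 0.36))
  r <- s$y - mu
  ll_direct <- -log(2 * pi) - 0.5 * log(det(V)) -
    0.5 * drop(t(r) %*% solve(V) %*% r)
  expect_equal(marginal_loglik(p, des), ll_direct, tolerance = 1e-10)
  # G = 0 reduces to the conditional likelihood with b = 0
  p0 <- lmm_params(betaC = c(2, 1), betaT = 0.36, G = matrix(0, 2, 2),
                   sigma2 = 1.1)
  expect_equal(marginal_loglik(p0, des),
               conditional_loglik(p0, list(c(0, 0)), des), tolerance = 1e-12)
})

test_that("tempered marginal likelihood is linear in the power", {
  des <- build_design(toy_historical(), for_study = "historical")
  p <- lmm_params(betaC = c(2, 1), G = diag(0.25, 2), sigma2 = 1)
  full <- marginal_loglik(p, des)
  expect_identical(tempered_marginal_loglik(p, 0, des), 0)
  expect_equal(tempered_marginal_loglik(p, 1, des), full)
  expect_equal(tempered_marginal_loglik(p, 0.5, des), full / 2)
  expect_error(tempered_marginal_loglik(p, 1.2, des), "alpha")
})

test_that("tempered conditional-integrated kernel matches 1-D quadrature", {
  # q = 1 (random intercept only) so the integral over b is one-dimensional
  d <- manual_data(subject = rep("h1", 2), study = "historical",
                   arm = "control", time = c(0, 1), y = c(2.4, 3.1))
  des <- build_design(d, for_study = "historical", z_cols = "intercept")
  tau2 <- 0.3
  p <- lmm_params(betaC = c(2, 1), G = matrix(tau2, 1, 1), sigma2 = 0.9)
  s <- des[[1]]
  mu <- drop(s$X %*% c(2, 1))
  for (alpha in c(0.25, 0.5, 0.9)) {
    integrand <- function(b) {
      vapply(b, function(bb) {
        ll <- sum(dnorm(s$y, mu + bb, sqrt(0.9), log = TRUE))
        exp(alpha * ll) * dnorm(bb, 0, sqrt(tau2))
      }, numeric(1))
    }
    oracle <- log(stats::integrate(integrand, -10, 10,
                                   rel.tol = 1e-12)$value)
    expect_equal(tempered_conditional_loglik(p, alpha, des), oracle,
                 tolerance = 1e-6)
  }
  # alpha = 1: no tempering, equals the marginal likelihood
  expect_equal(tempered_conditional_loglik(p, 1, des),
               marginal_loglik(p, des), tolerance = 1e-12)
  # alpha -> 0+: tempered likelihood tends to 1, integral of the RE density is 1
  expect_lt(abs(tempered_conditional_loglik(p, 1e-6, des)), 1e-3)
  expect_identical(tempered_conditional_loglik(p, 0, des), 0)
  expect_error(tempered_conditional_loglik(p, 0, des, zero_ok = FALSE),
               "positive")
})

test_that("the analytic alpha-derivative matches finite differences", {
  des <- build_design(toy_historical(), for_study = "historical")
  p <- lmm_params(betaC = c(2.1, 0.8), G = diag(c(0.3, 0.2)), sigma2 = 1.2)
  h <- 1e-5
  for (alpha in c(0.05, 0.3, 0.7, 0.95)) {
    fd <- (tempered_conditional_loglik(p, alpha + h, des) -
             tempered_conditional_loglik(p, alpha - h, des)) / (2 * h)
    expect_equal(dtempered_conditional_dalpha(p, alpha, des), fd,
                 tolerance = 1e-5)
  }
  # limit at 0 equals the prior expectation of the conditional log-likelihood
  fd0 <- tempered_conditional_loglik(p, h, des) / h
  expect_equal(dtempered_conditional_dalpha(p, 0, des), fd0,
               tolerance = 1e-3)
})

test_that("the C++ kernels agree with the reference R implementation", {
  hist <- toy_historical(n = 4, m = 3)
  des <- build_design(hist, for_study = "historical")
  grp <- lmmborrow:::make_groups(des)
  G <- matrix(c(0.3, -0.05, -0.05, 0.25), 2)
  p <- lmm_params(betaC = c(1.9, 1.1), G = G, sigma2 = 0.85)
  expect_equal(lmmborrow:::cpp_marginal_loglik(grp, c(1.9, 1.1), G, 0.85),
               marginal_loglik(p, des), tolerance = 1e-10)
  for (alpha in c(0, 0.4, 1)) {
    expect_equal(lmmborrow:::cpp_cond_integrand(grp, c(1.9, 1.1), G, 0.85,
                                                alpha),
                 dtempered_conditional_dalpha(p, alpha, des),
                 tolerance = 1e-9)
  }
})
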