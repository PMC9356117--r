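#' Linear mixed model parameters
#'
#' Container for the cLDA model parameters: `betaC` holds the fixed effects
#' shared between arms (intercept, covariates, time), `betaT` the
#' treatment-by-time interaction, `G` the random-effects covariance (q x q,
#' symmetric positive semi-definite) and `sigma2` the residual variance.
#'
#' @param betaC numeric vector of shared fixed effects.
#' @param betaT scalar treatment-by-time coefficient (0 for historical-only
#'   models).
#' @param G random-effects covariance matrix.
#' @param sigma2 residual variance (> 0).
#' @return an object of class `lmm_params`.
#' @export
lmm_params <- function(betaC, betaT = 0, G, sigma2) {
  G <- as.matrix(G)
  if (!isSymmetric(unname(G), tol = 1e-10)) stop("G must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("G must be positive semi-definite")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("sigma2 must be a positive scalar")
  }
  structure(list(betaC = as.numeric(betaC), betaT = as.numeric(betaT),
                 G = G, sigma2 = sigma2),
            class = "lmm_params")
}

# Full fixed-effect vector in the column order of a design (historical
# designs have no interaction column, so betaT is dropped).
full_beta <- function(params, design_subject) {
  p <- ncol(design_subject$X)
  has_trt <- "trt_time" %in% colnames(design_subject$X)
  if (has_trt) {
    if (length(params$betaC) != p - 1L) {
      stop("betaC length must equal design columns minus the interaction")
    }
    c(params$betaC, params$betaT)
  } else {
    if (length(params$betaC) != p) stop("betaC length must match design")
    params$betaC
  }
}

#' Conditional log-likelihood of the LMM given the random effects
#'
#' Sum over subjects of the Gaussian log-density of `y_i` given mean
#' `X_i beta + Z_i b_i` and covariance `sigma^2 I`.
#'
#' @param params an [lmm_params()] object.
#' @param b list with one q-vector of random effects per subject (in the
#'   order of `design`).
#' @param design a `design_matrices` object from [build_design()].
#' @return scalar log-likelihood.
#' @export
conditional_loglik <- function(params, b, design) {
  if (params$sigma2 <= 0) stop("sigma2 must be positive")
  if (length(b) != length(design)) stop("need one random-effect vector per subject")
  ll <- 0
  for (i in seq_along(design)) {
    s <- design[[i]]
    mu <- drop(s$X %*% full_beta(params, s) + s$Z %*% b[[i]])
    ll <- ll + sum(stats::dnorm(s$y, mu, sqrt(params$sigma2), log = TRUE))
  }
  ll
}

# log N(y; mu, V) via Cholesky of the dense m x m covariance.
dmvnorm_chol <- function(y, mu, V) {
  L <- tryCatch(chol(V), error = function(e)
    stop("implied marginal covariance is not positive definite"))
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi)) - sum(log(diag(L))) - 0.5 * sum(r^2)
}

#' Marginal log-likelihood of the LMM (random effects integrated out)
#'
#' Sum over subjects of `log N(y_i; X_i beta, Z_i G Z_i' + sigma^2 I)`.
#'
#' @inheritParams conditional_loglik
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(params, design) {
  if (params$sigma2 <= 0) stop("sigma2 must be positive")
  ll <- 0
  for (s in design) {
    mu <- drop(s$X %*% full_beta(params, s))
    V <- s$Z %*% params$G %*% t(s$Z) + diag(params$sigma2, length(s$y))
    ll <- ll + dmvnorm_chol(s$y, mu, V)
  }
  ll
}

#' Tempered marginal historical log-likelihood
#'
#' The marginal-MPP historical term: `alpha` times the marginal
#' log-likelihood of the historical data.
#'
#' @inheritParams conditional_loglik
#' @param alpha power parameter in \[0, 1\].
#' @return scalar.
#' @export
tempered_marginal_loglik <- function(params, alpha, design) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) return(0)
  alpha * marginal_loglik(params, design)
}

#' Tempered conditional historical log-likelihood, random effects integrated
#'
#' The conditional-MPP historical term: for each historical subject,
#' `log \int N(y; X betaC + Z b, sigma^2 I)^alpha N(b; 0, G) db`.
#' Raising the conditional Gaussian to `alpha` rescales the residual
#' variance to `sigma^2/alpha` up to the constant
#' `((1-alpha) m / 2) log(2 pi sigma^2) - (m/2) log alpha`, so the integral
#' is available in closed form:
#' `((1-alpha)m/2) log(2 pi sigma^2) - (m/2) log alpha +
#'  log N(y; X betaC, Z G Z' + (sigma^2/alpha) I)`.
#' The limit as `alpha -> 0+` is 0 (the tempered likelihood tends to 1 and
#' the random-effect density integrates to 1), which is the value returned
#' at `alpha = 0` when `zero_ok = TRUE`.
#'
#' @inheritParams tempered_marginal_loglik
#' @param zero_ok if `TRUE` (default), `alpha = 0` returns the analytic
#'   limit 0; otherwise it is a domain error.
#' @return scalar.
#' @export
tempered_conditional_loglik <- function(params, alpha, design,
                                        zero_ok = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) {
    if (zero_ok) return(0)
    stop("alpha must be positive")
  }
  s2 <- params$sigma2
  ll <- 0
  for (s in design) {
    m <- length(s$y)
    mu <- drop(s$X %*% full_beta(params, s))
    V <- s$Z %*% params$G %*% t(s$Z) + diag(s2 / alpha, m)
    ll <- ll + (1 - alpha) * m / 2 * log(2 * pi * s2) -
      m / 2 * log(alpha) + dmvnorm_chol(s$y, mu, V)
  }
  ll
}

#' Derivative in alpha of the tempered conditional integrated kernel
#'
#' The path-sampling integrand of the conditional MPP. Per subject, with
#' `V(alpha) = Z G Z' + (sigma^2/alpha) I` and residual `resid = y - X betaC`:
#' `-(m/2) log(2 pi sigma^2) - m/(2 alpha)
#'   + sigma^2/(2 alpha^2) (tr V^-1 - || V^-1 r ||^2)`.
#' At `alpha = 0` the analytic limit
#' `-(m/2) log(2 pi sigma^2) - (tr(Z G Z') + ||r||^2) / (2 sigma^2)`
#' (the prior expectation over the random effects of the conditional
#' log-likelihood) is used.
#'
#' @inheritParams tempered_marginal_loglik
#' @return scalar derivative.
#' @export
dtempered_conditional_dalpha <- function(params, alpha, design) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  s2 <- params$sigma2
  out <- 0
  for (s in design) {
    m <- length(s$y)
    r <- s$y - drop(s$X %*% full_beta(params, s))
    W <- s$Z %*% params$G %*% t(s$Z)
    if (alpha == 0) {
      out <- out - m / 2 * log(2 * pi * s2) -
        (sum(diag(W)) + sum(r^2)) / (2 * s2)
    } else {
      V <- W + diag(s2 / alpha, m)
      Vi <- chol2inv(chol(V))
      out <- out - m / 2 * log(2 * pi * s2) - m / (2 * alpha) +
        s2 / (2 * alpha^2) * (sum(diag(Vi)) - sum((Vi %*% r)^2))
    }
  }
  out
}
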