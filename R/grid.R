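#' Estimate the power-prior scaling constant on a grid by path sampling
#'
#' The modified power prior requires the scaling constant
#' `c(alpha) = integral L0(theta)^alpha p0(theta) dtheta` (with `L0` the
#' historical likelihood in either its marginal or conditional-integrated
#' form). Its log derivative is the expectation, over the alpha-tempered
#' historical posterior, of the alpha-derivative of the tempered log kernel
#' (thermodynamic integration): for the marginal MPP this is the historical
#' marginal log-likelihood itself; for the conditional MPP it is the
#' analytic derivative of the integrated tempered kernel. For each grid
#' node a short MCMC run on the tempered posterior estimates the integrand;
#' `log c(alpha)` is then the cumulative trapezoidal integral, anchored at
#' `log c(0) = 0`. The node at `alpha = 0` is sampled directly from the
#' prior; nodes warm-start from the previous node's final state.
#'
#' @param method `"marginal_mpp"` or `"conditional_mpp"`.
#' @param historical a `longitudinal_data` object holding the historical
#'   control arm.
#' @param config a [borrow_config()]; grid settings control the node grid
#'   and the per-node chains.
#' @param current optional `longitudinal_data` with the current study, used
#'   to form the g-prior for the shared coefficients (the prior uses the
#'   current-study design with g equal to the current observation count).
#'   If omitted, the historical design is used instead.
#' @param covariates covariate columns to include in the design.
#' @return an object of class `power_grid` with fields `alphas`,
#'   `mean_loglik` (per-node integrand estimates), `se` (naive per-node
#'   Monte Carlo SEs), `log_c`, `flagged` (per-node convergence flags) and
#'   metadata.
#' @export
estimate_power_grid <- function(method = c("marginal_mpp", "conditional_mpp"),
                                historical, config = borrow_config(),
                                current = NULL, covariates = character()) {
  method <- match.arg(method)
  stopifnot(inherits(config, "borrow_config"))
  hist_design <- build_design(historical, covariates, "historical")
  if (length(hist_design) == 0L) stop("historical dataset is empty")
  hist_groups <- make_groups(hist_design)
  q <- ncol(hist_design[[1]]$Z)
  p0 <- length(attr(hist_design, "x_cols"))
  prior <- config$prior

  if (!is.null(current)) {
    cur_design <- build_design(current, covariates, "current")
    gp <- gprior_setup(cur_design, NULL, prior)
  } else {
    # standalone use: unit-information prior from the historical design
    X0 <- do.call(rbind, lapply(hist_design, `[[`, "X"))
    g0 <- if (identical(prior$g, "auto")) nrow(X0) else prior$g
    gp <- list(g = g0, n_obs = nrow(X0),
               Q_CC = crossprod(X0) / g0, qT = 1)
  }
  S_CC_chol <- chol(solve(gp$Q_CC))  # upper chol of g * [(X'X)^-1]_CC

  gs <- config$grid
  alphas <- seq(0, 1, by = gs$step)
  n_keep <- gs$iterations_per_node - gs$node_burn_in
  mean_ll <- se_ll <- numeric(length(alphas))
  flagged <- logical(length(alphas))
  fx <- cpp_fixed(prior, q, p0)
  seeds <- derive_seeds(config$mcmc$seed + 777L, length(alphas))

  # node 0: direct prior draws (c(0) = 1 for proper priors)
  set.seed(seeds[1])
  draws0 <- replicate(gs$iterations_per_node, {
    sigma <- if (is.finite(fx$sigma)) fx$sigma else
      abs(stats::rnorm(1, 0, prior$err_sd_scale))
    tau <- ifelse(is.finite(fx$tau), fx$tau,
                  abs(stats::rnorm(q, 0, prior$re_sd_scale)))
    rho <- if (q == 2) {
      if (is.finite(fx$rho)) fx$rho else
        2 * stats::rbeta(1, prior$lkj_eta, prior$lkj_eta) - 1
    } else 0
    G <- diag(tau, q) %*% toeplitz(c(1, if (q == 2) rho)) %*% diag(tau, q)
    betaC <- drop(crossprod(S_CC_chol, stats::rnorm(p0)) * sigma)
    if (method == "marginal_mpp") {
      cpp_marginal_loglik(hist_groups, betaC, G, sigma^2)
    } else {
      cpp_cond_integrand(hist_groups, betaC, G, sigma^2, 0)
    }
  })
  mean_ll[1] <- mean(draws0)
  se_ll[1] <- stats::sd(draws0) / sqrt(length(draws0))

  method_code <- if (method == "marginal_mpp") 5L else 6L
  prior_list <- cpp_prior(prior, gp, beta_block = "betaC")
  grid_off <- list(use = FALSE, alphas = numeric(0), log_c = numeric(0),
                   log_scale = TRUE)
  ctrl <- list(iterations = gs$iterations_per_node,
               burn_in = gs$node_burn_in,
               n_sweeps = config$mcmc$sweeps %||% 5L,
               target_accept = rw_target(config$mcmc$target_accept),
               pbeta = p0, p0 = p0)
  warm <- NULL
  for (k in seq_along(alphas)[-1]) {
    set.seed(seeds[k])
    phiA <- if (is.null(warm)) init_phi(q, FALSE)$A else warm
    res <- cpp_run_chain(list(), hist_groups, method_code, q, prior_list,
                         fx, ctrl, grid_off, phiA, numeric(0), numeric(0),
                         alphas[k], FALSE)
    warm <- res$final_phiA
    x <- res$integrand
    mean_ll[k] <- mean(x)
    lag1 <- if (stats::sd(x) > 0) stats::cor(x[-1], x[-length(x)]) else 1
    neff <- length(x) * max(1 - lag1, 0.02) / (1 + lag1)
    se_ll[k] <- stats::sd(x) / sqrt(max(neff, 2))
    flagged[k] <- !all(is.finite(x)) || (stats::sd(x) == 0 && length(x) > 5)
    if (flagged[k]) {
      warning("path-sampling node alpha = ", alphas[k],
              " flagged as non-convergent; consider more iterations")
    }
  }

  log_c <- cumsum(c(0, 0.5 * (mean_ll[-1] + mean_ll[-length(mean_ll)]) *
                      diff(alphas)))
  structure(list(alphas = alphas, mean_loglik = mean_ll, se = se_ll,
                 log_c = log_c, flagged = flagged, method = method,
                 interpolation = gs$interpolation,
                 n_keep = n_keep, seed = config$mcmc$seed),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Power-prior scaling-constant grid (", x$method, ")\n", sep = "")
  cat("  nodes:", length(x$alphas), " step:", x$alphas[2] - x$alphas[1], "\n")
  cat("  log c(1) =", format(x$log_c[length(x$log_c)], digits = 6), "\n")
  if (any(x$flagged)) {
    cat("  flagged nodes:", sum(x$flagged), "\n")
  }
  invisible(x)
}

#' @export
plot.power_grid <- function(x, ...) {
  graphics::plot(x$alphas, x$log_c, type = "l", xlab = "power parameter",
                 ylab = "log c", ...)
  graphics::points(x$alphas, x$log_c, pch = 16, cex = 0.5)
  invisible(x)
}

#' Interpolate the log scaling constant at arbitrary powers
#'
#' Piecewise-linear interpolation between grid nodes, on the `log c` scale
#' by default or on the `c` scale (computed stably in logs) if the grid was
#' built with `interpolation = "c"`.
#'
#' @param grid a `power_grid` object.
#' @param alpha numeric vector of powers in \[0, 1\].
#' @return `log c(alpha)` values.
#' @export
interpolate_log_c <- function(grid, alpha) {
  stopifnot(inherits(grid, "power_grid"))
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]")
  vapply(alpha, function(a) {
    if (grid$interpolation == "log_c") {
      stats::approx(grid$alphas, grid$log_c, xout = a, rule = 1)$y
    } else {
      j <- findInterval(a, grid$alphas, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(grid$alphas) - 1L)
      w <- (a - grid$alphas[j]) / (grid$alphas[j + 1] - grid$alphas[j])
      lo <- grid$log_c[j]; hi <- grid$log_c[j + 1]
      mx <- max(lo, hi)
      mx + log((1 - w) * exp(lo - mx) + w * exp(hi - mx))
    }
  }, numeric(1))
}

#' Write / read a power grid as CSV
#'
#' Serialises the node table (alpha, mean_loglik, se, log_c, flagged) for
#' caching; metadata travel in a comment-style header column-free first row
#' is avoided by storing them as extra columns on the first row.
#'
#' @param grid a `power_grid` object.
#' @param path CSV path.
#' @return `path` (write) or a `power_grid` (read).
#' @export
write_power_grid <- function(grid, path) {
  df <- data.frame(alpha = grid$alphas, mean_loglik = grid$mean_loglik,
                   se = grid$se, log_c = grid$log_c,
                   flagged = as.integer(grid$flagged))
  attr_row <- data.frame(method = grid$method,
                         interpolation = grid$interpolation,
                         n_keep = grid$n_keep, seed = grid$seed)
  utils::write.csv(cbind(df, attr_row[rep(1, nrow(df)), ]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_power_grid
#' @export
read_power_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(alphas = df$alpha, mean_loglik = df$mean_loglik,
                 se = df$se, log_c = df$log_c,
                 flagged = as.logical(df$flagged),
                 method = df$method[1], interpolation = df$interpolation[1],
                 n_keep = df$n_keep[1], seed = df$seed[1]),
            class = "power_grid")
}

#' Cache key for a power grid
#'
#' MD5 digest of the historical records and prior specification, for keying
#' grid caches on disk.
#'
#' @param historical a `longitudinal_data` object.
#' @param prior a [prior_spec()].
#' @return character MD5 string.
#' @export
grid_cache_key <- function(historical, prior) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  obj <- list(records = as.data.frame(historical)[, c("subject", "study",
                                                      "arm", "time", "y")],
              prior = unclass(prior))
  saveRDS(obj, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
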