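# Chain orchestration around the C++ sampler, plus convergence diagnostics.

# Map the configured target acceptance rate to a random-walk-appropriate
# value: targets above 0.45 (natural for gradient-based samplers) are taken
# as "adapt carefully" and mapped to the random-walk optimum.
rw_target <- function(target_accept) {
  if (target_accept > 0.45) 0.35 else target_accept
}

# Deterministic per-stream seeds derived from a base seed.
derive_seeds <- function(base_seed, n) {
  (as.integer(base_seed) + 104729L * seq_len(n)) %% 2147483587L + 1L
}

# Stacked fixed-effect design of a study and derived g-prior quantities.
gprior_setup <- function(cur_design, hist_design, prior) {
  Xc <- do.call(rbind, lapply(cur_design, `[[`, "X"))
  n_obs <- nrow(Xc)
  g <- if (identical(prior$g, "auto")) n_obs else prior$g
  XtX <- crossprod(Xc)
  p <- ncol(XtX)
  S <- solve(XtX)
  out <- list(
    g = g, n_obs = n_obs,
    g_prec_full = XtX / g,                        # precision * sigma^2, full beta
    Q_CC = solve(S[-p, -p, drop = FALSE]) / g,    # marginal precision of betaC
    qT = 1 / (g * S[p, p])                        # marginal precision of betaT
  )
  if (!is.null(hist_design)) {
    X0 <- do.call(rbind, lapply(hist_design, `[[`, "X"))
    g0 <- if (identical(prior$g, "auto")) nrow(X0) else prior$g
    out$g_prec_hist <- crossprod(X0) / g0
    out$n_obs_hist <- nrow(X0)
  }
  out
}

# prior list handed to the C++ sampler
cpp_prior <- function(prior, gp, beta_block = c("full", "betaC", "commensurate")) {
  beta_block <- match.arg(beta_block)
  g_prec <- switch(beta_block,
                   full = gp$g_prec_full,
                   betaC = gp$Q_CC,
                   commensurate = matrix(0, 1, 1))
  list(g_prec = g_prec,
       g_prec_hist = gp$g_prec_hist %||% matrix(0, 1, 1),
       qT = gp$qT %||% 1,
       re_sd_scale = prior$re_sd_scale,
       err_sd_scale = prior$err_sd_scale,
       lkj_eta = prior$lkj_eta,
       alpha_a = prior$alpha_prior[1],
       alpha_b = prior$alpha_prior[2],
       comm_sd_scale = prior$commensurate_sd_scale)
}

cpp_fixed <- function(prior, q, p0 = 1L) {
  fx <- prior$fixed
  tau <- rep(NA_real_, q)
  if (!is.null(fx$tau)) {
    if (length(fx$tau) == 1L) tau[] <- fx$tau else tau <- fx$tau[seq_len(q)]
  }
  comm_sd <- rep(NA_real_, p0)
  if (!is.null(fx$comm_sd)) {
    if (length(fx$comm_sd) == 1L) comm_sd[] <- fx$comm_sd
    else comm_sd <- fx$comm_sd[seq_len(p0)]
  }
  list(tau = tau,
       rho = fx$rho %||% NA_real_,
       sigma = fx$sigma %||% NA_real_,
       comm_sd = comm_sd)
}

# random overdispersed initial values for the unconstrained blocks
init_phi <- function(q, alpha_free, p0 = 0L, commensurate = FALSE) {
  nA <- q + (q == 2L) + 1L + as.integer(alpha_free)
  phiA <- c(stats::rnorm(q, log(0.5), 0.3),
            if (q == 2L) stats::rnorm(1, 0, 0.3),
            stats::rnorm(1, 0, 0.3),
            if (alpha_free) stats::runif(1, -2.5, 2.5))
  stopifnot(length(phiA) == nA)
  phiB <- if (commensurate)
    c(stats::rnorm(q, log(0.5), 0.3),
      if (q == 2L) stats::rnorm(1, 0, 0.3),
      stats::rnorm(1, 0, 0.3)) else numeric(0)
  nz <- p0 * (p0 - 1) / 2
  phiC <- if (commensurate)
    c(stats::rnorm(p0, log(0.5), 0.3), stats::rnorm(nz, 0, 0.3)) else numeric(0)
  list(A = phiA, B = phiB, C = phiC)
}

# Run `chains` chains of the C++ sampler and assemble named draw matrices
# (kept iterations x chains per parameter).
run_chains <- function(cur_groups, hist_groups, method_code, q, prior_list,
                       fixed_list, mcmc, grid_info, pbeta, p0,
                       par_names, alpha_value, alpha_free,
                       commensurate = FALSE) {
  chains <- mcmc$chains
  seeds <- derive_seeds(mcmc$seed, chains)
  ctrl <- list(iterations = mcmc$iterations, burn_in = mcmc$burn_in,
               n_sweeps = mcmc$sweeps %||% 5L,
               target_accept = rw_target(mcmc$target_accept),
               pbeta = pbeta, p0 = p0)
  per_chain <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seeds[ch])
    ini <- init_phi(q, alpha_free, p0 = p0, commensurate = commensurate)
    per_chain[[ch]] <- cpp_run_chain(cur_groups, hist_groups, method_code, q,
                                     prior_list, fixed_list, ctrl, grid_info,
                                     ini$A, ini$B, ini$C,
                                     alpha_value, alpha_free)
  }
  keep <- mcmc$iterations - mcmc$burn_in
  bind_par <- function(extract) {
    vapply(per_chain, extract, numeric(keep))
  }
  draws <- list()
  for (j in seq_len(pbeta)) {
    draws[[par_names$beta[j]]] <- bind_par(function(r) r$beta[, j])
  }
  for (j in seq_along(par_names$var)) {
    draws[[par_names$var[j]]] <- bind_par(function(r) r$var[, j])
  }
  if (length(par_names$alpha)) {
    draws[[par_names$alpha]] <- bind_par(function(r) r$alpha)
  }
  for (j in seq_along(par_names$extra)) {
    draws[[par_names$extra[j]]] <- bind_par(function(r) r$extra[, j])
  }
  list(draws = draws,
       n_divergent = sum(vapply(per_chain, `[[`, 0L, "n_divergent")),
       final = per_chain[[chains]][c("final_phiA", "final_phiB",
                                     "final_phiC")])
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic split-R-hat: each chain is halved, and the ratio of pooled to
#' within-chain variance is computed across the resulting 2m sequences.
#'
#' @param draws iterations x chains matrix of posterior draws.
#' @return scalar R-hat (NA if fewer than 4 draws per chain or the
#'   parameter is constant).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sp)
  if (stats::var(as.vector(sp)) < 1e-300) return(NA_real_)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  varplus <- (half - 1) / half * W + B / half
  sqrt(varplus / W)
}

#' Bulk effective sample size
#'
#' Multi-chain effective sample size using chain-averaged autocorrelations
#' combined with Geyer's initial monotone positive sequence.
#'
#' @param draws iterations x chains matrix.
#' @return estimated effective sample size.
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  chain_vars <- apply(draws, 2, stats::var)
  if (all(chain_vars < 1e-300)) return(NA_real_)
  W <- mean(chain_vars)
  B_over_n <- if (m > 1) stats::var(colMeans(draws)) else 0
  varplus <- (n - 1) / n * W + B_over_n
  max_lag <- min(n - 1L, 1000L)
  acov <- vapply(seq_len(m), function(ch) {
    a <- stats::acf(draws[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / varplus
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  psum <- rho[seq(1, 2 * npair, by = 2)] + rho[seq(2, 2 * npair, by = 2)]
  keep <- which(psum <= 0)
  kmax <- if (length(keep)) keep[1] - 1L else npair
  if (kmax > 1L) psum[seq_len(kmax)] <- cummin(psum[seq_len(kmax)])
  tau_int <- 1 + 2 * sum(pmax(psum[seq_len(kmax)], 0))
  max(1, n * m / tau_int)
}

# summary/diagnostics table over a named list of iterations x chains draws
diagnostic_table <- function(draws) {
  do.call(rbind, lapply(names(draws), function(p) {
    x <- as.vector(draws[[p]])
    data.frame(parameter = p,
               mean = mean(x), sd = stats::sd(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               rhat = rhat(draws[[p]]),
               ess = ess_bulk(draws[[p]]),
               stringsAsFactors = FALSE)
  }))
}

#' Histogram mode of power-parameter draws
#'
#' Mode of the posterior of the power parameter estimated from a histogram
#' on \[0, 1\] with the given bin width; the mode is the midpoint of the
#' maximal bin, reported as exactly 1 when the maximal bin abuts the upper
#' boundary (and 0 when it abuts the lower boundary).
#'
#' @param alpha_draws numeric vector of draws in \[0, 1\].
#' @param bin_width histogram bin width.
#' @return scalar mode estimate.
#' @export
alpha_mode <- function(alpha_draws, bin_width = 0.02) {
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(pmin(pmax(alpha_draws, 0), 1), breaks = breaks,
                      plot = FALSE)
  j <- which.max(h$counts)
  if (j == length(h$counts)) return(1)
  if (j == 1L && h$counts[1] >= max(h$counts)) return(0)
  h$mids[j]
}

# Detect two well-separated alpha modes from the draw histogram: local
# maxima of lightly smoothed bin counts, separated by >= 0.2 with a trough
# below half the smaller peak.
detect_bimodality <- function(alpha_draws, bin_width = 0.02) {
  breaks <- seq(0, 1, by = bin_width)
  counts <- graphics::hist(pmin(pmax(alpha_draws, 0), 1), breaks = breaks,
                           plot = FALSE)$counts
  k <- length(counts)
  sm <- stats::filter(c(counts[1], counts, counts[k]), rep(1 / 3, 3))[2:(k + 1)]
  peaks <- which(sm >= c(-Inf, sm[-k]) & sm >= c(sm[-1], -Inf) & sm > 0)
  if (length(peaks) < 2) return(FALSE)
  ord <- order(sm[peaks], decreasing = TRUE)
  p1 <- peaks[ord[1]]; p2 <- peaks[ord[2]]
  if (abs(p1 - p2) * bin_width < 0.2) return(FALSE)
  trough <- min(sm[seq(min(p1, p2), max(p1, p2))])
  trough < 0.5 * min(sm[p1], sm[p2])
}
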