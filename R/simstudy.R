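#' Between-study heterogeneity scenarios
#'
#' The seven heterogeneity levels of the simulation design: no between-study
#' random effects; a between-study random intercept (RI) at low/moderate/high
#' variance; or a between-study random intercept and slope (RIS) at
#' low/moderate/high variance.
#'
#' @param name one of `"No"`, `"RI+Low"`, `"RI+Moderate"`, `"RI+High"`,
#'   `"RIS+Low"`, `"RIS+Moderate"`, `"RIS+High"`.
#' @param effect treatment-by-time coefficient `beta2`; 0 under the null,
#'   0.36 under the alternative.
#' @param n_per_arm subjects per arm (current treated, current control and
#'   historical control each get this many subjects).
#' @param times visit times.
#' @return an object of class `scenario_spec` with fields `name`,
#'   `sigma_d0_sq`, `sigma_d1_sq`, `beta2`, `n_per_arm`, `times`.
#' @export
scenario_spec <- function(name = c("No", "RI+Low", "RI+Moderate", "RI+High",
                                   "RIS+Low", "RIS+Moderate", "RIS+High"),
                          effect = 0, n_per_arm = 100L,
                          times = seq(0, 1, by = 0.2)) {
  name <- match.arg(name)
  tab <- list("No"           = c(0,    0),
              "RI+Low"       = c(0.01, 0),
              "RI+Moderate"  = c(0.09, 0),
              "RI+High"      = c(0.16, 0),
              "RIS+Low"      = c(0.01, 0.01),
              "RIS+Moderate" = c(0.09, 0.09),
              "RIS+High"     = c(0.16, 0.16))
  v <- tab[[name]]
  stopifnot(all(diff(times) > 0), n_per_arm >= 1)
  structure(list(name = name, sigma_d0_sq = v[1], sigma_d1_sq = v[2],
                 beta2 = effect, n_per_arm = as.integer(n_per_arm),
                 times = times),
            class = "scenario_spec")
}

#' Data-generating parameters of the trial simulator
#'
#' Population values of the generative model: intercept `beta0 = 2`, time
#' effect `beta1 = 1`, subject random-intercept and random-slope variances
#' 0.25 each with zero covariance, and unit error variance.
#'
#' @param beta0,beta1 intercept and time effect.
#' @param sigma_b0_sq,sigma_b1_sq,sigma_b0b1 subject-level random-effect
#'   (co)variances.
#' @param sigma_eps_sq error variance.
#' @return an object of class `gen_params`.
#' @export
gen_params <- function(beta0 = 2, beta1 = 1, sigma_b0_sq = 0.25,
                       sigma_b1_sq = 0.25, sigma_b0b1 = 0,
                       sigma_eps_sq = 1) {
  stopifnot(sigma_b0_sq >= 0, sigma_b1_sq >= 0, sigma_eps_sq > 0,
            sigma_b0b1^2 <= sigma_b0_sq * sigma_b1_sq)
  structure(list(beta0 = beta0, beta1 = beta1, sigma_b0_sq = sigma_b0_sq,
                 sigma_b1_sq = sigma_b1_sq, sigma_b0b1 = sigma_b0b1,
                 sigma_eps_sq = sigma_eps_sq),
            class = "gen_params")
}

#' Simulate one current trial plus a historical control arm
#'
#' Generates outcomes from the linear mixed model with subject-level random
#' intercepts and slopes and, to model between-study heterogeneity,
#' independent study-level random intercepts and slopes
#' `d_j ~ N(0, diag(sigma_d0^2, sigma_d1^2))` drawn separately for the
#' current study and the historical study:
#' `y = beta0 + beta1 t + beta2 trt t + b0 + b1 t + d0j + d1j t + e`.
#' The current study has `n_per_arm` treated plus `n_per_arm` control
#' subjects; the historical study has `n_per_arm` control subjects; every
#' subject is observed at all `times`.
#'
#' @param scenario a [scenario_spec()].
#' @param params a [gen_params()].
#' @param seed integer seed.
#' @return list with elements `current` and `historical`, each a
#'   `longitudinal_data`.
#' @export
simulate_trial <- function(scenario, params = gen_params(), seed) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(params, "gen_params"))
  set.seed(as.integer(seed))
  times <- scenario$times
  m <- length(times)
  n <- scenario$n_per_arm
  Gb <- matrix(c(params$sigma_b0_sq, params$sigma_b0b1,
                 params$sigma_b0b1, params$sigma_b1_sq), 2, 2)
  Lb <- t(chol(Gb + diag(1e-12, 2)))
  sd_eps <- sqrt(params$sigma_eps_sq)

  gen_study <- function(n_subj, trt, prefix, study) {
    d <- c(stats::rnorm(1, 0, sqrt(scenario$sigma_d0_sq)),
           stats::rnorm(1, 0, sqrt(scenario$sigma_d1_sq)))
    do.call(rbind, lapply(seq_len(n_subj), function(i) {
      b <- drop(Lb %*% stats::rnorm(2))
      mu <- params$beta0 + params$beta1 * times +
        scenario$beta2 * trt[i] * times +
        b[1] + b[2] * times + d[1] + d[2] * times
      data.frame(subject = sprintf("%s%04d", prefix, i), study = study,
                 arm = if (trt[i] == 1) "treatment" else "control",
                 time = times, y = mu + stats::rnorm(m, 0, sd_eps))
    }))
  }
  cur <- gen_study(2L * n, rep(c(1, 0), each = n), "C", "current")
  hist <- gen_study(n, rep(0, n), "H", "historical")
  list(current = longitudinal_data(cur),
       historical = longitudinal_data(hist))
}

#' Run one simulation scenario over replicated trials
#'
#' For each replicate `r`, a trial pair is simulated with seed
#' `base_seed + r` and every requested method is fitted to the *same* pair
#' (a paired design, enabling McNemar comparisons), the credible-interval
#' treatment-effect test is applied, and replicate-level results are
#' accumulated. Replicates failing the convergence contract
#' (R-hat over 1.05 on monitored parameters) are recorded and excluded from
#' the summaries; if more than 2% are excluded the run is flagged.
#'
#' @param methods character vector from
#'   `c("none", "pool", "mmpp", "cmpp", "commensurate")`.
#' @param scenario a [scenario_spec()].
#' @param R number of replicates (>= 2).
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @param config a [borrow_config()].
#' @param params a [gen_params()].
#' @param verbose print a progress line per replicate.
#' @return an object of class `oc_result`: per-method operating
#'   characteristics (`summary`) with Monte Carlo SEs, the replicate-level
#'   table (`table`), the exclusion count and the scenario.
#' @export
run_scenario <- function(methods, scenario, R, base_seed,
                         config = borrow_config(), params = gen_params(),
                         verbose = FALSE) {
  stopifnot(R >= 2)
  methods <- match.arg(methods, c("none", "pool", "mmpp", "cmpp",
                                  "commensurate"), several.ok = TRUE)
  rows <- vector("list", R * length(methods))
  n_excluded <- 0L
  k <- 0L
  for (r in seq_len(R)) {
    trial <- simulate_trial(scenario, params, seed = base_seed + r)
    cfg <- config
    cfg$mcmc$seed <- as.integer((base_seed + 7919 * r) %% 2147483587)
    for (mth in methods) {
      fit <- fit_borrow(trial$current,
                        if (mth == "none") NULL else trial$historical,
                        mth, cfg)
      tt <- suppressWarnings(test_treatment_effect(fit))
      mon <- fit$diagnostics
      converged <- all(mon$rhat < 1.05, na.rm = TRUE)
      if (!converged) n_excluded <- n_excluded + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, method = mth, seed = base_seed + r,
        estimate = tt$mean, post_sd = tt$sd,
        reject = tt$significant, tail_prob = tt$tail_prob,
        alpha_mean = if (!is.null(fit$alpha_summary))
          fit$alpha_summary$mean else NA_real_,
        alpha_mode = if (!is.null(fit$alpha_summary))
          fit$alpha_summary$mode else NA_real_,
        max_rhat = max(mon$rhat, na.rm = TRUE),
        converged = converged, stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("replicate %d/%d method=%s seed=%d est=%.3f%s",
                        r, R, mth, base_seed + r, tt$mean,
                        if (converged) "" else " [diagnostics flagged]"))
      }
    }
  }
  tab <- do.call(rbind, rows)
  excl_frac <- n_excluded / nrow(tab)
  if (excl_frac >= 0.02) {
    warning(sprintf("%.1f%% of fits failed convergence diagnostics",
                    100 * excl_frac))
  }
  ok <- tab[tab$converged, , drop = FALSE]
  truth <- scenario$beta2
  summ <- do.call(rbind, lapply(methods, function(mth) {
    d <- ok[ok$method == mth, , drop = FALSE]
    Rm <- nrow(d)
    p <- mean(d$reject)
    bias <- mean(d$estimate) - truth
    data.frame(method = mth, R = Rm,
               rejection_rate = p,
               rejection_mcse = sqrt(p * (1 - p) / Rm),
               bias = bias,
               bias_mcse = stats::sd(d$estimate) / sqrt(Rm),
               mean_post_sd = mean(d$post_sd),
               post_sd_mcse = stats::sd(d$post_sd) / sqrt(Rm),
               mse = mean((d$estimate - truth)^2),
               mse_mcse = stats::sd((d$estimate - truth)^2) / sqrt(Rm),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, table = tab, scenario = scenario,
                 n_excluded = n_excluded, base_seed = base_seed,
                 methods = methods),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Operating characteristics — scenario %s (beta2 = %g), R = %d\n",
    sc$name, sc$beta2, max(x$table$replicate)))
  cat(sprintf("  %s rate%s\n",
              if (sc$beta2 == 0) "type I error" else "power",
              if (x$n_excluded > 0)
                sprintf(" (%d fits excluded)", x$n_excluded) else ""))
  s <- x$summary
  out <- data.frame(method = s$method,
                    rate = sprintf("%.3f (%.3f)", s$rejection_rate,
                                   s$rejection_mcse),
                    bias = sprintf("%.4f (%.4f)", s$bias, s$bias_mcse),
                    post_sd = sprintf("%.4f", s$mean_post_sd),
                    mse = sprintf("%.5f", s$mse))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Power calibrated to a fixed type I error rate
#'
#' Recalibrates the rejection rule so every method has exactly the target
#' type I error on the null replicates: the decision statistic is the
#' two-sided posterior tail probability `p_r`; the calibrated threshold is
#' the empirical `target`-quantile of the null `p_r` values, and calibrated
#' power is the fraction of alternative replicates below that threshold.
#'
#' @param null_table,alt_table replicate tables (from
#'   [run_scenario()]`$table`, or any data frame with `method` and
#'   `tail_prob` columns) under the null and alternative.
#' @param target type I error rate to calibrate to.
#' @return data frame with per-method calibrated power and threshold.
#' @export
calibrated_power <- function(null_table, alt_table, target = 0.05) {
  methods <- intersect(unique(null_table$method), unique(alt_table$method))
  if (!length(methods)) stop("no shared methods between the two tables")
  do.call(rbind, lapply(methods, function(mth) {
    p0 <- null_table$tail_prob[null_table$method == mth]
    p1 <- alt_table$tail_prob[alt_table$method == mth]
    if (length(p0) * target < 1) {
      stop("too few null replicates for the ", target, " quantile")
    }
    thr <- unname(stats::quantile(p0, target, type = 1))
    data.frame(method = mth, threshold = thr,
               calibrated_power = mean(p1 < thr),
               R_null = length(p0), R_alt = length(p1),
               stringsAsFactors = FALSE)
  }))
}

#' McNemar paired test of two rejection indicator vectors
#'
#' Compares paired rejection decisions of two methods run on the same
#' replicates. With fewer than 25 discordant pairs the exact two-sided
#' binomial test is used (doubled smaller tail, capped at 1); otherwise the
#' continuity-corrected chi-square
#' `(|n12 - n21| - 1)^2 / (n12 + n21)` on 1 degree of freedom. Zero
#' discordant pairs give p = 1 by convention.
#'
#' @param reject_a,reject_b logical vectors of equal length, paired by
#'   replicate.
#' @return list with `statistic`, `p_value`, `discordant` (n12, n21) and
#'   `test` ("exact" or "chisq").
#' @export
mcnemar_paired <- function(reject_a, reject_b) {
  stopifnot(length(reject_a) == length(reject_b))
  a <- as.logical(reject_a); b <- as.logical(reject_b)
  n12 <- sum(a & !b)
  n21 <- sum(!a & b)
  nd <- n12 + n21
  if (nd == 0L) {
    return(list(statistic = 0, p_value = 1, discordant = c(n12, n21),
                test = "exact"))
  }
  if (nd < 25L) {
    p <- min(1, 2 * stats::pbinom(min(n12, n21), nd, 0.5))
    list(statistic = min(n12, n21), p_value = p,
         discordant = c(n12, n21), test = "exact")
  } else {
    stat <- (abs(n12 - n21) - 1)^2 / nd
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         discordant = c(n12, n21), test = "chisq")
  }
}

#' Summaries of the power-parameter posterior means across replicates
#'
#' Median, interquartile range and mean of the replicate-level posterior
#' means of the power parameter, plus a boundary-mode flag that is true
#' when the majority of replicates have their posterior mode at 1
#' (histogram mode with 0.02 bins abutting the upper boundary).
#'
#' @param table replicate table from [run_scenario()]`$table` (needs
#'   `alpha_mean` and `alpha_mode` columns), or a data frame with those
#'   columns.
#' @param method optional method to filter on (`"mmpp"` or `"cmpp"`).
#' @return list with `median`, `iqr`, `mean`, `boundary_mode`.
#' @export
summarize_alpha <- function(table, method = NULL) {
  d <- table
  if (!is.null(method)) d <- d[d$method == method, , drop = FALSE]
  x <- d$alpha_mean[!is.na(d$alpha_mean)]
  if (!length(x)) stop("no power-parameter summaries in this table")
  modes <- d$alpha_mode[!is.na(d$alpha_mode)]
  list(median = stats::median(x),
       iqr = unname(stats::quantile(x, c(0.25, 0.75))),
       mean = mean(x),
       boundary_mode = mean(modes >= 1) > 0.5)
}
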