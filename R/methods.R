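# S3 methods for fitted borrowing models.

#' @export
print.borrow_fit <- function(x, ...) {
  labels <- c(none = "no borrowing", pool = "pooling",
              mmpp = "marginal modified power prior",
              cmpp = "conditional modified power prior",
              commensurate = "commensurate prior")
  cat("Bayesian cLDA linear mixed model —", labels[[x$method]], "\n")
  cat("  current:", x$n_subjects["current"], "subjects /",
      x$n_obs["current"], "observations")
  if (x$n_subjects["historical"] > 0) {
    cat("; historical:", x$n_subjects["historical"], "subjects")
  }
  cat("\n")
  if (!is.null(x$fixed_alpha)) {
    cat("  power parameter fixed at", x$fixed_alpha, "\n")
  }
  show <- x$diagnostics[x$diagnostics$parameter %in%
                          c(x$x_cols, "sigma", "alpha"), ]
  print(cbind(round(show[, c("mean", "sd", "q2.5", "q97.5")], 4),
              rhat = round(show$rhat, 3), ess = round(show$ess)),
        row.names = show$parameter)
  invisible(x)
}

#' @export
summary.borrow_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.borrow_fit")
}

#' @export
print.summary.borrow_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAll monitored parameters:\n")
  d <- fit$diagnostics
  print(cbind(round(d[, c("mean", "sd", "q2.5", "q97.5")], 4),
              rhat = round(d$rhat, 3), ess = round(d$ess)),
        row.names = d$parameter)
  if (!is.null(fit$alpha_summary) && !isTRUE(fit$alpha_summary$fixed)) {
    a <- fit$alpha_summary
    cat(sprintf(
      "\nPower parameter: mean %.3f, median %.3f, IQR (%.3f, %.3f), mode %.2f%s\n",
      a$mean, a$median, a$iqr[1], a$iqr[2], a$mode,
      if (a$bimodal) " [bimodal posterior detected]" else ""))
  }
  tt <- test_treatment_effect(fit)
  print(tt)
  bad <- fit$diagnostics$rhat > 1.05
  if (any(bad, na.rm = TRUE)) {
    cat("warning: R-hat > 1.05 for",
        paste(fit$diagnostics$parameter[which(bad)], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.borrow_fit <- function(object, ...) {
  pars <- intersect(c(object$x_cols,
                      paste0(object$x_cols, "_hist")), names(object$draws))
  vapply(pars, function(p) mean(object$draws[[p]]), numeric(1))
}

#' Posterior draws of a fitted borrowing model
#'
#' @param fit a `borrow_fit`.
#' @param pars optional character vector of parameter names.
#' @return named list of iterations x chains matrices.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "borrow_fit"))
  if (is.null(pars)) return(fit$draws)
  missing_p <- setdiff(pars, names(fit$draws))
  if (length(missing_p)) stop("unknown parameter(s): ",
                              paste(missing_p, collapse = ", "))
  fit$draws[pars]
}

#' @export
confint.borrow_fit <- function(object, parm, level = 0.95, ...) {
  d <- object$draws
  if (missing(parm)) parm <- names(d)
  aa <- (1 - level) / 2
  out <- t(vapply(parm, function(p)
    unname(stats::quantile(as.vector(d[[p]]), c(aa, 1 - aa))), numeric(2)))
  colnames(out) <- paste0(100 * c(aa, 1 - aa), " %")
  out
}

#' @export
predict.borrow_fit <- function(object, times = NULL,
                               arm = c("control", "treatment"), ...) {
  arm <- match.arg(arm)
  if (is.null(times)) times <- object$times
  if (length(object$covariates)) {
    stop("predict() supports covariate-free fits only; use the draws directly")
  }
  b0 <- mean(object$draws[["intercept"]])
  b1 <- mean(object$draws[["time"]])
  bT <- mean(object$draws[["trt_time"]])
  trt <- as.numeric(arm == "treatment")
  data.frame(time = times, arm = arm,
             mean = b0 + b1 * times + bT * trt * times)
}

#' @export
residuals.borrow_fit <- function(object, data, ...) {
  if (missing(data)) {
    stop("supply the current-study dataset the model was fitted to")
  }
  design <- build_design(data, object$covariates, "current")
  cf <- coef(object)
  beta <- cf[object$x_cols]
  unlist(lapply(design, function(s) s$y - drop(s$X %*% beta)),
         use.names = FALSE)
}

#' @export
plot.borrow_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- intersect(c("trt_time", "time", "sigma", "alpha"),
                      names(x$draws))
  }
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    m <- x$draws[[p]]
    graphics::matplot(m, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Posterior-predictive simulation of current-study trials
#'
#' Draws `nsim` replicate current-study datasets from the posterior
#' predictive distribution of a covariate-free fit (a posterior draw of
#' `(beta, G, sigma^2)` per replicate, then new random effects and errors).
#'
#' @param object a `borrow_fit` without covariates.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param data the current-study dataset that was fitted (supplies the
#'   subject/visit structure).
#' @param ... unused.
#' @return list of `longitudinal_data` objects.
#' @export
simulate.borrow_fit <- function(object, nsim = 1, seed = NULL, data, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (length(object$covariates)) stop("covariate-free fits only")
  design <- build_design(data, character(), "current")
  q <- ncol(design[[1]]$Z)
  d <- object$draws
  total <- length(as.vector(d[[1]]))
  idx <- sample.int(total, nsim, replace = nsim > total)
  lapply(idx, function(k) {
    beta <- vapply(object$x_cols, function(p) as.vector(d[[p]])[k],
                   numeric(1))
    tau <- vapply(seq_len(q), function(j)
      as.vector(d[[paste0("tau", j)]])[k], numeric(1))
    rho <- if (q == 2) as.vector(d[["rho"]])[k] else 0
    sigma <- as.vector(d[["sigma"]])[k]
    G <- diag(tau, q) %*% toeplitz(c(1, if (q == 2) rho)) %*% diag(tau, q)
    Lg <- t(chol(G + diag(1e-12, q)))
    rows <- lapply(design, function(s) {
      b <- drop(Lg %*% stats::rnorm(q))
      mu <- drop(s$X %*% beta + s$Z %*% b)
      data.frame(subject = s$subject, study = "current",
                 arm = s$arm, time = s$X[, "time"],
                 y = mu + stats::rnorm(length(mu), 0, sigma))
    })
    longitudinal_data(do.call(rbind, rows))
  })
}
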