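#' Equation-wise nonlinear least squares for an SBA model form
#'
#' Fits a single SBA equation \eqn{y_i = f(b, X_i) + \varepsilon_i} by
#' Levenberg-Marquardt least squares with multi-start initialisation.  The
#' leading scale parameter (and the Richards rate parameters) are kept
#' positive by log-reparameterisation; all other parameters are unbounded.
#' Asymptotic standard errors come from \eqn{s^2 (J'J)^{-1}} with
#' \eqn{s^2 = SSE/(n - p)}.
#'
#' @param form an \code{\link{sba_form}} or form id string.
#' @param data a \code{\link{plot_table}}; the stratum's own (species-partial)
#'   covariates and observed SBA are used.  Alternatively supply \code{y} and
#'   \code{covariates} directly.
#' @param stratum \code{"P"}, \code{"B"} or \code{"t"} (with \code{data}).
#' @param y observed SBA vector (m2/ha), if \code{data} is not given.
#' @param covariates data.frame with columns \code{si}, \code{adbh},
#'   \code{sdi}, if \code{data} is not given.
#' @param start optional initial coefficient vector (b scale); default starts
#'   are centred on the published reference sets for the matching form.
#' @param seed integer seed for the multi-start perturbations (local to the
#'   fit; the caller's RNG stream is restored).
#' @param control a \code{\link{sba_control}} list.
#' @return an object of class \code{"sba_nls"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{deviance}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' sim <- sba_simulate(sba_sim_config(n_plots = 80, seed = 42))
#' fit <- sba_nls("M1", sim$table, stratum = "B", seed = 1)
#' coef(fit)
#' @export
sba_nls <- function(form, data = NULL, stratum = "t", y = NULL,
                    covariates = NULL, start = NULL, seed = NULL,
                    control = sba_control()) {
  form <- .as_sba_form(form)
  if (!is.null(data)) {
    sd_ <- .stratum_data(data, stratum)
    y <- sd_$y; covariates <- sd_$covariates
  }
  if (is.null(y) || is.null(covariates))
    stop("supply either `data` (+ `stratum`) or `y` and `covariates`")
  covariates <- as.data.frame(covariates)
  stopifnot(all(c("si", "adbh", "sdi") %in% names(covariates)))
  n <- length(y)
  p <- form$n_params
  if (n <= p)
    stop(sprintf("need more observations (%d) than parameters (%d)", n, p))

  log_idx <- .sba_form_table[[form$form_id]]$log_params
  resid_fun <- function(theta) {
    b <- .b_from_theta(theta, log_idx)
    y - sba_eval(form, b, covariates$si, covariates$adbh, covariates$sdi)
  }
  init <- if (is.null(start)) .default_init(form, y, stratum)
          else as.numeric(start)
  if (length(init) != p) stop("`start` has wrong length for form ", form$form_id)
  best <- .with_seed(seed, {
    starts <- .make_starts(init, log_idx, control$n_starts)
    .lm_multistart(resid_fun, starts, control, n_resid = n)
  })

  b_hat <- .b_from_theta(best$theta, log_idx)
  res <- resid_fun(best$theta)
  sse <- sum(res^2)
  out <- list(form = form, coefficients = b_hat, theta = best$theta,
              residuals = res, fitted.values = y - res, sse = sse,
              n_obs = n, df.residual = n - p, converged = best$converged,
              message = best$message, n_starts = best$n_starts, seed = seed,
              y = y, covariates = covariates, stratum = stratum,
              log_idx = log_idx,
              call = match.call())
  out <- c(out, .nls_vcov(resid_fun, best$theta, b_hat, log_idx, sse, n, p))
  out$metrics <- sba_metrics(y, out$fitted.values, p)
  class(out) <- "sba_nls"
  out
}

# vcov/se on the coefficient scale; degenerate (sse ~ 0) residual variance
# gives se = 0 with a flag rather than NaN; a singular J'J is reported via
# pseudo-inverse with the deficient directions flagged.
.nls_vcov <- function(resid_fun, theta, b_hat, log_idx, sse, n, p) {
  J <- .numjac(resid_fun, theta)
  JtJ <- crossprod(J)
  pin <- .pinv_info(JtJ)
  s2 <- sse / (n - p)
  degenerate <- sse < 1e-12 * max(1, n)
  vth <- pin$inv * s2
  d <- .theta_jacdiag(b_hat, log_idx)
  vb <- vth * tcrossprod(d)
  se <- sqrt(pmax(diag(vb), 0))
  if (degenerate) se <- rep(0, p)
  list(vcov = vb, se = se, jac_rank = pin$rank,
       rank_deficient = pin$rank < p, se_degenerate = degenerate)
}

#' @export
coef.sba_nls <- function(object, ...) {
  stats::setNames(object$coefficients,
                  paste0("b", seq_along(object$coefficients) - 1))
}

#' @export
vcov.sba_nls <- function(object, ...) object$vcov

#' @export
residuals.sba_nls <- function(object, ...) object$residuals

#' @export
fitted.sba_nls <- function(object, ...) object$fitted.values

#' @export
deviance.sba_nls <- function(object, ...) object$sse

#' @export
sigma.sba_nls <- function(object, ...)
  sqrt(object$sse / object$df.residual)

#' Predict SBA from a fitted single-equation model
#'
#' @param object a fitted \code{\link{sba_nls}} model.
#' @param newdata data.frame with columns \code{si}, \code{adbh}, \code{sdi},
#'   or a \code{\link{plot_table}} (the fitted stratum's columns are used).
#'   Defaults to the training covariates.
#' @param ... unused.
#' @return numeric vector of predicted SBA (m2/ha).
#' @export
predict.sba_nls <- function(object, newdata = NULL, ...) {
  cov <- if (is.null(newdata)) object$covariates
         else .as_covariates(newdata, object$stratum)
  sba_eval(object$form, object$coefficients, cov$si, cov$adbh, cov$sdi)
}

.as_covariates <- function(newdata, stratum) {
  if (inherits(newdata, "plot_table"))
    .stratum_data(newdata, stratum)$covariates
  else as.data.frame(newdata)
}

#' @export
print.sba_nls <- function(x, digits = 4, ...) {
  cat(sprintf("Nonlinear SBA model (%s), stratum %s: n = %d, %sconverged\n",
              x$form$form_id, x$stratum, x$n_obs,
              if (x$converged) "" else "NOT "))
  print(round(coef(x), digits))
  cat(sprintf("SSE %.4g, RMSE %.4g, adj. R2 %.4f\n",
              x$sse, x$metrics$rmse, x$metrics$r2_adj))
  invisible(x)
}

#' @export
summary.sba_nls <- function(object, ...) {
  b <- coef(object)
  tab <- cbind(Estimate = b, `Std. Error` = object$se,
               `t value` = b / ifelse(object$se > 0, object$se, NA),
               `Pr(>|t|)` = 2 * stats::pt(-abs(b / ifelse(object$se > 0,
                                                          object$se, NA)),
                                          object$df.residual))
  structure(list(fit = object, coef_table = tab), class = "summary.sba_nls")
}

#' @export
print.summary.sba_nls <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(x$coef_table, has.Pvalue = TRUE)
  m <- x$fit$metrics
  cat(sprintf("MAE %.4f  MPE %.2f%%  RMSE %.4f  R2 %.4f  adj. R2 %.4f\n",
              m$mae, m$mpe, m$rmse, m$r2, m$r2_adj))
  if (x$fit$rank_deficient)
    cat("Warning: Jacobian is rank deficient; SEs use a pseudo-inverse\n")
  invisible(x)
}

#' @export
plot.sba_nls <- function(x, ...) {
  graphics::plot(x$fitted.values, x$y,
                 xlab = "Predicted SBA (m2/ha)",
                 ylab = "Observed SBA (m2/ha)",
                 main = paste("Form", x$form$form_id), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.sba_nls <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    mu <- object$fitted.values
    s <- sigma.sba_nls(object)
    as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, s)))
  })
}

#' Rank candidate model forms for one SBA equation
#'
#' Fits each candidate form by \code{\link{sba_nls}} and orders the results
#' by descending adjusted R2, breaking ties by ascending RMSE and then
#' ascending parameter count.  Non-converged candidates are listed last and
#' flagged.
#'
#' @inheritParams sba_nls
#' @param forms character vector of form ids (or list of
#'   \code{\link{sba_form}}s).
#' @return object of class \code{"sba_rank"}: the ordered list of fits with
#'   a summary table in \code{$table}.
#' @export
sba_rank <- function(forms, data = NULL, stratum = "t", y = NULL,
                     covariates = NULL, seed = NULL,
                     control = sba_control()) {
  stopifnot(length(forms) >= 1)
  fits <- lapply(forms, function(f)
    tryCatch(sba_nls(f, data = data, stratum = stratum, y = y,
                     covariates = covariates, seed = seed, control = control),
             error = function(e) structure(list(form = .as_sba_form(f),
                                                error = conditionMessage(e)),
                                           class = "sba_nls_failure")))
  ok <- !vapply(fits, inherits, TRUE, "sba_nls_failure")
  if (!any(ok)) {
    msgs <- vapply(fits, function(f) f$error, "")
    stop("all candidate forms failed:\n",
         paste(sprintf("  %s: %s",
                       vapply(fits, function(f) f$form$form_id, ""), msgs),
               collapse = "\n"))
  }
  key <- function(f) {
    if (inherits(f, "sba_nls_failure") || !f$converged)
      return(c(1, -Inf, Inf, Inf))
    c(0, f$metrics$r2_adj, -f$metrics$rmse, -f$form$n_params)
  }
  keys <- t(vapply(fits, key, numeric(4)))
  ord <- order(keys[, 1], -keys[, 2], -keys[, 3], -keys[, 4])
  fits <- fits[ord]
  tab <- do.call(rbind, lapply(fits, function(f) {
    if (inherits(f, "sba_nls_failure"))
      data.frame(form = f$form$form_id, converged = FALSE, mae = NA,
                 mpe = NA, rmse = NA, r2 = NA, r2_adj = NA)
    else
      data.frame(form = f$form$form_id, converged = f$converged,
                 mae = f$metrics$mae, mpe = f$metrics$mpe,
                 rmse = f$metrics$rmse, r2 = f$metrics$r2,
                 r2_adj = f$metrics$r2_adj)
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "sba_rank")
}

#' @export
print.sba_rank <- function(x, digits = 4, ...) {
  cat("Model ranking (by adjusted R2):\n")
  print(x$table, digits = digits)
  invisible(x)
}
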