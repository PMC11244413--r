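#' Nonlinear seemingly unrelated regression (NSUR) additive SBA system
#'
#' Joint estimation of the two species SBA equations
#' \deqn{SBA_P = f_P(b, X) + \varepsilon_P, \quad
#'       SBA_B = f_B(b, X) + \varepsilon_B}
#' under an estimated cross-equation error covariance \eqn{\Sigma}, with the
#' stand total obtained structurally as \eqn{SBA_t = SBA_P + SBA_B}.  In
#' field data the observed total is the arithmetic sum of the components, so
#' \eqn{\varepsilon_t = \varepsilon_P + \varepsilon_B} and a three-equation
#' covariance is singular; the estimator therefore works with the two
#' species equations and a 2x2 \eqn{\Sigma} (the standard resolution for
#' additive component-total systems).  \code{include_total = TRUE} adds the
#' third equation with a ridge-stabilised 3x3 covariance for data whose
#' total is measured independently.
#'
#' Estimation is iterated feasible generalised least squares:
#' \enumerate{
#'   \item equation-wise \code{\link{sba_nls}} for starting values;
#'   \item \eqn{\hat\Sigma = R'R/n} from the species residual matrix;
#'   \item minimise \eqn{\sum_i r_i' \hat\Sigma^{-1} r_i} over all species
#'     parameters jointly (via Cholesky whitening of the residual pairs);
#'   \item re-estimate \eqn{\hat\Sigma} and repeat until the maximum
#'     relative parameter change falls below \code{tol} or
#'     \code{max_fgls_iter} is reached.
#' }
#' Standard errors come from the inverse GLS information matrix
#' \eqn{(J_w' J_w)^{-1}} of the whitened system.
#'
#' @param species_forms named list or character vector with entries \code{P}
#'   and \code{B} (order P, B if unnamed).
#' @param data a \code{\link{plot_table}} with complete P/B/total triples.
#' @param max_fgls_iter maximum outer FGLS iterations, default 50.
#' @param tol convergence tolerance on the maximum relative parameter
#'   change, default 1e-8.
#' @param sigma \code{"estimate"} (default), \code{"identity"} (fixes
#'   \eqn{\hat\Sigma} to the identity, making the inner step ordinary
#'   stacked least squares) or a fixed positive-definite matrix.
#' @param include_total add the total equation with a ridge-stabilised
#'   covariance.
#' @param ridge ridge fraction added to the covariance diagonal when
#'   \code{include_total = TRUE} (or when \eqn{\hat\Sigma} is singular and
#'   \code{ridge > 0}).
#' @param start optional list of initial coefficient vectors \code{P},
#'   \code{B} (bypasses stage-1 multi-start when given).
#' @param seed integer seed for stage-1 multi-start perturbations.
#' @param control a \code{\link{sba_control}}.
#' @return object of class \code{"sba_nsur"}: per-species coefficients and
#'   SEs, \code{sigma} (estimated residual covariance, m^4/ha^2),
#'   \code{n_fgls_iter}, per-stratum residuals/metrics, the objective trace,
#'   and methods \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{predict}, \code{residuals}, \code{fitted} and \code{simulate}.
#' @examples
#' sim <- sba_simulate(sba_sim_config(n_plots = 120, seed = 11))
#' fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table, seed = 1)
#' fit$sigma
#' @export
sba_nsur <- function(species_forms, data, max_fgls_iter = 50, tol = 1e-8,
                     sigma = "estimate", include_total = FALSE,
                     ridge = 0, start = NULL, seed = NULL,
                     control = sba_control()) {
  sp_forms <- .species_forms(species_forms)
  obs <- lapply(c(P = "P", B = "B", t = "t"), .stratum_data, data = data)
  n <- nrow(data)
  p_P <- sp_forms$P$n_params; p_B <- sp_forms$B$n_params
  p_tot <- p_P + p_B
  if (n <= p_tot)
    stop("too few plots: need more observations than total parameter count")
  log_P <- .sba_form_table[[sp_forms$P$form_id]]$log_params
  log_B <- .sba_form_table[[sp_forms$B$form_id]]$log_params
  log_all <- c(log_P, p_P + log_B)
  n_eq <- if (include_total) 3L else 2L

  # residual matrix (n x n_eq) at a stacked theta
  resid_mat <- function(theta) {
    bP <- .b_from_theta(theta[seq_len(p_P)], log_P)
    bB <- .b_from_theta(theta[p_P + seq_len(p_B)], log_B)
    fP <- sba_eval(sp_forms$P, bP, obs$P$covariates$si,
                   obs$P$covariates$adbh, obs$P$covariates$sdi)
    fB <- sba_eval(sp_forms$B, bB, obs$B$covariates$si,
                   obs$B$covariates$adbh, obs$B$covariates$sdi)
    R <- cbind(P = obs$P$y - fP, B = obs$B$y - fB)
    if (include_total) R <- cbind(R, t = obs$t$y - (fP + fB))
    R
  }

  # stage (i): equation-wise NLS starting values
  if (!is.null(start)) {
    theta <- c(.theta_from_b(as.numeric(start$P), log_P),
               .theta_from_b(as.numeric(start$B), log_B))
    stage1 <- NULL
  } else {
    stage1 <- list(
      P = sba_nls(sp_forms$P, data = data, stratum = "P", seed = seed,
                  control = control),
      B = sba_nls(sp_forms$B, data = data, stratum = "B", seed = seed,
                  control = control))
    theta <- c(stage1$P$theta, stage1$B$theta)
  }

  fixed_sigma <- NULL
  if (is.matrix(sigma)) fixed_sigma <- sigma
  else sigma <- match.arg(sigma, c("estimate", "identity"))
  if (identical(sigma, "identity")) fixed_sigma <- diag(n_eq)

  est_sigma <- function(R) {
    S <- crossprod(R) / n
    # guard against (near-)singular covariance; with the total equation
    # included, epsilon_t = epsilon_P + epsilon_B makes S exactly singular
    lam <- if (include_total) max(ridge, 1e-4) else ridge
    if (lam > 0) S <- S + lam * mean(diag(S)) * diag(n_eq)
    S
  }
  whitener <- function(S) {
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("estimated error covariance is singular (residual collinearity);",
           " consider the `ridge` option"))
    chol(Sinv)
  }

  objective <- function(theta, Sinv) {
    R <- resid_mat(theta)
    sum((R %*% Sinv) * R)
  }

  trace <- list()
  converged <- FALSE
  iter <- 0L
  S <- if (!is.null(fixed_sigma)) fixed_sigma else est_sigma(resid_mat(theta))
  repeat {
    iter <- iter + 1L
    C <- whitener(S)
    resid_fun <- function(th) as.vector(resid_mat(th) %*% t(C))
    run <- .lm_run(resid_fun, theta, control, n_resid = n * n_eq)
    Sinv <- crossprod(C)
    trace[[iter]] <- c(obj_before = objective(theta, Sinv),
                       obj_after = objective(run$theta, Sinv))
    delta <- max(abs(run$theta - theta) / pmax(abs(theta), 1e-8))
    theta <- run$theta
    if (!is.null(fixed_sigma)) { converged <- run$converged; break }
    S_new <- est_sigma(resid_mat(theta))
    if (iter >= max_fgls_iter) { converged <- delta < tol; break }
    if (delta < tol) { converged <- TRUE; S <- S_new; break }
    S <- S_new
  }

  bP <- .b_from_theta(theta[seq_len(p_P)], log_P)
  bB <- .b_from_theta(theta[p_P + seq_len(p_B)], log_B)
  R <- resid_mat(theta)
  C <- whitener(S)
  wresid_fun <- function(th) as.vector(resid_mat(th) %*% t(C))
  Jw <- .numjac(wresid_fun, theta)
  pin <- .pinv_info(crossprod(Jw))
  d <- .theta_jacdiag(c(bP, bB), log_all)
  vb <- pin$inv * tcrossprod(d)
  se <- sqrt(pmax(diag(vb), 0))

  fit_P <- obs$P$y - R[, "P"]
  fit_B <- obs$B$y - R[, "B"]
  fit_t <- fit_P + fit_B
  out <- list(
    species = list(
      P = list(form = sp_forms$P, coefficients = bP,
               se = se[seq_len(p_P)]),
      B = list(form = sp_forms$B, coefficients = bB,
               se = se[p_P + seq_len(p_B)])),
    sigma = S[1:2, 1:2], sigma_full = S, n_fgls_iter = iter,
    converged = converged, include_total = include_total,
    residuals = list(P = R[, "P"], B = R[, "B"], t = obs$t$y - fit_t),
    fitted = list(P = fit_P, B = fit_B, t = fit_t),
    metrics = list(P = sba_metrics(obs$P$y, fit_P, p_P),
                   B = sba_metrics(obs$B$y, fit_B, p_B),
                   t = sba_metrics(obs$t$y, fit_t, p_tot)),
    vcov = vb, rank_deficient = pin$rank < p_tot,
    stage1 = stage1, trace = do.call(rbind, trace),
    theta = theta, n_obs = n, seed = seed, data = data,
    call = match.call())
  class(out) <- "sba_nsur"
  out
}

.species_forms <- function(species_forms) {
  sf <- as.list(species_forms)
  if (is.null(names(sf)) || !all(c("P", "B") %in% names(sf))) {
    if (length(sf) != 2)
      stop("`species_forms` must have entries P and B")
    names(sf) <- c("P", "B")
  }
  lapply(sf[c("P", "B")], .as_sba_form)
}

#' @export
coef.sba_nsur <- function(object, ...) {
  list(P = stats::setNames(object$species$P$coefficients,
                           paste0("b", seq_along(object$species$P$coefficients) - 1)),
       B = stats::setNames(object$species$B$coefficients,
                           paste0("b", seq_along(object$species$B$coefficients) - 1)))
}

#' @export
vcov.sba_nsur <- function(object, ...) object$vcov

#' @export
residuals.sba_nsur <- function(object, ...) object$residuals

#' @export
fitted.sba_nsur <- function(object, ...) object$fitted

#' Predict from a fitted NSUR additive system
#'
#' Species components come from their fitted predictors and the total is
#' their exact sum, so additivity is structural.
#'
#' @param object a fitted \code{\link{sba_nsur}}.
#' @param newdata a \code{\link{plot_table}} or a list with per-stratum
#'   covariate data.frames \code{P} and \code{B}.  Defaults to the training
#'   data.
#' @param ... unused.
#' @return data.frame with columns \code{sba_P}, \code{sba_B}, \code{sba_t}.
#' @export
predict.sba_nsur <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict_additive(
    method = "nsur",
    species_forms = list(P = object$species$P$form, B = object$species$B$form),
    species_coefs = list(P = object$species$P$coefficients,
                         B = object$species$B$coefficients),
    newdata = newdata)
}

#' @export
print.sba_nsur <- function(x, digits = 4, ...) {
  cat(sprintf("NSUR additive SBA system: n = %d, %d FGLS iteration(s), %sconverged\n",
              x$n_obs, x$n_fgls_iter, if (x$converged) "" else "NOT "))
  for (s in c("P", "B")) {
    cat(sprintf("species %s (%s): ", s, x$species[[s]]$form$form_id))
    cat(round(x$species[[s]]$coefficients, digits), "\n")
  }
  cat("cross-equation residual covariance (m^4/ha^2):\n")
  print(round(x$sigma, digits))
  for (s in c("P", "B", "t"))
    cat(sprintf("stratum %s: RMSE %.4f, adj. R2 %.4f\n",
                s, x$metrics[[s]]$rmse, x$metrics[[s]]$r2_adj))
  invisible(x)
}

#' @export
summary.sba_nsur <- function(object, ...) {
  print(object)
  for (s in c("P", "B")) {
    b <- object$species[[s]]$coefficients
    tab <- cbind(Estimate = b, `Std. Error` = object$species[[s]]$se)
    rownames(tab) <- paste0("b", seq_along(b) - 1)
    cat("\nspecies", s, "coefficients:\n")
    print(round(tab, 5))
  }
  invisible(object)
}

#' @export
simulate.sba_nsur <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    n <- object$n_obs
    L <- chol(object$sigma)
    out <- vector("list", nsim)
    for (k in seq_len(nsim)) {
      E <- matrix(stats::rnorm(2 * n), n, 2) %*% L
      out[[k]] <- data.frame(sba_P = object$fitted$P + E[, 1],
                             sba_B = object$fitted$B + E[, 2])
    }
    out
  })
}

#' Additive-system prediction without a fitted object
#'
#' Low-level predictor shared by the AP and NSUR systems: given forms and
#' coefficient vectors, returns the species and total SBA predictions with
#' additivity holding to machine precision.  Used by the \code{predict}
#' methods and directly useful for property checks and simulation.
#'
#' @param method \code{"ap"} or \code{"nsur"}.
#' @param species_forms list with forms \code{P} and \code{B}.
#' @param species_coefs list with coefficient vectors \code{P} and \code{B}.
#' @param newdata a \code{\link{plot_table}} or a list of per-stratum
#'   covariate data.frames (\code{P}, \code{B} and, for AP, \code{t}).
#' @param total_form,total_coef the total equation (AP only).
#' @return data.frame with columns \code{sba_P}, \code{sba_B}, \code{sba_t}.
#' @export
predict_additive <- function(method = c("ap", "nsur"), species_forms,
                             species_coefs, newdata,
                             total_form = NULL, total_coef = NULL) {
  method <- match.arg(method)
  cov <- .per_stratum_covariates(newdata, need_total = method == "ap")
  fP <- sba_eval(species_forms$P, species_coefs$P,
                 cov$P$si, cov$P$adbh, cov$P$sdi)
  fB <- sba_eval(species_forms$B, species_coefs$B,
                 cov$B$si, cov$B$adbh, cov$B$sdi)
  if (method == "nsur") {
    out <- data.frame(sba_P = fP, sba_B = fB, sba_t = fP + fB)
  } else {
    if (is.null(total_form) || is.null(total_coef))
      stop("AP prediction needs `total_form` and `total_coef`")
    denom <- fP + fB
    if (any(denom <= 0))
      stop("AP weight denominator f_P + f_B <= 0 at row ",
           which(denom <= 0)[1])
    ft <- sba_eval(total_form, total_coef, cov$t$si, cov$t$adbh, cov$t$sdi)
    sba_P <- fP / denom * ft
    out <- data.frame(sba_P = sba_P, sba_B = ft - sba_P, sba_t = ft)
  }
  out
}

.per_stratum_covariates <- function(newdata, need_total = TRUE) {
  if (inherits(newdata, "plot_table")) {
    strata <- c("P", "B", if (need_total) "t")
    lapply(stats::setNames(strata, strata),
           function(s) .stratum_data(newdata, s)$covariates)
  } else {
    nd <- lapply(newdata, as.data.frame)
    need <- c("P", "B", if (need_total) "t")
    if (!all(need %in% names(nd)))
      stop("`newdata` must contain per-stratum covariates: ",
           paste(need, collapse = ", "))
    nd
  }
}

#' Efficiency gain of NSUR over equation-wise NLS
#'
#' Ratio of NSUR to NLS standard errors per parameter, for fits of the same
#' forms on the same data.  Ratios below one indicate the efficiency gain
#' expected from exploiting cross-equation error correlation.
#'
#' @param nsur_fit a fitted \code{\link{sba_nsur}}.
#' @param nls_fits list with fitted \code{\link{sba_nls}} models \code{P}
#'   and \code{B}.
#' @return data.frame with columns \code{species}, \code{param},
#'   \code{se_nsur}, \code{se_nls}, \code{ratio}.
#' @export
efficiency_gain <- function(nsur_fit, nls_fits) {
  stopifnot(inherits(nsur_fit, "sba_nsur"))
  rows <- list()
  for (s in c("P", "B")) {
    nf <- nls_fits[[s]]
    if (is.null(nf) || !inherits(nf, "sba_nls"))
      stop("`nls_fits` must contain sba_nls fits P and B")
    if (nf$form$form_id != nsur_fit$species[[s]]$form$form_id)
      stop("mismatched forms for species ", s)
    se_n <- nsur_fit$species[[s]]$se
    se_o <- nf$se
    rows[[s]] <- data.frame(
      species = s, param = paste0("b", seq_along(se_n) - 1),
      se_nsur = se_n, se_nls = se_o,
      ratio = ifelse(se_o > 0, se_n / se_o, NA_real_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
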