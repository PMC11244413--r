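#' Adjustment-in-proportion (AP) additive SBA system
#'
#' Two-stage estimator of the proportional-adjustment additive system for a
#' two-species mixed stand:
#' \deqn{SBA_P = \frac{f_P(b, X)}{f_P(b, X) + f_B(b, X)} \, SBA_t + \varepsilon_P}
#' \deqn{SBA_B = \frac{f_B(b, X)}{f_P(b, X) + f_B(b, X)} \, SBA_t + \varepsilon_B}
#' \deqn{SBA_t = f_t(b, X) + \varepsilon_t}
#'
#' Stage 1 fits the total equation \eqn{f_t} by \code{\link{sba_nls}};
#' stage 2 estimates both species' parameters jointly (the share weights
#' couple them) by minimising the stacked SSE of the two species residual
#' vectors, with the predicted total \eqn{\hat f_t} standing in for
#' \eqn{SBA_t}.  Since the two stages share no parameters they are
#' separable; \code{simultaneous = TRUE} instead fits all three equations
#' in one stacked minimisation for comparison.
#'
#' The share weights are invariant to a common rescaling of \eqn{f_P} and
#' \eqn{f_B}, so the joint scale of the two species equations is not
#' identified; no normalisation is imposed (the published systems report a
#' free leading scale for both species) and stage-2 standard errors use a
#' pseudo-inverse over the identified directions, with the deficiency
#' flagged.
#'
#' @param total_form form id (or \code{\link{sba_form}}) for the total
#'   equation.
#' @param species_forms named list or character vector with entries \code{P}
#'   and \code{B}.
#' @param data a \code{\link{plot_table}} with complete P/B/total triples.
#' @param start optional list with entries \code{P}, \code{B} (and \code{t})
#'   of initial coefficient vectors.
#' @param simultaneous fit all three equations in one stacked least-squares
#'   problem instead of the two separable stages.
#' @param seed integer seed for multi-start perturbations.
#' @param control a \code{\link{sba_control}}.
#' @return object of class \code{"sba_ap"} with \code{total_fit}, per-species
#'   coefficients and SEs, per-stratum residuals and metrics, and methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals} and \code{fitted}.
#' @examples
#' sim <- sba_simulate(sba_sim_config(n_plots = 100, seed = 7,
#'                                    structure = "proportional"))
#' fit <- sba_ap("M1", c(P = "M6", B = "M1"), sim$table, seed = 1)
#' fit
#' @export
sba_ap <- function(total_form, species_forms, data, start = NULL,
                   simultaneous = FALSE, seed = NULL,
                   control = sba_control()) {
  total_form <- .as_sba_form(total_form)
  sp_forms <- .species_forms(species_forms)
  obs <- lapply(c(P = "P", B = "B", t = "t"), .stratum_data, data = data)
  n <- nrow(data)
  p_P <- sp_forms$P$n_params; p_B <- sp_forms$B$n_params
  p_t <- total_form$n_params
  if (n <= max(p_P + p_B, p_t))
    stop("too few plots for the requested system")

  log_P <- .sba_form_table[[sp_forms$P$form_id]]$log_params
  log_B <- .sba_form_table[[sp_forms$B$form_id]]$log_params
  init_P <- .ap_init(start$P, sp_forms$P, "P", obs$P$y)
  init_B <- .ap_init(start$B, sp_forms$B, "B", obs$B$y)
  init_t <- if (!is.null(start$t)) as.numeric(start$t)
            else if (total_form$form_id == "M1") .ref_ap$t$b
            else .default_init(total_form, obs$t$y, "t")

  split_theta <- function(theta)
    list(P = .b_from_theta(theta[seq_len(p_P)], log_P),
         B = .b_from_theta(theta[p_P + seq_len(p_B)], log_B))
  species_resid <- function(theta, ft_hat) {
    b <- split_theta(theta)
    fP <- sba_eval(sp_forms$P, b$P, obs$P$covariates$si,
                   obs$P$covariates$adbh, obs$P$covariates$sdi)
    fB <- sba_eval(sp_forms$B, b$B, obs$B$covariates$si,
                   obs$B$covariates$adbh, obs$B$covariates$sdi)
    denom <- fP + fB
    if (any(denom <= 0))
      stop(sprintf("AP weight degeneracy (f_P + f_B <= 0) at plot %s",
                   data$plot_id[which(denom <= 0)[1]]))
    predP <- fP / denom * ft_hat
    c(obs$P$y - predP, obs$B$y - (ft_hat - predP))
  }

  if (!simultaneous) {
    total_fit <- sba_nls(total_form, data = data, stratum = "t",
                         start = init_t, seed = seed, control = control)
    if (!total_fit$converged)
      stop("AP stage 1 (total equation) did not converge: ",
           total_fit$message)
    ft_hat <- total_fit$fitted.values
    resid_fun <- function(theta) species_resid(theta, ft_hat)
    best <- .with_seed(seed, {
      s1 <- .make_starts(init_P, log_P, control$n_starts)
      s2 <- .make_starts(init_B, log_B, control$n_starts)
      starts <- Map(c, s1, s2)
      .lm_multistart(resid_fun, starts, control, n_resid = 2 * n)
    })
    theta_sp <- best$theta
  } else {
    log_t <- .sba_form_table[[total_form$form_id]]$log_params
    resid_fun_all <- function(theta) {
      th_t <- theta[p_P + p_B + seq_len(p_t)]
      b_t <- .b_from_theta(th_t, log_t)
      ft <- sba_eval(total_form, b_t, obs$t$covariates$si,
                     obs$t$covariates$adbh, obs$t$covariates$sdi)
      c(species_resid(theta[seq_len(p_P + p_B)], ft), obs$t$y - ft)
    }
    best <- .with_seed(seed, {
      s1 <- .make_starts(init_P, log_P, control$n_starts)
      s2 <- .make_starts(init_B, log_B, control$n_starts)
      s3 <- .make_starts(init_t, log_t, control$n_starts)
      starts <- Map(c, s1, s2, s3)
      .lm_multistart(resid_fun_all, starts, control, n_resid = 3 * n)
    })
    th_t <- best$theta[p_P + p_B + seq_len(p_t)]
    b_t <- .b_from_theta(th_t, log_t)
    # package the simultaneous total as an sba_nls-like refit at fixed start
    total_fit <- sba_nls(total_form, data = data, stratum = "t",
                         start = b_t, seed = seed,
                         control = sba_control(n_starts = 1))
    ft_hat <- sba_eval(total_form, b_t, obs$t$covariates$si,
                       obs$t$covariates$adbh, obs$t$covariates$sdi)
    total_fit$coefficients <- b_t
    total_fit$fitted.values <- ft_hat
    total_fit$residuals <- obs$t$y - ft_hat
    resid_fun <- function(theta) species_resid(theta, ft_hat)
    theta_sp <- best$theta[seq_len(p_P + p_B)]
  }

  b_sp <- split_theta(theta_sp)
  r <- resid_fun(theta_sp)
  res_P <- r[seq_len(n)]; res_B <- r[n + seq_len(n)]
  sse <- sum(r^2)
  vc <- .nls_vcov(resid_fun, theta_sp,
                  c(b_sp$P, b_sp$B), c(log_P, p_P + log_B),
                  sse, 2 * n, p_P + p_B)
  se_P <- vc$se[seq_len(p_P)]; se_B <- vc$se[p_P + seq_len(p_B)]

  pred_P <- obs$P$y - res_P
  pred_B <- obs$B$y - res_B
  out <- list(
    total_fit = total_fit,
    species = list(
      P = list(form = sp_forms$P, coefficients = b_sp$P, se = se_P),
      B = list(form = sp_forms$B, coefficients = b_sp$B, se = se_B)),
    residuals = list(P = res_P, B = res_B, t = total_fit$residuals),
    fitted = list(P = pred_P, B = pred_B, t = total_fit$fitted.values),
    metrics = list(P = sba_metrics(obs$P$y, pred_P, p_P),
                   B = sba_metrics(obs$B$y, pred_B, p_B),
                   t = sba_metrics(obs$t$y, total_fit$fitted.values, p_t)),
    sse_species = sse, converged = best$converged,
    rank_deficient = vc$rank_deficient, vcov_species = vc$vcov,
    simultaneous = simultaneous, seed = seed, n_obs = n,
    data = data, call = match.call())
  class(out) <- "sba_ap"
  out
}

.ap_init <- function(user, form, stratum, y) {
  if (!is.null(user)) return(as.numeric(user))
  ref <- if (form$form_id %in% paste0("M", 1:6) &&
             !is.null(.ref_ap[[stratum]]) &&
             .ref_ap[[stratum]]$form == form$form_id) .ref_ap[[stratum]]$b
  if (!is.null(ref)) ref else .default_init(form, y, stratum)
}

#' @export
coef.sba_ap <- function(object, ...) {
  list(P = stats::setNames(object$species$P$coefficients,
                           paste0("b", seq_along(object$species$P$coefficients) - 1)),
       B = stats::setNames(object$species$B$coefficients,
                           paste0("b", seq_along(object$species$B$coefficients) - 1)),
       t = coef(object$total_fit))
}

#' @export
residuals.sba_ap <- function(object, ...) object$residuals

#' @export
fitted.sba_ap <- function(object, ...) object$fitted

#' Predict from a fitted AP additive system
#'
#' Components are model-based shares of the predicted total, so
#' \code{sba_P + sba_B == sba_t} holds to machine precision for every input.
#'
#' @param object a fitted \code{\link{sba_ap}}.
#' @param newdata a \code{\link{plot_table}} or a list with per-stratum
#'   covariate data.frames \code{P}, \code{B}, \code{t} (columns \code{si},
#'   \code{adbh}, \code{sdi}).  Defaults to the training data.
#' @param ... unused.
#' @return data.frame with columns \code{sba_P}, \code{sba_B}, \code{sba_t}.
#' @export
predict.sba_ap <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict_additive(
    method = "ap",
    species_forms = list(P = object$species$P$form, B = object$species$B$form),
    species_coefs = list(P = object$species$P$coefficients,
                         B = object$species$B$coefficients),
    newdata = newdata,
    total_form = object$total_fit$form,
    total_coef = object$total_fit$coefficients)
}

#' @export
print.sba_ap <- function(x, digits = 4, ...) {
  cat(sprintf("AP additive SBA system (%s joint stage 2): n = %d, %sconverged\n",
              if (x$simultaneous) "simultaneous" else "two-stage",
              x$n_obs, if (x$converged) "" else "NOT "))
  cat(sprintf("total (%s): ", x$total_fit$form$form_id))
  cat(round(x$total_fit$coefficients, digits), "\n")
  for (s in c("P", "B")) {
    cat(sprintf("species %s (%s): ", s, x$species[[s]]$form$form_id))
    cat(round(x$species[[s]]$coefficients, digits), "\n")
  }
  for (s in c("P", "B", "t"))
    cat(sprintf("stratum %s: RMSE %.4f, adj. R2 %.4f\n",
                s, x$metrics[[s]]$rmse, x$metrics[[s]]$r2_adj))
  if (x$rank_deficient)
    cat("note: species scale not separately identified (shares are\n",
        "  invariant to a common rescaling); SEs use a pseudo-inverse\n")
  invisible(x)
}

#' @export
summary.sba_ap <- function(object, ...) {
  print(object)
  invisible(object)
}
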