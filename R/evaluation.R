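#' Goodness-of-fit metrics for SBA predictions
#'
#' Computes the five evaluation statistics used throughout the package:
#' \itemize{
#'   \item MAE \eqn{= \frac{1}{n}\sum |y_i - \hat y_i|} (m2/ha)
#'   \item MPE \eqn{= \frac{\sum |y_i - \hat y_i|}{\sum y_i} \times 100}
#'     (percent; the aggregate relative absolute error)
#'   \item RMSE \eqn{= \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}} (m2/ha)
#'   \item \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}
#'   \item \eqn{R^2_{adj} = 1 - \frac{n-1}{n-p} (1 - R^2)}
#' }
#'
#' A zero observed total leaves MPE \code{NA}; zero variance of \code{y}
#' leaves R2 and adjusted R2 \code{NA}; both cases are flagged rather than
#' raised as errors.
#'
#' @param y observed values.
#' @param yhat predicted values (same length, n >= 2).
#' @param p number of model parameters (for adjusted R2).
#' @return a list of class \code{"sba_metrics"} with elements \code{mae},
#'   \code{mpe}, \code{rmse}, \code{r2}, \code{r2_adj}, \code{n_obs},
#'   \code{n_params} and \code{flags}.
#' @examples
#' sba_metrics(c(2, 4), c(1, 5), p = 1)
#' @export
sba_metrics <- function(y, yhat, p = 1) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  e <- y - yhat
  n <- length(y)
  mae <- sum(abs(e)) / n
  rmse <- sqrt(sum(e^2) / n)
  flags <- character(0)
  ytot <- sum(y)
  if (ytot > 0) mpe <- sum(abs(e)) / ytot * 100
  else { mpe <- NA_real_; flags <- c(flags, "mpe_undefined") }
  tss <- sum((y - mean(y))^2)
  if (tss > 0) {
    r2 <- 1 - sum(e^2) / tss
    r2_adj <- if (n > p) 1 - (n - 1) / (n - p) * (1 - r2) else NA_real_
  } else {
    r2 <- NA_real_; r2_adj <- NA_real_
    flags <- c(flags, "r2_undefined")
  }
  structure(list(mae = mae, mpe = mpe, rmse = rmse, r2 = r2,
                 r2_adj = r2_adj, n_obs = n, n_params = p, flags = flags),
            class = "sba_metrics")
}

#' @export
print.sba_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d, p = %d\n", x$n_obs, x$n_params))
  cat(sprintf("MAE %.*f  MPE %.*f%%  RMSE %.*f  R2 %.*f  adj. R2 %.*f\n",
              digits, x$mae, digits, x$mpe, digits, x$rmse,
              digits, x$r2, digits, x$r2_adj))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Signed percent change between two metric values
#'
#' Reports the relative change of a goodness-of-fit statistic between two
#' fits as \eqn{(before - after)/before \times 100}: positive values mean
#' the statistic \emph{decreased} (an improvement for error metrics),
#' negative values that it increased.
#'
#' @param before baseline metric value (> 0).
#' @param after comparison metric value.
#' @return signed percent decrease.
#' @examples
#' percent_change(1.776, 1.170)  # RMSE decreased by 34.12%
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("`before` must be positive")
  (before - after) / before * 100
}

#' Method-comparison table of percent changes
#'
#' Compares error metrics (MAE, MPE, RMSE) of two estimation methods for
#' each stratum, in the style of an additive-system evaluation: each entry
#' is the percent decrease from the baseline method.  R2-type metrics are
#' reported as percent \emph{increase} over the baseline.
#'
#' @param metrics a data.frame like \code{\link{sba_reference_metrics}}
#'   (columns \code{method}, \code{stratum}, \code{mae}, \code{mpe},
#'   \code{rmse}, \code{r2}, \code{r2_adj}).
#' @param baseline method name used as the reference, default \code{"NLS"}.
#' @return a data.frame with one row per (method, stratum) and the signed
#'   percent changes; error metrics as decreases, R2 metrics as increases.
#' @examples
#' sba_compare_methods(sba_reference_metrics())
#' @export
sba_compare_methods <- function(metrics = sba_reference_metrics(),
                                baseline = "NLS") {
  stopifnot(baseline %in% metrics$method)
  others <- setdiff(unique(metrics$method), baseline)
  rows <- list()
  for (m in others) for (s in unique(metrics$stratum)) {
    b <- metrics[metrics$method == baseline & metrics$stratum == s, ]
    a <- metrics[metrics$method == m & metrics$stratum == s, ]
    if (!nrow(b) || !nrow(a)) next
    rows[[length(rows) + 1]] <- data.frame(
      method = m, baseline = baseline, stratum = s,
      mae_decrease = percent_change(b$mae, a$mae),
      mpe_decrease = percent_change(b$mpe, a$mpe),
      rmse_decrease = percent_change(b$rmse, a$rmse),
      r2_increase = -percent_change(b$r2, a$r2),
      r2_adj_increase = -percent_change(b$r2_adj, a$r2_adj))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' k-fold cross-validation fold assignment
#'
#' Seeded shuffle followed by contiguous blocks; fold sizes differ by at
#' most one (the first \code{n %% k} folds get the extra observation).
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed (mandatory, recorded in reports).
#' @return integer vector of fold indices in 1..k, one per observation.
#' @export
cv_folds <- function(n, k = 10, seed) {
  if (n < k) stop("need at least k observations")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  perm <- .with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), sizes)
  folds
}

#' k-fold cross-validation of a fitted SBA model
#'
#' Re-fits the model on each training complement and predicts the held-out
#' fold; pooled metrics are computed on the concatenated out-of-fold
#' predictions.  Works for single equations (\code{\link{sba_nls}}) and for
#' the additive systems (\code{\link{sba_ap}}, \code{\link{sba_nsur}}),
#' which report pooled metrics per stratum.  Re-fits start from the
#' full-data estimates.
#'
#' @param object a fitted \code{sba_nls}, \code{sba_ap} or \code{sba_nsur}.
#' @param data the \code{\link{plot_table}} to partition; defaults to the
#'   data stored in the fit.
#' @param k number of folds, default 10.
#' @param seed integer seed for the fold shuffle (mandatory).
#' @return a list of class \code{"sba_cv"}: \code{fold_assignments},
#'   \code{pooled} (metrics, or per-stratum list for systems),
#'   \code{per_fold}, \code{failed_folds}, \code{seed}, \code{k}.
#' @export
sba_cv <- function(object, data = NULL, k = 10, seed) UseMethod("sba_cv")

#' @export
sba_cv.sba_nls <- function(object, data = NULL, k = 10, seed) {
  y <- object$y; cov <- object$covariates
  n <- length(y)
  folds <- cv_folds(n, k, seed)
  yhat <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  failed <- integer(0)
  p <- object$form$n_params
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- tryCatch(
      sba_nls(object$form, y = y[tr], covariates = cov[tr, , drop = FALSE],
              start = object$coefficients, seed = seed,
              control = sba_control(n_starts = 1)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- c(failed, f); next }
    yhat[!tr] <- predict(fit, cov[!tr, , drop = FALSE])
    per_fold[[f]] <- sba_metrics(y[!tr], yhat[!tr], p)
  }
  keep <- !is.na(yhat)
  pooled <- if (sum(keep) >= 2) sba_metrics(y[keep], yhat[keep], p) else NULL
  structure(list(fold_assignments = folds, per_fold = per_fold,
                 pooled = pooled, predictions = yhat,
                 failed_folds = failed, k = k, seed = seed),
            class = "sba_cv")
}

#' @export
print.sba_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n", x$k,
              format(x$seed)))
  if (length(x$failed_folds))
    cat("failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  if (inherits(x$pooled, "sba_metrics")) {
    cat("pooled out-of-fold metrics:\n"); print(x$pooled)
  } else if (is.list(x$pooled)) {
    for (s in names(x$pooled)) {
      cat("stratum", s, "pooled out-of-fold metrics:\n")
      print(x$pooled[[s]])
    }
  }
  invisible(x)
}

#' @export
sba_cv.sba_ap <- function(object, data = NULL, k = 10, seed) {
  if (is.null(data)) data <- object$data
  .sba_cv_system(object, data, k, seed, refit = function(train, obj)
    sba_ap(obj$total_fit$form,
           list(P = obj$species$P$form, B = obj$species$B$form),
           train,
           start = list(P = obj$species$P$coefficients,
                        B = obj$species$B$coefficients,
                        t = obj$total_fit$coefficients),
           simultaneous = obj$simultaneous, seed = seed,
           control = sba_control(n_starts = 1)),
    p = c(P = object$species$P$form$n_params,
          B = object$species$B$form$n_params,
          t = object$total_fit$form$n_params))
}

#' @export
sba_cv.sba_nsur <- function(object, data = NULL, k = 10, seed) {
  if (is.null(data)) data <- object$data
  p_sys <- object$species$P$form$n_params + object$species$B$form$n_params
  .sba_cv_system(object, data, k, seed, refit = function(train, obj)
    sba_nsur(list(P = obj$species$P$form, B = obj$species$B$form),
             train,
             start = list(P = obj$species$P$coefficients,
                          B = obj$species$B$coefficients),
             include_total = obj$include_total, seed = seed,
             control = sba_control(n_starts = 1)),
    p = c(P = object$species$P$form$n_params,
          B = object$species$B$form$n_params, t = p_sys))
}

# shared CV driver for the additive systems: refit on each training
# complement, predict the held-out triple, pool out-of-fold metrics per
# stratum
.sba_cv_system <- function(object, data, k, seed, refit, p) {
  n <- nrow(data)
  folds <- cv_folds(n, k, seed)
  pred <- data.frame(sba_P = rep(NA_real_, n), sba_B = NA_real_,
                     sba_t = NA_real_)
  per_fold <- vector("list", k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- tryCatch(refit(data[tr, , drop = FALSE], object),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- c(failed, f); next }
    pr <- predict(fit, data[!tr, , drop = FALSE])
    pred[!tr, ] <- pr
    per_fold[[f]] <- lapply(stats::setNames(c("P", "B", "t"),
                                            c("P", "B", "t")), function(s)
      sba_metrics(data[[paste0("sba_", s)]][!tr], pr[[paste0("sba_", s)]],
                  p[[s]]))
  }
  keep <- !is.na(pred$sba_t)
  pooled <- NULL
  if (sum(keep) >= 2)
    pooled <- lapply(stats::setNames(c("P", "B", "t"), c("P", "B", "t")),
                     function(s)
      sba_metrics(data[[paste0("sba_", s)]][keep],
                  pred[[paste0("sba_", s)]][keep], p[[s]]))
  structure(list(fold_assignments = folds, per_fold = per_fold,
                 pooled = pooled, predictions = pred,
                 failed_folds = failed, k = k, seed = seed),
            class = "sba_cv")
}
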