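# Internal least-squares machinery shared by sba_nls, sba_ap and sba_nsur.
#
# Positivity constraints (b0 everywhere; the Richards rate parameters) are
# enforced by log-reparameterisation: the optimizer works on theta, where
# theta[j] = log(b[j]) for the form's `log_params` positions and b[j]
# otherwise.  Invalid evaluations (overflow, negative Richards bracket) are
# penalised with large residuals rather than clamped.

.theta_from_b <- function(b, log_idx) {
  th <- as.numeric(b)
  if (length(log_idx)) {
    if (any(b[log_idx] <= 0))
      stop("parameters at positions ", paste(log_idx, collapse = ","),
           " must be positive")
    th[log_idx] <- log(b[log_idx])
  }
  th
}

.b_from_theta <- function(theta, log_idx) {
  b <- as.numeric(theta)
  if (length(log_idx)) b[log_idx] <- exp(theta[log_idx])
  b
}

# d b / d theta, for the delta method on vcov
.theta_jacdiag <- function(b, log_idx) {
  d <- rep(1, length(b))
  if (length(log_idx)) d[log_idx] <- b[log_idx]
  d
}

# Central finite-difference Jacobian of a vector-valued function
.numjac <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Moore-Penrose pseudo-inverse with rank information
.pinv_info <- function(A, tol = NULL) {
  s <- svd(A)
  # truncate only numerically exact null directions (e.g. the AP common-scale
  # invariance); weakly identified directions keep their honest huge variance
  if (is.null(tol)) tol <- max(s$d) * 1e-12
  keep <- s$d > tol
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = sum(keep),
       null_dirs = s$v[, !keep, drop = FALSE])
}

# Large-but-finite residuals signal an invalid parameter region to the LM
# driver without derailing its finite differencing.
.penalty_resid <- function(n) rep(1e6, n)

.safe_resid <- function(fn, n) {
  function(theta) {
    r <- tryCatch(fn(theta), sba_eval_error = function(e) NULL,
                  error = function(e) NULL)
    if (is.null(r) || anyNA(r) || any(!is.finite(r))) .penalty_resid(n) else r
  }
}

#' Control settings for the least-squares drivers
#'
#' @param ftol relative tolerance on the sum-of-squares change, default 1e-10.
#' @param maxiter maximum Levenberg-Marquardt iterations per start, default 500.
#' @param n_starts number of multi-start initialisations, default 5.
#' @return a list of class \code{"sba_control"}.
#' @export
sba_control <- function(ftol = 1e-10, maxiter = 500, n_starts = 5) {
  structure(list(ftol = ftol, maxiter = maxiter, n_starts = n_starts),
            class = "sba_control")
}

# One Levenberg-Marquardt run from a single start
.lm_run <- function(resid_fun, theta0, control, n_resid) {
  fn <- .safe_resid(resid_fun, n_resid)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = control$ftol, ptol = 1e-12,
                         maxiter = min(control$maxiter, 1024))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(theta = theta0, sse = sum(fn(theta0)^2),
                converged = FALSE, message = "optimizer failure"))
  r <- fn(fit$par)
  list(theta = fit$par, sse = sum(r^2),
       converged = fit$info %in% 1:4 && all(abs(r) < 1e6),
       message = fit$message, niter = fit$niter)
}

# Multi-start driver: runs LM from each start, returns the best converged
# run by SSE (or the best run overall if none converged).
.lm_multistart <- function(resid_fun, starts, control, n_resid) {
  runs <- lapply(starts, .lm_run, resid_fun = resid_fun, control = control,
                 n_resid = n_resid)
  sses <- vapply(runs, function(r) r$sse, 0)
  conv <- vapply(runs, function(r) r$converged, TRUE)
  best <- if (any(conv)) which(conv)[which.min(sses[conv])] else which.min(sses)
  out <- runs[[best]]
  out$converged <- conv[best]
  out$n_starts <- length(starts)
  out
}

# Perturbed starts on the b scale: the leading scale parameter varies by up
# to one order of magnitude, all others by +/-50%; the first start is used
# unperturbed.
.make_starts <- function(b0, log_idx, n_starts) {
  starts <- vector("list", n_starts)
  starts[[1]] <- .theta_from_b(b0, log_idx)
  if (n_starts > 1) {
    for (k in 2:n_starts) {
      b <- b0
      b[1] <- b[1] * 10^stats::runif(1, -1, 1)
      if (length(b) > 1) {
        j <- 2:length(b)
        b[j] <- b[j] * stats::runif(length(j), 0.5, 1.5)
      }
      starts[[k]] <- .theta_from_b(b, log_idx)
    }
  }
  starts
}

# Default initial coefficients for a form: reference published sets where
# available (stratum-specific when known), otherwise data-driven heuristics
# for the base forms.
.default_init <- function(form, y, stratum = "P") {
  id <- form$form_id
  if (id %in% paste0("M", 1:6)) {
    if (!stratum %in% c("P", "B")) stratum <- "P"
    return(.ref_nls[[stratum]][[id]]$b)
  }
  top <- max(y) * 1.2
  switch(id,
    korf = c(top, 5, 0.5),
    schumacher = c(top, 10),
    richards = c(top, 0.05, 1))
}

# Evaluate with local, restored RNG state so fits don't disturb the caller's
# random stream; seed = NULL leaves the global stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
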