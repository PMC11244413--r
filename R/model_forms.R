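#' Stand basal area model forms
#'
#' The package implements three base growth forms and six extended forms for
#' predicting stand basal area (SBA, m2/ha) from stand covariates: site index
#' \code{si} (dominant height, m), age at breast height \code{adbh} (years)
#' and Reineke stand density index \code{sdi} (trees/ha).
#'
#' Base forms (time variable \eqn{t} = ADBH):
#' \itemize{
#'   \item \code{korf}: \eqn{b_0 \exp(-b_1 t^{-b_2})}
#'   \item \code{schumacher}: \eqn{b_0 \exp(-b_1 / t)}
#'   \item \code{richards}: \eqn{b_0 (1 - \exp(-b_1 t))^{b_2}}
#' }
#'
#' Extended forms:
#' \itemize{
#'   \item \code{M1}: \eqn{b_0\, SI^{b_1} \exp(-b_2/ADBH)\, SDI^{b_3}}
#'   \item \code{M2}: as M1 with SDI/1000
#'   \item \code{M3}: \eqn{\exp(b_0 + b_1/ADBH)\, SDI^{b_2 + b_4/ADBH}\, SI^{b_3 + b_5/ADBH}}
#'   \item \code{M4}: as M3 with SDI/1000
#'   \item \code{M5}: \eqn{b_0\, SI^{b_1} [1 - \exp(-b_2\, SDI^{b_3} ADBH)]^{b_4}}
#'   \item \code{M6}: as M5 with SDI/1000
#' }
#'
#' Forms M2, M4 and M6 use the dimensionless convention SDI/1000; the unscaled
#' SDI is always supplied and the scaling is applied inside the predictor.
#'
#' @param form_id one of \code{"korf"}, \code{"schumacher"}, \code{"richards"},
#'   \code{"M1"} ... \code{"M6"}.
#' @return \code{sba_form} returns an object of class \code{"sba_form"} with
#'   elements \code{form_id}, \code{n_params} and \code{sdi_scaled}.
#' @examples
#' f <- sba_form("M1")
#' f$n_params
#' sba_forms()
#' @export
sba_form <- function(form_id) {
  form_id <- match.arg(form_id, names(.sba_form_table))
  spec <- .sba_form_table[[form_id]]
  structure(list(form_id = form_id,
                 n_params = spec$n_params,
                 sdi_scaled = spec$sdi_scaled),
            class = "sba_form")
}

#' @rdname sba_form
#' @export
sba_forms <- function() names(.sba_form_table)

# n_params per form; sdi_scaled marks the SDI/1000 variants; log_params are
# the 1-based positions of parameters constrained positive during fitting
# (handled by log-reparameterisation, never by clamping).
.sba_form_table <- list(
  korf       = list(n_params = 3L, sdi_scaled = FALSE, log_params = 1L),
  schumacher = list(n_params = 2L, sdi_scaled = FALSE, log_params = 1L),
  richards   = list(n_params = 3L, sdi_scaled = FALSE, log_params = c(1L, 2L)),
  M1 = list(n_params = 4L, sdi_scaled = FALSE, log_params = 1L),
  M2 = list(n_params = 4L, sdi_scaled = TRUE,  log_params = 1L),
  M3 = list(n_params = 6L, sdi_scaled = FALSE, log_params = integer(0)),
  M4 = list(n_params = 6L, sdi_scaled = TRUE,  log_params = integer(0)),
  M5 = list(n_params = 5L, sdi_scaled = FALSE, log_params = c(1L, 3L)),
  M6 = list(n_params = 5L, sdi_scaled = TRUE,  log_params = c(1L, 3L))
)

#' @export
print.sba_form <- function(x, ...) {
  cat("SBA model form", x$form_id,
      sprintf("(%d parameters%s)\n", x$n_params,
              if (x$sdi_scaled) ", SDI/1000" else ""))
  invisible(x)
}

.as_sba_form <- function(form) {
  if (inherits(form, "sba_form")) form else sba_form(form)
}

#' Reineke stand density index
#'
#' Computes the stand density index \eqn{SDI = N (D_0/D_g)^{-1.605}} from
#' stem count and quadratic mean diameter at breast height.
#'
#' @param n_stems stems per hectare (> 0).
#' @param dg quadratic mean DBH in cm (> 0).
#' @param d0 reference diameter in cm, default 20.
#' @param exponent Reineke exponent, default -1.605.
#' @return SDI in trees/ha; strictly increasing in \code{dg} for fixed
#'   \code{n_stems}.
#' @examples
#' reineke_sdi(500, 20)   # dg at the reference diameter: SDI == N
#' reineke_sdi(1000, 10)
#' @export
reineke_sdi <- function(n_stems, dg, d0 = 20, exponent = -1.605) {
  if (any(!is.finite(n_stems)) || any(n_stems <= 0))
    stop("`n_stems` must be positive and finite")
  if (any(!is.finite(dg)) || any(dg <= 0))
    stop("`dg` must be positive and finite")
  if (d0 <= 0) stop("`d0` must be positive")
  n_stems * (d0 / dg)^exponent
}

#' Evaluate an SBA model form
#'
#' Vectorised predictor for any of the base or extended SBA model forms.
#' Power terms are evaluated in log space; when the log prediction exceeds
#' 700 in magnitude the evaluation fails (rather than silently saturating),
#' carrying the offending covariate rows, so that fitting code can penalise
#' such parameter values.
#'
#' @param form an \code{\link{sba_form}} or a form id string.
#' @param b numeric coefficient vector, length \code{form$n_params}; the
#'   leading scale \code{b[1]} must be positive (except M3/M4, where the
#'   leading parameter enters through \code{exp()}).
#' @param si,adbh,sdi positive covariate vectors (recycled to a common
#'   length).  \code{sdi} is always the unscaled stand density index.
#' @return numeric vector of predicted SBA (m2/ha).
#' @examples
#' sba_eval("M1", c(0.008, 0.4216, 1.4756, 1.0338),
#'          si = 14.8, adbh = 29, sdi = 242.7)
#' @export
sba_eval <- function(form, b, si, adbh, sdi) {
  form <- .as_sba_form(form)
  b <- as.numeric(b)
  if (length(b) != form$n_params)
    stop(sprintf("form %s needs %d parameters, got %d",
                 form$form_id, form$n_params, length(b)))
  n <- max(length(si), length(adbh), length(sdi))
  si <- rep_len(si, n); adbh <- rep_len(adbh, n); sdi <- rep_len(sdi, n)
  if (any(!is.finite(si)) || any(si <= 0)) stop("`si` must be positive")
  if (any(!is.finite(adbh)) || any(adbh <= 0)) stop("`adbh` must be positive")
  if (any(!is.finite(sdi)) || any(sdi <= 0)) stop("`sdi` must be positive")
  s <- if (form$sdi_scaled) sdi / 1000 else sdi

  id <- form$form_id
  if (id %in% c("korf", "schumacher", "richards", "M1", "M2", "M5", "M6") &&
      b[1] <= 0)
    stop("leading scale parameter b0 must be positive for form ", id)

  pred <- switch(id,
    korf = .sba_exp(log(b[1]) - b[2] * adbh^(-b[3]), si, adbh, sdi),
    schumacher = .sba_exp(log(b[1]) - b[2] / adbh, si, adbh, sdi),
    richards = .sba_bracket(b[1], 0, b[2] * adbh, b[3], si, adbh, sdi),
    M1 = ,
    M2 = .sba_exp(log(b[1]) + b[2] * log(si) - b[3] / adbh + b[4] * log(s),
                  si, adbh, sdi),
    M3 = ,
    M4 = .sba_exp(b[1] + b[2] / adbh + (b[3] + b[5] / adbh) * log(s) +
                    (b[4] + b[6] / adbh) * log(si), si, adbh, sdi),
    M5 = ,
    M6 = {
      if (b[3] < 0)
        stop("Richards rate parameter b2 must be non-negative for form ", id)
      .sba_bracket(b[1], b[2] * log(si), b[3] * s^b[4] * adbh, b[5],
                   si, adbh, sdi)
    })
  pred
}

# exp(logp) with the overflow/underflow policy
.sba_exp <- function(logp, si, adbh, sdi) {
  bad <- !is.finite(logp) | abs(logp) > 700
  if (any(bad)) .sba_eval_error(which(bad), si, adbh, sdi)
  exp(logp)
}

# scale * si-part * (1 - exp(-inner))^shape for the Richards family;
# inner == 0 yields an exact 0 (allowed when shape > 0)
.sba_bracket <- function(b0, log_si_part, inner, shape, si, adbh, sdi) {
  if (any(inner < 0)) .sba_eval_error(which(inner < 0), si, adbh, sdi)
  bracket <- -expm1(-inner)
  out <- numeric(length(bracket))
  zero <- bracket == 0
  if (any(zero) && shape <= 0) .sba_eval_error(which(zero), si, adbh, sdi)
  nz <- !zero
  if (any(nz)) {
    logp <- log(b0) + log_si_part + shape * log(bracket[nz])
    bad <- !is.finite(logp) | abs(logp) > 700
    if (any(bad)) .sba_eval_error(which(nz)[bad], si, adbh, sdi)
    out[nz] <- exp(logp)
  }
  out
}

.sba_eval_error <- function(rows, si, adbh, sdi) {
  i <- rows[1]
  cond <- structure(
    class = c("sba_eval_error", "error", "condition"),
    list(message = sprintf(
           paste0("non-finite or out-of-range SBA prediction at %d covariate",
                  " row(s); first offender: si=%g, adbh=%g, sdi=%g"),
           length(rows), si[i], adbh[i], sdi[i]),
         call = sys.call(-1),
         rows = rows,
         covariates = data.frame(si = si[rows], adbh = adbh[rows],
                                 sdi = sdi[rows])))
  stop(cond)
}
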