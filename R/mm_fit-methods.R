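# S3 methods for fitted models (mm_fit): Cox and modified-Poisson fits share
# the same accessor surface.

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' Covariance matrix of an mm_fit
#'
#' @param object An `mm_fit`.
#' @param type `"robust"` (default; equals the model-based matrix for Cox
#'   fits) or `"model"`.
#' @param ... Unused.
#' @return Covariance matrix of the coefficients.
#' @export
vcov.mm_fit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "model") object$vcov_model else object$vcov
}

#' @export
confint.mm_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  dimnames(ci) <- list(names(cf),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Fitted model:", x$family, "\n")
  cat("n =", x$n_obs,
      if (!is.null(x$n_events)) paste0("(", x$n_events, " events)"), "\n")
  print(round(x$coefficients, 5))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, level = 0.95, ...) {
  cf <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- cf / se
  pv <- 2 * stats::pnorm(-abs(z))
  ci <- confint(object, level = level)
  tab <- data.frame(estimate = cf, exp_estimate = exp(cf), se = se,
                    ci_low = exp(ci[, 1]), ci_high = exp(ci[, 2]),
                    z = z, p = pv)
  names(tab)[2] <- tolower(object$exp_label %||% "exp(coef)")
  structure(list(table = tab, family = object$family, n_obs = object$n_obs,
                 converged = object$converged, loglik = object$loglik),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat(x$family, " fit, n = ", x$n_obs, ", logLik = ",
      format(x$loglik, digits = 6), "\n", sep = "")
  print(round(x$table, 5))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
logLik.mm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
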