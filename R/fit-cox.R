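# Cox proportional hazards regression: Newton-Raphson maximization of the
# Breslow partial likelihood.

#' Cox proportional hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving. Used to compare the incidence of the k-th condition between
#' genders and age groups. Ties are handled by the Breslow approximation
#' (each tied death contributes the full risk-set denominator).
#'
#' Degenerate designs are reported, not silently returned: a covariate with
#' no variation gives a singular information matrix error, and a monotone
#' partial likelihood (complete separation, coefficients diverging) raises
#' an error as well.
#'
#' @param time Nonnegative follow-up times.
#' @param status Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param x Covariate matrix (no intercept; the partial likelihood has
#'   none).
#' @param tol Convergence tolerance on the score max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `mm_fit`; `exp(coef(fit))` are hazard ratios
#'   and `vcov(fit)` is the inverse information (model-based).
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 50)
#' t <- rexp(100, 0.1 * exp(log(2) * g))
#' fit <- cox_ph(t, rep(1, 100), cbind(group = g))
#' exp(coef(fit))
cox_ph <- function(time, status, x, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (nrow(x) != n || length(status) != n) stop("inconsistent input lengths")
  if (any(time < 0)) stop("negative follow-up times")
  if (!any(status == 1)) stop("no events")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (any(apply(x, 2L, function(cc) length(unique(cc)) == 1L)))
    stop("covariate with no variation: no estimable coefficient")

  # sort by decreasing time so risk-set sums are cumulative sums; within a
  # tied time block every row shares the block-end cumulative sum
  o <- order(time, decreasing = TRUE)
  x <- x[o, , drop = FALSE]
  status <- status[o]
  td <- time[o]
  r <- rle(td)
  block_end <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(status == 1)
  ev_end <- block_end[ev]

  partial_loglik <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    s0 <- cumsum(w)
    sum(eta[ev]) - sum(log(s0[ev_end]))
  }

  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    s0 <- cumsum(w)[ev_end]
    s1 <- apply(x * w, 2L, cumsum)[ev_end, , drop = FALSE]
    xbar <- s1 / s0
    score <- colSums(x[ev, , drop = FALSE] - xbar)
    info <- matrix(0, p, p)
    for (a in seq_len(p)) for (b in a:p) {
      s2ab <- cumsum(x[, a] * x[, b] * w)[ev_end]
      info[a, b] <- info[b, a] <- sum(s2ab / s0 - xbar[, a] * xbar[, b])
    }
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    step <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix: no estimable coefficient"))
    ll_old <- partial_loglik(beta)
    h <- 1
    repeat {
      beta_new <- beta + h * step
      ll_new <- partial_loglik(beta_new)
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-12 || h < 1e-8)) break
      h <- h / 2
    }
    beta <- beta_new
    iter <- iter + 1L
    if (any(abs(beta) > 20))
      stop("monotone partial likelihood (complete separation): coefficients diverge")
  }
  if (!converged)
    warning("cox_ph did not converge in ", max_iter, " iterations")

  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  fit <- list(
    coefficients = stats::setNames(drop(beta), colnames(x)),
    vcov = vc,
    vcov_model = vc,
    loglik = partial_loglik(beta),
    n_obs = n,
    n_events = length(ev),
    iterations = iter,
    converged = converged,
    family = "cox (Breslow partial likelihood)",
    exp_label = "HR"
  )
  class(fit) <- "mm_fit"
  fit
}

#' Breslow partial log-likelihood
#'
#' Evaluates the Breslow partial log-likelihood at an arbitrary coefficient
#' vector (exposed so the maximum returned by [cox_ph()] can be checked
#' against grid or numerical optimizers).
#'
#' @inheritParams cox_ph
#' @param beta Coefficient vector.
#' @return Scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(time, status, x, beta) {
  x <- as.matrix(x)
  o <- order(time, decreasing = TRUE)
  x <- x[o, , drop = FALSE]
  status <- as.numeric(status)[o]
  td <- as.numeric(time)[o]
  r <- rle(td)
  block_end <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(status == 1)
  eta <- drop(x %*% beta)
  sum(eta[ev]) - sum(log(cumsum(exp(eta))[block_end[ev]]))
}
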