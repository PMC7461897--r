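test_that("modified Poisson on a saturated model reduces to the risk ratio", {
  x <- cbind(`(Intercept)` = 1, exposed = rep(c(1, 0), c(100, 100)))
  y <- c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(5, 95)))
  fit <- poisson_rr(y, x)
  expect_equal(unname(exp(coef(fit)["exposed"])), 2, tolerance = 1e-10)
  expect_equal(unname(exp(coef(fit)["(Intercept)"])), 0.05, tolerance = 1e-10)
})

test_that("Poisson coefficients match direct likelihood maximization", {
  # 12-row fixture with a continuous and a binary regressor
  x <- cbind(1,
             z = c(0.2, 1.1, -0.4, 0.8, 1.9, -1.2, 0.5, 0.0, 1.4, -0.7, 0.3, 2.1),
             g = rep(0:1, 6))
  y <- c(1, 3, 0, 2, 5, 0, 1, 1, 4, 0, 2, 6)
  fit <- poisson_rr(y, x)
  nll <- function(b) -sum(y * drop(x %*% b) - exp(drop(x %*% b)))
  ngr <- function(b) -drop(crossprod(x, y - exp(drop(x %*% b))))
  opt <- stats::optim(c(0, 0, 0), nll, ngr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
})

test_that("sandwich variance collapses to model variance under exact equidispersion", {
  # per stratum, sum of squared deviations equals n * mean exactly
  y <- c(0, 2, 2, 4, 2, 2, 2, 6)
  x <- cbind(1, exposed = rep(0:1, each = 4))
  fit <- poisson_rr(y, x)
  expect_equal(vcov(fit, "robust"), vcov(fit, "model"), tolerance = 1e-10)
})

test_that("robust covariance matches the sandwich package oracle", {
  set.seed(606)
  n <- 200
  g <- rep(0:1, each = n / 2)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * g + 0.3 * z))
  X <- cbind(1, g = g, z = z)
  fit <- poisson_rr(y, X)
  ref <- stats::glm(y ~ g + z, family = poisson())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  skip_if_not_installed("sandwich")
  vr <- sandwich::vcovHC(ref, type = "HC0")
  expect_equal(unname(vcov(fit)), unname(vr), tolerance = 1e-4)
})

test_that("weighted aggregation reproduces the row-level Poisson fit", {
  set.seed(77)
  g <- rep(0:1, c(60, 40))
  y <- rbinom(100, 1, 0.1 + 0.15 * g)
  X <- cbind(1, exposed = g)
  full <- poisson_rr(y, X)
  key <- paste(g, y)
  agg <- !duplicated(key)
  w <- as.integer(table(key)[key[agg]])
  wfit <- poisson_rr(y[agg], X[agg, , drop = FALSE], weights = w)
  expect_equal(coef(full), coef(wfit), tolerance = 1e-10)
  expect_equal(vcov(full), vcov(wfit), tolerance = 1e-10)
})

test_that("degenerate Poisson inputs are rejected", {
  X <- cbind(1, x = rep(0:1, 5))
  expect_error(poisson_rr(rep(0, 10), X), "all-zero")
  expect_error(poisson_rr(c(-1, rep(1, 9)), X), "nonnegative")
})

test_that("Cox fit rejects degenerate designs", {
  expect_error(cox_ph(1:6, rep(1, 6), cbind(x = rep(1, 6))), "no variation")
  expect_error(cox_ph(1:4, rep(0, 4), cbind(x = c(0, 1, 0, 1))), "no events")
})

test_that("Cox coefficient maximizes the Breslow partial likelihood", {
  # 6-record fixtures, including one with a tied event time
  fixtures <- list(
    list(time = c(1, 2, 3, 4, 5, 6), status = c(1, 0, 1, 1, 0, 1),
         x = c(0, 1, 1, 0, 1, 0)),
    list(time = c(2, 2, 3, 5, 7, 9), status = c(1, 1, 0, 1, 1, 0),
         x = c(1, 0, 1, 0, 1, 1)),
    list(time = c(4, 1, 6, 2, 8, 3), status = c(1, 1, 1, 0, 1, 1),
         x = c(0.5, -1, 2, 0, 1.5, -0.5))
  )
  for (fx in fixtures) {
    X <- cbind(x = fx$x)
    fit <- cox_ph(fx$time, fx$status, X)
    b <- unname(coef(fit))
    ll_hat <- cox_partial_loglik(fx$time, fx$status, X, b)
    grid <- b + seq(-2, 2, length.out = 101)
    ll_grid <- vapply(grid, function(g)
      cox_partial_loglik(fx$time, fx$status, X, g), numeric(1))
    expect_true(all(ll_hat >= ll_grid - 1e-10))
  }
})

test_that("Cox estimates agree with the survival package (Breslow ties)", {
  skip_if_not_installed("survival")
  set.seed(808)
  n <- 400
  g <- rep(0:1, each = n / 2)
  z <- rnorm(n)
  t <- rexp(n, 0.1 * exp(0.7 * g - 0.3 * z))
  cens <- runif(n, 0, 15)
  time <- round(pmin(t, cens), 1)  # rounding induces ties
  status <- as.numeric(t <= cens)
  fit <- cox_ph(time, status, cbind(g = g, z = z))
  ref <- survival::coxph(survival::Surv(time, status) ~ g + z,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("Cox recovers a known hazard ratio in a two-group simulation", {
  set.seed(909)
  n <- 10000
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.1 * exp(log(2) * g))
  fit <- cox_ph(t, rep(1, n), cbind(g = g))
  hr <- unname(exp(coef(fit)))
  expect_gt(hr, 1.85)
  expect_lt(hr, 2.15)
})

test_that("complete separation in the Cox model is reported", {
  # every event subject has the strictly largest covariate in its risk set,
  # so the partial likelihood is monotone in the coefficient
  time <- 1:6
  status <- rep(1, 6)
  x <- 6:1
  expect_error(suppressWarnings(cox_ph(time, status, cbind(x = x))),
               "separation|diverge")
})

test_that("mm_fit accessor methods are coherent", {
  x <- cbind(`(Intercept)` = 1, exposed = rep(c(1, 0), c(50, 50)))
  y <- c(rep(c(1, 0), c(20, 30)), rep(c(1, 0), c(10, 40)))
  fit <- poisson_rr(y, x)
  s <- summary(fit)
  expect_s3_class(s, "summary.mm_fit")
  expect_equal(s$table$rr[2], 2, tolerance = 1e-8)
  ci <- confint(fit)
  expect_true(ci["exposed", 1] < coef(fit)["exposed"])
  expect_true(ci["exposed", 2] > coef(fit)["exposed"])
  expect_output(print(fit), "poisson")
})
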