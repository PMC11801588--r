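test_that("log-likelihood equals the sum of log densities", {
  set.seed(5)
  x <- rlgeo(40, 0.5, 0.5)
  for (pars in list(c(0.3, 0.2), c(0.9, 0.6), c(2, 0.1))) {
    expect_equal(lg_loglik(x, pars[1], pars[2]),
                 sum(dlgeo(x, pars[1], pars[2], log = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("boundary parameters yield the -Inf sentinel, not an error", {
  x <- c(0.5, 1, 2)
  expect_identical(lg_loglik(x, 1, 1), -Inf)
  expect_identical(lg_loglik(x, -1, 0.5), -Inf)
})

test_that("analytic score matches finite differences of the log-likelihood", {
  set.seed(6)
  samples <- list(rlgeo(25, 0.5, 0.5), rlgeo(50, 0.25, 0.25), survival_vec())
  pts <- list(c(0.4, 0.3), c(0.9, 0.6), c(1.5, 0.15))
  for (x in samples) for (par in pts) {
    expect_equal(unname(lg_score(x, par[1], par[2])),
                 numeric_score(x, par[1], par[2]),
                 tolerance = 1e-5 * max(1, abs(numeric_score(x, par[1], par[2]))))
  }
})

test_that("score p-component at p = 0 reduces to its closed form", {
  set.seed(7)
  x <- rlgeo(20, 0.7, 0.3)
  th <- 0.7
  s <- lg_score(x, th, 0)
  expect_equal(unname(s["dp"]),
               -length(x) + 2 * sum((1 + th * x / (th + 1)) * exp(-th * x)),
               tolerance = 1e-12)
})

test_that("score is approximately zero at the MLE of a large sample", {
  set.seed(8)
  x <- rlgeo(5000, 0.5, 0.5)
  fit <- fit_lg(x)
  s <- lg_score(x, fit$theta, fit$p)
  expect_lt(max(abs(s)), 0.5)  # optim's own convergence scale on n = 5000
  expect_lt(max(abs(coef(fit) - c(0.5, 0.5))), 0.05)
})

test_that("optimum beats a dense grid search on a small sample", {
  set.seed(9)
  x <- rlgeo(50, 0.5, 0.5)
  fit <- fit_lg(x)
  grid_th <- seq(0.01, 10, length.out = 200)
  grid_p <- seq(0.01, 0.999, length.out = 200)
  best <- max(vapply(grid_th, function(t)
    max(vapply(grid_p, function(pp) lg_loglik(x, t, pp), numeric(1))),
    numeric(1)))
  expect_gte(fit$loglik + 1e-8, best)
})

test_that("likelihood at the optimum dominates start and truth on simulated data", {
  set.seed(10)
  for (i in 1:5) {
    x <- rlgeo(100, 0.75, 0.75)
    fit <- fit_lg(x)
    expect_gte(fit$loglik, lg_loglik(x, 0.5, 0.5))
    expect_gte(fit$loglik, lg_loglik(x, 0.75, 0.75))
  }
})

test_that("parameter recovery: median bias small at n = 250", {
  set.seed(12)
  for (pars in list(c(0.25, 0.25), c(0.75, 0.75))) {
    est <- replicate(200, coef(fit_lg(rlgeo(250, pars[1], pars[2]))))
    expect_lt(abs(median(est[1, ]) - pars[1]), 0.05)
    expect_lt(abs(median(est[2, ]) - pars[2]), 0.05)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_lg(c(1, 2)), "at least 3")
  expect_error(fit_lg(rep(1.5, 10)), "identical")
  expect_error(fit_lg(c(1, -1, 2)), "positive")
})

test_that("fit object accessors are coherent", {
  set.seed(13)
  fit <- fit_lg(rlgeo(80, 0.5, 0.5))
  expect_s3_class(fit, "lg_fit")
  expect_named(coef(fit), c("theta", "p"))
  expect_equal(as.numeric(logLik(fit)),
               lg_loglik(fit$data, fit$theta, fit$p))
  expect_equal(unname(quantile(fit, 0.5)), qlgeo(0.5, fit$theta, fit$p))
  set.seed(1); s1 <- simulate(fit, 10)
  set.seed(1); s2 <- simulate(fit, 10)
  expect_identical(s1, s2)
})

test_that("AIC/BIC identities hold for every fit", {
  set.seed(14)
  for (i in 1:3) {
    fit <- fit_lg(rlgeo(30 + 10 * i, 0.5, 0.4))
    g <- gof_lg(fit)
    expect_equal(g$aic, -2 * fit$loglik + 4, tolerance = 1e-12)
    expect_equal(g$bic, -2 * fit$loglik + 2 * log(fit$n), tolerance = 1e-12)
  }
})

test_that("EDF statistics agree with the fitdistrplus implementation", {
  skip_if_not_installed("fitdistrplus")
  fit <- fit_lg(survival_vec())
  g <- gof_lg(fit)
  # fitdistrplus resolves d<name>/p<name> in the global environment
  assign("dlg", function(x, theta, p) dlgeo(x, theta, p), envir = globalenv())
  assign("plg", function(q, theta, p) plgeo(q, theta, p), envir = globalenv())
  on.exit(rm("dlg", "plg", envir = globalenv()))
  fd <- suppressWarnings(fitdistrplus::fitdist(
    survival_vec(), "lg",
    start = list(theta = 0.5, p = 0.5),
    lower = c(0.01, 0.01), upper = c(10, 0.999)))
  # fitdist optimizes the same likelihood without the analytic gradient, so
  # its optimum differs in the 4th decimal; 1e-3 still catches formula errors
  expect_equal(unname(fd$estimate), unname(coef(fit)), tolerance = 1e-3)
  gs <- fitdistrplus::gofstat(fd)
  expect_equal(unname(g$ks), unname(gs$ks), tolerance = 1e-3)
  expect_equal(unname(g$cvm), unname(gs$cvm), tolerance = 1e-3)
  expect_equal(unname(g$ad), unname(gs$ad), tolerance = 1e-3)
})

test_that("KS statistic shrinks as sample size grows under the true model", {
  set.seed(15)
  ks <- vapply(c(1e2, 1e3, 1e4), function(n) {
    x <- rlgeo(n, 0.5, 0.5)
    gof_lg(fit_lg(x))$ks
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[3], 0.02)
})
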