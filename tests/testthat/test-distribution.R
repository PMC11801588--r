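test_that("lambert_wm1 inverts w*exp(w) and matches an independent routine", {
  xs <- -exp(-1) * c(1, 1 - 1e-10, 0.999, 0.9, 0.5, 0.27, 0.1, 1e-3, 1e-8)
  w <- lambert_wm1(xs)
  expect_true(all(w <= -1))
  expect_equal(w * exp(w), xs, tolerance = 1e-12)
  skip_if_not_installed("pracma")
  oracle <- vapply(xs, pracma::lambertWn, numeric(1))
  expect_equal(w, oracle, tolerance = 1e-9)
})

test_that("lambert_wm1 handles the branch point, round-off clamp and bad input", {
  expect_identical(lambert_wm1(-exp(-1)), -1)
  # round-off slightly past the branch point is clamped onto it
  expect_equal(lambert_wm1(-exp(-1) - 1e-13), -1)
  expect_true(is.nan(lambert_wm1(-exp(-1) - 1e-6)))
  expect_true(is.nan(lambert_wm1(0.5)))
})

test_that("density integrates to 1 over the parameter grid", {
  for (i in seq_len(nrow(param_grid))) {
    th <- param_grid$theta[i]; p <- param_grid$p[i]
    total <- integrate(dlgeo, 0, Inf, theta = th, p = p,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8,
                 label = sprintf("integral at theta=%g p=%g", th, p))
  }
})

test_that("cdf matches the integrated density and is monotone", {
  ys <- c(0.1, 0.5, 1, 2, 5)
  for (pars in list(c(0.25, 0.25), c(0.75, 0.5), c(2, 0.9))) {
    F_int <- vapply(ys, function(y)
      integrate(dlgeo, 0, y, theta = pars[1], p = pars[2],
                rel.tol = 1e-10)$value, numeric(1))
    expect_equal(plgeo(ys, pars[1], pars[2]), F_int, tolerance = 1e-8)
  }
  expect_identical(plgeo(0, 1, 0.5), 0)
  expect_true(all(diff(plgeo(seq(0, 50, 0.5), 0.25, 0.25)) >= 0))
  expect_equal(plgeo(1e4, 0.25, 0.25), 1, tolerance = 1e-10)
})

test_that("cdf is increasing in p at fixed y (concentration near zero)", {
  y <- 0.8
  ps <- c(0, 0.25, 0.5, 0.75, 0.95)
  expect_true(all(diff(vapply(ps, function(p) plgeo(y, 0.5, p), numeric(1))) > 0))
})

test_that("support convention: negative arguments give density 0 and cdf 0", {
  expect_identical(dlgeo(c(-1, -0.1), 0.5, 0.5), c(0, 0))
  expect_identical(plgeo(-2, 0.5, 0.5), 0)
})

test_that("p = 0 reproduces the Lindley sub-model in closed form", {
  y <- c(0.1, 0.7, 1.5, 4)
  th <- 0.5
  lindley_pdf <- th^2 / (th + 1) * (1 + y) * exp(-th * y)
  lindley_cdf <- 1 - (1 + th * y / (th + 1)) * exp(-th * y)
  expect_equal(dlgeo(y, th, 0), lindley_pdf, tolerance = 1e-14)
  expect_equal(plgeo(y, th, 0), lindley_cdf, tolerance = 1e-14)
  expect_equal(lg_moment(1, th, 0), (th + 2) / (th * (th + 1)), tolerance = 1e-12)
  # Lindley median via bisection on the cdf as an independent oracle
  med_oracle <- uniroot(function(y) plgeo(y, th, 0) - 0.5, c(1e-9, 100),
                        tol = 1e-12)$root
  expect_equal(qlgeo(0.5, th, 0), med_oracle, tolerance = 1e-8)
})

test_that("quantile and cdf are inverse on the probability grid", {
  u <- c(0.001, 0.05, 0.1, 0.5, 0.75, 0.9, 0.999)
  for (i in seq_len(nrow(param_grid))) {
    th <- param_grid$theta[i]; p <- param_grid$p[i]
    expect_equal(plgeo(qlgeo(u, th, p), th, p), u, tolerance = 1e-8,
                 label = sprintf("round trip at theta=%g p=%g", th, p))
  }
})

test_that("quantile is increasing in u and decreasing in each parameter", {
  u <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(qlgeo(u, 0.25, 0.25)) > 0))
  for (uu in c(0.05, 0.5, 0.9)) {
    q_th <- vapply(c(0.25, 0.5, 1, 2), function(t) qlgeo(uu, t, 0.5), numeric(1))
    q_p <- vapply(c(0, 0.25, 0.5, 0.9), function(p) qlgeo(uu, 0.5, p), numeric(1))
    expect_true(all(diff(q_th) < 0))
    expect_true(all(diff(q_p) < 0))
  }
})

test_that("quantile tends to zero as u tends to zero", {
  expect_lt(qlgeo(1e-10, 0.25, 0.25), 1e-8)
  expect_error(qlgeo(0, 0.25, 0.25), "inside")
  expect_error(qlgeo(1, 0.25, 0.25), "inside")
})

test_that("series moments agree with adaptive quadrature", {
  for (pars in list(c(0.25, 0.25), c(0.5, 0.5), c(0.75, 0.75), c(2, 0.95))) {
    for (r in 1:2) {
      quad <- integrate(function(y) y^r * dlgeo(y, pars[1], pars[2]), 0, Inf,
                        rel.tol = 1e-10)$value
      expect_equal(lg_moment(r, pars[1], pars[2]), quad, tolerance = 1e-6,
                   label = sprintf("E[Y^%d] at theta=%g p=%g", r, pars[1], pars[2]))
    }
    v <- lg_moment(2, pars[1], pars[2]) - lg_moment(1, pars[1], pars[2])^2
    expect_gt(v, 0)
  }
})

test_that("random generation is seed-reproducible and matches the cdf", {
  set.seed(11); a <- rlgeo(100, 0.25, 0.25)
  set.seed(11); b <- rlgeo(100, 0.25, 0.25)
  expect_identical(a, b)
  expect_true(all(a > 0))
  set.seed(99)
  x <- rlgeo(1e5, 0.25, 0.25)
  ks <- suppressWarnings(ks.test(x, function(q) plgeo(q, 0.25, 0.25)))
  expect_lt(ks$statistic, 0.01)
  expect_gt(ks$p.value, 0.01)
  # sample mean within 3 standard errors of the series mean
  mu <- lg_moment(1, 0.25, 0.25)
  sdev <- sqrt(lg_moment(2, 0.25, 0.25) - mu^2)
  expect_lt(abs(mean(x) - mu), 3 * sdev / sqrt(length(x)))
})

test_that("shape classification matches the density's behaviour near zero", {
  expect_identical(lg_shape(0.25, 0.25), "unimodal")
  expect_identical(lg_shape(3, 0.5), "decreasing")
  for (i in seq_len(nrow(param_grid))) {
    th <- param_grid$theta[i]; p <- param_grid$p[i]
    thr <- (1 - th^2) / (1 + th^2)
    if (abs(p - thr) < 0.05) next  # skip near-threshold ties of the derivative
    slope <- dlgeo(1e-4, th, p) - dlgeo(0, th, p)
    expect_identical(lg_shape(th, p),
                     if (slope < 0) "decreasing" else "unimodal",
                     label = sprintf("shape at theta=%g p=%g", th, p))
  }
})

test_that("invalid parameters are rejected", {
  expect_error(dlgeo(1, -1, 0.5), "theta")
  expect_error(plgeo(1, 0.5, 1), "p")
  expect_error(qlgeo(0.5, 0, 0.5), "theta")
  expect_error(lg_moment(0, 0.5, 0.5), "positive integer")
})
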