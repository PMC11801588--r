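#' Log-likelihood of the Lindley-Geometric model
#'
#' Evaluates
#' \deqn{\ell(\theta, p) = 2n\log\theta - n\log(\theta+1) + n\log(1-p)
#'   + \sum_i \log(1+x_i) - \theta\sum_i x_i
#'   - 2\sum_i \log\left[1 - p\left(1+\frac{\theta x_i}{\theta+1}\right)
#'     e^{-\theta x_i}\right]}
#' for a positive sample \code{x}. Parameter values that drive a log
#' argument to zero or below return \code{-Inf} rather than erroring, so
#' numerical optimizers can retreat from the boundary.
#'
#' @param x numeric vector of positive observations.
#' @param theta,p LG parameters (see \code{\link{lgeo}}).
#' @return the log-likelihood, a single number (possibly \code{-Inf}).
#' @seealso \code{\link{lg_score}}, \code{\link{fit_lg}}
#' @export
lg_loglik <- function(x, theta, p) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be a vector of positive finite values", call. = FALSE)
  if (!is.finite(theta) || theta <= 0 || !is.finite(p) || p >= 1) return(-Inf)
  n <- length(x)
  g <- lg_kernel(x, theta)
  s <- 1 - p * g
  if (any(s <= 0)) return(-Inf)
  2 * n * log(theta) - n * log(theta + 1) + n * log1p(-p) +
    sum(log1p(x)) - theta * sum(x) - 2 * sum(log(s))
}

#' Score (gradient) of the Lindley-Geometric log-likelihood
#'
#' Analytic partial derivatives of the log-likelihood with respect to
#' \eqn{\theta} and \eqn{p}:
#' \deqn{\frac{\partial \ell}{\partial \theta} = \frac{2n}{\theta}
#'   - \frac{n}{\theta+1} - \sum_i x_i
#'   - 2p \sum_i \frac{x_i e^{-\theta x_i}\left(1 + \frac{\theta x_i}{\theta+1}
#'     - \frac{1}{(\theta+1)^2}\right)}{1 - p g_i},\qquad
#'   \frac{\partial \ell}{\partial p} = -\frac{n}{1-p}
#'   + 2 \sum_i \frac{g_i}{1 - p g_i},}
#' with \eqn{g_i = (1 + \theta x_i/(\theta+1)) e^{-\theta x_i}}.
#'
#' @inheritParams lg_loglik
#' @return numeric vector \code{c(dtheta, dp)}.
#' @export
lg_score <- function(x, theta, p) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be a vector of positive finite values", call. = FALSE)
  if (!is.finite(theta) || theta <= 0 || !is.finite(p) || p >= 1)
    stop("score undefined outside the parameter domain", call. = FALSE)
  n <- length(x)
  e <- exp(-theta * x)
  g <- (1 + theta * x / (theta + 1)) * e
  s <- 1 - p * g
  if (any(s <= 0)) stop("score undefined: log argument nonpositive", call. = FALSE)
  dg <- x * e * (1 / (theta + 1)^2 - 1 - theta * x / (theta + 1))
  dtheta <- 2 * n / theta - n / (theta + 1) - sum(x) + 2 * p * sum(dg / s)
  dp <- -n / (1 - p) + 2 * sum(g / s)
  c(dtheta = dtheta, dp = dp)
}

# negative log-likelihood and gradient in optim() parameterisation
lg_nll <- function(par, x) {
  v <- lg_loglik(x, par[1], par[2])
  if (!is.finite(v)) 1e300 else -v
}
lg_nll_grad <- function(par, x) {
  g <- tryCatch(-lg_score(x, par[1], par[2]), error = function(e) NULL)
  if (is.null(g) || any(!is.finite(g))) c(0, 0) else g
}

#' Fit the Lindley-Geometric distribution by maximum likelihood
#'
#' Maximizes the LG log-likelihood over \eqn{(\theta, p)} by bounded
#' quasi-Newton (\code{L-BFGS-B}) with the analytic score as gradient.
#' If the first optimization fails to converge, a small deterministic grid
#' of restarts (\eqn{\theta \in \{0.1, 0.5, 2\}} by
#' \eqn{p \in \{0.1, 0.5, 0.9\}}) is tried and the best converged optimum
#' kept; \code{converged} is \code{FALSE} only if every start fails.
#'
#' @param x numeric vector of positive observations, at least 3 and not all
#'   identical.
#' @param start numeric length-2 starting value \code{c(theta, p)}.
#' @param lower,upper box constraints on \code{c(theta, p)}. The default
#'   box \eqn{\theta \in [0.01, 10]}, \eqn{p \in [0.01, 0.999]} keeps tiny
#'   subgroup fits away from the degenerate \eqn{p \to 1} escape.
#' @return an object of class \code{"lg_fit"}: a list with components
#'   \code{theta}, \code{p}, \code{loglik}, \code{converged},
#'   \code{n_restarts}, \code{n}, \code{data} and \code{call}. Methods are
#'   provided for \code{print}, \code{summary} (adds goodness-of-fit
#'   statistics), \code{coef}, \code{logLik}, \code{quantile},
#'   \code{simulate} and \code{plot}.
#' @examples
#' set.seed(42)
#' fit <- fit_lg(rlgeo(200, theta = 0.5, p = 0.5))
#' coef(fit)
#' quantile(fit, 0.05)
#' summary(fit)
#' @export
fit_lg <- function(x, start = c(0.5, 0.5),
                   lower = c(0.01, 0.01), upper = c(10, 0.999)) {
  if (!is.numeric(x) || length(x) < 3L)
    stop("need at least 3 observations to fit", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all observations must be positive and finite", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate sample: all observations identical", call. = FALSE)

  try_one <- function(st) {
    tryCatch(
      stats::optim(st, lg_nll, lg_nll_grad, x = x, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
  }
  opt <- try_one(start)
  n_restarts <- 0L
  if (is.null(opt) || opt$convergence != 0) {
    grid <- expand.grid(theta = c(0.1, 0.5, 2), p = c(0.1, 0.5, 0.9))
    cand <- list()
    for (i in seq_len(nrow(grid))) {
      o <- try_one(as.numeric(grid[i, ]))
      n_restarts <- n_restarts + 1L
      if (!is.null(o) && o$convergence == 0) cand[[length(cand) + 1L]] <- o
    }
    if (length(cand)) {
      opt <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
    } else if (is.null(opt)) {
      stop("LG fit failed from every start", call. = FALSE)
    }
  }
  structure(list(
    theta = opt$par[1], p = opt$par[2],
    loglik = -opt$value,
    converged = opt$convergence == 0,
    n_restarts = n_restarts,
    n = length(x), data = x,
    call = match.call()), class = "lg_fit")
}

#' @export
print.lg_fit <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat("Lindley-Geometric fit (maximum likelihood)\n")
  cat(sprintf("  n = %d, theta = %s, p = %s\n", x$n,
              format(x$theta, digits = digits), format(x$p, digits = digits)))
  cat(sprintf("  log-likelihood = %s%s\n", format(x$loglik, digits = digits),
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
coef.lg_fit <- function(object, ...) c(theta = object$theta, p = object$p)

#' @export
logLik.lg_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' Quantiles of a fitted Lindley-Geometric model
#'
#' Plug-in quantile estimate: the closed-form LG quantile function
#' evaluated at the fitted \eqn{(\hat\theta, \hat p)}.
#'
#' @param x an \code{\link{fit_lg}} object.
#' @param probs probabilities in (0, 1).
#' @param ... ignored.
#' @export
quantile.lg_fit <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), ...) {
  q <- qlgeo(probs, x$theta, x$p)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  q
}

#' @export
simulate.lg_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rlgeo(nsim, object$theta, object$p)
}

#' Goodness-of-fit statistics for a fitted Lindley-Geometric model
#'
#' One-sample EDF statistics of the data against the fitted cdf
#' \eqn{\hat F}, using the standard definitions on the order statistics
#' \eqn{x_{(1)} \le \dots \le x_{(n)}}:
#' Kolmogorov-Smirnov
#' \eqn{D = \max_i \max(i/n - \hat F(x_{(i)}), \hat F(x_{(i)}) - (i-1)/n)},
#' Cramer-von Mises
#' \eqn{W^2 = \frac{1}{12n} + \sum_i (\hat F(x_{(i)}) - \frac{2i-1}{2n})^2},
#' Anderson-Darling
#' \eqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)[\log \hat F(x_{(i)}) +
#'   \log(1-\hat F(x_{(n+1-i)}))]},
#' plus AIC and BIC with 2 estimated parameters. Fitted cdf values are
#' clamped away from 0 and 1 by 1e-15 before the AD logarithms.
#'
#' @param fit an \code{\link{fit_lg}} object (must have converged).
#' @return a list with components \code{ks}, \code{cvm}, \code{ad},
#'   \code{aic}, \code{bic}.
#' @export
gof_lg <- function(fit) {
  stopifnot(inherits(fit, "lg_fit"))
  if (!fit$converged) stop("goodness of fit requires a converged fit", call. = FALSE)
  xs <- sort(fit$data)
  n <- length(xs)
  Fh <- plgeo(xs, fit$theta, fit$p)
  i <- seq_len(n)
  ks <- max(pmax(i / n - Fh, Fh - (i - 1) / n))
  cvm <- 1 / (12 * n) + sum((Fh - (2 * i - 1) / (2 * n))^2)
  Fc <- pmin(pmax(Fh, 1e-15), 1 - 1e-15)
  ad <- -n - sum((2 * i - 1) * (log(Fc) + log1p(-rev(Fc)))) / n
  list(ks = ks, cvm = cvm, ad = ad,
       aic = -2 * fit$loglik + 4,
       bic = -2 * fit$loglik + 2 * log(n))
}

#' @export
summary.lg_fit <- function(object, ...) {
  structure(c(unclass(object), list(gof = gof_lg(object))),
            class = "summary.lg_fit")
}

#' @export
print.summary.lg_fit <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  print.lg_fit(x, digits = digits)
  g <- x$gof
  cat(sprintf("  AIC = %s, BIC = %s\n",
              format(g$aic, digits = digits), format(g$bic, digits = digits)))
  cat(sprintf("  KS = %s, Cramer-von Mises = %s, Anderson-Darling = %s\n",
              format(g$ks, digits = digits), format(g$cvm, digits = digits),
              format(g$ad, digits = digits)))
  invisible(x)
}

#' @export
plot.lg_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$data, freq = FALSE, main = "Histogram + fitted density",
                 xlab = "x", col = "grey90", border = "grey60")
  grid <- seq(1e-6, max(x$data) * 1.05, length.out = 400)
  graphics::lines(grid, dlgeo(grid, x$theta, x$p), col = "steelblue", lwd = 2)
  n <- x$n
  qq <- qlgeo((seq_len(n) - 0.5) / n, x$theta, x$p)
  graphics::plot(qq, sort(x$data), main = "Q-Q plot",
                 xlab = "theoretical quantiles", ylab = "sample quantiles")
  graphics::abline(0, 1, col = "steelblue")
  invisible(x)
}
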