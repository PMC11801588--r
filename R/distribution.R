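#' The Lindley-Geometric distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the two-parameter Lindley-Geometric (LG) lifetime distribution with
#' rate-like shape parameter \code{theta} and concentration parameter
#' \code{p}. The LG model compounds a Lindley distribution with a geometric
#' number of latent components; at \code{p = 0} it reduces to the Lindley
#' distribution, and as \code{p} approaches 1 the mass concentrates at zero.
#'
#' The density is
#' \deqn{f(y) = \frac{\theta^2}{\theta+1}(1-p)(1+y)e^{-\theta y}
#'   \left[1 - p\left(1 + \frac{\theta y}{\theta+1}\right)e^{-\theta y}\right]^{-2},}
#' and the cdf
#' \deqn{F(y) = \frac{1 - (1 + \theta y/(\theta+1))e^{-\theta y}}
#'   {1 - p(1 + \theta y/(\theta+1))e^{-\theta y}},\qquad y \ge 0.}
#' The quantile function inverts \eqn{F} in closed form through the lower
#' branch of the Lambert W function (\code{\link{lambert_wm1}}):
#' \deqn{Q(u) = \frac{-W_{-1}\!\left(\frac{-(u-1)(\theta+1)e^{-(\theta+1)}}{pu-1}\right)
#'   - (\theta+1)}{\theta}.}
#' Random generation is by inverse transform: a Uniform(0,1) draw is pushed
#' through \eqn{Q}.
#'
#' The density is decreasing on its support when
#' \eqn{p > (1-\theta^2)/(1+\theta^2)} and unimodal otherwise
#' (see \code{\link{lg_shape}}).
#'
#' @param x,q vector of quantiles. Values below 0 are outside the support
#'   and get density 0 / cdf 0.
#' @param u vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param theta shape parameter, \eqn{\theta > 0} (scalar).
#' @param p concentration parameter, \eqn{0 \le p < 1} (scalar). \code{p = 0}
#'   gives the Lindley sub-model; \code{p = 1} is rejected as degenerate.
#' @param log,log.p logical; if TRUE, probabilities/densities are returned
#'   on the log scale.
#' @return \code{dlgeo} gives the density, \code{plgeo} the distribution
#'   function, \code{qlgeo} the quantile function and \code{rlgeo} generates
#'   random deviates.
#' @seealso \code{\link{lg_moment}}, \code{\link{fit_lg}}
#' @examples
#' dlgeo(1, theta = 0.25, p = 0.25)
#' plgeo(qlgeo(0.3, 0.25, 0.25), 0.25, 0.25)  # 0.3
#' set.seed(1); rlgeo(5, 0.5, 0.5)
#' @name lgeo
NULL

check_lg_params <- function(theta, p) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    stop("'p' must be a single number in [0, 1); p = 1 is degenerate at zero",
         call. = FALSE)
  invisible(TRUE)
}

# shared kernel g(y) = (1 + theta*y/(theta+1)) * exp(-theta*y), in (0, 1] on y >= 0
lg_kernel <- function(y, theta) (1 + theta * y / (theta + 1)) * exp(-theta * y)

#' @rdname lgeo
#' @export
dlgeo <- function(x, theta, p, log = FALSE) {
  check_lg_params(theta, p)
  d <- rep(if (log) -Inf else 0, length(x))
  ok <- !is.na(x) & x >= 0
  d[is.na(x)] <- NA_real_
  if (any(ok)) {
    y <- x[ok]
    g <- lg_kernel(y, theta)
    ld <- 2 * log(theta) - log(theta + 1) + log1p(-p) + log1p(y) -
      theta * y - 2 * log1p(-p * g)
    d[ok] <- if (log) ld else exp(ld)
  }
  d
}

#' @rdname lgeo
#' @export
plgeo <- function(q, theta, p, log.p = FALSE) {
  check_lg_params(theta, p)
  pr <- rep(0, length(q))
  pr[is.na(q)] <- NA_real_
  ok <- !is.na(q) & q >= 0
  if (any(ok)) {
    g <- lg_kernel(q[ok], theta)
    pr[ok] <- (1 - g) / (1 - p * g)
  }
  if (log.p) log(pr) else pr
}

#' @rdname lgeo
#' @export
qlgeo <- function(u, theta, p) {
  check_lg_params(theta, p)
  if (!is.numeric(u) || any(!is.na(u) & (u <= 0 | u >= 1)))
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  arg <- -(u - 1) * (theta + 1) * exp(-(theta + 1)) / (p * u - 1)
  (-lambert_wm1(arg) - (theta + 1)) / theta
}

#' @rdname lgeo
#' @export
rlgeo <- function(n, theta, p) {
  check_lg_params(theta, p)
  qlgeo(stats::runif(n), theta, p)
}

#' Raw moments of the Lindley-Geometric distribution
#'
#' Evaluates \eqn{E[Y^r]} for an LG(\eqn{\theta}, \eqn{p}) variable by its
#' convergent double series: the squared geometric denominator of the
#' density is expanded as \eqn{\sum_j (j+1) p^j g(y)^j} and the binomial
#' theorem applied to \eqn{(1+\theta y/(\theta+1))^j}, giving
#' \deqn{E[Y^r] = \frac{\theta^2(1-p)}{\theta+1} \sum_{j\ge 0}\sum_{i=0}^{j}
#'   \binom{j}{i}(j+1)p^j \left(\frac{\theta}{\theta+1}\right)^{i}
#'   \frac{\Gamma(r+i+1)}{(\theta(j+1))^{r+i+1}}
#'   \left(1 + \frac{r+i+1}{\theta(j+1)}\right).}
#' The \eqn{p^j} weight makes the outer sum geometrically convergent for
#' \eqn{p < 1}; the sum is truncated once an outer term falls below
#' \code{tol} in absolute value. Inner terms are accumulated in log space
#' so large series indices do not overflow the Gamma factors.
#'
#' @param r moment order, a positive integer.
#' @param theta,p LG parameters (see \code{\link{lgeo}}); requires
#'   \code{p < 1}.
#' @param tol absolute truncation tolerance for the outer series term.
#' @param max_terms cap on the number of outer terms; exceeding it without
#'   meeting \code{tol} is an error (reporting the partial sum).
#' @return the raw moment \eqn{E[Y^r]}, a positive number.
#' @examples
#' lg_moment(1, theta = 0.5, p = 0)   # Lindley mean (theta+2)/(theta*(theta+1))
#' lg_moment(2, 0.25, 0.25) - lg_moment(1, 0.25, 0.25)^2  # variance
#' @export
lg_moment <- function(r, theta, p, tol = 1e-12, max_terms = 10000L) {
  check_lg_params(theta, p)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != floor(r))
    stop("'r' must be a positive integer", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive", call. = FALSE)
  pref <- theta^2 * (1 - p) / (theta + 1)
  total <- 0
  for (j in 0:max_terms) {
    pj <- if (j == 0) 1 else p^j
    i <- 0:j
    lt <- lchoose(j, i) + i * (log(theta) - log(theta + 1)) +
      lgamma(r + i + 1) - (r + i + 1) * log(theta * (j + 1)) +
      log1p((r + i + 1) / (theta * (j + 1)))
    mx <- max(lt)
    inner <- exp(mx) * sum(exp(lt - mx))
    term <- pref * (j + 1) * pj * inner
    if (j == 0 && p == 0) return(term)
    total <- total + term
    if (j > 0 && term < tol) return(total)
  }
  stop(sprintf("moment series not converged in %d terms; partial sum %.10g",
               max_terms, total), call. = FALSE)
}

#' Shape classification of the Lindley-Geometric density
#'
#' The LG density is strictly decreasing on \eqn{[0, \infty)} exactly when
#' \eqn{p > (1-\theta^2)/(1+\theta^2)}, and unimodal with an interior mode
#' otherwise.
#'
#' @inheritParams lg_moment
#' @return \code{"decreasing"} or \code{"unimodal"}.
#' @examples
#' lg_shape(0.25, 0.25)  # unimodal
#' lg_shape(3, 0.5)      # decreasing
#' @export
lg_shape <- function(theta, p) {
  check_lg_params(theta, p)
  if (p > (1 - theta^2) / (1 + theta^2)) "decreasing" else "unimodal"
}
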