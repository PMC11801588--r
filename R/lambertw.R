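#' Lower real branch of the Lambert W function
#'
#' Computes \eqn{W_{-1}(x)}, the lower real branch of the inverse of
#' \eqn{w e^w}, for arguments in \eqn{[-e^{-1}, 0)}. This branch maps its
#' domain onto \eqn{(-\infty, -1]} and is the one needed to invert the
#' Lindley-Geometric cdf in closed form.
#'
#' Evaluation uses the standard branch-point series (near \eqn{-e^{-1}})
#' or the asymptotic expansion in \eqn{\log(-x)} (near 0) as the initial
#' guess, refined by Halley iteration to full double precision.
#' Arguments that fall below \eqn{-e^{-1}} by no more than \code{1e-12}
#' (floating-point round-off from upstream arithmetic) are clamped onto
#' the branch point; anything further outside the domain yields \code{NaN}.
#'
#' @param x numeric vector of arguments in \eqn{[-e^{-1}, 0)}.
#' @return numeric vector of the same length, values in \eqn{(-\infty, -1]}.
#' @examples
#' lambert_wm1(-0.2) * exp(lambert_wm1(-0.2))  # recovers -0.2
#' lambert_wm1(-exp(-1))                        # branch point: -1
#' @export
lambert_wm1 <- function(x) {
  stopifnot(is.numeric(x))
  w <- rep(NaN, length(x))
  bp <- -exp(-1)
  x <- ifelse(x < bp & x >= bp - 1e-12, bp, x)
  ok <- !is.na(x) & x >= bp & x < 0
  if (!any(ok)) return(w)
  xv <- x[ok]
  wv <- numeric(length(xv))

  # initial guess: branch-point series for x close to -1/e, log asymptotics
  # toward 0- (crossover at -0.27 keeps both expansions in their good range)
  near <- xv > -0.27
  if (any(!near)) {
    q <- -sqrt(2 * (1 + exp(1) * xv[!near]))
    wv[!near] <- -1 + q - q^2 / 3 + 11 * q^3 / 72
  }
  if (any(near)) {
    L1 <- log(-xv[near])
    L2 <- log(-L1)
    wv[near] <- L1 - L2 + L2 / L1
  }

  # the branch point itself needs no iteration (and Halley's denominator
  # vanishes at w = -1)
  at_bp <- xv == bp
  wv[at_bp] <- -1
  for (iter in 1:50) {
    e <- exp(wv)
    f <- wv * e - xv
    # Halley step
    step <- f / (e * (wv + 1) - (wv + 2) * f / (2 * (wv + 1)))
    step[at_bp | !is.finite(step)] <- 0
    wv <- wv - step
    if (all(abs(step) < 1e-13 * (1 + abs(wv)))) break
  }
  w[ok] <- wv
  w
}
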