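#' Plug-in percentile estimate for one subgroup
#'
#' Fits the LG distribution to a single subgroup by maximum likelihood and
#' returns the closed-form quantile of the fitted distribution at
#' probability \code{u} -- the statistic plotted on the percentile control
#' chart.
#'
#' @param x numeric vector of positive observations (one subgroup, n >= 3).
#' @param u monitored percentile, in (0, 1).
#' @param ... passed to \code{\link{fit_lg}}.
#' @return the estimated 100u-th percentile, a positive number.
#' @examples
#' subgroup_qhat(c(0.540, 0.507, 0.466, 0.047, 0.334), u = 0.05)
#' @export
subgroup_qhat <- function(x, u = 0.05, ...) {
  fit <- fit_lg(x, ...)
  unname(quantile(fit, u))
}

check_subgroups <- function(subgroups) {
  subgroups <- as.matrix(subgroups)
  if (!is.numeric(subgroups) || any(!is.finite(subgroups)))
    stop("subgroups must be a numeric matrix without missing values", call. = FALSE)
  if (any(subgroups <= 0))
    stop("subgroups must contain positive values only", call. = FALSE)
  if (ncol(subgroups) < 3L)
    stop("subgroup size n must be at least 3", call. = FALSE)
  subgroups
}

# one bootstrap percentile estimate; redraws (bounded) if the refit fails
boot_qhat <- function(n, theta, p, u, max_retries) {
  for (try in 0:max_retries) {
    xstar <- rlgeo(n, theta, p)
    fit <- tryCatch(fit_lg(xstar), error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      return(list(q = qlgeo(u, fit$theta, fit$p), retries = try))
  }
  stop(sprintf("bootstrap refit failed %d consecutive times", max_retries + 1),
       call. = FALSE)
}

#' Phase-I parametric bootstrap percentile control limits
#'
#' Constructs control limits for the 100u-th LG percentile from an
#' in-control reference sample of \code{m} subgroups of size \code{n}:
#' \enumerate{
#'   \item pool all \eqn{m \times n} observations and fit the LG MLE
#'     \eqn{(\hat\theta, \hat p)};
#'   \item \code{B} times, draw a parametric bootstrap subgroup of size
#'     \code{n} from LG(\eqn{\hat\theta, \hat p}), refit the MLE, and
#'     evaluate the fitted quantile \eqn{Q^*(u)};
#'   \item sort the \code{B} estimates; the LCL is the order statistic at
#'     rank \eqn{\lfloor (\alpha/2) B \rfloor} and the UCL the one at rank
#'     \eqn{\lfloor (1-\alpha/2) B \rfloor}.
#' }
#' A bootstrap replicate whose refit fails is redrawn (bounded retries) so
#' failed fits never contaminate the order statistics.
#'
#' @param subgroups numeric matrix, one row per subgroup (m rows of n
#'   positive observations).
#' @param u monitored percentile, in (0, 1).
#' @param alpha false-alarm rate; the default 0.0027 is the conventional
#'   Shewhart-equivalent rate. \code{floor(alpha/2 * B)} must be >= 1.
#' @param B number of bootstrap replicates (paper-scale default 10000).
#' @param seed optional integer seed for the bootstrap stream.
#' @param max_retries redraw budget per bootstrap replicate.
#' @param keep_boot if TRUE, the sorted bootstrap percentile estimates are
#'   stored in the result (component \code{q_boot}).
#' @return an object of class \code{"lg_limits"}: list with \code{lcl},
#'   \code{ucl}, \code{u}, \code{alpha}, \code{B}, \code{n},
#'   \code{theta_hat}, \code{p_hat}, \code{retries}.
#' @examples
#' set.seed(7)
#' sg <- lg_simulate_subgroups(m = 25, n = 5, theta = 0.25, p = 0.25)
#' lg_phase1_limits(sg, u = 0.05, alpha = 0.0027, B = 500)
#' @export
lg_phase1_limits <- function(subgroups, u = 0.05, alpha = 0.0027, B = 10000,
                             seed = NULL, max_retries = 20L, keep_boot = FALSE) {
  subgroups <- check_subgroups(subgroups)
  if (!is.numeric(u) || length(u) != 1L || u <= 0 || u >= 1)
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
  lo <- floor(alpha / 2 * B)
  hi <- floor((1 - alpha / 2) * B)
  if (lo < 1)
    stop("alpha/2 * B < 1: no bootstrap order statistic below the LCL rank; ",
         "increase B or alpha", call. = FALSE)
  n <- ncol(subgroups)
  m <- nrow(subgroups)
  if (m * n < 20)
    warning("pooled sample has fewer than 20 observations; ",
            "phase-I parameter estimates may be unstable")
  if (!is.null(seed)) set.seed(seed)
  pooled_fit <- fit_lg(as.numeric(subgroups))
  qs <- numeric(B)
  retries <- 0L
  for (b in seq_len(B)) {
    bq <- boot_qhat(n, pooled_fit$theta, pooled_fit$p, u, max_retries)
    qs[b] <- bq$q
    retries <- retries + bq$retries
  }
  qs <- sort(qs)
  structure(list(lcl = qs[lo], ucl = qs[hi], u = u, alpha = alpha, B = B,
                 n = n, m = m, theta_hat = pooled_fit$theta,
                 p_hat = pooled_fit$p, retries = retries,
                 q_boot = if (keep_boot) qs else NULL),
            class = "lg_limits")
}

#' Bootstrap percentile limits from known LG parameters
#'
#' Runs the bootstrap stages of the limit construction -- draw a subgroup
#' of size \code{n} from LG(theta, p), refit, evaluate the fitted
#' percentile, repeat \code{B} times, take the order statistics at the
#' \code{alpha} ranks -- directly from the given parameters, without
#' simulating or refitting a phase-I pool. With \code{k > 1} the
#' construction is repeated and the limits averaged. This is the right
#' phase-I builder when the in-control parameters are already estimated
#' (or known): for a worked example, fit the pooled reference sample once
#' with \code{\link{fit_lg}} and hand the estimates to this function.
#'
#' @param theta,p LG parameters the bootstrap subgroups are drawn from.
#' @param n subgroup size.
#' @inheritParams lg_phase1_limits
#' @param k constructions to average (1 = a single run).
#' @return an \code{\link{lg_limits}} object (averaged over \code{k}).
#' @examples
#' lg_boot_limits(0.9136, 0.3792, n = 5, u = 0.05, alpha = 0.05, B = 200,
#'                seed = 1)
#' @export
lg_boot_limits <- function(theta, p, n, u = 0.05, alpha = 0.0027, B = 10000,
                           k = 1, seed = NULL, max_retries = 20L) {
  check_lg_params(theta, p)
  lo <- floor(alpha / 2 * B)
  hi <- floor((1 - alpha / 2) * B)
  if (lo < 1)
    stop("alpha/2 * B < 1: no bootstrap order statistic below the LCL rank; ",
         "increase B or alpha", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lcl <- ucl <- numeric(k)
  for (i in seq_len(k)) {
    qs <- vapply(seq_len(B), function(b)
      boot_qhat(n, theta, p, u, max_retries)$q, numeric(1))
    qs <- sort(qs)
    lcl[i] <- qs[lo]
    ucl[i] <- qs[hi]
  }
  lim <- lg_limits(mean(lcl), mean(ucl), u = u, alpha = alpha)
  lim$B <- B
  lim$n <- n
  lim$theta_hat <- theta
  lim$p_hat <- p
  lim
}

#' Construct an lg_limits object from known limit values
#'
#' Wraps externally obtained control limits (for example published values,
#' or the averaged limits of a simulation study) so they can be passed to
#' \code{\link{lg_monitor}} and \code{\link{lg_run_length}}.
#'
#' @param lcl,ucl lower and upper control limits, 0 < lcl < ucl.
#' @param u,alpha the percentile and false-alarm rate the limits refer to.
#' @return an object of class \code{"lg_limits"}.
#' @export
lg_limits <- function(lcl, ucl, u = 0.05, alpha = 0.0027) {
  if (!is.numeric(lcl) || !is.numeric(ucl) || lcl < 0 || ucl <= lcl)
    stop("need 0 <= lcl < ucl", call. = FALSE)
  structure(list(lcl = lcl, ucl = ucl, u = u, alpha = alpha),
            class = "lg_limits")
}

#' @export
print.lg_limits <- function(x, digits = 6, ...) {
  cat(sprintf("LG percentile control limits (u = %g, alpha = %g)\n", x$u, x$alpha))
  cat(sprintf("  LCL = %s, UCL = %s\n",
              format(x$lcl, digits = digits), format(x$ucl, digits = digits)))
  if (!is.null(x$theta_hat))
    cat(sprintf("  phase-I fit: theta = %s, p = %s (m = %d, n = %d, B = %d)\n",
                format(x$theta_hat, digits = digits),
                format(x$p_hat, digits = digits), x$m, x$n, x$B))
  invisible(x)
}

#' Monte-Carlo summary of the bootstrap limit construction
#'
#' Repeats the whole phase-I construction \code{k} times -- each repetition
#' simulates \code{m} fresh subgroups of size \code{n} from LG(theta, p)
#' and runs \code{\link{lg_phase1_limits}} -- and summarises the limits by
#' their means (MLCL, MUCL) and standard deviations (SDLCL, SDUCL) across
#' repetitions. This is the design behind the published average-limit
#' tables; the averaged limits are also the recommended phase-I limits for
#' a worked example where a single bootstrap run is considered too noisy.
#'
#' @param theta,p in-control LG parameters.
#' @param n subgroup size; \code{m} number of subgroups per repetition.
#' @param u,alpha,B as in \code{\link{lg_phase1_limits}}.
#' @param k number of Monte-Carlo repetitions (paper-scale default 100).
#' @param seed optional master seed; each repetition gets a child seed
#'   derived from it so results are reproducible and prefix-stable in
#'   \code{k}.
#' @return an object of class \code{"lg_limit_summary"}: list with
#'   \code{mlcl}, \code{sdlcl}, \code{mucl}, \code{sducl}, \code{k},
#'   the per-repetition \code{lcl}/\code{ucl} vectors, and \code{limits},
#'   an \code{\link{lg_limits}} object holding the averaged limits.
#' @export
lg_limit_summary <- function(theta, p, n, m = 25, u = 0.05, alpha = 0.0027,
                             B = 10000, k = 100, seed = NULL) {
  check_lg_params(theta, p)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, k)
  lcl <- ucl <- numeric(k)
  for (i in seq_len(k)) {
    set.seed(rep_seeds[i])
    sg <- matrix(rlgeo(m * n, theta, p), nrow = m, ncol = n)
    lim <- lg_phase1_limits(sg, u = u, alpha = alpha, B = B)
    lcl[i] <- lim$lcl
    ucl[i] <- lim$ucl
  }
  structure(list(mlcl = mean(lcl), sdlcl = stats::sd(lcl),
                 mucl = mean(ucl), sducl = stats::sd(ucl),
                 k = k, lcl = lcl, ucl = ucl,
                 limits = lg_limits(mean(lcl), mean(ucl), u = u, alpha = alpha)),
            class = "lg_limit_summary")
}

#' @export
print.lg_limit_summary <- function(x, digits = 6, ...) {
  cat(sprintf("Bootstrap limit summary over k = %d repetitions\n", x$k))
  cat(sprintf("  MLCL = %s (SD %s)\n", format(x$mlcl, digits = digits),
              format(x$sdlcl, digits = digits)))
  cat(sprintf("  MUCL = %s (SD %s)\n", format(x$mucl, digits = digits),
              format(x$sducl, digits = digits)))
  invisible(x)
}

#' Phase-II monitoring of subgroup percentile estimates
#'
#' Computes the plug-in percentile estimate \eqn{\hat Q(u)} for each new
#' subgroup and classifies it against the phase-I control limits: below
#' the LCL, above the UCL, or in control. A subgroup whose MLE fit fails
#' even after restarts is flagged \code{unresolvable} rather than silently
#' passed as in-control.
#'
#' @param subgroups numeric matrix of phase-II subgroups (rows).
#' @param limits an \code{\link{lg_limits}} object.
#' @param u monitored percentile; defaults to the one the limits were
#'   built for. A warning is issued if the subgroup size differs from the
#'   phase-I size recorded in \code{limits}.
#' @return an object of class \code{"lg_chart"}: a data.frame with columns
#'   \code{index}, \code{qhat}, \code{status}, carrying the limits as an
#'   attribute. \code{plot()} draws the control chart.
#' @examples
#' lim <- lg_limits(0.003753354, 0.2262595, u = 0.05)
#' chart <- lg_monitor(lg_phase2_data(), lim)
#' chart
#' @export
lg_monitor <- function(subgroups, limits, u = limits$u) {
  stopifnot(inherits(limits, "lg_limits"))
  subgroups <- check_subgroups(subgroups)
  if (!is.null(limits$n) && ncol(subgroups) != limits$n)
    warning(sprintf("subgroup size %d differs from phase-I size %d",
                    ncol(subgroups), limits$n))
  m <- nrow(subgroups)
  qhat <- rep(NA_real_, m)
  status <- character(m)
  for (i in seq_len(m)) {
    q <- tryCatch(subgroup_qhat(subgroups[i, ], u), error = function(e) NULL)
    if (is.null(q)) {
      status[i] <- "unresolvable"
    } else {
      qhat[i] <- q
      status[i] <- if (q < limits$lcl) "out_of_control_low"
        else if (q > limits$ucl) "out_of_control_high"
        else "in_control"
    }
  }
  out <- data.frame(index = seq_len(m), qhat = qhat, status = status)
  structure(out, limits = limits, u = u,
            class = c("lg_chart", "data.frame"))
}

#' @export
print.lg_chart <- function(x, ...) {
  lim <- attr(x, "limits")
  cat(sprintf("LG percentile control chart (u = %g): %d subgroups, %d signal(s)\n",
              attr(x, "u"), nrow(x), sum(x$status != "in_control")))
  cat(sprintf("  LCL = %g, UCL = %g\n", lim$lcl, lim$ucl))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.lg_chart <- function(x, ...) {
  lim <- attr(x, "limits")
  ooc <- x$status != "in_control"
  ylim <- range(c(x$qhat, lim$lcl, lim$ucl), na.rm = TRUE)
  graphics::plot(x$index, x$qhat, type = "b", pch = ifelse(ooc, 19, 1),
                 col = ifelse(ooc, "firebrick", "black"),
                 xlab = "subgroup", ylab = sprintf("Q(%g) estimate", attr(x, "u")),
                 ylim = ylim, main = "Bootstrap percentile control chart", ...)
  graphics::abline(h = c(lim$lcl, lim$ucl), lty = 2, col = "steelblue")
  invisible(x)
}
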