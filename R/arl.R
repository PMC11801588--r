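#' Run length of the percentile chart under a given process state
#'
#' Simulates subgroups of size \code{n} from LG(theta, p), computes the
#' plug-in percentile estimate for each, and counts subgroups until the
#' first estimate falls outside the control limits. The count includes the
#' signalling subgroup. If no signal occurs within \code{cap} subgroups
#' the run is censored at \code{cap}.
#'
#' @param limits an \code{\link{lg_limits}} object.
#' @param theta,p parameters of the process generating phase-II subgroups
#'   (shifted values for an out-of-control run).
#' @param n subgroup size.
#' @param u monitored percentile (defaults to the limits' percentile).
#' @param cap maximum run length before censoring.
#' @return integer run length, with attribute \code{censored} (logical).
#' @export
lg_run_length <- function(limits, theta, p, n, u = limits$u, cap = 1e6) {
  stopifnot(inherits(limits, "lg_limits"), cap >= 1)
  check_lg_params(theta, p)
  rl <- 0L
  repeat {
    rl <- rl + 1L
    q <- subgroup_qhat(rlgeo(n, theta, p), u)
    if (q < limits$lcl || q > limits$ucl)
      return(structure(rl, censored = FALSE))
    if (rl >= cap) return(structure(as.integer(cap), censored = TRUE))
  }
}

#' Average run length of the bootstrap percentile chart
#'
#' Monte-Carlo estimate of the ARL and SDRL. Each replication re-enacts
#' the full chart construction: \code{m} in-control subgroups of size
#' \code{n} are simulated from \code{(theta_in, p_in)}, one set of
#' parametric bootstrap limits is built from them, and the run length is
#' then measured on subgroups simulated from \code{(theta_out, p_out)}
#' (equal to the in-control parameters for the in-control ARL).
#' Alternatively a fixed, precomputed set of limits can be supplied via
#' \code{limits}, in which case the phase-I stage is skipped -- this is
#' how the sensitivity curves hold the chart fixed while the process
#' shifts.
#'
#' @param theta_in,p_in in-control LG parameters.
#' @param theta_out,p_out process parameters during monitoring; default to
#'   the in-control values.
#' @param n subgroup size; \code{m} number of phase-I subgroups.
#' @param u,alpha,B chart construction settings
#'   (see \code{\link{lg_phase1_limits}}).
#' @param reps number of Monte-Carlo replications (paper-scale 1000).
#' @param cap run-length censoring cap.
#' @param limits optional fixed \code{\link{lg_limits}}; skips phase I.
#' @param seed optional master seed; child seeds are derived per
#'   replication, so increasing \code{reps} extends rather than reshuffles
#'   the replication stream.
#' @return an object of class \code{"lg_arl"}: list with \code{arl},
#'   \code{sdrl}, \code{reps}, \code{censored} (count of capped runs) and
#'   the vector of run lengths.
#' @examples
#' lg_arl(0.25, 0.25, n = 4, u = 0.05, B = 200, reps = 5, seed = 1)
#' @export
lg_arl <- function(theta_in, p_in, theta_out = theta_in, p_out = p_in,
                   n = 5, m = 25, u = 0.05, alpha = 0.0027, B = 10000,
                   reps = 1000, cap = 1e6, limits = NULL, seed = NULL) {
  check_lg_params(theta_in, p_in)
  check_lg_params(theta_out, p_out)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  rl <- integer(reps)
  cens <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    lim <- limits
    if (is.null(lim)) {
      sg <- matrix(rlgeo(m * n, theta_in, p_in), nrow = m, ncol = n)
      lim <- lg_phase1_limits(sg, u = u, alpha = alpha, B = B)
    }
    r <- lg_run_length(lim, theta_out, p_out, n = n, u = u, cap = cap)
    rl[i] <- r
    cens[i] <- attr(r, "censored")
  }
  structure(list(arl = mean(rl), sdrl = stats::sd(rl), reps = reps,
                 censored = sum(cens), run_lengths = rl),
            class = "lg_arl")
}

#' @export
print.lg_arl <- function(x, digits = 5, ...) {
  cat(sprintf("ARL = %s, SDRL = %s  (%d replications, %d censored)\n",
              format(x$arl, digits = digits), format(x$sdrl, digits = digits),
              x$reps, x$censored))
  invisible(x)
}

#' Sensitivity of the chart's ARL to distribution parameters
#'
#' Quantifies how mis-specification or drift in one quantity affects the
#' time to signal. For \code{vary = "theta"} or \code{"p"}, a single set
#' of base control limits is built from the in-control distribution
#' (averaged over \code{k} bootstrap constructions), and the ARL is then
#' estimated at each grid value with the varied parameter shifted and the
#' other held at its base value. For \code{vary = "u"}, the limits are
#' rebuilt at each monitored percentile and the ARL measured under the
#' fixed shift \code{shift_to} -- here the percentile choice, not the
#' process, is what varies.
#'
#' Defaults mirror a conventional study design: subgroups of 5,
#' \code{alpha} = 0.0027, monitored percentile 0.1, base distribution
#' LG(0.5, 0.5).
#'
#' @param vary which quantity the grid sweeps: "theta", "p" or "u".
#' @param grid numeric vector of values for the varied quantity.
#' @param theta,p base (in-control) LG parameters.
#' @param n,u,alpha,B,k chart construction settings; \code{k} repetitions
#'   are averaged into the base limits.
#' @param shift_to length-2 vector (theta, p) of the shifted process used
#'   when \code{vary = "u"}.
#' @param reps,cap,seed Monte-Carlo controls as in \code{\link{lg_arl}}.
#' @return a data.frame with one row per grid value: the varied value,
#'   \code{arl}, \code{sdrl}, \code{reps}, \code{censored}.
#' @export
lg_sensitivity <- function(vary = c("p", "theta", "u"), grid,
                           theta = 0.5, p = 0.5, n = 5, u = 0.1,
                           alpha = 0.0027, B = 10000, k = 100,
                           shift_to = c(0.75, 0.25),
                           reps = 1000, cap = 1e6, seed = NULL) {
  vary <- match.arg(vary)
  if (!is.null(seed)) set.seed(seed)
  base_seed <- sample.int(.Machine$integer.max - 1L, 1)
  grid_seeds <- sample.int(.Machine$integer.max - 1L, length(grid))
  rows <- vector("list", length(grid))
  if (vary != "u") {
    base <- lg_limit_summary(theta, p, n = n, u = u, alpha = alpha,
                             B = B, k = k, seed = base_seed)$limits
  }
  for (i in seq_along(grid)) {
    v <- grid[[i]]
    if (vary == "u") {
      lim <- lg_limit_summary(theta, p, n = n, u = v, alpha = alpha,
                              B = B, k = k, seed = base_seed)$limits
      res <- lg_arl(theta, p, shift_to[1], shift_to[2], n = n, u = v,
                    limits = lim, reps = reps, cap = cap,
                    seed = grid_seeds[i])
    } else {
      th_out <- if (vary == "theta") v else theta
      p_out <- if (vary == "p") v else p
      res <- lg_arl(theta, p, th_out, p_out, n = n, u = u, limits = base,
                    reps = reps, cap = cap, seed = grid_seeds[i])
    }
    rows[[i]] <- data.frame(value = v, arl = res$arl, sdrl = res$sdrl,
                            reps = res$reps, censored = res$censored)
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- vary
  out
}
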