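#' Sinusoidal influx drive
#'
#' \eqn{k_{in}(t) = A_{in}\cos(2\pi f t) + k_{in0}}.  The drive must keep the
#' influx non-negative (\code{kin0 >= Ain}).
#'
#' @param t time (vectorised).
#' @param Ain drive amplitude (rate units, >= 0).
#' @param f drive frequency (> 0).
#' @param kin0 mean influx rate.
#' @return The influx rate at \code{t}.
#' @export
ccc_drive <- function(t, Ain, f, kin0) {
  stopifnot(Ain >= 0, f > 0, kin0 - Ain >= -1e-12)
  Ain * cos(2 * pi * f * t) + kin0
}

#' Amplitude response of the driven cascade
#'
#' Integrates the five-ODE model under the sinusoidal drive, discards the
#' transient cycles, and returns the swing (max - min) of the free active
#' carrier over the measurement cycles.  Because the slow variable m0 relaxes
#' on the leak timescale 1/kleak, the transient is floored at
#' \code{10 / kleak} time units regardless of the cycle count.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak > 0} (the driven
#'   cascade is unbounded for kleak = 0 when the drive exceeds capacity).
#' @param Ain,f,kin0 drive specification (see \code{\link{ccc_drive}}).
#' @param state0 initial state (default: all carrier active, pool 2).
#' @param n_transient_cycles,n_measure_cycles cycles discarded / measured.
#' @param samples_per_cycle output samples per drive period (>= 64).
#' @return The swing of \[c\] (a single non-negative number).
#' @export
amplitude_response <- function(params, Ain, f, kin0,
                               state0 = ccc_state(c = 2),
                               n_transient_cycles = 5, n_measure_cycles = 5,
                               samples_per_cycle = 64) {
  if (params$kleak <= 0) stop("amplitude_response requires kleak > 0")
  samples_per_cycle <- max(samples_per_cycle, 64)
  period <- 1 / f
  t_trans <- max(n_transient_cycles * period, 10 / params$kleak)
  t_trans <- ceiling(t_trans / period) * period  # whole cycles
  t_end <- t_trans + n_measure_cycles * period
  tr <- ccc_integrate(params, state0, t_end = t_end,
                      sample_dt = period / samples_per_cycle,
                      model = "reduced5",
                      kin_fun = function(t) ccc_drive(t, Ain, f, kin0))
  cwin <- tr$c[tr$time >= t_trans]
  max(cwin) - min(cwin)
}

#' Response map over drive amplitudes and frequencies
#'
#' Fills a matrix of active-carrier swings over an (Ain, f) grid and attaches
#' the analytic cut-off frequency per amplitude
#' (\code{\link{cutoff_frequency}}).  Cells whose integration fails are
#' flagged \code{NA} rather than aborting the map.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak > 0}.
#' @param Ain_values,f_values grid (nonempty).
#' @param kin0 mean influx rate.
#' @param cpool,csum conserved pools used for the analytic cut-off curve
#'   (defaults match the default initial state of
#'   \code{\link{amplitude_response}}).
#' @param ... passed to \code{\link{amplitude_response}}.
#' @return List of class \code{ccc_response_map}: \code{response} (rows = f,
#'   columns = Ain), \code{Ain_values}, \code{f_values}, \code{cutoff_curve}.
#' @export
response_map <- function(params, Ain_values, f_values, kin0,
                         cpool = 2, csum = 2, ...) {
  stopifnot(length(Ain_values) > 0, length(f_values) > 0)
  resp <- matrix(NA_real_, length(f_values), length(Ain_values),
                 dimnames = list(format(f_values, digits = 4),
                                 format(Ain_values, digits = 4)))
  for (j in seq_along(Ain_values))
    for (i in seq_along(f_values))
      resp[i, j] <- tryCatch(
        amplitude_response(params, Ain_values[j], f_values[i], kin0, ...),
        error = function(e) NA_real_)
  kth <- kin_threshold(ccc_update(params, kleak = 0), cpool = cpool, csum = csum)
  cut <- vapply(Ain_values, function(a)
    tryCatch(cutoff_frequency(params, a, kin0, kth), error = function(e) NA_real_),
    numeric(1))
  structure(list(response = resp, Ain_values = Ain_values,
                 f_values = f_values, cutoff_curve = cut),
            class = "ccc_response_map")
}

#' Measured half-maximum cut-off of one response column
#'
#' The frequency at which the swing falls to half its low-frequency plateau
#' (the lowest-frequency cell), located by log-linear interpolation between
#' the bracketing grid frequencies.
#'
#' @param f_values frequencies (increasing).
#' @param response swings at those frequencies.
#' @return The interpolated half-maximum frequency (NA when the response
#'   never falls below half its plateau on the grid).
#' @export
half_max_cutoff <- function(f_values, response) {
  ok <- is.finite(response)
  f <- f_values[ok]; r <- response[ok]
  if (length(r) < 2) return(NA_real_)
  half <- r[1] / 2
  below <- which(r < half)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  exp(stats::approx(r[(i - 1):i], log(f[(i - 1):i]), xout = half)$y)
}

#' One-dimensional slow dynamics of the jammed cascade
#'
#' When m0 is large both catalytic steps are saturated and the cascade runs
#' at its capacity; the dynamics collapse onto the m1-nullcline and only the
#' m0 backlog evolves:
#' \deqn{\frac{d[m_0]}{dt} = k_{in}(t) - k_{leak}[m_0] -
#'       \frac{k_c k_p c_{sum}}{k_c+k_p}.}
#' For kleak = 0 this is influx minus capacity, the perfect-binding jamming
#' threshold of \code{\link{kin_threshold_limit}} (with cpool >= csum).
#'
#' @param m0 backlog concentration.
#' @param t time.
#' @param params a \code{\link{ccc_params}}.
#' @param csum conserved sum.
#' @param kin_fun influx as a function of time (defaults to the constant
#'   \code{params$kin}).
#' @return dm0/dt.
#' @export
reduced_1d_rhs <- function(m0, t, params, csum, kin_fun = NULL) {
  kin <- if (is.null(kin_fun)) params$kin else kin_fun(t)
  kin - params$kleak * m0 - params$kc * params$kp * csum / (params$kc + params$kp)
}

#' Analytic cut-off frequency of the driven cascade
#'
#' Below the cut-off the drive's low phase drains the m0 buffer within a
#' cycle and the carrier responds; above it the buffer never empties and the
#' cascade is insensitive — a low-pass filter whose corner is
#' \deqn{2\pi f_c = \frac{k_{leak} k_c A_{in}}
#'   {k_c k_{in0} - (k_c + k_{leak}) k_{in}^{th} - k_{leak} k_c}.}
#' The numerator is linear in the drive amplitude: stronger inputs pass at
#' higher frequencies.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak > 0}.
#' @param Ain drive amplitude.
#' @param kin0 mean influx rate.
#' @param kin_th the jamming threshold computed from the kleak = 0 formula
#'   (\code{\link{kin_threshold}}).
#' @return The cut-off frequency (cycles per unit time), or \code{NA} with a
#'   warning when the denominator is non-positive (outside the validity
#'   regime of the one-dimensional reduction).
#' @export
cutoff_frequency <- function(params, Ain, kin0, kin_th) {
  if (params$kleak <= 0) stop("cutoff_frequency requires kleak > 0")
  denom <- params$kc * kin0 - (params$kc + params$kleak) * kin_th -
    params$kleak * params$kc
  if (denom <= 0) {
    warning("non-positive denominator: outside the validity regime")
    return(NA_real_)
  }
  params$kleak * params$kc * Ain / denom / (2 * pi)
}
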