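#' Exact stochastic simulation of the full cascade
#'
#' Gillespie (direct-method) simulation of the nine-reaction mass-action
#' network with explicit complexes, at volume Omega = 1 so copy numbers and
#' concentrations coincide.  The carrier copy total
#' c + cm0 + c* + c*m1 is conserved exactly at every event.  Paths are
#' reproducible: the same \code{seed} gives a bit-identical event sequence.
#'
#' @param params a \code{\link{ccc_params}} (association rates \code{ka0},
#'   \code{ka1} set the binding speed; dissociation rates are
#'   \code{ka * K}).
#' @param state0 integer initial copy numbers (named as
#'   \code{\link{ccc_state}}).
#' @param t_end simulated time span.
#' @param seed RNG seed (integer); \code{NULL} leaves the RNG state alone.
#' @param track which species' path to record; the defaults
#'   \code{"m1_total"} (\code{m1 + cstarm1}) and \code{"m0_total"}
#'   (\code{m0 + cm0}) are the reduced models' metabolite variables, or any
#'   single species name.
#' @param max_events event budget; exceeding it truncates the run.
#' @return List of class \code{ccc_ssa}: \code{time}, \code{n} (the tracked
#'   species after each of its change-points), \code{t_final},
#'   \code{n_events}, \code{final_state}, \code{carrier_conserved},
#'   \code{overflow}, \code{track}.
#' @export
ssa_full <- function(params, state0, t_end, seed = NULL, track = "m1_total",
                     max_events = 5e7) {
  species <- c("m0", "m1", "m2", "c", "cstar", "cm0", "cstarm1",
               "m1_total", "m0_total")
  x0 <- as.integer(round(as.numeric(state0)[match(species[1:7], names(state0))]))
  x0[is.na(x0)] <- 0L
  if (any(x0 < 0)) stop("negative copy number")
  track_i <- match(track, species)
  if (is.na(track_i)) stop("unknown tracked species: ", track)
  if (!is.null(seed)) set.seed(seed)
  pars <- c(kin = params$kin, kleak = params$kleak, kout = params$kout,
            kc = params$kc, kp = params$kp,
            ka0 = params$ka0, kd0 = params$ka0 * params$K0,
            ka1 = params$ka1, kd1 = params$ka1 * params$K1)
  out <- ssa_full_cpp(pars, x0, t_end, track_i - 1L, max_events)
  if (out$overflow)
    warning("propensity overflow (unbounded m0 growth); run stopped early")
  names(out$final_state) <- species[1:7]
  out$track <- track
  structure(out, class = "ccc_ssa")
}

#' Perfect-binding limit model of the intermediate count
#'
#' Birth-death dynamics of the m1 copy number n in the K0, K1 -> 0 limit.
#' In the saturated (carrier-limited) regime, m0 is in excess and every
#' active carrier is bound, so production is \eqn{k_c (c_{max} - n)} — the
#' moiety conservation feeds n back onto its own production — while
#' consumption is \eqn{k_p n}.  The stationary law is
#' binomial(cmax, kc/(kc+kp)) with Fano factor \eqn{1 - k_c/(k_c+k_p)}.
#' In the unsaturated regime production is the constant influx \code{kin}
#' and the stationary law is Poisson (Fano 1).
#'
#' @param kc,kp turnover rates (> 0).
#' @param cmax carrier capacity in copies, \code{min(cpool, csum)}
#'   (saturated regime only).
#' @param kin influx rate (unsaturated regime only).
#' @param saturated logical regime switch.
#' @param n0 initial count.
#' @param t_end simulated time span.
#' @param seed RNG seed.
#' @param max_events event budget.
#' @return A \code{ccc_ssa} list (\code{time}, \code{n}, ...).
#' @examples
#' s <- ssa_limit(kc = 1, kp = 1, cmax = 20, saturated = TRUE,
#'                t_end = 200, seed = 1)
#' count_statistics(s, burn_in = 20)
#' @export
ssa_limit <- function(kc, kp, cmax = NULL, kin = NULL, saturated,
                      n0 = 0, t_end, seed = NULL, max_events = 5e7) {
  stopifnot(kc > 0, kp > 0)
  if (saturated) {
    stopifnot(!is.null(cmax), cmax >= 1, n0 <= cmax)
    kin <- 0
  } else {
    stopifnot(!is.null(kin), kin > 0)
    cmax <- 0L
  }
  if (!is.null(seed)) set.seed(seed)
  out <- ssa_limit_cpp(kc, kp, as.integer(cmax), kin, saturated,
                       as.integer(n0), t_end, max_events)
  out$track <- "m1"
  structure(out, class = "ccc_ssa")
}

#' Double Michaelis-Menten comparator without shared conservation
#'
#' The control model for the feedback claim: production and consumption of a
#' metabolite are each saturated Michaelis-Menten steps driven by two
#' *independent* carrier pools c1 and c2 (no moiety conservation links
#' them), so both rates are independent of the count n.  The count performs
#' an unbiased random walk when \code{kc*c1 == kp*c2}, drifts to zero or
#' diverges otherwise, and its ensemble Fano factor never falls below 1.
#'
#' @param kc,kp turnover rates.
#' @param c1,c2 the two carrier pool sizes (copies).
#' @param n0 initial count.
#' @param t_end simulated time span.
#' @param seed RNG seed.
#' @param max_events event budget.
#' @param n_cap report truncation when the count exceeds this bound.
#' @return A \code{ccc_ssa} list; \code{truncated} flags a capped run.
#' @export
ssa_double_mm <- function(kc, kp, c1, c2, n0, t_end, seed = NULL,
                          max_events = 5e7, n_cap = 1e7) {
  if (!is.null(seed)) set.seed(seed)
  out <- ssa_double_mm_cpp(kc, kp, c1, c2, as.integer(n0), t_end,
                           max_events, n_cap)
  out$track <- "m0"
  structure(out, class = "ccc_ssa")
}

#' General birth-death chain (tabulated rates)
#'
#' Exact simulation of a birth-death chain on \code{0..nmax} with arbitrary
#' tabulated rates; the stochastic cross-check for
#' \code{\link{master_equation_stationary}}.
#'
#' @param birth,death rate vectors over states \code{0..nmax}
#'   (\code{death[1]}, i.e. death at 0, is ignored).
#' @param n0 initial state.
#' @param t_end simulated time span.
#' @param seed RNG seed.
#' @param max_events event budget.
#' @return A \code{ccc_ssa} list.
#' @export
ssa_birth_death <- function(birth, death, n0, t_end, seed = NULL,
                            max_events = 5e7) {
  if (!is.null(seed)) set.seed(seed)
  out <- ssa_bd_cpp(birth, death, as.integer(n0), t_end, max_events)
  out$track <- "n"
  structure(out, class = "ccc_ssa")
}

#' @export
print.ccc_ssa <- function(x, ...) {
  cat(sprintf("SSA path of %s: %g events, t = [0, %g], final value %g\n",
              x$track, x$n_events, x$t_final, x$n[length(x$n)]))
  invisible(x)
}

#' Time-weighted count statistics of a stochastic path
#'
#' Mean, variance and Fano factor of a piecewise-constant molecule-count
#' path, weighting each value by its dwell time over \code{(burn_in,
#' t_final]}.  A zero mean yields an undefined (NA) Fano factor.
#'
#' @param traj a \code{ccc_ssa} path (or a list with \code{time}, \code{n},
#'   \code{t_final}).
#' @param burn_in initial time span discarded before averaging.
#' @return List of class \code{ccc_count_stats}: \code{mean},
#'   \code{variance}, \code{fano}, \code{n_samples} (change-points used),
#'   \code{burn_in_used}, \code{t_total} (averaging span).
#' @export
count_statistics <- function(traj, burn_in = 0) {
  t <- traj$time; n <- traj$n
  t_final <- if (!is.null(traj$t_final)) traj$t_final else t[length(t)]
  if (burn_in >= t_final) stop("burn_in leaves no averaging window")
  # value n[i] holds on [t[i], t[i+1]); extend the last to t_final
  t_ext <- c(t, t_final)
  lo <- pmax(t_ext[-length(t_ext)], burn_in)
  hi <- pmin(t_ext[-1], t_final)
  w <- pmax(hi - lo, 0)
  keep <- w > 0
  w <- w[keep]; nv <- n[keep]
  W <- sum(w)
  if (W <= 0) stop("empty post-burn-in window")
  m <- sum(w * nv) / W
  v <- sum(w * (nv - m)^2) / W
  structure(list(mean = m, variance = v,
                 fano = if (m > 0) v / m else NA_real_,
                 n_samples = sum(keep), burn_in_used = burn_in,
                 t_total = W),
            class = "ccc_count_stats")
}

#' @export
print.ccc_count_stats <- function(x, ...) {
  cat(sprintf("mean = %.4g, variance = %.4g, Fano = %.4g (%d change-points, t = %.4g)\n",
              x$mean, x$variance, x$fano, x$n_samples, x$t_total))
  invisible(x)
}

#' Analytic Fano factor under carrier feedback
#'
#' In the saturated regime the moiety conservation turns production into a
#' negative feedback and the stationary intermediate count is binomial; its
#' Fano factor is
#' \deqn{\sigma^2/\langle n \rangle = 1 - \frac{k_c}{k_c + k_p}.}
#'
#' @param kc,kp turnover rates (> 0).
#' @return The Fano factor, in (0, 1).
#' @examples
#' fano_analytic(1, 1)    # 0.5
#' fano_analytic(50, 12)  # ~0.19, the E. coli glycolysis estimate
#' @export
fano_analytic <- function(kc, kp) {
  stopifnot(kc > 0, kp > 0)
  1 - kc / (kc + kp)
}

#' Stationary law of a birth-death chain (master-equation oracle)
#'
#' Detailed balance gives \eqn{\pi(n) \propto \prod_{k=1}^{n} b(k-1)/d(k)};
#' the product is accumulated in log space and normalised.
#'
#' @param birth,death rate functions of the count n.
#' @param nmax truncation bound; \code{death(0)} is never used and the tail
#'   mass beyond nmax must be negligible for open chains.
#' @return Probability vector over \code{0:nmax}.
#' @examples
#' p <- master_equation_stationary(function(n) 1 * (20 - n),
#'                                 function(n) 1 * n, nmax = 20)
#' sum(p * 0:20)  # binomial mean 10
#' @export
master_equation_stationary <- function(birth, death, nmax) {
  n <- 0:nmax
  b <- vapply(n, birth, numeric(1))
  d <- vapply(n, death, numeric(1))
  if (any(d[-1] <= 0)) stop("death rate must be positive for n >= 1")
  logpi <- c(0, cumsum(log(b[-(nmax + 1)]) - log(d[-1])))
  logpi[is.nan(logpi) | logpi == -Inf] <- -Inf
  # states unreachable past a zero birth rate get probability 0
  z <- which(b == 0)
  if (length(z) && min(z) <= nmax) logpi[n > n[min(z)]] <- -Inf
  p <- exp(logpi - max(logpi[is.finite(logpi)]))
  p[!is.finite(p)] <- 0
  s <- sum(p)
  if (s <= 0) stop("zero normalisation")
  p / s
}

#' Moments of a probability vector over 0..nmax
#'
#' @param p probability vector over counts \code{0:(length(p)-1)}.
#' @return List with \code{mean}, \code{variance}, \code{fano}.
#' @export
distribution_moments <- function(p) {
  n <- seq_along(p) - 1
  m <- sum(p * n)
  v <- sum(p * (n - m)^2)
  list(mean = m, variance = v, fano = if (m > 0) v / m else NA_real_)
}

#' Fano-factor sweep over the carrier pool size
#'
#' Reproduces the crossover of the intermediate-count statistics as the
#' carrier pool grows: below the critical pool size \code{2 * kin /
#' min(kc, kp)}-ish (capacity smaller than influx) the cascade is saturated,
#' the mean count grows linearly with the pool and the Fano factor sits at
#' \code{fano_analytic(kc, kp)}; above it the count is Poissonian with mean
#' \code{kin / kp} and Fano 1.  Each pool size is simulated with the
#' perfect-binding limit model, choosing the regime by comparing the
#' cascade's capacity \code{kc*kp*cmax/(kc+kp)} with the influx.
#'
#' @param kin influx rate (copies per unit time).
#' @param kc,kp turnover rates.
#' @param cpool_values carrier pool sizes (csum = cpool).
#' @param t_end simulated span per pool size.
#' @param burn_in discarded initial span.
#' @param seed RNG seed (one stream across the sweep).
#' @return data.frame with columns \code{cpool}, \code{saturated},
#'   \code{mean}, \code{fano}.
#' @export
fano_pool_sweep <- function(kin = 100, kc = 1, kp = 1,
                            cpool_values = c(25, 50, 100, 150, 300, 400, 600),
                            t_end = 2000, burn_in = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(cpool_values, function(cp) {
    sat <- kin_threshold_limit(kc, kp, cp, cp) < kin
    s <- if (sat)
      ssa_limit(kc, kp, cmax = cp, saturated = TRUE,
                n0 = round(cp * kc / (kc + kp)), t_end = t_end)
    else
      ssa_limit(kc, kp, kin = kin, saturated = FALSE,
                n0 = round(kin / kp), t_end = t_end)
    st <- count_statistics(s, burn_in = burn_in)
    data.frame(cpool = cp, saturated = sat, mean = st$mean, fano = st$fano)
  })
  do.call(rbind, rows)
}
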