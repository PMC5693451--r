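#' Closed-form jamming threshold of the influx rate
#'
#' For a leak-free cascade (kleak = 0) the influx rate above which no fixed
#' point exists — the cascade's maximal flux capacity — is
#' \deqn{k_{in}^{th} = \frac{k_c k_p}{2(k_c+k_p)}\left\{c_{pool}+c_{sum}+\alpha
#'  - \sqrt{(c_{pool}-c_{sum}+\alpha)^2 + 4 c_{sum}\alpha}\right\}, \quad
#'  \alpha = \frac{k_c K_1}{k_c+k_p}.}
#' With the package defaults (kc = kp = 1, K1 = 1e-3, cpool = csum = 2) this
#' evaluates to 0.984313.  Above the threshold the first metabolite
#' accumulates without bound ("jamming"); just below it, relaxation to the
#' fixed point slows down as \eqn{(k_{in}^{th}-k_{in})^{-1}}.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak = 0}; the
#'   threshold is undefined for a leaky cascade (the m0-nullcline tilts and a
#'   fixed point exists for any influx).
#' @param cpool,csum conserved pools (> 0).
#' @return The critical influx rate.
#' @examples
#' kin_threshold(ccc_params(), cpool = 2, csum = 2)
#' @export
kin_threshold <- function(params, cpool, csum) {
  if (params$kleak != 0)
    stop("the jamming threshold is defined only for kleak = 0; ",
         "a leaky cascade always has a fixed point")
  stopifnot(cpool > 0, csum > 0)
  kc <- params$kc; kp <- params$kp
  alpha <- kc * params$K1 / (kc + kp)
  kc * kp / (2 * (kc + kp)) *
    (cpool + csum + alpha - sqrt((cpool - csum + alpha)^2 + 4 * csum * alpha))
}

#' Perfect-binding limit of the jamming threshold
#'
#' In the limit K1 -> 0 (m1 binds the inactive carrier perfectly) the
#' threshold reduces to the capacity
#' \eqn{k_c k_p \min(c_{pool}, c_{sum}) / (k_c + k_p)}.
#'
#' @param kc,kp turnover rates.
#' @param cpool,csum conserved pools.
#' @return The limiting critical influx rate.
#' @export
kin_threshold_limit <- function(kc, kp, cpool, csum) {
  stopifnot(kc > 0, kp > 0, cpool > 0, csum > 0)
  kc * kp * pmin(cpool, csum) / (kc + kp)
}

#' Numerical jamming threshold by divergence bisection
#'
#' Independent numerical oracle for \code{\link{kin_threshold}}: bisects the
#' influx rate on the predicate "m0 diverges" versus "the system relaxes to a
#' fixed point".  Each probe integrates the two-variable reduction from a
#' small m0 (default 1) to the horizon; a run counts as divergent when m0 is
#' still rising at the end and has exceeded 10 times its initial value, and
#' as convergent otherwise (relaxed, falling, or still creeping toward a
#' large fixed point).  Near the boundary the backlog grows at rate
#' |kin - kin_th|, so the horizon sets the resolution: the default 2e4
#' resolves the boundary to a few 1e-4.  A bracket whose ends do not
#' straddle the predicate is an error.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak = 0}.
#' @param cpool,csum conserved pools.
#' @param bracket initial \code{c(lo, hi)} influx bracket; defaults to the
#'   closed-form value \code{* c(0.5, 1.5)}.
#' @param tol bisection tolerance on kin (default 1e-4).
#' @param horizon integration horizon per probe (default 1e4).
#' @param m0_init initial m0 for the probes.
#' @return The bisected critical influx rate.
#' @export
kin_threshold_bisect <- function(params, cpool, csum, bracket = NULL,
                                 tol = 1e-4, horizon = 2e4, m0_init = 1) {
  if (params$kleak != 0) stop("divergence bisection requires kleak = 0")
  if (is.null(bracket))
    bracket <- kin_threshold(params, cpool, csum) * c(0.5, 1.5)
  ct0 <- min(cpool, csum)  # start on the conservation surface for any csum
  s0 <- ccc_state(m0 = m0_init, m1 = csum - ct0, c = ct0, cstar = cpool - ct0)
  diverges <- function(kin) {
    p <- ccc_update(params, kin = kin)
    tr <- ccc_integrate(p, s0,
                        t_end = horizon, sample_dt = horizon / 2000,
                        model = "reduced2")
    n <- nrow(tr)
    rising <- tr$m0[n] > tr$m0[n - 1]
    rising && tr$m0[n] > 10 * m0_init
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (diverges(lo) || !diverges(hi))
    stop("bracket does not straddle the divergence boundary")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (diverges(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Relaxation time of a trajectory
#'
#' The relaxation time tau is the earliest sample time at which the sum over
#' species of the absolute change since the previous sample falls below a
#' threshold (default 1e-7), excluding t = 0.  Returns \code{Inf} ("not
#' relaxed") when the criterion is never met.
#'
#' @param traj a \code{ccc_trajectory} on a uniform grid (at least 2 samples).
#' @param threshold positive convergence threshold.
#' @return The relaxation time, or \code{Inf}.
#' @export
relaxation_time <- function(traj, threshold = 1e-7) {
  stopifnot(threshold > 0)
  if (nrow(traj) < 2) stop("trajectory needs at least 2 samples")
  x <- as.matrix(as.data.frame(traj)[setdiff(names(traj), "time")])
  d <- rowSums(abs(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]))
  hit <- which(d < threshold)
  if (!length(hit)) return(Inf)
  traj$time[hit[1] + 1]
}

#' Step change of the influx rate
#'
#' Runs the cascade at \code{kin_before} for \code{pre_run} time units (from
#' \code{state0}), then switches the influx to \code{kin_after} at time 0 and
#' integrates for \code{t_end}.  When \code{kin_before} exceeds the jamming
#' threshold no true steady state exists; the pre-run then prepares the
#' quasi-steady jammed plateau with accumulated m0.
#'
#' @param params a \code{\link{ccc_params}} (its \code{kin} is ignored).
#' @param kin_before,kin_after influx rates before/after the switch.
#' @param pre_run pre-switch duration (> 0), default 100.
#' @param t_end post-switch duration.
#' @param state0 state at the start of the pre-run.
#' @param model formulation to integrate.
#' @inheritParams ccc_integrate
#' @return The post-switch \code{ccc_trajectory} (t = 0 is the switch).
#' @export
ccc_step_response <- function(params, kin_before, kin_after, pre_run = 100,
                              t_end = 2000, state0 = ccc_state(c = 2),
                              model = "reduced5", sample_dt = 1) {
  stopifnot(pre_run > 0)
  pre <- ccc_integrate(ccc_update(params, kin = kin_before), state0,
                       t_end = pre_run, sample_dt = pre_run / 50, model = model)
  s1 <- trajectory_end_state(pre, params, model)
  ccc_integrate(ccc_update(params, kin = kin_after), s1, t_end = t_end,
                sample_dt = sample_dt, model = model)
}

# Rebuild a ccc_state (totals convention) from the last row of a trajectory.
trajectory_end_state <- function(traj, params, model) {
  n <- nrow(traj)
  if (model == "full")
    return(ccc_state(m0 = traj$m0[n], m1 = traj$m1[n], m2 = traj$m2[n],
                     c = traj$c[n], cstar = traj$cstar[n],
                     cm0 = traj$cm0[n], cstarm1 = traj$cstarm1[n]))
  cons <- attr(traj, "conserved")
  ct <- traj$c[n] + traj$m0[n] * traj$c[n] / (params$K0 + traj$c[n])
  ccc_state(m0 = traj$m0[n], m1 = traj$m1[n], m2 = traj$m2[n],
            c = ct, cstar = max(cons$cpool - ct, 0))
}

#' Sudden change of the active/inactive carrier ratio
#'
#' After a pre-run to (quasi-)steady state, the carrier totals are reassigned
#' to \code{ratio_active_after * cpool} active and the complement inactive,
#' holding the metabolites fixed.  This changes c_sum but not c_pool, and
#' probes the same slow relaxation as an influx step.
#'
#' @param params a \code{\link{ccc_params}}.
#' @param ratio_active_after fraction of the pool set active (in (0,1)).
#' @param pre_run,t_end durations before/after the jump.
#' @param state0 state at the start of the pre-run.
#' @param sample_dt sampling interval.
#' @return The post-jump \code{ccc_trajectory}.
#' @export
carrier_ratio_perturbation <- function(params, ratio_active_after,
                                       pre_run = 200, t_end = 2000,
                                       state0 = ccc_state(c = 1, cstar = 1),
                                       sample_dt = 1) {
  stopifnot(ratio_active_after > 0, ratio_active_after < 1)
  pre <- ccc_integrate(params, state0, t_end = pre_run,
                       sample_dt = pre_run / 50, model = "reduced5")
  s1 <- trajectory_end_state(pre, params, "reduced5")
  cpool <- conserved_quantities(state0)$cpool
  s2 <- ccc_state(m0 = s1[["m0"]], m1 = s1[["m1"]], m2 = s1[["m2"]],
                  c = ratio_active_after * cpool,
                  cstar = (1 - ratio_active_after) * cpool)
  ccc_integrate(params, s2, t_end = t_end, sample_dt = sample_dt,
                model = "reduced5")
}

#' Relaxation-time scan below the jamming threshold
#'
#' Measures tau for each influx rate from the jammed initial condition
#' (m0 = 100, m1 = m2 = 0, all carrier active) and fits the log-log slope of
#' tau against the distance below threshold.  Near the threshold the cascade
#' drains its m0 backlog at the constant rate kin_th - kin, so tau scales as
#' \eqn{(k_{in}^{th}-k_{in})^{-1}} (slope -1) — critical slowing down with an
#' exponent distinct from the saddle-node value 1/2.
#'
#' @param params a \code{\link{ccc_params}} with \code{kleak = 0}.
#' @param kin_values influx rates, all below the threshold.
#' @param threshold relaxation criterion threshold (default 1e-7).
#' @param m0_init initial m0 backlog (default 100).
#' @param cpool carrier pool, all active initially (default 2).
#' @param sample_dt sampling interval for tau (default 1).
#' @return List of class \code{ccc_relaxation_scan}: data.frame \code{rows}
#'   (kin, tau), \code{fitted_exponent}, \code{kin_th_used}; non-relaxing
#'   runs are excluded from the fit and reported in \code{excluded}.
#' @export
relaxation_scan <- function(params, kin_values = c(0.90, 0.92, 0.94, 0.96, 0.97, 0.98),
                            threshold = 1e-7, m0_init = 100, cpool = 2,
                            sample_dt = 1) {
  kth <- kin_threshold(params, cpool = cpool, csum = cpool)
  if (any(kin_values >= kth)) stop("all kin values must lie below the threshold")
  tau <- vapply(kin_values, function(kin) {
    p <- ccc_update(params, kin = kin)
    t_end <- ceiling(3 * m0_init / (kth - kin))
    tr <- ccc_integrate(p, ccc_state(m0 = m0_init, c = cpool, cstar = 0),
                        t_end = t_end, sample_dt = sample_dt,
                        model = "reduced5")
    relaxation_time(tr, threshold)
  }, numeric(1))
  ok <- is.finite(tau)
  fit <- stats::lm(log(tau[ok]) ~ log(kth - kin_values[ok]))
  structure(list(rows = data.frame(kin = kin_values, tau = tau),
                 fitted_exponent = unname(stats::coef(fit)[2]),
                 kin_th_used = kth,
                 excluded = kin_values[!ok]),
            class = "ccc_relaxation_scan")
}

#' @export
print.ccc_relaxation_scan <- function(x, ...) {
  cat("Relaxation-time scan (jammed initial condition)\n")
  print(x$rows, row.names = FALSE)
  cat(sprintf("kin_th = %.6f; fitted log-log exponent = %.3f\n",
              x$kin_th_used, x$fitted_exponent))
  if (length(x$excluded))
    cat("excluded (not relaxed):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Classify plateau decay as linear versus exponential
#'
#' In the jammed plateau m0 drains at a constant rate, so its decay is linear
#' in time rather than exponential.  Fits both forms by least squares over
#' the window \code{[0.1, 0.8] * tau} and compares residual sums of squares.
#'
#' @param traj a \code{ccc_trajectory} containing the plateau.
#' @param tau the relaxation time of the trajectory (e.g. from
#'   \code{\link{relaxation_time}}).
#' @return List with \code{rss_linear}, \code{rss_exponential},
#'   \code{r2_linear}, \code{r2_exponential} and \code{better} ("linear" or
#'   "exponential").
#' @export
classify_plateau_decay <- function(traj, tau) {
  stopifnot(is.finite(tau), tau > 0)
  win <- traj$time >= 0.1 * tau & traj$time <= 0.8 * tau & traj$m0 > 0
  t <- traj$time[win]; m0 <- traj$m0[win]
  if (length(t) < 4) stop("plateau window too short to classify")
  lin <- stats::lm(m0 ~ t)
  expo <- stats::lm(log(m0) ~ t)
  rss_lin <- sum(stats::resid(lin)^2)
  rss_exp <- sum((m0 - exp(stats::fitted(expo)))^2)
  r2 <- function(rss) 1 - rss / sum((m0 - mean(m0))^2)
  list(rss_linear = rss_lin, rss_exponential = rss_exp,
       r2_linear = r2(rss_lin), r2_exponential = r2(rss_exp),
       better = if (rss_lin < rss_exp) "linear" else "exponential")
}
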