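#' Parameters for N cascades sharing one carrier pool
#'
#' Each cascade has its own rate constants; all consuming steps draw the
#' same free active carrier and all producing steps regenerate it, so a
#' single pool c_pool is conserved.  With N = 1 the model reduces exactly to
#' the single cascade.
#'
#' @param cascades a list of \code{\link{ccc_params}} objects (length N >= 1).
#' @return List of class \code{ccc_coupled_params}.
#' @export
coupled_params <- function(cascades) {
  if (!length(cascades)) stop("need at least one cascade")
  ok <- vapply(cascades, inherits, logical(1), what = "ccc_params")
  if (!all(ok)) stop("every cascade must be a ccc_params object")
  structure(list(cascades = cascades, n = length(cascades)),
            class = "ccc_coupled_params")
}

# Free carrier shared by several substrates with distinct dissociation
# constants: solve T = x + sum_i P_i x/(K_i + x) for x in [0, T].  For one
# substrate this is the quadratic of free_carrier(); with two or more it is
# a 1-D bracketed root find (tolerance ~1e-12 relative).
free_carrier_multi <- function(total, partner_totals, K) {
  if (total <= 0) return(0)
  if (length(partner_totals) == 1) return(free_carrier(total, partner_totals, K))
  g <- function(x) x + sum(partner_totals * x / (K + x)) - total
  stats::uniroot(g, c(0, total), tol = 1e-12 * max(total, 1))$root
}

#' Time derivatives of coupled cascades
#'
#' Five-ODE-style reduction with a shared carrier: states are per-cascade
#' (m0_i, m1_i, m2_i) plus the shared totals \[c\]_t and \[c*\]_t.  Free
#' carriers come from the competitive-binding closure over all bound
#' substrates.  The pool \[c\]_t + \[c*\]_t is conserved exactly, as is
#' \[c\]_t + sum_i \[m1_i\]; the per-cascade c_sum is no longer individually
#' conserved.
#'
#' @param state named vector: \code{m0_1, m1_1, m2_1, ..., ct, cstart}.
#' @param params a \code{\link{coupled_params}}.
#' @return Named derivative vector.
#' @export
ccc_rhs_coupled <- function(state, params) {
  n <- params$n
  m0 <- state[paste0("m0_", seq_len(n))]
  m1 <- state[paste0("m1_", seq_len(n))]
  m2 <- state[paste0("m2_", seq_len(n))]
  K0 <- vapply(params$cascades, `[[`, numeric(1), "K0")
  K1 <- vapply(params$cascades, `[[`, numeric(1), "K1")
  c_free <- free_carrier_multi(state[["ct"]], m0, K0)
  cs_free <- free_carrier_multi(state[["cstart"]], m1, K1)
  d <- numeric(length(state))
  names(d) <- names(state)
  vc_tot <- vp_tot <- 0
  for (i in seq_len(n)) {
    p <- params$cascades[[i]]
    vc <- p$kc * m0[i] * c_free / (K0[i] + c_free)
    vp <- p$kp * m1[i] * cs_free / (K1[i] + cs_free)
    d[paste0("m0_", i)] <- p$kin - vc - p$kleak * m0[i]
    d[paste0("m1_", i)] <- vc - vp
    d[paste0("m2_", i)] <- vp - p$kout * m2[i]
    vc_tot <- vc_tot + vc
    vp_tot <- vp_tot + vp
  }
  d[["ct"]] <- -vc_tot + vp_tot
  d[["cstart"]] <- vc_tot - vp_tot
  d
}

#' Integrate coupled cascades
#'
#' @param params a \code{\link{coupled_params}}.
#' @param state0 named vector (\code{m0_i, m1_i, m2_i} per cascade plus
#'   shared carrier totals \code{ct}, \code{cstart}).
#' @param t_end,sample_dt as in \code{\link{ccc_integrate}}.
#' @param rtol,atol integrator tolerances.
#' @return data.frame of class \code{ccc_trajectory} with suffixed columns.
#' @export
ccc_integrate_coupled <- function(params, state0, t_end, sample_dt = 1,
                                  rtol = 1e-9, atol = 1e-12) {
  times <- seq(0, t_end, by = sample_dt)
  sol <- deSolve::ode(y = state0, times = times,
                      func = function(t, y, p) list(ccc_rhs_coupled(y, p)),
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed near time %g", max(sol[, "time"])))
  out <- as.data.frame(sol)
  num <- setdiff(names(out), "time")
  out[num] <- lapply(out[num], function(x) pmax(x, 0))
  structure(out, model = "coupled", params = params,
            class = c("ccc_trajectory", "data.frame"))
}

#' Default coupled initial state
#'
#' @param n number of cascades.
#' @param cpool shared carrier pool, all active initially.
#' @param m0 per-cascade initial m0 (recycled to length n).
#' @return Named state vector for \code{\link{ccc_integrate_coupled}}.
#' @export
coupled_state <- function(n, cpool = 2, m0 = 0) {
  m0 <- rep_len(m0, n)
  s <- c(rbind(m0, 0, 0))
  names(s) <- paste0(rep(c("m0_", "m1_", "m2_"), n), rep(seq_len(n), each = 3))
  c(s, ct = cpool, cstart = 0)
}

#' Influx step for cascade 1 of a coupled system
#'
#' Pre-runs the coupled system with \code{kin1_before}, then switches cascade
#' 1's influx to \code{kin1_after} at time 0, as in the single-cascade
#' \code{\link{ccc_step_response}}.  The slow jammed relaxation of cascade 1
#' survives the coupling through the shared pool.
#'
#' @param params a \code{\link{coupled_params}}.
#' @param kin1_before,kin1_after influx of cascade 1 before/after the switch.
#' @param pre_run,t_end durations.
#' @param state0 initial state for the pre-run.
#' @param sample_dt sampling interval.
#' @return Post-switch trajectory.
#' @export
coupled_step_response <- function(params, kin1_before, kin1_after,
                                  pre_run = 100, t_end = 2000,
                                  state0 = NULL, sample_dt = 1) {
  if (is.null(state0)) state0 <- coupled_state(params$n)
  p_before <- params
  p_before$cascades[[1]] <- ccc_update(params$cascades[[1]], kin = kin1_before)
  pre <- ccc_integrate_coupled(p_before, state0, t_end = pre_run,
                               sample_dt = pre_run / 50)
  s1 <- unlist(pre[nrow(pre), setdiff(names(pre), "time")])
  p_after <- params
  p_after$cascades[[1]] <- ccc_update(params$cascades[[1]], kin = kin1_after)
  ccc_integrate_coupled(p_after, s1, t_end = t_end, sample_dt = sample_dt)
}
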