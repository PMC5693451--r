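#' Free carrier concentration from a bound+free total
#'
#' Under rapid binding equilibrium the total carrier satisfies
#' \eqn{T = x + P x / (K + x)} where \eqn{x} is the free carrier, \eqn{P} the
#' total of the metabolite it binds, and \eqn{K} the dissociation constant.
#' This is the quadratic \eqn{x^2 + (K + P - T)x - KT = 0}; the unique
#' non-negative root is returned in the numerically stable form
#' \eqn{x = (-b + \sqrt{b^2 + 4KT})/2} with \eqn{b = K + P - T}.
#'
#' @param total total (free + bound) carrier concentration.
#' @param partner_total total concentration of the binding metabolite.
#' @param K dissociation constant (> 0).
#' @return Free carrier concentration in \code{[0, total]}.
#' @examples
#' free_carrier(2, 1, 1)  # sqrt(2)
#' @export
free_carrier <- function(total, partner_total, K) {
  if (any(K <= 0)) stop("K must be > 0 (use the stochastic limit model for K -> 0)")
  if (any(total < 0) || any(partner_total < 0))
    stop("totals must be non-negative")
  b <- K + partner_total - total
  disc <- b * b + 4 * K * total
  x <- (-b + sqrt(disc)) / 2
  # -b + sqrt cancels badly when b >> 0; rationalised form is stable there
  pos <- b > 0
  x[pos] <- 2 * K * total[pos] / (b[pos] + sqrt(disc[pos]))
  pmin(pmax(x, 0), total)
}

#' Michaelis-Menten fluxes of the cascade
#'
#' \eqn{v_c = k_c [m_0][c]/(K_0+[c])} (active-carrier consumption) and
#' \eqn{v_p = k_p [m_1][c^*]/(K_1+[c^*])} (regeneration), with free carrier
#' concentrations.
#'
#' @param m0,m1 metabolite concentrations.
#' @param c,cstar free carrier concentrations.
#' @param params a \code{\link{ccc_params}}.
#' @return A list with components \code{vc} and \code{vp}.
#' @export
ccc_fluxes <- function(m0, m1, c, cstar, params) {
  list(vc = params$kc * m0 * c / (params$K0 + c),
       vp = params$kp * m1 * cstar / (params$K1 + cstar))
}

#' Time derivatives of the full mass-action model
#'
#' Seven species (m0, m1, m2, free c, free c*, and the complexes cm0, c*m1),
#' nine elementary reactions: influx and leak of m0, association/dissociation
#' of c.m0 and c*.m1 (dissociation rates \code{ka0*K0}, \code{ka1*K1}),
#' catalysis cm0 -> m1 + c* (kc) and c*m1 -> m2 + c (kp), and efflux of m2.
#' The carrier total c + cm0 + c* + c*m1 is conserved exactly, as is
#' c + cm0 + m1 + c*m1.
#'
#' @param state named vector with entries m0, m1, m2, c, cstar, cm0, cstarm1.
#' @param params a \code{\link{ccc_params}}.
#' @return Named vector of derivatives.
#' @export
ccc_rhs_full <- function(state, params) {
  s <- state
  assoc0 <- params$ka0 * s[["c"]] * s[["m0"]]
  dissoc0 <- params$ka0 * params$K0 * s[["cm0"]]
  cat_c <- params$kc * s[["cm0"]]
  assoc1 <- params$ka1 * s[["cstar"]] * s[["m1"]]
  dissoc1 <- params$ka1 * params$K1 * s[["cstarm1"]]
  cat_p <- params$kp * s[["cstarm1"]]
  c(m0 = params$kin - params$kleak * s[["m0"]] - assoc0 + dissoc0,
    m1 = cat_c - assoc1 + dissoc1,
    m2 = cat_p - params$kout * s[["m2"]],
    c = -assoc0 + dissoc0 + cat_p,
    cstar = cat_c - assoc1 + dissoc1,
    cm0 = assoc0 - dissoc0 - cat_c,
    cstarm1 = assoc1 - dissoc1 - cat_p)
}

#' Time derivatives of the adiabatic five-ODE model
#'
#' Binding is eliminated by rapid equilibrium: the evolved carrier variables
#' are the totals \[c\]_t and \[c*\]_t and the free concentrations are recovered
#' with \code{\link{free_carrier}}.  The fluxes are the Michaelis-Menten forms
#' of \code{\link{ccc_fluxes}} and d\[c\]_t/dt = -v_c + v_p = -d\[c*\]_t/dt, so
#' c_pool and c_sum are conserved by construction.
#'
#' @param state named vector with entries m0, m1, m2, ct, cstart.
#' @param params a \code{\link{ccc_params}}.
#' @return Named vector of derivatives (m0, m1, m2, ct, cstart).
#' @export
ccc_rhs_reduced5 <- function(state, params) {
  # the integrator may probe states a rounding error below zero
  c_free <- free_carrier(max(state[["ct"]], 0), max(state[["m0"]], 0), params$K0)
  cs_free <- free_carrier(max(state[["cstart"]], 0), max(state[["m1"]], 0), params$K1)
  fl <- ccc_fluxes(state[["m0"]], state[["m1"]], c_free, cs_free, params)
  c(m0 = params$kin - fl$vc - params$kleak * state[["m0"]],
    m1 = fl$vc - fl$vp,
    m2 = fl$vp - params$kout * state[["m2"]],
    ct = -fl$vc + fl$vp,
    cstart = fl$vc - fl$vp)
}

#' Time derivatives of the conservation-reduced two-ODE model
#'
#' Using the two conserved quantities, the five-ODE model collapses to
#' dynamics of (m0, m1) alone.  The free carriers are
#' \deqn{[c] = \frac{-\beta + \sqrt{\beta^2 + 4K_0(c_{sum}-[m_1])}}{2},\quad
#'       \beta = [m_0] + K_0 - c_{sum} + [m_1],}
#' \deqn{[c^*] = \frac{-\gamma + \sqrt{\gamma^2 + 4K_1(c_{pool}-c_{sum}+[m_1])}}{2},\quad
#'       \gamma = K_1 + c_{sum} - c_{pool},}
#' i.e. \code{free_carrier(csum - m1, m0, K0)} and
#' \code{free_carrier(cpool - csum + m1, m1, K1)}.
#'
#' @param m0,m1 metabolite concentrations, with \code{0 <= m1 <= csum}.
#' @param params a \code{\link{ccc_params}}.
#' @param cpool,csum the conserved pools.
#' @return List with \code{dm0}, \code{dm1} and the free carriers \code{c},
#'   \code{cstar}.
#' @export
ccc_rhs_reduced2 <- function(m0, m1, params, cpool, csum) {
  if (any(m1 > csum + 1e-12))
    stop("m1 exceeds csum: state violates the conservation law")
  c_free <- free_carrier(pmax(csum - m1, 0), m0, params$K0)
  cs_free <- free_carrier(cpool - csum + m1, m1, params$K1)
  fl <- ccc_fluxes(m0, m1, c_free, cs_free, params)
  list(dm0 = params$kin - fl$vc - params$kleak * m0,
       dm1 = fl$vc - fl$vp,
       c = c_free, cstar = cs_free, vc = fl$vc, vp = fl$vp)
}

state_to_internal <- function(state0, model) {
  s <- as.numeric(state0)
  names(s) <- names(state0)
  switch(model,
    full = s[c("m0", "m1", "m2", "c", "cstar", "cm0", "cstarm1")],
    reduced5 = c(m0 = s[["m0"]], m1 = s[["m1"]], m2 = s[["m2"]],
                 ct = s[["c"]], cstart = s[["cstar"]]),
    reduced2 = c(m0 = s[["m0"]], m1 = s[["m1"]], m2 = s[["m2"]]))
}

#' Integrate a cascade
#'
#' Stiff-capable integration (\code{deSolve::ode}, lsoda) of any of the three
#' formulations, sampled on a uniform grid.  Tolerances default to
#' rtol = 1e-9, atol = 1e-12: the jammed regime separates timescales by a
#' factor of order 1e3, and the conservation laws are required to drift by
#' less than 1e-8 relative over a run.  Sampled concentrations are clipped at
#' zero on output only.
#'
#' @param params a \code{\link{ccc_params}}.
#' @param state0 initial \code{\link{ccc_state}} (carrier entries are totals
#'   for the reduced models).
#' @param t_end final time (> 0).
#' @param sample_dt sampling interval (> 0), default 1 (one catalytic turnover).
#' @param model \code{"reduced5"} (default), \code{"reduced2"} or \code{"full"}.
#' @param rtol,atol integrator tolerances.
#' @param kin_fun optional function of time overriding the constant influx
#'   rate (used by the driven-influx experiments).
#' @return A \code{ccc_trajectory}: a data.frame with columns \code{time},
#'   \code{m0}, \code{m1}, \code{m2}, \code{c}, \code{cstar} (free carrier
#'   concentrations) and, for the full model, \code{cm0}, \code{cstarm1};
#'   attributes \code{model}, \code{params}, \code{conserved}.
#' @examples
#' p <- ccc_params(kin = 0.9)
#' tr <- ccc_integrate(p, ccc_state(m0 = 10, c = 2), t_end = 50)
#' tail(tr, 3)
#' @export
ccc_integrate <- function(params, state0, t_end, sample_dt = 1,
                          model = c("reduced5", "reduced2", "full"),
                          rtol = 1e-9, atol = 1e-12, kin_fun = NULL) {
  model <- match.arg(model)
  stopifnot(t_end > 0, sample_dt > 0)
  y0 <- state_to_internal(state0, model)
  cons <- conserved_quantities(state0,
                               model = if (model == "full") "full" else "reduced5")
  times <- seq(0, t_end, by = sample_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  deriv <- switch(model,
    full = function(t, y, parms) {
      p <- parms
      if (!is.null(kin_fun)) p$kin <- kin_fun(t)
      list(ccc_rhs_full(y, p))
    },
    reduced5 = function(t, y, parms) {
      p <- parms
      if (!is.null(kin_fun)) p$kin <- kin_fun(t)
      list(ccc_rhs_reduced5(y, p))
    },
    reduced2 = function(t, y, parms) {
      p <- parms
      if (!is.null(kin_fun)) p$kin <- kin_fun(t)
      d <- ccc_rhs_reduced2(max(y[["m0"]], 0),
                            min(max(y[["m1"]], 0), cons$csum), p,
                            cons$cpool, cons$csum)
      list(c(d$dm0, d$dm1, d$vp - p$kout * y[["m2"]]))
    })

  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed near time %g", max(sol[, "time"])))
  sol <- as.data.frame(sol)
  if (any(vapply(sol, min, numeric(1)) < -1e-6))
    stop("internal state went below -1e-6: integration unreliable")

  out <- data.frame(time = sol$time)
  if (model == "full") {
    out$m0 <- sol$m0; out$m1 <- sol$m1; out$m2 <- sol$m2
    out$c <- sol$c; out$cstar <- sol$cstar
    out$cm0 <- sol$cm0; out$cstarm1 <- sol$cstarm1
  } else if (model == "reduced5") {
    out$m0 <- sol$m0; out$m1 <- sol$m1; out$m2 <- sol$m2
    out$c <- free_carrier(pmax(sol$ct, 0), pmax(sol$m0, 0), params$K0)
    out$cstar <- free_carrier(pmax(sol$cstart, 0), pmax(sol$m1, 0), params$K1)
  } else {
    m1c <- pmin(pmax(sol$m1, 0), cons$csum)
    d <- ccc_rhs_reduced2(pmax(sol$m0, 0), m1c, params, cons$cpool, cons$csum)
    out$m0 <- sol$m0; out$m1 <- sol$m1; out$m2 <- sol$m2
    out$c <- d$c; out$cstar <- d$cstar
  }
  num <- setdiff(names(out), "time")
  out[num] <- lapply(out[num], function(x) pmax(x, 0))
  structure(out, model = model, params = params, conserved = cons,
            class = c("ccc_trajectory", "data.frame"))
}

#' @export
print.ccc_trajectory <- function(x, ...) {
  cat(sprintf("CCC trajectory (%s model): %d samples over t = [%g, %g]\n",
              attr(x, "model"), nrow(x), min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.ccc_trajectory <- function(x, species = c("m0", "m1", "c", "cstar"),
                                log = "", ...) {
  species <- intersect(species, names(x))
  cols <- seq_along(species) + 1
  graphics::matplot(x$time, as.matrix(as.data.frame(x)[species]), type = "l",
                    lty = 1, col = cols, xlab = "time", ylab = "concentration",
                    log = log, ...)
  graphics::legend("topright", legend = species, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Nullclines of the two-variable reduction
#'
#' For each m1 on a grid, finds (by bracketed 1-D root finding) the m0 value
#' on the m1-nullcline (\eqn{v_c = v_p}) and on the m0-nullcline
#' (\eqn{k_{in} = v_c + k_{leak} [m_0]}).  Where no root exists in the
#' bracket (e.g. influx above capacity, so the m0-nullcline is absent) the
#' point is returned as \code{NA} rather than an error.
#'
#' @param params a \code{\link{ccc_params}}.
#' @param cpool,csum conserved pools.
#' @param m1_grid m1 values in \code{[0, csum)}.
#' @param m0_max upper end of the root bracket; defaults to
#'   \code{max(10 * kin / max(kleak, 1e-4), 1e4)}.
#' @return data.frame with columns \code{m1}, \code{m0_nullcline_m0} (root of
#'   dm0/dt = 0) and \code{m1_nullcline_m0} (root of dm1/dt = 0).
#' @export
ccc_nullclines <- function(params, cpool, csum, m1_grid, m0_max = NULL) {
  stopifnot(all(m1_grid >= 0), all(m1_grid < csum))
  if (is.null(m0_max))
    m0_max <- max(10 * params$kin / max(params$kleak, 1e-4), 1e4)
  root_on <- function(f) {
    if (!is.finite(f(0)) || !is.finite(f(m0_max))) return(NA_real_)
    if (f(0) * f(m0_max) > 0) return(NA_real_)
    stats::uniroot(f, c(0, m0_max), tol = 1e-10)$root
  }
  m0_nc <- m1_nc <- numeric(length(m1_grid))
  for (i in seq_along(m1_grid)) {
    m1 <- m1_grid[i]
    m0_nc[i] <- root_on(function(m0)
      ccc_rhs_reduced2(m0, m1, params, cpool, csum)$dm0)
    m1_nc[i] <- root_on(function(m0)
      ccc_rhs_reduced2(m0, m1, params, cpool, csum)$dm1)
  }
  data.frame(m1 = m1_grid, m0_nullcline_m0 = m0_nc, m1_nullcline_m0 = m1_nc)
}

#' Steady state of the two-variable reduction
#'
#' Finds the crossing of the two nullclines by a 1-D root search in m1: at
#' each m1 the m0-nullcline fixes m0, and the residual is dm1/dt there.
#' Returns \code{NULL} when no fixed point exists (kleak = 0 with influx
#' above the jamming threshold).
#'
#' @inheritParams ccc_nullclines
#' @return List with \code{m0}, \code{m1}, \code{c}, \code{cstar}, \code{vc},
#'   \code{vp} at the fixed point, or \code{NULL}.
#' @export
ccc_steady_state <- function(params, cpool, csum, m0_max = NULL) {
  if (is.null(m0_max))
    m0_max <- max(10 * params$kin / max(params$kleak, 1e-4), 1e4)
  m0_on_m0nc <- function(m1) {
    f <- function(m0) ccc_rhs_reduced2(m0, m1, params, cpool, csum)$dm0
    if (f(0) * f(m0_max) > 0) return(NA_real_)
    stats::uniroot(f, c(0, m0_max), tol = 1e-12)$root
  }
  g <- function(m1) {
    m0 <- m0_on_m0nc(m1)
    if (is.na(m0)) return(NA_real_)
    ccc_rhs_reduced2(m0, m1, params, cpool, csum)$dm1
  }
  eps <- csum * 1e-9
  grid <- seq(eps, csum - eps, length.out = 200)
  vals <- vapply(grid, g, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2) return(NULL)
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(NULL)
  i <- ok[flip[1]]; j <- ok[flip[1] + 1]
  m1s <- stats::uniroot(g, c(grid[i], grid[j]), tol = 1e-13)$root
  m0s <- m0_on_m0nc(m1s)
  d <- ccc_rhs_reduced2(m0s, m1s, params, cpool, csum)
  list(m0 = m0s, m1 = m1s, c = d$c, cstar = d$cstar, vc = d$vc, vp = d$vp,
       residual = max(abs(d$dm0), abs(d$dm1)))
}
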