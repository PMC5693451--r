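#' Rate and equilibrium constants of one carrier cycling cascade
#'
#' A carrier cycling cascade (CCC) is the minimal metabolic motif
#' m0 -> m1 -> m2 in which the first step consumes the active carrier c
#' (turning it into the inactive form c*) and the second step regenerates it.
#' Complex formation between carrier and substrate gives the
#' Michaelis-Menten-like fluxes
#' \deqn{v_c = k_c [m_0][c]/(K_0+[c]), \quad v_p = k_p [m_1][c^*]/(K_1+[c^*]).}
#'
#' Time and concentration are dimensionless; the default \code{kc = kp = 1}
#' sets the unit of time to the catalytic turnover.
#'
#' @param kin influx rate of the first metabolite m0 (concentration/time).
#' @param kleak first-order leak (dilution) rate of m0 (1/time).
#' @param kout first-order efflux rate of the product m2 (1/time).
#' @param kc turnover rate of the active-carrier-consuming step (1/time).
#' @param kp turnover rate of the active-carrier-producing step (1/time).
#' @param K0 dissociation constant of the c.m0 complex (concentration).
#' @param K1 dissociation constant of the c*.m1 complex (concentration).
#' @param ka0,ka1 association rate constants of the two binding reactions,
#'   used only by the full mass-action model (1/(concentration.time)); the
#'   dissociation rates are \code{ka0*K0} and \code{ka1*K1}.  The defaults are
#'   fast relative to \code{kc}, \code{kp} so the adiabatic (rapid
#'   equilibrium) reductions apply.
#'
#' @return An object of class \code{ccc_params}: a named list of the rates.
#' @examples
#' p <- ccc_params(kin = 0.9)
#' p
#' @export
ccc_params <- function(kin = 1, kleak = 0, kout = 1, kc = 1, kp = 1,
                       K0 = 1e-3, K1 = 1e-3, ka0 = 1e6, ka1 = 1e6) {
  p <- list(kin = kin, kleak = kleak, kout = kout, kc = kc, kp = kp,
            K0 = K0, K1 = K1, ka0 = ka0, ka1 = ka1)
  validate_ccc_params(p)
  structure(p, class = "ccc_params")
}

validate_ccc_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-numeric or non-scalar parameter: ",
         paste(names(p)[!num], collapse = ", "))
  if (any(unlist(p) < 0))
    stop("negative parameter: ",
         paste(names(p)[unlist(p) < 0], collapse = ", "))
  if (p$kc <= 0 || p$kp <= 0) stop("kc and kp must be positive")
  if (p$K0 <= 0 || p$K1 <= 0)
    stop("K0 and K1 must be positive for the deterministic models; ",
         "use the stochastic limit model for the K -> 0 case")
  invisible(p)
}

#' @export
print.ccc_params <- function(x, ...) {
  cat("Carrier cycling cascade parameters\n")
  cat(sprintf("  influx/leak/efflux : kin=%g  kleak=%g  kout=%g\n",
              x$kin, x$kleak, x$kout))
  cat(sprintf("  turnover           : kc=%g  kp=%g\n", x$kc, x$kp))
  cat(sprintf("  dissociation       : K0=%g  K1=%g\n", x$K0, x$K1))
  cat(sprintf("  association (full) : ka0=%g  ka1=%g\n", x$ka0, x$ka1))
  invisible(x)
}

#' Update a parameter set
#'
#' @param params a \code{\link{ccc_params}} object.
#' @param ... named fields to replace (e.g. \code{kin = 0.9}).
#' @return A new \code{ccc_params} object.
#' @export
ccc_update <- function(params, ...) {
  stopifnot(inherits(params, "ccc_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad)) stop("unknown parameter field: ", paste(bad, collapse = ", "))
  do.call(ccc_params, utils::modifyList(unclass(params), repl))
}

#' Initial state of a cascade
#'
#' For the reduced models (\code{reduced5}, \code{reduced2}) the carrier
#' entries \code{c} and \code{cstar} are the *total* active and inactive
#' carrier pools (\[c\]_t, \[c*\]_t, free + bound); the free concentrations are
#' derived through the binding equilibrium.  For the full model they are the
#' free species and the complexes \code{cm0}, \code{cstarm1} are explicit.
#'
#' @param m0,m1,m2 metabolite concentrations.
#' @param c,cstar active / inactive carrier (totals for reduced models).
#' @param cm0,cstarm1 complex concentrations (full model only).
#' @return A named numeric vector of class \code{ccc_state}.
#' @examples
#' ccc_state(m0 = 100, c = 2)  # the jammed start used in relaxation scans
#' @export
ccc_state <- function(m0 = 0, m1 = 0, m2 = 0, c = 2, cstar = 0,
                      cm0 = 0, cstarm1 = 0) {
  s <- c(m0 = m0, m1 = m1, m2 = m2, c = c, cstar = cstar,
         cm0 = cm0, cstarm1 = cstarm1)
  if (any(!is.finite(s))) stop("non-finite concentration")
  if (any(s < 0)) stop("negative concentration: ",
                       paste(names(s)[s < 0], collapse = ", "))
  structure(s, class = "ccc_state")
}

#' Conserved quantities of a cascade state
#'
#' The CCC conserves the total carrier pool
#' \eqn{c_{pool} = [c]_t + [c^*]_t} and, because producing one m1 consumes
#' exactly one active carrier, the sum \eqn{c_{sum} = [c]_t + [m_1]} (and its
#' complement \eqn{c^*_{diff} = [c^*]_t - [m_1]}).  Only two of the three are
#' independent: \eqn{c_{pool} = c_{sum} + c^*_{diff}}.
#'
#' For \code{model = "full"} the totals include the complexes
#' (\eqn{[c]_t = [c] + [cm_0]}, \eqn{[c^*]_t = [c^*] + [c^*m_1]}), and the
#' metabolite entering \eqn{c_{sum}} is likewise the total
#' \eqn{[m_1] + [c^*m_1]} — the reduced models' \eqn{[m_1]} variable is the
#' free-plus-bound metabolite, which is what makes \eqn{c_{sum}} an exact
#' invariant of the mass-action network.
#'
#' @param state a \code{\link{ccc_state}} (or named vector).
#' @param model which formulation the state belongs to:
#'   \code{"reduced5"}, \code{"reduced2"} (carrier entries are totals) or
#'   \code{"full"} (free species + complexes).
#' @return A list with components \code{cpool}, \code{csum}, \code{cdiff_star}.
#' @examples
#' conserved_quantities(ccc_state(m1 = 0.3, c = 1.5, cstar = 0.5))
#' @export
conserved_quantities <- function(state, model = c("reduced5", "reduced2", "full")) {
  model <- match.arg(model)
  s <- as.numeric(state)[match(c("m0", "m1", "m2", "c", "cstar", "cm0", "cstarm1"),
                               names(state))]
  names(s) <- c("m0", "m1", "m2", "c", "cstar", "cm0", "cstarm1")
  s[is.na(s)] <- 0
  if (any(s < 0)) stop("negative concentration in state")
  if (model == "full") {
    ct <- s[["c"]] + s[["cm0"]]
    cstart <- s[["cstar"]] + s[["cstarm1"]]
    m1 <- s[["m1"]] + s[["cstarm1"]]
  } else {
    ct <- s[["c"]]
    cstart <- s[["cstar"]]
    m1 <- s[["m1"]]
  }
  list(cpool = ct + cstart,
       csum = ct + m1,
       cdiff_star = cstart - m1)
}
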