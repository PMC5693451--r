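---
title: "Modelling metabolic dynamics restricted by conserved carriers"
author: "cccsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic dynamics restricted by conserved carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccsim)
```

## The model

Central metabolism recycles a small set of coenzymes — ATP/ADP as an energy
carrier, NADH/NAD⁺ as a hydrogen carrier — whose **total** amount is
conserved on physiological timescales (moiety conservation). The carrier
cycling cascade (CCC) is the minimal motif that captures this: a substrate
m0 is converted to an intermediate m1 by a step that consumes the active
carrier c (producing the inactive form c*), and m1 is converted to the
product m2 by a step that regenerates c. Glycolysis (ATP invested by
phosphofructokinase, regenerated by pyruvate kinase) and lactic fermentation
(NAD⁺ reduced by GAPDH, reoxidised by LDH) are instances of this "turbo"
architecture.

`cccsim` implements the cascade at three levels of description:

1. **Full mass-action model** (`ccc_rhs_full`, `model = "full"`): seven
   species — m0, m1, m2, free c, free c*, and the complexes c·m0 and c*·m1 —
   with nine elementary reactions (influx, leak, two reversible binding
   steps with association rates `ka0`, `ka1` and dissociation rates
   `ka*K`, two catalytic conversions with turnover rates `kc`, `kp`, and
   product efflux `kout`).
2. **Adiabatic five-ODE reduction** (`model = "reduced5"`): binding is
   assumed at rapid equilibrium, eliminating the complexes. The evolved
   carrier variables are the totals [c]\_t, [c*]\_t, and the fluxes take the
   Michaelis–Menten forms v_c = kc·[m0][c]/(K0+[c]) and
   v_p = kp·[m1][c*]/(K1+[c*]). In this description [m0] and [m1] denote
   the free-plus-bound metabolite totals; the binding terms partition each
   total between free and complexed forms. That bookkeeping is what makes
   the conserved sums exact (below).
3. **Conservation-reduced two-ODE model** (`model = "reduced2"`): using the
   two independent conserved quantities, only (m0, m1) evolve and the free
   carriers follow from quadratic binding closures
   (`free_carrier`). This is the phase-plane model used for nullclines and
   fixed points.

The conserved quantities (`conserved_quantities`) are the carrier pool
c_pool = [c]\_t + [c*]\_t and the sum c_sum = [c]\_t + [m1] (equivalently its
complement c*\_diff = [c*]\_t − [m1]); only two are independent. In the full
model the exact invariants are c + cm0 + c* + c*m1 and
c + cm0 + m1 + c*m1, i.e. the totals including complexes.

## Default parameters and units

Time and concentration are dimensionless. The defaults, shared by every
experiment preset, are

| parameter | default | meaning |
|---|---|---|
| `kc`, `kp` | 1 | catalytic turnover rates; they set the unit of time |
| `K0`, `K1` | 1e-3 | dissociation constants (tight binding) |
| `kleak` | 0 | leak of m0 (1e-3 in the driven-influx experiments) |
| `kout` | 1 | product efflux; m2 is slaved and feeds back on nothing |
| `ka0`, `ka1` | 1e6 | association rates (full model only), fast enough that the adiabatic reduction holds |
| pool | `cpool = csum = 2` | all carrier initially active in the standard runs |

With these values the closed-form jamming threshold (below) evaluates to
`r sprintf("%.6f", kin_threshold(ccc_params(), 2, 2))`, which together with
the K1 → 0 limit pins down the self-consistent parameter set. `kout` only
sets the (exponential) relaxation of m2 and does not affect any other
variable, so its exact value is immaterial to every reported quantity.

## Jamming and the critical influx rate

For a leak-free cascade the flux through the carrier-consuming step cannot
exceed a capacity set by the pools and turnover rates. `kin_threshold`
implements the closed form

$$k_{in}^{th} = \frac{k_c k_p}{2(k_c+k_p)}\left\{c_{pool}+c_{sum}+\alpha
 - \sqrt{(c_{pool}-c_{sum}+\alpha)^2 + 4 c_{sum}\alpha}\right\},\qquad
 \alpha = \frac{k_c K_1}{k_c+k_p},$$

whose K1 → 0 limit is the capacity
k_c k_p min(c_pool, c_sum)/(k_c+k_p) (`kin_threshold_limit`). The sign in
front of the radical is fixed by that limit: only the minus branch reduces
to the capacity formula and yields a threshold below the symmetric-pool
capacity of 1. Above the threshold the m0-nullcline and the m1-nullcline of
the two-variable reduction no longer cross (`ccc_nullclines`), no fixed
point exists, and m0 accumulates without bound — the cascade jams. With a
finite leak the m0-nullcline tilts and a fixed point exists at any influx,
so the threshold is defined only for `kleak = 0` (the function refuses
otherwise).

`kin_threshold_bisect` is an independent numerical check: it bisects the
influx on a divergence predicate. Because near the boundary the backlog
grows at rate |k_in − k_in^th|, a fixed-horizon predicate has resolution
of order (detection excursion)/horizon; the implementation probes from a
small backlog (m0 = 1) over a horizon of 2·10⁴ time units, calling a run
divergent when m0 is still rising at the end and has exceeded ten times its
initial value. Empirically this agrees with the closed form to a few 10⁻⁴
across random parameter draws.

## Slow relaxation and critical scaling

Just below the threshold, relaxation to the fixed point is anomalously
slow. From a jammed start (m0 = 100, all carrier active) the cascade sits
in a quasi-steady plateau in which every concentration except m0 is nearly
constant and m0 drains at the *constant* rate k_in^th − k_in — linearly in
time, not exponentially (`classify_plateau_decay` fits both forms and
compares residuals over the window [0.1, 0.8]·τ). The relaxation time
therefore scales as (k_in^th − k_in)⁻¹, an exponent of −1, distinct from
the 1/2 of a saddle-node bifurcation. `relaxation_time` implements the
operational definition of τ: the first sample time at which the summed
absolute change of all concentrations since the previous sample on a unit
grid drops below 10⁻⁷. τ is insensitive to the sampling interval within
[0.1, 2] because during the plateau the per-unit-time change is set by the
drainage rate, orders of magnitude above the criterion, and after the snap
it collapses exponentially on the turnover timescale.

```{r scan, eval = FALSE}
scan <- relaxation_scan(ccc_params(),
                        kin_values = c(0.90, 0.92, 0.94, 0.96, 0.97, 0.98))
scan$fitted_exponent  # ~ -1
```

`ccc_step_response` reproduces the influx-step protocol. When the pre-step
influx exceeds the threshold no true steady state exists; the default
100-unit pre-run prepares the quasi-steady plateau with an accumulated
backlog, which is the only sensible reading of "reached the steady state"
for a super-threshold start. `carrier_ratio_perturbation` probes the same
slow mode by reassigning the active/inactive split of the pool (changing
c_sum while conserving c_pool).

## Robustness and responsiveness to a fluctuating influx

Under a sinusoidal influx k_in(t) = A_in cos(2πft) + k_in0 with a small
leak (`kleak = 1e-3` keeps the driven system bounded), the jammed backlog
of m0 acts as a buffer: fast fluctuations are absorbed without any change
in the carrier or intermediate concentrations, while slow ones drain the
buffer and elicit a full response — a low-pass filter with a sharp corner.
In the saturated regime the dynamics collapse onto the m1-nullcline and
only the backlog evolves (`reduced_1d_rhs`):

$$\frac{d[m_0]}{dt} = k_{in}(t) - k_{leak}[m_0] - \frac{k_c k_p c_{sum}}{k_c+k_p},$$

influx minus leak minus capacity; for kleak → 0 this is exactly influx
minus the perfect-binding threshold. The analytic corner frequency
(`cutoff_frequency`)

$$2\pi f_c = \frac{k_{leak} k_c A_{in}}
  {k_c k_{in0} - (k_c + k_{leak})\,k_{in}^{th} - k_{leak} k_c}$$

is linear in the drive amplitude: stronger inputs pass at higher
frequencies. The threshold entering the formula is the `kleak = 0` closed
form, by convention. Simulated response maps (`response_map`,
`amplitude_response`: swing of free [c] after discarding transients, with
the transient floored at 10/kleak so the slow backlog equilibrates at low
frequency) confirm that the response collapses to zero at this frequency
essentially exactly.

One measurement caveat, found while validating: if the *measured* cut-off
is defined as the frequency where the swing falls to half its low-frequency
plateau, it sits systematically below the analytic corner — a factor 1.3 at
A_in = 0.1 growing to ~3.5 at A_in = 1.0, where the drive dips to zero
influx and the quasi-static plateau is the full pool swing, widening the
shoulder below the sharp collapse. The half-maximum measure
(`half_max_cutoff`) is retained for comparability, but the analytic corner
should be compared against the collapse point of the response, not the
half-maximum crossing, at large amplitudes.

## Intrinsic noise and feedback through the conserved pool

`ssa_full` runs an exact Gillespie simulation of the nine-reaction network
at volume Ω = 1 (copy numbers and concentrations identified), conserving
carrier copies exactly at every event and reproducing event sequences
bit-identically for a given seed. Binding rates default to `ka = 1e3` in
stochastic runs — fast enough for the rapid-equilibrium behaviour at
feasible event counts; the perfect-binding limit model exists precisely to
avoid that cost where K → 0 is intended.

In the limit K0, K1 → 0 the intermediate count n follows a birth–death
chain (`ssa_limit`):

* **saturated regime** (m0 accumulates; pool below the critical value
  2·k_in when kc = kp): production k_c(c_max − n), consumption k_p n. The
  moiety conservation converts production into a negative feedback; the
  stationary law is binomial(c_max, k_c/(k_c+k_p)) and the Fano factor is
  $$\sigma^2/\langle n\rangle = 1 - \frac{k_c}{k_c+k_p}$$
  (`fano_analytic`): 0.5 for symmetric turnover, below 1 always.
* **unsaturated regime**: production is the constant influx, the law is
  Poisson, and the Fano factor is 1.

`master_equation_stationary` provides the exact stationary distribution of
any birth–death chain by detailed balance and serves as the oracle for both
laws; `count_statistics` computes dwell-time-weighted (time-averaged)
means, variances and Fano factors, the natural convention for asynchronous
event paths. `fano_pool_sweep` reproduces the crossover: the mean count
grows linearly with the pool in the saturated regime and plateaus at
k_in/k_p above the critical pool size, while the Fano factor steps from
1 − k_c/(k_c+k_p) up to 1. The regime per pool size is chosen by comparing
the capacity with the influx — the same criterion that decides whether m0
accumulates.

The control model `ssa_double_mm` shows the feedback is really due to the
*shared* conservation: with production and consumption saturated by two
independent pools, both rates are count-independent, the count performs an
unbiased random walk (or drifts to zero/infinity), and the ensemble Fano
factor grows linearly in time — never below 1.

## Estimating turnover rates in real pathways

`turnover_rate` inverts the Michaelis–Menten flux
v = k·[m][c]/(K+[c]) for k given measured substrate and carrier
concentrations, the dissociation constant, and the flux (all in mM, mM/s).
The bundled table (`ccc_datasets`) carries two measured pathways:

```{r estimate}
d <- ccc_datasets()
pathway_estimate(d$`ecoli-glycolysis`$consuming,
                 d$`ecoli-glycolysis`$producing, signif_kc = 1)
pathway_estimate(d$`llactis-fermentation`$consuming,
                 d$`llactis-fermentation`$producing)
```

For aerobic E. coli glycolysis the PFK flux is the glucose uptake
(1.8 mM/s) corrected for the ~20% diverted into the pentose phosphate
pathway (`effective_flux(1.8, 0.20)` = 1.44 mM/s). Internal values are kept
unrounded; the reporting layer quotes kc to one significant figure for the
E. coli pathway and two elsewhere, matching how the source measurements are
quoted, and the predicted Fano factor is computed from the quoted rates.
The LDH substrate (pyruvate) concentration is taken as 1.0 mM; the source
table's row label for that cell is ambiguous between enzyme and substrate,
and only the substrate reading reproduces the quoted rates.

## Coupled cascades

`coupled_params`/`ccc_integrate_coupled` implement N cascades competing
for one carrier pool. The free carrier is obtained from the multi-substrate
binding closure T = x + Σᵢ Pᵢx/(Kᵢ+x) — a quadratic for one substrate, a
bracketed 1-D root find (tolerance 1e-12) for several with distinct K's.
The shared c_pool and the complementary sum [c]\_t + Σᵢ[m1ᵢ] are conserved
exactly; the per-cascade c_sum no longer is. With N = 1 the equations
reduce to the single cascade at machine precision. The jammed slow
relaxation of a cascade survives coupling to a competitor — including a
weak-binding competitor (K0 = 100) whose own backlog equilibrates on a far
longer timescale, which is why the coupled relaxation checks monitor the
first cascade's variables.

## Numerical choices

* Integration: `deSolve::ode` (lsoda) with rtol = 1e-9, atol = 1e-12. The
  jammed regime separates timescales by ~10³ and the conservation laws are
  required to drift less than 1e-8 relative over any run (tested).
* Negative concentrations: the integrator may probe a rounding error below
  zero; right-hand sides clamp such excursions, sampled output is clipped
  at zero, and an internal excursion below −10⁻⁶ aborts the run.
* Nullcline/steady-state roots: bracketed bisection (`stats::uniroot`) on
  m0 ∈ [0, max(10·k_in/k_leak, 10⁴)]; absence of a sign change after
  bracketing means "no nullcline point", by design not an error (that is
  the jammed phase portrait).
* SSA: direct-method Gillespie in C++ using R's RNG, so `set.seed` gives
  bit-identical paths; statistics are time-weighted; default burn-in is
  explicit per experiment rather than inferred.
* Problem sizes: the relaxation scan uses influx values up to 0.98 (τ up to
  ~2.3·10⁴ time units); stochastic estimates use ≥10⁶ events per point;
  the double-MM ensemble uses 300 trajectories. These sizes hold every
  reported statistic well inside its stated tolerance.

## What the experiments do and do not show

All experiments here are exercises of the model itself — the package ships
no external time-series data, and the bundled pathway table is a set of
point measurements, not dynamics. The synthetic experiments demonstrate
the mechanisms (jamming, critical slowing, low-pass filtering, noise
suppression by conservation feedback) under mass-action/Michaelis–Menten
kinetics with a strictly conserved pool and no enzyme-level regulation,
growth dilution, reversibility of the catalytic steps, or branched fluxes.
Real pathways violate all of these to some degree; the turnover-rate
estimates quantify only where real systems sit on the feedback-strength
axis, not the full dynamics. Reversible catalytic steps and branched
topologies are out of scope.
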