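# cccsim — carrier cycling cascades with conserved coenzyme pools

Metabolic pathways recycle coenzymes whose total amount is conserved:
glycolysis invests ATP early and regenerates it downstream; anaerobic
fermentation reduces NAD⁺ in upper glycolysis and reoxidises NADH at the
end. `cccsim` is an R package for simulating and analysing the **carrier
cycling cascade (CCC)** — the minimal motif m0 → m1 → m2 in which the
first step consumes the active carrier c and the second regenerates it —
and for quantifying the two dynamical consequences of moiety conservation:

* **Jamming.** For a leak-free cascade the influx of m0 cannot exceed the
  carrier-limited capacity

  $$k_{in}^{th} = \frac{k_c k_p}{2(k_c+k_p)}\Big\{c_{pool}+c_{sum}+\alpha
    - \sqrt{(c_{pool}-c_{sum}+\alpha)^2 + 4c_{sum}\alpha}\Big\},\quad
    \alpha = \tfrac{k_c K_1}{k_c+k_p},$$

  which tends to $k_ck_p\min(c_{pool},c_{sum})/(k_c+k_p)$ as $K_1\to 0$.
  Above it m0 accumulates without bound; just below it the system relaxes
  through a quasi-steady plateau in a time diverging as
  $(k_{in}^{th}-k_{in})^{-1}$ — critical slowing down with exponent −1,
  with m0 draining linearly (not exponentially) in time. Under a
  sinusoidal influx the backlog acts as a buffer, making the cascade a
  low-pass filter whose corner frequency grows linearly with the drive
  amplitude.

* **Feedback.** Because producing one intermediate consumes exactly one
  active carrier, the conservation law feeds the intermediate count back
  onto its own production. In the saturated regime the stationary count is
  binomial and its Fano factor is

  $$\sigma^2/\langle n\rangle = 1 - k_c/(k_c+k_p) < 1,$$

  versus 1 (Poisson) without saturation and ≥ 1 for the comparator model
  with two independent carrier pools.

The package provides the full mass-action model with explicit
carrier–substrate complexes, its adiabatic five-ODE and conservation-based
two-ODE reductions, phase-plane tools (nullclines, steady states), exact
Gillespie simulation with chemical-master-equation oracles, and estimation
of the turnover rates $k_c$, $k_p$ (and the predicted noise suppression)
from measured pathway concentrations and fluxes, with tables for E. coli
glycolysis and L. lactis lactic fermentation bundled.

## Worked example

```r
library(cccsim)

p <- ccc_params(kin = 0.97)                 # defaults: kc = kp = 1, K = 1e-3
kin_threshold(p, cpool = 2, csum = 2)
#> [1] 0.9843131

tr <- ccc_integrate(p, ccc_state(m0 = 100, c = 2), t_end = 8000)
relaxation_time(tr)
#> [1] 6948

relaxation_scan(ccc_params(), kin_values = c(0.90, 0.94, 0.97))
#> Relaxation-time scan (jammed initial condition)
#>  kin  tau
#>  0.90 1190
#>  0.94 2249
#>  0.97 6948
#> kin_th = 0.984313; fitted log-log exponent = -0.995
```

The influx 0.97 sits 0.0143 below the capacity 0.984313, so the backlog of
100 drains at that constant rate: τ ≈ 100/0.0143 ≈ 7·10³ — about seven
thousand catalytic turnover times, and the log–log slope of τ against the
distance to threshold is −1.

```r
s <- ssa_limit(kc = 1, kp = 1, cmax = 20, saturated = TRUE, n0 = 10,
               t_end = 2e4, seed = 1)
count_statistics(s, burn_in = 100)
#> mean = 10, variance = 4.99, Fano = 0.4988 (397715 change-points, t = 1.99e+04)
```

In the carrier-limited regime the intermediate count fluctuates at half
the Poisson variance: the conservation feedback at work
(`fano_analytic(1, 1)` = 0.5).

```r
d <- ccc_datasets()
pathway_estimate(d$`ecoli-glycolysis`$consuming,
                 d$`ecoli-glycolysis`$producing, signif_kc = 1)
#> kc (PFK) = 53.53 /s [reported 50]
#> kp (PK) = 12.27 /s [reported 12]
#> predicted Fano factor = 0.1865 [reported 0.19]
```

So glycolytic ATP cycling in aerobic E. coli is predicted to suppress
intermediate-metabolite noise five-fold (Fano ≈ 0.2), while the measured
L. lactis fermentation parameters give only mild suppression (0.85).

A thin command-line front end is installed with the package
(`system.file("scripts", "ccc", package = "cccsim")`) with subcommands
`simulate`, `threshold`, `relax-scan`, `step`, `freq-sweep`, `ssa`,
`estimate` and `preset`, writing TSV trajectories and JSON reports.

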