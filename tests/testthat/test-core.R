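test_that("free_carrier solves the binding equilibrium", {
  expect_equal(free_carrier(2, 0, 1), 2)              # no partner, all free
  expect_equal(free_carrier(2, 1, 1), sqrt(2))        # x^2 - 2 = 0
  expect_lt(free_carrier(1, 10, 1e-6), 1e-6)          # perfect-binding limit
  expect_error(free_carrier(1, 1, 0), "K")

  # implicit total equation T = x + P x/(K + x) holds to 1e-12 relative
  set.seed(2)
  for (i in 1:50) {
    T <- runif(1, 1e-3, 10); P <- runif(1, 0, 20); K <- 10^runif(1, -8, 2)
    x <- free_carrier(T, P, K)
    expect_gte(x, 0); expect_lte(x, T)
    expect_lt(abs(x + P * x / (K + x) - T) / T, 1e-12)
  }
})

test_that("full mass-action derivatives conserve the carrier exactly", {
  p <- default_params(kin = 1)
  d0 <- ccc_rhs_full(ccc_state(c = 0, cstar = 0), p)
  expect_equal(unname(d0), c(1, 0, 0, 0, 0, 0, 0))  # empty system: influx only

  set.seed(3)
  for (i in 1:20) {
    s <- random_full_state()
    d <- ccc_rhs_full(s, default_params(kin = runif(1, 0, 2),
                                        kleak = runif(1, 0, 0.5)))
    # carrier moiety: c + cm0 + c* + c*m1
    expect_identical(d[["c"]] + d[["cm0"]] + d[["cstar"]] + d[["cstarm1"]], 0)
    # total intermediate + total active carrier (exact csum invariant)
    expect_identical(d[["c"]] + d[["cm0"]] + d[["m1"]] + d[["cstarm1"]], 0)
  }
})

test_that("five-ODE reduction conserves cpool and csum and loses flux without carrier", {
  p <- default_params(kin = 0.7)
  s <- c(m0 = 3, m1 = 0.4, m2 = 0.1, ct = 0, cstart = 2)
  d <- ccc_rhs_reduced5(s, p)
  expect_equal(d[["m1"]], -unname(ccc_fluxes(3, 0.4,
    0, free_carrier(2, 0.4, p$K1), p)$vp))  # vc = 0 with no active carrier
  expect_lte(d[["m1"]], 0)

  set.seed(4)
  for (i in 1:20) {
    s <- c(m0 = runif(1, 0, 5), m1 = runif(1, 0, 1), m2 = runif(1, 0, 1),
           ct = runif(1, 0, 2), cstart = runif(1, 0, 2))
    d <- ccc_rhs_reduced5(s, p)
    expect_equal(d[["ct"]] + d[["cstart"]], 0)   # cpool
    expect_equal(d[["ct"]] + d[["m1"]], 0)       # csum
  }
})

test_that("adiabatic limit: full-model trajectory converges to the five-ODE one as binding speeds up", {
  p5 <- default_params(kin = 0.8)
  s0 <- ccc_state(m0 = 2, c = 2)
  tr <- ccc_integrate(p5, s0, t_end = 40, model = "reduced5")
  late <- tr$time >= 5  # skip the fast binding transient
  dev_for_ka <- vapply(c(1e2, 1e4, 1e6), function(ka) {
    pf <- ccc_update(p5, ka0 = ka, ka1 = ka)
    tf <- ccc_integrate(pf, s0, t_end = 40, model = "full")
    max(abs((tf$m0 + tf$cm0)[late] - tr$m0[late]),
        abs((tf$m1 + tf$cstarm1)[late] - tr$m1[late]))
  }, numeric(1))
  expect_true(all(diff(dev_for_ka) < 0))  # monotone improvement with ka
  expect_lt(dev_for_ka[3], 1e-4)
})

test_that("two-ODE reduction reproduces the five-ODE trajectory", {
  p <- default_params(kin = 0.9)
  s0 <- jammed_state(m0 = 10)
  t5 <- ccc_integrate(p, s0, t_end = 200, model = "reduced5")
  t2 <- ccc_integrate(p, s0, t_end = 200, model = "reduced2")
  expect_lt(max(abs(t5$m0 - t2$m0)), 1e-6)
  expect_lt(max(abs(t5$m1 - t2$m1)), 1e-6)
  expect_lt(max(abs(t5$m2 - t2$m2)), 1e-6)
  expect_error(ccc_rhs_reduced2(1, 3, p, cpool = 2, csum = 2), "csum")
})

test_that("full-model trajectory agrees with the reductions after the binding transient", {
  p <- default_params(kin = 0.8)
  s0f <- ccc_state(m0 = 2, c = 2)
  tf <- ccc_integrate(p, s0f, t_end = 50, model = "full")
  tr <- ccc_integrate(p, ccc_state(m0 = 2, c = 2), t_end = 50,
                      model = "reduced5")
  # compare totals m0 + cm0 and m1 + c*m1 after the fast binding transient
  late <- tf$time >= 5
  m0f <- tf$m0 + tf$cm0; m1f <- tf$m1 + tf$cstarm1
  expect_lt(max(abs(m0f[late] - tr$m0[late]) / pmax(tr$m0[late], 1e-3)), 1e-4)
  expect_lt(max(abs(m1f[late] - tr$m1[late]) / pmax(tr$m1[late], 1e-3)), 1e-4)
})

test_that("integration conserves the pools and drains when influx stops", {
  p <- default_params(kin = 0)
  tr <- ccc_integrate(p, ccc_state(m0 = 5, m1 = 0.5, c = 1.2, cstar = 0.8),
                      t_end = 300, model = "reduced5")
  n <- nrow(tr)
  expect_lt(tr$m0[n], 1e-8)
  expect_lt(tr$m1[n], 1e-8)
  expect_lt(tr$m2[n], 1e-8)
  # drained cascade: all of csum ends up as active carrier
  cq0 <- conserved_quantities(ccc_state(m0 = 5, m1 = 0.5, c = 1.2, cstar = 0.8))
  ctn <- tr$c[n] + tr$m0[n] * tr$c[n] / (p$K0 + tr$c[n])
  expect_equal(ctn, cq0$csum, tolerance = 1e-6)

  # conservation drift over a long jammed run
  p2 <- default_params(kin = 0.95)
  tr2 <- ccc_integrate(p2, jammed_state(50), t_end = 1500, model = "reduced5")
  ct <- tr2$c * (1 + tr2$m0 / (p2$K0 + tr2$c))
  cst <- tr2$cstar * (1 + tr2$m1 / (p2$K1 + tr2$cstar))
  expect_lt(max(abs(ct + cst - 2)) / 2, 1e-8)
  expect_lt(max(abs(ct + tr2$m1 - 2)) / 2, 1e-8)
})

test_that("nullclines cross below threshold, not above, and tilt with leak", {
  p <- default_params()
  grid <- seq(0.05, 1.9, length.out = 30)

  nc_lo <- ccc_nullclines(ccc_update(p, kin = 0.8), 2, 2, grid)
  cross <- nc_lo$m0_nullcline_m0 - nc_lo$m1_nullcline_m0
  expect_true(any(diff(sign(cross[is.finite(cross)])) != 0))
  ss <- ccc_steady_state(ccc_update(p, kin = 0.8), 2, 2)
  i <- which.min(abs(nc_lo$m1 - ss$m1))
  expect_equal(ss$vc, 0.8, tolerance = 1e-8)   # flux balance at the crossing

  nc_hi <- ccc_nullclines(ccc_update(p, kin = 1.2), 2, 2, grid)
  d <- nc_hi$m0_nullcline_m0 - nc_hi$m1_nullcline_m0
  expect_false(any(diff(sign(d[is.finite(d)])) != 0))  # no crossing: jammed

  # with leak the m0-nullcline is tilted and a fixed point exists above kin_th
  pl <- ccc_update(p, kleak = 0.05)
  ssl <- ccc_steady_state(ccc_update(pl, kin = 1.2), 2, 2)
  expect_false(is.null(ssl))
  expect_lt(ssl$residual, 1e-10)
})

test_that("steady state exists below threshold and vanishes above (kleak = 0)", {
  p <- default_params()
  ss <- ccc_steady_state(ccc_update(p, kin = 0.9), 2, 2)
  expect_equal(ss$vc, 0.9, tolerance = 1e-9)
  expect_equal(ss$vp, 0.9, tolerance = 1e-9)
  expect_lt(ss$residual, 1e-10)
  expect_null(ccc_steady_state(ccc_update(p, kin = 1.1), 2, 2))
})
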