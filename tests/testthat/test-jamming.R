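test_that("closed-form threshold matches its perfect-binding limit and rejects leaky cascades", {
  p <- default_params()
  expect_equal(kin_threshold(p, 2, 2), 0.984313, tolerance = 1e-6)
  expect_error(kin_threshold(ccc_update(p, kleak = 0.01), 2, 2), "kleak")

  # K1 -> 0 limit: capacity kc*kp*min(cpool,csum)/(kc+kp)
  expect_equal(kin_threshold_limit(1, 1, 3, 2), 1.0)
  expect_equal(kin_threshold_limit(1, 1, 400, 400), 200)
  set.seed(10)
  for (i in 1:20) {
    kc <- runif(1, 0.2, 3); kp <- runif(1, 0.2, 3)
    cp <- runif(1, 0.5, 5); cs <- runif(1, 0.5, 5)
    q <- ccc_params(kc = kc, kp = kp, K1 = 1e-8)
    lim <- kin_threshold_limit(kc, kp, cp, cs)
    expect_equal(kin_threshold(q, cp, cs), lim, tolerance = 1e-6)
  }
  # branch continuity at cpool == csum
  expect_equal(kin_threshold_limit(2, 1, 3, 3),
               kin_threshold_limit(2, 1, 3, 3 + 1e-12))
})

test_that("threshold is monotone in capacity parameters and decreasing in K1", {
  set.seed(11)
  for (i in 1:15) {
    kc <- runif(1, 0.3, 2); kp <- runif(1, 0.3, 2); K1 <- 10^runif(1, -4, -1)
    cp <- runif(1, 1, 4); cs <- runif(1, 1, 4)
    base <- kin_threshold(ccc_params(kc = kc, kp = kp, K1 = K1), cp, cs)
    h <- 1e-4
    expect_gte(kin_threshold(ccc_params(kc = kc + h, kp = kp, K1 = K1), cp, cs), base)
    expect_gte(kin_threshold(ccc_params(kc = kc, kp = kp + h, K1 = K1), cp, cs), base)
    expect_gte(kin_threshold(ccc_params(kc = kc, kp = kp, K1 = K1), cp + h, cs), base)
    expect_gte(kin_threshold(ccc_params(kc = kc, kp = kp, K1 = K1), cp, cs + h), base)
    expect_lte(kin_threshold(ccc_params(kc = kc, kp = kp, K1 = K1 + h), cp, cs), base)
  }
})

test_that("divergence bisection reproduces the analytic threshold", {
  p <- default_params()
  expect_lt(abs(kin_threshold_bisect(p, 2, 2, tol = 2e-4) -
                kin_threshold(p, 2, 2)), 1e-3)
  set.seed(12)
  for (i in 1:3) {
    q <- ccc_params(kc = runif(1, 0.5, 2), kp = runif(1, 0.5, 2),
                    K1 = 10^runif(1, -4, -2))
    cp <- runif(1, 1, 4); cs <- runif(1, 1, 4)
    expect_lt(abs(kin_threshold_bisect(q, cp, cs, tol = 2e-4) -
                  kin_threshold(q, cp, cs)), 1e-3)
  }
})

test_that("relaxation time detects settling and divergence", {
  p <- default_params(kin = 0.9)
  tr <- ccc_integrate(p, jammed_state(10), t_end = 400, model = "reduced5")
  tau <- relaxation_time(tr)
  expect_true(is.finite(tau))
  expect_gt(tau, 10)

  # constant trajectory relaxes at the first eligible sample
  flat <- tr
  flat[setdiff(names(flat), "time")] <-
    lapply(flat[setdiff(names(flat), "time")], function(x) rep(x[1], length(x)))
  expect_equal(relaxation_time(flat), flat$time[2])

  # divergent run never relaxes
  td <- ccc_integrate(ccc_update(p, kin = 1.1), jammed_state(1), t_end = 300,
                      model = "reduced5")
  expect_identical(relaxation_time(td), Inf)
  expect_error(relaxation_time(tr[1, ]), "samples")
})

test_that("influx step: no perturbation means a flat path; jammed plateau decays linearly", {
  p <- default_params()
  flat <- ccc_step_response(p, 0.8, 0.8, pre_run = 400, t_end = 50)
  expect_lt(max(abs(flat$m0 - flat$m0[1])), 1e-6)

  tr <- ccc_step_response(p, 1.1, 0.9, pre_run = 100, t_end = 500)
  tau <- relaxation_time(tr)
  expect_true(is.finite(tau))
  # during the plateau the carriers barely move while m0 drains
  mid <- tr$time > 0.2 * tau & tr$time < 0.6 * tau
  expect_lt(diff(range(tr$c[mid])), 1e-3)
  cls <- classify_plateau_decay(tr, tau)
  expect_identical(cls$better, "linear")
  expect_gt(cls$r2_linear, 0.999)
})

test_that("carrier-ratio perturbation conserves the pool and relaxes slowly", {
  p <- default_params(kin = 0.6)
  tr <- carrier_ratio_perturbation(p, ratio_active_after = 0.99,
                                   pre_run = 200, t_end = 1500)
  ct <- tr$c * (1 + tr$m0 / (p$K0 + tr$c))
  cst <- tr$cstar * (1 + tr$m1 / (p$K1 + tr$cstar))
  expect_lt(max(abs(ct + cst - 2)) / 2, 1e-7)  # cpool unchanged by the jump
  tau <- relaxation_time(tr)
  expect_true(is.finite(tau))
  expect_gt(tau, 50)  # slow transient, then snap

  # unchanged ratio at steady state: nothing happens (pre-run from the
  # all-active pool, whose csum matches the steady state being reassigned)
  ss <- ccc_steady_state(p, 2, 2)
  ct0 <- ss$c * (1 + ss$m0 / (p$K0 + ss$c))
  tr2 <- carrier_ratio_perturbation(p, ratio_active_after = ct0 / 2,
                                    pre_run = 2000, t_end = 50,
                                    state0 = ccc_state(c = 2))
  expect_lt(diff(range(tr2$m0)), 1e-4)
})

test_that("relaxation-time scan shows (kin_th - kin)^-1 critical scaling", {
  p <- default_params()
  sc <- relaxation_scan(p, kin_values = c(0.90, 0.93, 0.96, 0.98))
  expect_true(all(is.finite(sc$rows$tau)))
  expect_true(all(diff(sc$rows$tau) > 0))  # tau grows toward the threshold
  expect_equal(sc$fitted_exponent, -1, tolerance = 0.1)
  # doubling the backlog roughly doubles tau (constant-rate drainage)
  sc2 <- relaxation_scan(p, kin_values = 0.96, m0_init = 200)
  expect_equal(sc2$rows$tau / sc$rows$tau[3], 2, tolerance = 0.1)
  expect_error(relaxation_scan(p, kin_values = 0.99), "below")
})
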