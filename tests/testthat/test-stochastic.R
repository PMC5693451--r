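test_that("SSA paths are reproducible given a seed and conserve the carrier exactly", {
  p <- ccc_params(kin = 5, ka0 = 1e3, ka1 = 1e3)
  s0 <- ccc_state(m0 = 0, c = 20)
  a <- ssa_full(p, s0, t_end = 100, seed = 99)
  b <- ssa_full(p, s0, t_end = 100, seed = 99)
  expect_identical(a$time, b$time)
  expect_identical(a$n, b$n)
  expect_true(a$carrier_conserved)
  d <- ssa_full(p, s0, t_end = 100, seed = 100)
  expect_false(identical(a$time, d$time))

  # conservation over a long run with many events
  long <- ssa_full(p, s0, t_end = 3000, seed = 1)
  expect_gt(long$n_events, 1e5)
  expect_true(long$carrier_conserved)
  expect_equal(sum(long$final_state[c("c", "cstar", "cm0", "cstarm1")]), 20)
})

test_that("one-way conversion reaches the absorbing state", {
  # vanishing kp and kin: active carrier converts m0 to m1 until exhausted
  p <- ccc_params(kin = 1e-12, kp = 1e-12, kleak = 0, kout = 1,
                  ka0 = 1e3, ka1 = 1e3)
  s <- ssa_full(p, ccc_state(m0 = 50, c = 10), t_end = 500, seed = 7)
  fs <- s$final_state
  expect_equal(unname(fs[["c"]] + fs[["cm0"]]), 0)  # no active carrier left
  expect_lte(fs[["m1"]] + fs[["cstarm1"]], 50)
})

test_that("long-run full-model averages match the deterministic steady state", {
  p <- ccc_params(kin = 5, ka0 = 1e3, ka1 = 1e3)
  s <- ssa_full(p, ccc_state(m0 = 0, c = 20), t_end = 3000, seed = 3)
  st <- count_statistics(s, burn_in = 300)
  det <- ccc_steady_state(p, 20, 20)
  # time-averaged total m1 vs deterministic m1 (correlated samples: allow a
  # generous 3-sigma-ish band via the batch std error)
  expect_equal(st$mean, det$m1, tolerance = 0.15)
})

test_that("count statistics weight dwell times correctly", {
  # hand-built path: n = 2 on [0,1), 4 on [1,3): mean = (2 + 8)/3
  tr <- list(time = c(0, 1), n = c(2, 4), t_final = 3)
  st <- count_statistics(tr)
  expect_equal(st$mean, 10 / 3)
  expect_equal(st$variance, (1 * (2 - 10/3)^2 + 2 * (4 - 10/3)^2) / 3)

  # constant path: zero variance, zero Fano
  cst <- count_statistics(list(time = 0, n = 5, t_final = 10))
  expect_equal(cst$mean, 5)
  expect_equal(cst$fano, 0)
  expect_error(count_statistics(tr, burn_in = 5), "burn_in")
})

test_that("saturated limit model has the binomial Fano factor, unsaturated is Poissonian", {
  sat <- ssa_limit(kc = 1, kp = 1, cmax = 20, saturated = TRUE, n0 = 10,
                   t_end = 5e4, seed = 21)
  st <- count_statistics(sat, burn_in = 100)
  expect_equal(st$fano, 0.5, tolerance = 0.05)
  expect_equal(st$mean, 10, tolerance = 0.5)

  uns <- ssa_limit(kc = 1, kp = 1, kin = 100, saturated = FALSE, n0 = 100,
                   t_end = 5e3, seed = 22)
  su <- count_statistics(uns, burn_in = 100)
  expect_equal(su$fano, 1, tolerance = 0.1)
  expect_equal(su$mean, 100, tolerance = 2)
})

test_that("analytic Fano factor and its limits", {
  expect_equal(fano_analytic(1, 1), 0.5)
  expect_equal(fano_analytic(50, 12), 12 / 62)
  expect_equal(fano_analytic(1e-9, 1), 1, tolerance = 1e-8)
  # decreasing in kc, increasing in kp
  expect_lt(fano_analytic(2, 1), fano_analytic(1, 1))
  expect_gt(fano_analytic(1, 2), fano_analytic(1, 1))
})

test_that("master-equation oracle reproduces the closed-form stationary laws", {
  # carrier-feedback chain: binomial(cmax, kc/(kc+kp))
  kc <- 1.3; kp <- 0.7; cmax <- 30
  p <- master_equation_stationary(function(n) kc * (cmax - n),
                                  function(n) kp * n, nmax = cmax)
  q <- kc / (kc + kp)
  expect_equal(p, stats::dbinom(0:cmax, cmax, q), tolerance = 1e-12)
  m <- distribution_moments(p)
  expect_equal(m$fano, fano_analytic(kc, kp), tolerance = 1e-12)

  # constant birth: Poisson(lambda / kp)
  lam <- 5; kp2 <- 1.25
  pp <- master_equation_stationary(function(n) lam, function(n) kp2 * n,
                                   nmax = 80)
  expect_equal(pp, stats::dpois(0:80, lam / kp2) /
                 sum(stats::dpois(0:80, lam / kp2)), tolerance = 1e-10)
  expect_equal(distribution_moments(pp)$fano, 1, tolerance = 1e-6)
})

test_that("tabulated-rate SSA agrees with the master-equation stationary law", {
  # arbitrary rates on 0..25
  birth <- function(n) 2 + 0.5 * (25 - n) * (n < 25)
  death <- function(n) 0.9 * n
  pi_cme <- master_equation_stationary(birth, death, nmax = 40)
  s <- ssa_birth_death(vapply(0:40, birth, numeric(1)),
                       vapply(0:40, death, numeric(1)),
                       n0 = 5, t_end = 3e4, seed = 31)
  st <- count_statistics(s, burn_in = 100)
  mm <- distribution_moments(pi_cme)
  expect_equal(st$mean, mm$mean, tolerance = 0.03)
  expect_equal(st$fano, mm$fano, tolerance = 0.05)

  # empirical dwell-time distribution close in total variation
  w <- diff(c(s$time[s$time > 100], s$t_final))
  emp <- vapply(0:40, function(k)
    sum(w[s$n[s$time > 100] == k]), numeric(1))
  emp <- emp / sum(emp)
  expect_lt(0.5 * sum(abs(emp - pi_cme)), 0.02)
})

test_that("Fano sweep crosses from feedback suppression to Poisson as the pool grows", {
  sw <- fano_pool_sweep(kin = 100, kc = 1, kp = 1,
                        cpool_values = c(50, 100, 400, 600),
                        t_end = 1500, burn_in = 100, seed = 41)
  expect_true(all(sw$saturated == c(TRUE, TRUE, FALSE, FALSE)))
  expect_true(all(abs(sw$fano[1:2] - 0.5) < 0.05))
  expect_true(all(abs(sw$fano[3:4] - 1) < 0.1))
  # saturated mean grows ~linearly with the pool; unsaturated mean plateaus
  expect_equal(sw$mean[2] / sw$mean[1], 2, tolerance = 0.1)
  expect_equal(sw$mean[4], sw$mean[3], tolerance = 0.05)
})

test_that("Fano factor tracks 1 - kc/(kc+kp) across turnover ratios", {
  ratios <- c(0.2, 0.5, 0.8)
  for (r in ratios) {
    kc <- r / (1 - r)  # kp = 1
    s <- ssa_limit(kc = kc, kp = 1, cmax = 50, saturated = TRUE,
                   n0 = round(50 * r), t_end = 3e4 / max(kc, 1), seed = 50 + r * 10)
    st <- count_statistics(s, burn_in = 50)
    expect_equal(st$fano, 1 - r, tolerance = 0.05)
  }
})

test_that("double Michaelis-Menten comparator performs a random walk with Fano >= 1", {
  set.seed(61)
  finals <- vapply(1:150, function(i) {
    s <- ssa_double_mm(1, 1, 100, 100, n0 = 100, t_end = 4)
    s$n[length(s$n)]
  }, numeric(1))
  fano <- stats::var(finals) / mean(finals)
  expect_gt(fano, 1)   # never below 1: no conservation feedback
  # variance grows ~linearly: rate (kc c1 + kp c2) * t = 800 at t = 4
  expect_equal(stats::var(finals), 800, tolerance = 0.35)

  # biased walks hit zero or run away
  dn <- ssa_double_mm(1, 1, 50, 100, n0 = 30, t_end = 10, seed = 62)
  expect_lte(min(dn$n), 1)
  up <- ssa_double_mm(1, 1, 100, 50, n0 = 30, t_end = 50, seed = 63,
                      n_cap = 2000)
  expect_true(up$truncated || up$n[length(up$n)] > 1000)
})
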