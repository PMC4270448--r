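test_that("exponential progress model matches closed-form identities", {
  # no time elapsed, plateau, and the half-life identity t1/2 = ln(2)/kc
  expect_identical(exp_progress(Ff = 0.9, kc = 0.01, t = 0), 0)
  expect_equal(exp_progress(Ff = 0.9, kc = 0.01, t = Inf), 0.9)
  expect_equal(exp_progress(Ff = 1.0, kc = 0.01, t = log(2) / 0.01), 0.5)
  # monotone nondecreasing in t, bounded by Ff
  tt <- seq(0, 1000, length.out = 200)
  Fv <- exp_progress(Ff = 0.9, kc = 0.01, t = tt)
  expect_true(all(diff(Fv) >= 0))
  expect_true(all(Fv <= 0.9))
  expect_error(exp_progress(0.9, 0.01, -1), class = "resolvr_domain_error")
  expect_error(exp_progress(0.9, -0.01, 1), class = "resolvr_domain_error")
  expect_error(exp_progress(1.5, 0.01, 1), class = "resolvr_domain_error")
})

test_that("closed-form cruciform fractions match initial condition and ODE oracle", {
  r <- cruciform_rates(0.019, 0.20, "per_min")
  st0 <- cruciform_fractions(r, 0)
  expect_equal(unlist(st0[, c("fS", "fN", "fL")], use.names = FALSE), c(1, 0, 0))
  # value near the nicked-intermediate peak, checked against the integrator
  grid <- seq(0, 120, length.out = 241)
  ana <- cruciform_fractions(r, grid)
  num <- cruciform_ode(r, grid)
  expect_lt(max(abs(as.matrix(ana[, 2:4]) - as.matrix(num[, 2:4]))), 1e-6)
  expect_equal(cruciform_fractions(r, 13.0)$fN, 0.074, tolerance = 1e-2)
  expect_error(cruciform_fractions(r, -1), class = "resolvr_domain_error")
})

test_that("degenerate k1 == k2 branch uses the confluent limit, continuously", {
  # analytic limit k1*t*exp(-k1*t) at k1 = k2 = 0.1, t = 10 -> e^-1
  st <- cruciform_fractions(cruciform_rates(0.1, 0.1), 10)
  expect_equal(st$fN, exp(-1), tolerance = 1e-12)
  # against the ODE oracle on a grid
  r <- cruciform_rates(0.05, 0.05)
  grid <- seq(0, 200, length.out = 101)
  expect_lt(max(abs(cruciform_fractions(r, grid)$fN - cruciform_ode(r, grid)$fN)),
            1e-6)
  # continuity across the degeneracy threshold
  k1 <- 0.1
  near <- cruciform_fractions(cruciform_rates(k1, k1 * (1 + 1e-9)), grid)
  lim <- cruciform_fractions(cruciform_rates(k1, k1), grid)
  expect_lt(max(abs(near$fN - lim$fN)), 1e-8)
})

test_that("species fractions conserve mass and are monotone/unimodal", {
  set.seed(42)
  for (i in 1:100) {
    # rate pairs spanning 4 orders of magnitude
    k <- 10^runif(2, -2, 2)
    r <- cruciform_rates(k[1], k[2])
    tt <- seq(0, 10 / min(k), length.out = 50)
    st <- cruciform_fractions(r, tt)
    expect_lt(max(abs(st$fS + st$fN + st$fL - 1)), 1e-12)
    # strict monotonicity, away from floating-point saturation at 0 / 1
    live <- st$fS > 1e-12 & st$fL < 1 - 1e-12
    expect_true(all(diff(st$fS[live]) < 0))
    expect_true(all(diff(st$fL[live]) > 0))
    # fN rises then falls: exactly one sign change in its differences
    dN <- diff(st$fN)
    expect_lte(sum(diff(sign(dN[dN != 0])) != 0), 1)
  }
})

test_that("analytic and numerically integrated trajectories agree broadly", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    k <- 10^runif(2, -2, 2)
    r <- cruciform_rates(k[1], k[2])
    tt <- seq(0, 10 / min(k), length.out = 40)
    d <- max(abs(as.matrix(cruciform_fractions(r, tt)[, 2:4]) -
                 as.matrix(cruciform_ode(r, tt)[, 2:4])))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-6)
})

test_that("nicked-intermediate peak location and height are the argmax", {
  # degenerate-limit formula t* = 1/k1
  expect_equal(nicked_peak(cruciform_rates(0.1, 0.1))$time, 10)
  # grid-search oracle for the asymmetric case
  r <- cruciform_rates(0.019, 0.20)
  pk <- nicked_peak(r)
  grid <- seq(0.01, 120, length.out = 20000)
  fN <- cruciform_fractions(r, grid)$fN
  expect_equal(pk$time, grid[which.max(fN)], tolerance = 1e-3)
  expect_equal(pk$time, 13.0, tolerance = 5e-3)
  expect_lt(pk$height, 1)
  # local maximality for assorted rate pairs
  set.seed(11)
  for (i in 1:20) {
    k <- 10^runif(2, -1.5, 1.5)
    r <- cruciform_rates(k[1], k[2])
    pk <- nicked_peak(r)
    eps <- pk$time * 1e-4
    f <- function(t) cruciform_fractions(r, t)$fN
    expect_gte(pk$height, f(pk$time - eps))
    expect_gte(pk$height, f(pk$time + eps))
  }
})

test_that("rate-unit conversion is explicit and exact", {
  expect_equal(convert_rate(0.008, "per_s", "per_min"), 0.48)
  expect_equal(convert_rate(0.48, "per_min", "per_s"), 0.008)
  expect_equal(convert_rate(1.5, "per_min", "per_min"), 1.5)
  r <- cruciform_rates(0.019, 0.20, unit = "per_min")
  expect_equal(r$acceleration, 0.20 / 0.019)
  expect_error(cruciform_rates(-1, 1), class = "resolvr_domain_error")
  expect_error(cruciform_rates(0.1, 0.2, unit = "per_hour"),
               class = "resolvr_domain_error")
})
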