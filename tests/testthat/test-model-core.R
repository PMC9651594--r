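test_that("production and uptake kinetics hit their half-max and limit identities", {
  expect_equal(fixation_rate(0, b = 2, ell = 3), 2)
  expect_equal(fixation_rate(3, b = 2, ell = 3), 1)       # half-inhibition
  expect_equal(fixation_rate(Inf, b = 2, ell = 3), 0)
  expect_equal(fixation_rate(5, b = 0, ell = 3), 0)       # LOF mutant
  expect_equal(siderophore_production_rate(0, q = 1.75, m = 1), 1.75)
  expect_equal(siderophore_production_rate(1, q = 1.75, m = 1), 0.875)
  expect_equal(nitrogen_uptake(0, a = 3, d = 2), 0)
  expect_equal(nitrogen_uptake(2, a = 3, d = 2), 1.5)     # half-saturation
  expect_equal(nitrogen_uptake(Inf, a = 3, d = 2), 3)
  expect_equal(siderophore_uptake(1.85, u = 1, p = 1.85), 0.5)
  expect_equal(siderophore_uptake(Inf, u = 1, p = 1.85), 1)
  expect_error(fixation_rate(-1, 1, 1), "non-negative")
  expect_error(nitrogen_uptake(c(1, -2), 1, 1), "non-negative")
})

test_that("nitrogen acquisition combines privatized fixation and uptake", {
  p <- colim_params(b = 2)           # alpha 0.875, a 3, d 2, ell 3
  expect_equal(nitrogen_acquisition(1, p), 0.875 * 1.5 + 1)  # 2.3125
  p0 <- p
  p0$b <- 0
  expect_equal(nitrogen_acquisition(1.3, p0), nitrogen_uptake(1.3, 3, 2))
  expect_equal(nitrogen_acquisition(0, p), 0.875 * 2)
})

test_that("half-saturation for growth follows siderophore uptake", {
  p <- colim_params(b = 1)
  # S where siderophore uptake equals k_S: h doubles the uptake-unlimited value
  S_half <- p$p * p$k_S / (p$u - p$k_S)
  expect_equal(half_saturation(S_half, p), 2 * p$r / p$c, tolerance = 1e-12)
  expect_equal(half_saturation(Inf, p), (p$r / p$c) * (1 + p$k_S / p$u))
  expect_identical(half_saturation(0, p), Inf)
  # strictly decreasing in S
  S <- seq(0.01, 5, length.out = 50)
  expect_true(all(diff(half_saturation(S, p)) < 0))
})

test_that("colimited growth saturates at r and vanishes without siderophores", {
  p <- colim_params(b = 1)
  expect_equal(colimited_growth(0, 1, p), 0)
  expect_lt(colimited_growth(10, 50, p), p$r)
  expect_equal(colimited_growth(Inf, Inf, p),
               p$r * p$a / (p$a + half_saturation(Inf, p)))
  # monotone in both resources
  S <- seq(0.01, 4, length.out = 30)
  N <- seq(0, 4, length.out = 30)
  expect_true(all(diff(colimited_growth(S, 1, p)) > 0))
  expect_true(all(diff(colimited_growth(1, N, p)) > 0))
})

test_that("strains differing only in siderophore production differ in growth by its cost", {
  set.seed(42)
  for (i in 1:20) {
    b <- small_batch()
    sv <- derive_strains(batch_params(b, sample(b$n_accepted, 1)))
    S <- runif(1, 0, 3)
    N <- runif(1, 0, 3)
    dg <- per_capita_growth(S, N, sv$LOFS) - per_capita_growth(S, N, sv$Full)
    cost <- sv$Full$beta *
      siderophore_production_rate(S, sv$Full$q, sv$Full$m)
    expect_equal(dg, cost, tolerance = 1e-12)
    # and the same with fixation: LOFN vs Full at equal resources
    dgn <- per_capita_growth(S, N, sv$Full) - per_capita_growth(S, N, sv$LOFN)
    Gdiff <- colimited_growth(S, N, sv$Full) - colimited_growth(S, N, sv$LOFN)
    expect_equal(dgn, Gdiff - sv$Full$gamma * fixation_rate(N, sv$Full$b, sv$Full$ell),
                 tolerance = 1e-12)
  }
  lofb <- derive_strains(colim_params(b = 1))$LOFB
  expect_equal(per_capita_growth(0, 0.5, lofb), -lofb$delta)
})

test_that("growth sensitivity equals the numerical derivative of growth in acquisition", {
  set.seed(8)
  b <- small_batch()
  for (i in 1:15) {
    pr <- batch_params(b, sample(b$n_accepted, 1))
    S <- runif(1, 0.05, 3)
    N <- runif(1, 0.05, 3)
    h <- 1e-5
    dG <- (colimited_growth(S, N + h, pr) - colimited_growth(S, N - h, pr)) / (2 * h)
    deta <- (nitrogen_acquisition(N + h, pr) - nitrogen_acquisition(N - h, pr)) / (2 * h)
    if (abs(deta) < 1e-10) next
    expect_equal(growth_sensitivity(S, N, pr), dG / deta, tolerance = 1e-6)
  }
  # closed-form spot check at eta == h: sensitivity = r / (4 h)
  p <- colim_params(b = 1)
  S0 <- 1
  hval <- half_saturation(S0, p)
  eta_target <- function(N) nitrogen_acquisition(N, p) - hval
  if (eta_target(0) < 0 && eta_target(1e6) > 0) {
    Nstar <- uniroot(eta_target, c(0, 1e6), tol = 1e-12)$root
    expect_equal(growth_sensitivity(S0, Nstar, p), p$r / (4 * hval),
                 tolerance = 1e-8)
  }
})

test_that("colimitation dynamics respect supply points, privatization, and positivity", {
  p <- colim_params(b = 1.2)
  sv <- derive_strains(p)
  # no cells: supply point is a fixed point of the resource dynamics
  d0 <- rhs_colimitation(0, c(p$mu_N / p$rho, p$mu_S / p$rho, 0),
                         list(sv$Full))
  expect_equal(d0[[1]], c(0, 0, 0), tolerance = 1e-12)
  # full privatization: no leakage of fixed nitrogen into the pool
  p1 <- p
  p1$alpha <- 1
  s1 <- derive_strains(p1)$Full
  d1 <- rhs_colimitation(0, c(0.5, 0.5, 2), list(s1))
  UN <- nitrogen_uptake(0.5, p$a, p$d)
  expect_equal(d1[[1]][1], p$mu_N - p$rho * 0.5 - 2 * UN, tolerance = 1e-12)
  # trajectories from random non-negative states stay non-negative
  set.seed(11)
  for (i in 1:8) {
    init <- runif(4, 0, 2)
    eq <- integrate_to_equilibrium(list(sv$Full, sv$LOFB), init = init,
                                   horizon = 500)
    expect_true(all(eq$state > -1e-8))
  }
})

test_that("solver-reported derivatives match the model right-hand side along a trajectory", {
  sv <- derive_strains(colim_params(b = 1))
  strains <- list(sv$Full, sv$LOFS)
  times <- seq(0, 10, by = 0.05)
  out <- deSolve::ode(c(0.3, 0.3, 0.3, 0.3), times,
                      function(t, y, parms) rhs_colimitation(t, y, strains),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  # central finite differences of the dense solution against the RHS
  for (k in c(40, 100, 160)) {
    fd <- (out[k + 1, -1] - out[k - 1, -1]) / (times[k + 1] - times[k - 1])
    rhs <- rhs_colimitation(times[k], out[k, -1], strains)[[1]]
    expect_lt(max(abs(unname(fd) - rhs)), 1e-3)
  }
})
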