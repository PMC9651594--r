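test_that("fitness gradients push leakiness down and siderophore production out", {
  p <- colim_params(b = 1)
  expect_gt(fitness_gradient(p, "alpha", 0.875), 0)
  expect_lt(fitness_gradient(p, "q", 1.75), 0)
  g0 <- fitness_gradient(p, "q", 0.8)
  expect_lt(g0, 0)
  # a non-viable resident reports its status instead of a number
  pdead <- colim_params(b = 0, q = 0, r = 0.3, delta = 0.45)
  gna <- fitness_gradient(pdead, "b", 0)
  expect_true(is.na(gna))
  expect_identical(attr(gna, "status"), "extinct")
})

test_that("pairwise invasibility grids have a zero diagonal and mark dead residents", {
  p <- colim_params(alpha = 0.62, gamma = 0.25)
  pip <- compute_pip(p, "b", grid = seq(0, 2, length.out = 9))
  ok <- pip$resident_status == "viable_equilibrium"
  expect_true(any(ok))
  expect_true(all(abs(diag(pip$growth)[ok]) < 1e-8))
  expect_true(all(is.na(pip$growth[, !ok])))
})

test_that("the two fixation regimes separate by privatization and cost", {
  e1 <- find_ess(colim_params(alpha = 0.5, gamma = 0.35), "b", n_grid = 11)
  expect_identical(e1$regime, "loss_of_trait")
  expect_equal(e1$ess_value, 0)
  e2 <- find_ess(colim_params(alpha = 0.62, gamma = 0.25), "b", n_grid = 11)
  expect_identical(e2$regime, "interior_ESS")
  expect_gt(e2$ess_value, 0)
  expect_true(e2$uninvasible)
  # fitness gradient vanishes at the interior strategy
  expect_lt(abs(fitness_gradient(colim_params(alpha = 0.62, gamma = 0.25),
                                 "b", e2$ess_value)), 1e-3)
})

test_that("siderophore production is never evolutionarily stable", {
  for (ag in list(c(0.875, 0.4), c(0.62, 0.25))) {
    e <- find_ess(colim_params(b = 1, alpha = ag[1], gamma = ag[2]), "q",
                  n_grid = 9)
    expect_identical(e$regime, "loss_of_trait")
    expect_equal(e$ess_value, 0)
  }
})

test_that("the isocline envelope is uninvasible and orders fixation along limitation", {
  p <- colim_params(alpha = 0.62, gamma = 0.25)
  vals <- seq(0, 2, length.out = 21)
  env <- zngi_envelope(p, "b", values = vals, n = 60)
  # single member: envelope equals that strain's isocline
  one <- zngi_envelope(p, "b", values = 1.2, S_grid = env$S[seq(5, 40, by = 5)])
  expect_equal(one$N, zngi_nitrogen(one$S, set_trait_pg(p, 1.2)),
               tolerance = 1e-7)
  # envelope points admit no invader from the trait family
  idx <- seq(2, nrow(env), length.out = 12)
  for (k in round(idx)) {
    g <- vapply(vals, function(v) {
      per_capita_growth(env$S[k], env$N[k], set_trait_pg(p, v))
    }, numeric(1))
    expect_lt(max(g), 1e-7)
  }
  # fixation turns on moving from siderophore- to nitrogen-limited ends
  expect_equal(env$trait_value[1], 0)
  expect_gt(env$trait_value[nrow(env)], 0)
  flips <- sum(diff(env$trait_value > 1e-9) != 0)
  expect_identical(flips, 1L)
})

test_that("the critical supply ratio moves with privatization and brackets the transition", {
  p <- colim_params(alpha = 0.62, gamma = 0.25)
  cr <- critical_ns_ratio(p, values = seq(0, 2, length.out = 21), n = 60)
  expect_gt(cr$ratio, 0)
  # the envelope trait flips across the located transition point
  fam_zero <- set_trait_pg(p, 0)
  eps <- cr$S * 1e-3
  nm <- function(S) {
    vals <- seq(0, 2, length.out = 21)
    Ns <- vapply(vals, function(v) {
      privgoods:::envelope_N(S, set_trait_pg(p, v))
    }, numeric(1))
    vals[which.min(Ns)]
  }
  expect_identical(nm(cr$S - eps) > 1e-9, !(nm(cr$S + eps) > 1e-9))
  # more privatization extends fixation into less nitrogen-limited systems
  p_hi <- colim_params(alpha = 0.875, gamma = 0.25)
  cr_hi <- critical_ns_ratio(p_hi, values = seq(0, 2, length.out = 21), n = 60)
  expect_gt(cr_hi$ratio, cr$ratio)
  # a hopeless trait family reports the loss sentinel
  p_loss <- colim_params(alpha = 0.1, gamma = 0.9)
  cr_loss <- critical_ns_ratio(p_loss, values = seq(0, 2, length.out = 11),
                               n = 40)
  expect_true(is.na(cr_loss$ratio))
  expect_match(cr_loss$reason, "loss")
})
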