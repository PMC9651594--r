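test_that("integration protocol classifies empty, extinct and viable communities", {
  p <- colim_params(b = 1)
  # cell-free environment relaxes to the supply point
  eq0 <- integrate_to_equilibrium(list(), env = p)
  expect_equal(unname(eq0$resources), c(p$mu_S / p$rho, p$mu_N / p$rho),
               tolerance = 1e-6)
  # mortality above the growth ceiling is always fatal
  pdead <- colim_params(b = 0, q = 0, r = 0.3, delta = 0.45)
  eqd <- integrate_to_equilibrium(derive_strains(pdead)$LOFB)
  expect_identical(eqd$status, "extinct")
  expect_lt(eqd$density, 1e-8)
  # the default strain equilibrates with zero net per-capita growth
  eq <- integrate_to_equilibrium(derive_strains(p)$Full)
  expect_identical(eq$status, "viable_equilibrium")
  expect_lt(abs(per_capita_growth(eq$resources[["S"]], eq$resources[["N"]],
                                  derive_strains(p)$Full)), 1e-9)
})

test_that("minimum resource requirements depend only on the relevant production trait", {
  p <- colim_params(b = 1)
  sv <- derive_strains(p)
  # hand-derived chain for the dual-loss strain at the default point
  expect_equal(asymptote_nstar(sv$LOFB), 0.34375, tolerance = 1e-9)
  # N* shared within fixer / non-fixer groups
  expect_equal(asymptote_nstar(sv$Full), asymptote_nstar(sv$LOFS), tolerance = 1e-10)
  expect_equal(asymptote_nstar(sv$LOFN), asymptote_nstar(sv$LOFB), tolerance = 1e-10)
  # S* shared within siderophore producer / non-producer groups
  expect_equal(asymptote_sstar(sv$Full), asymptote_sstar(sv$LOFN), tolerance = 1e-10)
  expect_equal(asymptote_sstar(sv$LOFS), asymptote_sstar(sv$LOFB), tolerance = 1e-10)
  # production always raises the producer's own siderophore requirement
  expect_gt(asymptote_sstar(sv$Full), asymptote_sstar(sv$LOFB))
  # unless it is free
  pfree <- p
  pfree$beta <- 0
  expect_equal(asymptote_sstar(derive_strains(pfree)$Full),
               asymptote_sstar(derive_strains(pfree)$LOFB), tolerance = 1e-10)
  # higher mortality demands more nitrogen
  phigh <- p
  phigh$delta <- 0.45
  expect_gt(asymptote_nstar(derive_strains(phigh)$LOFB),
            asymptote_nstar(sv$LOFB))
})

test_that("traced isoclines satisfy the zero-growth definition and their asymptotes", {
  sv <- derive_strains(colim_params(b = 1))
  z <- trace_zngi(sv$Full, n = 40)
  pts <- z[!is.na(z$N), ]
  g <- per_capita_growth(pts$S, pts$N, sv$Full)
  expect_true(all(abs(g) < 1e-9))
  expect_true(all(diff(pts$N) <= 1e-9))            # non-increasing
  expect_true(all(pts$S > attr(z, "S_star")))
  expect_true(all(pts$N > attr(z, "N_star")))
  # approaches N* from above at high S, diverges near S*
  expect_equal(pts$N[nrow(pts)], attr(z, "N_star"), tolerance = 1e-2)
  expect_gt(pts$N[1], 10 * attr(z, "N_star"))
  # the siderophore producer's isocline encloses the non-producer's
  zs <- zngi_nitrogen(pts$S, sv$LOFS)
  expect_true(all(pts$N > zs | is.na(zs)))
  # grid points at or below S* are dropped with a count
  z2 <- trace_zngi(sv$Full, S_grid = c(attr(z, "S_star") * 0.5, pts$S[1:3]))
  expect_identical(attr(z2, "dropped"), 1L)
})

test_that("impact vectors encode net resource consumption and production", {
  p <- colim_params(b = 1)
  sv <- derive_strains(p)
  iv <- impact_vector(0.8, 0.7, sv$LOFB)
  expect_lt(iv[["I_S"]], 0)                        # pure consumer
  expect_lt(iv[["I_N"]], 0)
  expect_equal(iv[["I_N"]], -nitrogen_uptake(0.7, p$a, p$d))
  p1 <- p
  p1$alpha <- 1
  iv1 <- impact_vector(0.8, 0.7, derive_strains(p1)$Full)
  expect_equal(iv1[["I_N"]], -nitrogen_uptake(0.7, p$a, p$d))
  # angular ordering at a shared point: sweeping from LOFN through LOFB to
  # LOFS is one consistent rotation (siderophore production rotates the
  # impact one way, nitrogen leakage the other)
  set.seed(13)
  b <- small_batch()
  for (i in 1:25) {
    svr <- derive_strains(batch_params(b, sample(b$n_accepted, 1)))
    S <- runif(1, 0.05, 2)
    N <- runif(1, 0.05, 2)
    ivs <- lapply(svr[c("LOFN", "LOFB", "LOFS")],
                  function(pr) impact_vector(S, N, pr))
    expect_gte(cross2(ivs$LOFB, ivs$LOFN), -1e-12)
    expect_lte(cross2(ivs$LOFB, ivs$LOFS), 1e-12)
  }
})

test_that("algebraic supply-point mapping matches time integration", {
  sv <- derive_strains(colim_params(b = 1))
  mp <- map_supply_to_equilibrium(sv$Full)
  expect_identical(mp$status, "viable_equilibrium")
  expect_true(mp$matched)
  # the equilibrium sits on the strain's isocline
  expect_equal(zngi_nitrogen(mp$resources[["S"]], sv$Full),
               mp$resources[["N"]], tolerance = 1e-7)
  # an empty environment keeps the supply point
  pzero <- colim_params(b = 0, q = 0, mu_S = 0, mu_N = 0)
  mp0 <- map_supply_to_equilibrium(derive_strains(pzero)$LOFB)
  expect_identical(mp0$status, "extinct")
  expect_equal(unname(mp0$resources), c(0, 0))
  expect_equal(mp0$density, 0)
})
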