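test_that("invasion growth vanishes for the resident and follows the cost identity", {
  sv <- derive_strains(colim_params(b = 1))
  eq <- integrate_to_equilibrium(sv$Full)
  expect_lt(abs(invasion_growth_rate(sv$Full, eq)), 1e-9)
  gS <- invasion_growth_rate(sv$LOFS, eq)
  expect_equal(gS, sv$Full$beta *
                 siderophore_production_rate(eq$resources[["S"]], sv$Full$q,
                                             sv$Full$m),
               tolerance = 1e-8)
  expect_gt(gS, 0)
  expect_error(invasion_growth_rate(sv$LOFS, integrate_to_equilibrium(
    derive_strains(colim_params(b = 0, q = 0, r = 0.3, delta = 0.45))$LOFB)),
    "not at a viable equilibrium")
})

test_that("loss of siderophore production always wins its pairwise competitions", {
  b <- small_batch()
  checked <- 0
  for (i in seq_len(b$n_accepted)) {
    sv <- derive_strains(batch_params(b, i))
    eqF <- integrate_to_equilibrium(sv$Full)
    if (eqF$status != "viable_equilibrium") next
    oc <- classify_pairwise(sv$Full, sv$LOFS)
    expect_identical(oc$classification, "B_excludes_A")
    ocn <- classify_pairwise(sv$LOFN, sv$LOFB)
    expect_true(ocn$classification %in% c("B_excludes_A", "neither_viable"))
    checked <- checked + 1
    if (checked >= 6) break
  }
  expect_gte(checked, 3)
})

test_that("invasion signs agree with direct two-strain integration", {
  set.seed(17)
  b <- small_batch()
  checked <- 0
  for (i in seq_len(b$n_accepted)) {
    sv <- derive_strains(batch_params(b, i))
    eqR <- integrate_to_equilibrium(sv$Full)
    if (eqR$status != "viable_equilibrium") next
    inv <- sv$LOFN
    g <- invasion_growth_rate(inv, eqR)
    if (abs(g) < 1e-6) next
    init <- c(eqR$resources[["N"]], eqR$resources[["S"]], eqR$density[1], 1e-6)
    two <- integrate_to_equilibrium(list(sv$Full, inv), init = init,
                                    horizon = 2e4)
    if (two$status == "unbounded") next
    grew <- two$density[2] > 1e-5
    expect_identical(grew, g > 0)
    checked <- checked + 1
    if (checked >= 8) break
  }
  expect_gte(checked, 4)
})

test_that("coexistence points lie on both isoclines and geometry matches integration", {
  expect_error(find_coexistence(derive_strains(colim_params(b = 1))$Full,
                                derive_strains(colim_params(b = 1))$Full),
               "degenerate")
  set.seed(9)
  bb <- sample_parameters(260, seed = 9)
  n_found <- 0
  for (i in seq_len(260)) {
    sv <- derive_strains(batch_params(bb, i))
    cx <- tryCatch(find_coexistence(sv$LOFS, sv$LOFB),
                   error = function(e) NULL)
    if (is.null(cx) || nrow(cx) == 0) next
    for (k in seq_len(nrow(cx))) {
      expect_equal(zngi_nitrogen(cx$S[k], sv$LOFS), cx$N[k], tolerance = 1e-6)
      expect_equal(zngi_nitrogen(cx$S[k], sv$LOFB), cx$N[k], tolerance = 1e-6)
    }
    feas <- cx[cx$feasible, , drop = FALSE]
    if (nrow(feas) == 0) next
    # fixation trading off across the two limitation regimes: coexistence
    # between the two non-siderophore producers is stable
    expect_true(all(feas$stable))
    out <- privgoods:::pairwise_integration(sv$LOFS, sv$LOFB)
    surv <- vapply(out, function(o) all(o$survivors), logical(1))
    expect_true(all(surv))
    n_found <- n_found + 1
    if (n_found >= 2) break
  }
  expect_gte(n_found, 1)
})

test_that("privatization bounds order correctly and classify the three regimes", {
  p <- colim_params(b = 1)
  p0 <- p
  p0$gamma <- 0
  expect_equal(privatization_bound(p0, "N_limited"), 0)
  b <- small_batch()
  for (i in seq_len(20)) {
    pr <- batch_params(b, i)
    bN <- privatization_bound(pr, "N_limited", from_absence = TRUE)
    bS <- privatization_bound(pr, "S_limited", from_absence = TRUE)
    if (is.na(bN) || is.na(bS)) next
    expect_lte(bN, bS + 1e-9)
  }
  # regime agrees with the sign of dN*/db at small b (finite differences)
  for (i in seq_len(15)) {
    pr <- batch_params(b, i)
    pr$b <- 0
    reg <- classify_fixation_regime(pr)
    if (is.na(reg)) next
    h <- 1e-4
    n0 <- asymptote_nstar(pr)
    prh <- pr
    prh$b <- h
    n1 <- asymptote_nstar(prh)
    if (is.na(n0) || is.na(n1) || n0 == 0) next
    dNdb <- (n1 - n0) / h
    if (abs(dNdb) < 1e-8) next
    expect_identical(dNdb < 0, reg %in% c("net_benefit", "environment_dependent"))
  }
})

test_that("fixation can invade from absence only under permissive demography", {
  base <- colim_params(b = 1)
  # death near the growth ceiling: bound diverges
  pd <- base
  pd$delta <- 1.99
  pd$r <- 2
  pd <- do.call(colim_params, pd[param_names()])
  expect_false(isTRUE(fixation_benefit_at_b0(pd)))
  # strong colimitation also blocks it
  pk <- base
  pk$k_S <- 50
  pk <- do.call(colim_params, pk[param_names()])
  expect_false(isTRUE(fixation_benefit_at_b0(pk)))
  # the numeric bound matches the independently derived closed form at b = 0
  for (al in c(0.3, 0.875)) {
    p <- colim_params(b = 0)
    p$alpha <- al
    bound <- privatization_bound(p, "N_limited")
    closed <- p$gamma * p$r^2 * (1 + p$k_S / p$u) / (p$c * (p$r - p$delta)^2)
    expect_equal(bound, closed, tolerance = 1e-8)
    expect_identical(fixation_benefit_at_b0(p), al > closed)
  }
})
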