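#' Invasion growth rate of a rare strain at a resident's equilibrium
#'
#' The per-capita growth rate a vanishingly rare invader would experience in
#' the resource environment `(S*, N*)` set by the resident at equilibrium.
#' A positive value means the invader can increase from rarity.
#'
#' @param invader a strain-realized [colim_params()] object.
#' @param resident_eq an `equilibrium_result` from
#'   [integrate_to_equilibrium()] (status must be `"viable_equilibrium"`),
#'   or a named vector `c(S, N)` of resident equilibrium concentrations.
#' @return The invasion growth rate (scalar).
#' @export
invasion_growth_rate <- function(invader, resident_eq) {
  if (inherits(resident_eq, "equilibrium_result")) {
    if (resident_eq$status != "viable_equilibrium") {
      stop("resident is not at a viable equilibrium (status: ",
           resident_eq$status, ")")
    }
    res <- resident_eq$resources
  } else {
    res <- resident_eq
  }
  per_capita_growth(res[["S"]], res[["N"]], invader)
}

# Geometric stability of a coexistence point from the orientation of the
# two strains' impact vectors relative to their ZNGI normals (the gradients
# of per-capita growth). Stable when each strain impacts most the resource
# that limits its own growth; crossed orientations give a priority effect.
geometric_stability <- function(S, N, paramsA, paramsB, h = 1e-6) {
  grad <- function(pr) {
    c(dS = (per_capita_growth(S + h, N, pr) - per_capita_growth(max(S - h, 0), N, pr)) /
        (S + h - max(S - h, 0)),
      dN = (per_capita_growth(S, N + h, pr) - per_capita_growth(S, max(N - h, 0), pr)) /
        (N + h - max(N - h, 0)))
  }
  nA <- grad(paramsA)
  nB <- grad(paramsB)
  IA <- impact_vector(S, N, paramsA)
  IB <- impact_vector(S, N, paramsB)
  det2 <- function(v, w) v[1] * w[2] - v[2] * w[1]
  # sign convention verified against perturbed integration (see tests):
  # stable iff the impact vectors are ordered the same way (by angle) as the
  # growth-limitation normals
  stable <- det2(nA, nB) * det2(IA, IB) > 0
  list(stable = stable, normals = list(A = nA, B = nB),
       impacts = list(A = IA, B = IB))
}

#' Locate coexistence equilibria of two strains
#'
#' Any coexistence equilibrium must lie at an intersection of the two
#' strains' ZNGIs. The intersections are located by scanning the difference
#' of the two isoclines over a log-spaced siderophore grid and refining sign
#' changes; at each intersection the equilibrium densities are obtained from
#' the linear resource-balance equations and stability is classified from
#' the relative orientation of the two impact vectors.
#'
#' @param paramsA,paramsB strain-realized [colim_params()] objects sharing
#'   the environmental parameters.
#' @param S_range search range of siderophore concentrations; defaults to
#'   a wide log-spaced window above both strains' `S*`.
#' @param n grid resolution.
#' @return A data.frame with one row per intersection: `S`, `N`, densities
#'   `x_A`, `x_B` (from the supply-balance equations; may be negative when
#'   the point is infeasible for the current supply), `feasible`, and
#'   `stable` (impact-vector geometry). Zero rows when the ZNGIs do not
#'   cross. Strains with identical production traits are rejected as
#'   degenerate.
#' @export
find_coexistence <- function(paramsA, paramsB, S_range = NULL, n = 160) {
  if (isTRUE(all.equal(paramsA$b, paramsB$b)) &&
      isTRUE(all.equal(paramsA$q, paramsB$q))) {
    stop("degenerate pair: identical production traits give identical ZNGIs")
  }
  sA <- asymptote_sstar(paramsA)
  sB <- asymptote_sstar(paramsB)
  if (is.na(sA) || is.na(sB)) {
    return(coexistence_frame())
  }
  lo <- max(sA, sB) * (1 + 1e-9) + 1e-12
  if (is.null(S_range)) S_range <- c(lo, lo + 1e4)
  grid <- lo + exp(seq(log(1e-8), log(S_range[2] - lo), length.out = n))
  dN <- function(s) {
    zngi_nitrogen(s, paramsA) - zngi_nitrogen(s, paramsB)
  }
  vals <- vapply(grid, dN, numeric(1))
  ok <- is.finite(vals)
  rows <- list()
  idx <- which(ok[-1] & ok[-length(ok)] & vals[-1] * vals[-length(vals)] <= 0)
  for (i in idx) {
    rt <- tryCatch(
      stats::uniroot(dN, c(grid[i], grid[i + 1]), tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.na(rt)) next
    Nc <- zngi_nitrogen(rt, paramsA)
    IA <- impact_vector(rt, Nc, paramsA)
    IB <- impact_vector(rt, Nc, paramsB)
    M <- rbind(c(IA[["I_N"]], IB[["I_N"]]), c(IA[["I_S"]], IB[["I_S"]]))
    rhs <- c(paramsA$rho * Nc - paramsA$mu_N, paramsA$rho * rt - paramsA$mu_S)
    x <- tryCatch(solve(M, rhs), error = function(e) c(NA_real_, NA_real_))
    geo <- geometric_stability(rt, Nc, paramsA, paramsB)
    rows[[length(rows) + 1]] <- data.frame(
      S = rt, N = Nc, x_A = x[1], x_B = x[2],
      feasible = all(is.finite(x)) && all(x > 0),
      stable = geo$stable)
  }
  if (length(rows) == 0) return(coexistence_frame())
  do.call(rbind, rows)
}

coexistence_frame <- function() {
  data.frame(S = numeric(0), N = numeric(0), x_A = numeric(0),
             x_B = numeric(0), feasible = logical(0), stable = logical(0))
}

#' Classify the outcome of pairwise competition between two strains
#'
#' Runs both monoculture equilibria, evaluates the two reciprocal invasion
#' growth rates, and classifies the pair: one-way invasion gives exclusion;
#' mutual invasibility or mutual non-invasibility triggers the
#' coexistence-point analysis (stable coexistence versus priority effect).
#' Invasion growth within `tie_tol` of zero counts as failed invasion
#' (conservative at the measure-zero boundary).
#'
#' @param paramsA,paramsB strain-realized [colim_params()] objects sharing
#'   environmental parameters.
#' @param tie_tol invasion-growth magnitude below which invasion is treated
#'   as failed.
#' @param integrate_check also integrate the two-strain system from several
#'   initial conditions (including near-monoculture corners) and report the
#'   surviving strains per start.
#' @return A list of class `competition_outcome` with fields `pair`,
#'   `classification` (one of `"A_excludes_B"`, `"B_excludes_A"`,
#'   `"stable_coexistence"`, `"priority_effect"`, `"neither_viable"`,
#'   `"unbounded"`), `invasion` (the two invasion growth rates),
#'   `coexistence` (data.frame from [find_coexistence()]), and optionally
#'   `integration` (per-start survivor sets).
#' @export
classify_pairwise <- function(paramsA, paramsB, tie_tol = 1e-9,
                              integrate_check = FALSE) {
  labA <- attr(paramsA, "strain") %||% "A"
  labB <- attr(paramsB, "strain") %||% "B"
  eqA <- integrate_to_equilibrium(paramsA)
  eqB <- integrate_to_equilibrium(paramsB)
  if (eqA$status == "unbounded" || eqB$status == "unbounded") {
    return(competition_outcome(labA, labB, "unbounded", c(NA, NA), NULL))
  }
  vA <- eqA$status == "viable_equilibrium"
  vB <- eqB$status == "viable_equilibrium"
  if (!vA && !vB) {
    return(competition_outcome(labA, labB, "neither_viable", c(NA, NA), NULL))
  }
  gBatA <- if (vA) invasion_growth_rate(paramsB, eqA) else NA_real_
  gAatB <- if (vB) invasion_growth_rate(paramsA, eqB) else NA_real_
  invB <- vA && gBatA > tie_tol   # B invades A's equilibrium
  invA <- vB && gAatB > tie_tol   # A invades B's equilibrium
  cls <- if (!vB) {
    if (!invB) "A_excludes_B" else "mutual"
  } else if (!vA) {
    if (!invA) "B_excludes_A" else "mutual"
  } else if (invA && !invB) {
    "A_excludes_B"
  } else if (invB && !invA) {
    "B_excludes_A"
  } else {
    "mutual"
  }
  coex <- NULL
  if (cls == "mutual") {
    coex <- tryCatch(find_coexistence(paramsA, paramsB),
                     error = function(e) coexistence_frame())
    feas <- coex[coex$feasible, , drop = FALSE]
    cls <- if (nrow(feas) > 0) {
      if (any(feas$stable)) "stable_coexistence" else "priority_effect"
    } else if (invA && invB) {
      # mutually invasible but no feasible interior point located
      "stable_coexistence"
    } else {
      # mutually uninvasible: bistability decided by initial conditions
      "priority_effect"
    }
  }
  out <- competition_outcome(labA, labB, cls, c(A_at_B = gAatB, B_at_A = gBatA),
                             coex)
  if (integrate_check) out$integration <- pairwise_integration(paramsA, paramsB)
  out
}

competition_outcome <- function(labA, labB, cls, inv, coex) {
  names(inv) <- c("A_at_B", "B_at_A")
  structure(list(pair = c(labA, labB), classification = cls,
                 invasion = inv,
                 coexistence = coex %||% coexistence_frame()),
            class = "competition_outcome")
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat("Pairwise competition ", x$pair[1], " vs ", x$pair[2], ": ",
      x$classification, "\n", sep = "")
  cat("  invasion growth (A at B's eq, B at A's eq):",
      format(x$invasion), "\n")
  if (nrow(x$coexistence) > 0) print(x$coexistence)
  invisible(x)
}

# Integrate the two-strain community from several initial conditions
# (interior and near-monoculture corners) and report which strains survive.
pairwise_integration <- function(paramsA, paramsB, horizon = 1e5) {
  inits <- list(c(0.3, 0.3, 0.3, 0.3),
                c(0.3, 0.3, 0.3, 1e-6),
                c(0.3, 0.3, 1e-6, 0.3),
                c(0.3, 0.3, 1, 0.01),
                c(0.3, 0.3, 0.01, 1))
  lapply(inits, function(ii) {
    eq <- integrate_to_equilibrium(list(paramsA, paramsB), init = ii,
                                   horizon = horizon)
    list(init = ii, status = eq$status,
         survivors = c(A = eq$density[1] >= 1e-8, B = eq$density[2] >= 1e-8),
         density = eq$density)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Privatization bounds for nitrogen fixation to be beneficial
#'
#' Fixation pays off only if the privatized share of fixed nitrogen,
#' weighted by the marginal growth return on acquired nitrogen (the
#' sensitivity, [growth_sensitivity()]), exceeds the direct cost `gamma`.
#' Near the nitrogen-limited end of a strain's ZNGI (siderophores unlimited,
#' `N = N*`) the bound is `alpha > gamma / sens(Inf, N*)`; near the
#' siderophore-limited end (`N` unlimited, `S = S*`) it is
#' `alpha > gamma / sens(S*, Inf)`. The siderophore-limited bound is always
#' the stricter of the two, so the two bounds split parameter space into
#' three regimes.
#'
#' @details The nitrogen-limited bound comes from asking whether increasing
#' the fixation maximum lowers the strain's own `N*`; by default it is
#' therefore evaluated at the strain's own asymptote. With
#' `from_absence = TRUE` both bounds are instead evaluated at the
#' non-fixing (`b = 0`) variant's asymptote — the relevant reference when
#' asking whether fixation can invade a population that does not fix. The
#' ordering `bound(N_limited) <= bound(S_limited)` is guaranteed for the
#' from-absence evaluation (it reduces to `h(S*) > h(Inf)`); at the
#' strain's own fixation rate marginal reversals can occur because nitrogen
#' acquisition at `N*` grows with the fixation maximum.
#'
#' @param params a strain-realized [colim_params()] object.
#' @param regime `"N_limited"` or `"S_limited"`.
#' @param from_absence evaluate at the `b = 0` reference variant (see
#'   Details).
#' @return The lower bound on `alpha` (may exceed 1, meaning no amount of
#'   privatization makes fixation beneficial there); `Inf` when the
#'   sensitivity vanishes.
#' @export
privatization_bound <- function(params, regime = c("N_limited", "S_limited"),
                                from_absence = FALSE) {
  regime <- match.arg(regime)
  if (params$gamma == 0) return(0)
  ref <- params
  if (from_absence) ref$b <- 0
  sens <- if (regime == "N_limited") {
    Ns <- asymptote_nstar(ref)
    if (is.na(Ns)) return(NA_real_)
    growth_sensitivity(Inf, Ns, ref)
  } else {
    Ss <- asymptote_sstar(ref)
    if (is.na(Ss)) return(NA_real_)
    growth_sensitivity(Ss, Inf, ref)
  }
  if (sens <= 0) return(Inf)
  params$gamma / sens
}

#' @rdname privatization_bound
#' @return `classify_fixation_regime()` returns one of `"net_benefit"`
#'   (fixation pays off even under siderophore limitation),
#'   `"environment_dependent"`, or `"net_cost"` (fixation never pays off,
#'   even under nitrogen limitation).
#' @export
classify_fixation_regime <- function(params) {
  bN <- privatization_bound(params, "N_limited")
  bS <- privatization_bound(params, "S_limited")
  if (is.na(bN) || is.na(bS)) return(NA_character_)
  if (params$alpha > bS) "net_benefit"
  else if (params$alpha > bN) "environment_dependent"
  else "net_cost"
}

#' Can fixation invade a non-fixing population?
#'
#' Evaluates the nitrogen-limited privatization bound at `b = 0`: whether a
#' rare mutant with infinitesimal fixation would gain from it at the
#' non-fixer's minimum nitrogen requirement. Fixation evolves from absence
#' most easily at large maximum growth rate `r`, low death rate `delta` and
#' weak colimitation (low `k_S`).
#'
#' @param params a [colim_params()] object (its `b` is ignored).
#' @return Logical: is `alpha` above the `b = 0` nitrogen-limited bound?
#' @export
fixation_benefit_at_b0 <- function(params) {
  p0 <- params
  p0$b <- 0
  bound <- privatization_bound(p0, "N_limited")
  if (is.na(bound)) return(NA)
  params$alpha > bound
}
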