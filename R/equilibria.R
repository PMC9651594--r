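#' @importFrom deSolve lsodar
NULL

# Root of an increasing function g with g(0) < 0: doubling bracket + Brent.
# Used for the resource coordinates of ZNGIs and asymptotes, which are
# monotone in the searched concentration.
monotone_root <- function(g, upper0 = 1, max_double = 60) {
  hi <- upper0
  ghi <- g(hi)
  k <- 0
  while (ghi <= 0 && k < max_double) {
    hi <- hi * 2
    ghi <- g(hi)
    k <- k + 1
  }
  if (ghi <= 0) return(NA_real_)
  stats::uniroot(g, c(0, hi), tol = 1e-12)$root
}

# Bracket-scan + uniroot: scan a log-spaced grid for a sign change and refine.
# Returns the smallest root found, or NA.
scan_uniroot <- function(g, lower = 1e-12, upper = 1e6, n = 200) {
  grid <- exp(seq(log(lower), log(upper), length.out = n))
  vals <- vapply(grid, g, numeric(1))
  ok <- is.finite(vals)
  grid <- grid[ok]
  vals <- vals[ok]
  sw <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(sw) == 0) return(NA_real_)
  i <- sw[1]
  if (vals[i] == 0) return(grid[i])
  stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

# Shared trajectory classifier. func is a deSolve-style RHS; the last n_dens
# state components are population densities. Steady state is declared when
# resource derivatives are tiny (relative tolerance 1e-9) and every density
# is either at per-capita equilibrium (|g_i| < 1e-10) or effectively zero;
# this early exit cannot reclassify a slowly dying strain as viable, because
# a strain with |g_i| above tolerance keeps integrating until its density
# crosses the extinction threshold or the horizon is reached.
integrate_rhs <- function(func, init, horizon, n_dens,
                          extinct_tol = 1e-8, cap = 1e6,
                          rtol = 1e-8, atol = 1e-12) {
  nres <- length(init) - n_dens
  res_idx <- seq_len(nres)
  dens_idx <- nres + seq_len(n_dens)
  rootfun <- function(t, y, p) {
    d <- func(t, y, p)[[1]]
    scale <- max(abs(y), 1)
    r_res <- max(abs(d[res_idx])) / scale - 1e-9
    r_dens <- if (n_dens > 0) {
      x <- y[dens_idx]
      g <- ifelse(x > 0, abs(d[dens_idx]) / x, 0)
      max(pmin(g, x)) - 1e-10
    } else -1
    c(max(r_res, r_dens), max(y) - cap)
  }
  out <- tryCatch(
    deSolve::lsodar(init, times = c(0, horizon), func = func, parms = NULL,
                    rootfunc = rootfun, rtol = rtol, atol = atol,
                    maxsteps = 5e5),
    error = function(e) e, warning = function(w) w)
  if (inherits(out, "condition")) {
    return(list(state = init, time = 0, status = "not_converged",
                converged = FALSE, message = conditionMessage(out)))
  }
  fin <- out[nrow(out), -1]
  tend <- out[nrow(out), 1]
  converged <- tend < horizon
  status <- if (max(fin) >= cap * (1 - 1e-6)) {
    "unbounded"
  } else if (n_dens > 0 && all(fin[dens_idx] < extinct_tol)) {
    "extinct"
  } else {
    "viable_equilibrium"
  }
  list(state = unname(fin), time = tend, status = status,
       converged = converged, message = NULL)
}

#' Integrate the colimitation model to its attractor
#'
#' Numerically integrates a community of strains from given initial
#' conditions and classifies the outcome. The default protocol is the one
#' used throughout the screens: initial conditions
#' `N(0) = S(0) = x_i(0) = 0.3`, horizon `1e5` time units, extinction
#' threshold `1e-8` on final density, with steady-state early exit (see
#' Details) and an unbounded-growth cap at `1e6`.
#'
#' @details Early exit triggers when the scaled resource derivatives fall
#' below `1e-9` and every strain is either at per-capita equilibrium or at
#' effectively zero density, so it never changes the final-density
#' classification relative to running out the full horizon.
#'
#' @param strains a [colim_params()] object or list of them (see
#'   [derive_strains()]); may be an empty list for a cell-free environment,
#'   in which case `env` supplies the resource parameters.
#' @param env a [colim_params()] object providing `mu_N`, `mu_S`, `rho` when
#'   `strains` is empty; ignored otherwise.
#' @param init initial state `c(N, S, x...)`; defaults to 0.3 everywhere.
#' @param horizon integration horizon (model time units).
#' @param extinct_tol final densities below this are classified extinct.
#' @return An object of class `equilibrium_result`: list with `resources`
#'   (`c(S, N)` at the final state), `density` (final strain densities),
#'   `status` (one of `"viable_equilibrium"`, `"extinct"`, `"unbounded"`,
#'   `"not_converged"`), `converged` (logical: steady state reached before
#'   the horizon), `time` and `state`.
#' @examples
#' eq <- integrate_to_equilibrium(derive_strains(colim_params(b = 1))$LOFB)
#' eq$status
#' @export
integrate_to_equilibrium <- function(strains, init = NULL, horizon = 1e5,
                                     extinct_tol = 1e-8, env = NULL) {
  if (inherits(strains, "colim_params")) strains <- list(strains)
  n <- length(strains)
  if (is.null(init)) init <- rep(0.3, 2 + n)
  stopifnot(length(init) == 2 + n, all(init >= 0), horizon > 0)
  if (n == 0) {
    if (is.null(env)) stop("an 'env' parameter set is required when no strains are given")
    res <- integrate_rhs(function(t, y, p) {
      list(c(env$mu_N - env$rho * y[1], env$mu_S - env$rho * y[2]))
    }, init, horizon, 0)
  } else {
    pl <- flatten_strains(strains)
    res <- integrate_rhs(function(t, y, p) rhs_colim_fast(t, y, pl),
                         init, horizon, n_dens = n,
                         extinct_tol = extinct_tol)
  }
  fin <- res$state
  structure(list(resources = c(S = fin[2], N = fin[1]),
                 density = if (n > 0) fin[-(1:2)] else numeric(0),
                 status = res$status, converged = res$converged,
                 time = res$time, state = fin,
                 labels = vapply(seq_len(n), function(i) {
                   lb <- attr(strains[[i]], "strain")
                   if (is.null(lb)) paste0("strain", i) else lb
                 }, character(1))),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium result [", x$status, "] at t = ", format(x$time), "\n",
      sep = "")
  cat("  resources: S =", format(x$resources[["S"]]),
      " N =", format(x$resources[["N"]]), "\n")
  if (length(x$density) > 0) {
    cat("  densities:", paste(x$labels, format(x$density), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Minimum resource requirements (ZNGI asymptotes)
#'
#' `asymptote_nstar()` returns `N*`, the minimum fixed-nitrogen concentration
#' at which a strain can grow when siderophores are unlimited (the horizontal
#' asymptote of its ZNGI); `asymptote_sstar()` returns `S*`, the minimum
#' siderophore concentration at which it can grow when nitrogen is unlimited
#' (the vertical asymptote). The limits are evaluated analytically
#' (production costs vanish and uptake saturates as the corresponding
#' resource grows large), not at large finite concentrations. `N*` depends
#' only on whether the strain fixes nitrogen; `S*` only on whether it
#' produces siderophores.
#'
#' @param params a strain-realized [colim_params()] object.
#' @return The asymptote concentration; 0 if the strain can grow even at zero
#'   concentration of the focal resource; `NA` (with a `"reason"` attribute)
#'   if the strain cannot grow even with both resources unlimited.
#' @examples
#' lofb <- derive_strains(colim_params())$LOFB
#' asymptote_nstar(lofb)  # 0.34375 at the default parameter point
#' @export
asymptote_nstar <- function(params) {
  if (per_capita_growth(Inf, Inf, params) <= 0) {
    return(structure(NA_real_, reason = "cannot grow even with unlimited resources"))
  }
  g <- function(N) per_capita_growth(Inf, N, params)
  if (g(0) >= 0) return(0)
  monotone_root(g)
}

#' @rdname asymptote_nstar
#' @export
asymptote_sstar <- function(params) {
  if (per_capita_growth(Inf, Inf, params) <= 0) {
    return(structure(NA_real_, reason = "cannot grow even with unlimited resources"))
  }
  g <- function(S) per_capita_growth(S, Inf, params)
  monotone_root(g)
}

#' Nitrogen coordinate of a strain's ZNGI
#'
#' For each siderophore concentration `S` above the strain's `S*`, solves
#' `per_capita_growth(S, N) = 0` for the nitrogen concentration `N` on the
#' strain's zero net growth isocline.
#'
#' @param S siderophore concentration(s).
#' @param params a strain-realized [colim_params()] object.
#' @return Numeric vector: `N(S)` on the ZNGI; `NA` where no non-negative
#'   solution exists (either `S <= S*`, where no N suffices, or the strain
#'   grows even at `N = 0`, where the isocline lies below the axis).
#' @export
zngi_nitrogen <- function(S, params) {
  vapply(S, function(s) {
    g <- function(N) per_capita_growth(s, N, params)
    glim <- per_capita_growth(s, Inf, params)
    if (glim <= 0) return(NA_real_)   # S at or below S*
    g0 <- g(0)
    if (g0 > 0) return(NA_real_)      # grows even without external N
    if (g0 == 0) return(0)
    monotone_root(g)
  }, numeric(1))
}

#' Trace a strain's zero net growth isocline
#'
#' Samples the ZNGI over a grid of siderophore concentrations and attaches
#' the two asymptotes. The default grid is log-spaced in distance above
#' `S*` so both the diverging arm near `S*` and the approach to `N*` are
#' resolved.
#'
#' @param params a strain-realized [colim_params()] object.
#' @param S_grid optional explicit grid of S values (entries at or below
#'   `S*` are dropped with a note).
#' @param n grid size when `S_grid` is NULL.
#' @param span decades of distance above `S*` covered by the default grid.
#' @return A data.frame of class `zngi` with columns `S`, `N`, and attributes
#'   `S_star`, `N_star`, `strain`, `dropped` (count of skipped grid points).
#' @export
trace_zngi <- function(params, S_grid = NULL, n = 100, span = c(1e-3, 1e3)) {
  S_star <- asymptote_sstar(params)
  N_star <- asymptote_nstar(params)
  if (is.na(S_star)) stop("strain is not viable for any resource concentrations")
  if (is.null(S_grid)) {
    S_grid <- S_star + exp(seq(log(span[1]), log(span[2]), length.out = n))
  }
  keep <- S_grid > S_star
  dropped <- sum(!keep)
  S_grid <- S_grid[keep]
  N <- zngi_nitrogen(S_grid, params)
  out <- data.frame(S = S_grid, N = N)
  structure(out, S_star = S_star, N_star = N_star,
            strain = attr(params, "strain"), dropped = dropped,
            class = c("zngi", "data.frame"))
}

#' Per-capita impact vector of a strain on the resource environment
#'
#' The net per-capita effect of one cell on each resource pool:
#' `I_N = (1 - alpha) * f_N(N) - U_N(N)` (leaked fixation minus uptake) and
#' `I_S = f_S(S) - U_S(S)` (production minus uptake). Impact vectors map
#' supply points onto equilibrium resource concentrations, and their relative
#' orientation at a coexistence point decides its stability.
#'
#' @param S,N resource concentrations.
#' @param params a strain-realized [colim_params()] object.
#' @return Named numeric vector `c(I_S, I_N)`.
#' @export
impact_vector <- function(S, N, params) {
  c(I_S = siderophore_production_rate(S, params$q, params$m) -
      siderophore_uptake(S, params$u, params$p),
    I_N = (1 - params$alpha) * fixation_rate(N, params$b, params$ell) -
      nitrogen_uptake(N, params$a, params$d))
}

#' Map a supply point onto the resident's equilibrium
#'
#' Solves the single-resident steady state algebraically: the equilibrium
#' `(S, N, x)` satisfies zero net per-capita growth (the resident sits on its
#' ZNGI) and zero net change of both resources given the resident's impact.
#' Parameterizing the ZNGI by `S` reduces this to a one-dimensional
#' root-finding problem, scanned over a log grid and refined by Brent's
#' method. If the supply point `(mu_S / rho, mu_N / rho)` lies outside the
#' strain's growth region the cell-free equilibrium is returned.
#'
#' @param params a strain-realized [colim_params()] object (with `rho > 0`).
#' @param cross_check integrate the dynamics as well and flag disagreement
#'   beyond `tol`; with several algebraic roots the one matching the
#'   integration is selected.
#' @param tol agreement tolerance on resource concentrations.
#' @return List with `resources` (`c(S, N)`), `density`, `status`, `matched`
#'   (NA when `cross_check = FALSE`), and the integration result under
#'   `integration` when requested.
#' @export
map_supply_to_equilibrium <- function(params, cross_check = TRUE, tol = 1e-6) {
  stopifnot(params$rho > 0)
  S0 <- params$mu_S / params$rho
  N0 <- params$mu_N / params$rho
  # two parameterizations of the one-dimensional steady-state problem along
  # the ZNGI: solve the resident density from the siderophore balance and
  # demand zero nitrogen residual, or vice versa. Each is singular where
  # the corresponding impact component vanishes, so both are scanned.
  resid_x <- function(s, via = c("S", "N")) {
    via <- match.arg(via)
    nn <- zngi_nitrogen(s, params)
    if (is.na(nn)) return(c(NA_real_, NA_real_))
    iv <- impact_vector(s, nn, params)
    if (via == "S") {
      if (abs(iv[["I_S"]]) < 1e-14) return(c(NA_real_, NA_real_))
      x <- (params$rho * s - params$mu_S) / iv[["I_S"]]
      c(params$mu_N - params$rho * nn + x * iv[["I_N"]], x)
    } else {
      if (abs(iv[["I_N"]]) < 1e-14) return(c(NA_real_, NA_real_))
      x <- (params$rho * nn - params$mu_N) / iv[["I_N"]]
      c(params$mu_S - params$rho * s + x * iv[["I_S"]], x)
    }
  }
  grid <- exp(seq(log(1e-9), log(max(10 * max(S0, 1), 1e3)), length.out = 400))
  # the resident density changes sign exactly at the supply coordinate, so
  # S0 must be a grid point or roots just inside it are missed
  grid <- sort(unique(c(grid, S0)))
  roots <- list()
  for (via in c("S", "N")) {
    vals <- t(vapply(grid, resid_x, numeric(2), via = via))
    ok <- is.finite(vals[, 1]) & vals[, 2] > -1e-12
    idx <- which(ok[-1] & ok[-length(ok)] &
                   vals[-1, 1] * vals[-nrow(vals), 1] <= 0)
    for (i in idx) {
      rt <- tryCatch(
        stats::uniroot(function(s) resid_x(s, via)[1],
                       c(grid[i], grid[i + 1]), tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (is.na(rt)) next
      nn <- zngi_nitrogen(rt, params)
      rx <- resid_x(rt, via)
      dup <- any(vapply(roots, function(r) {
        abs(r[["S"]] - rt) < 1e-7 * max(rt, 1)
      }, logical(1)))
      if (!dup) roots[[length(roots) + 1]] <- c(S = rt, N = nn, x = rx[2])
    }
  }
  integ <- if (cross_check || length(roots) > 1) {
    integrate_to_equilibrium(params)
  } else NULL
  if (length(roots) == 0) {
    # no interior equilibrium: the cell-free state at the supply point
    # (a strain that cannot grow at the supply point and has no
    # self-sustaining interior root washes out)
    grows <- per_capita_growth(S0, N0, params) > 0
    return(list(resources = c(S = S0, N = N0), density = 0,
                status = if (grows) "no_root" else "extinct",
                matched = if (is.null(integ)) NA else integ$status != "viable_equilibrium",
                integration = integ))
  }
  pick <- 1L
  if (!is.null(integ) && length(roots) > 1) {
    dd <- vapply(roots, function(rt) {
      sum(abs(rt[c("S", "N")] - integ$resources[c("S", "N")]))
    }, numeric(1))
    pick <- which.min(dd)
  }
  sol <- roots[[pick]]
  matched <- if (is.null(integ)) NA else {
    integ$status == "viable_equilibrium" &&
      max(abs(sol[c("S", "N")] - integ$resources[c("S", "N")]),
          abs(sol[["x"]] - integ$density[1])) < tol
  }
  list(resources = c(S = sol[["S"]], N = sol[["N"]]), density = sol[["x"]],
       status = "viable_equilibrium", matched = matched, integration = integ)
}
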