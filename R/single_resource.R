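#' Single-resource producer / non-producer model
#'
#' The abstract single-resource model: two strains limited by one resource
#' `R`, identical except that strain 1 facultatively produces the resource at
#' rate `f(R)` (privatizing a fraction `alpha`, at cost `gamma` per unit
#' produced) while strain 2 is a loss-of-function non-producer. Growth
#' functions are `g1(R) = (alpha - gamma) * f(R) + U(R)` and
#' `g2(R) = U(R)`; resource concentration is driven by external supply `mu`,
#' washout `rho * R`, leakage `(1 - alpha) * f(R) * x1` and uptake
#' `U(R) * (x1 + x2)`. Resource units are chosen so one unit of acquired
#' resource buys one unit of per-capita growth (stoichiometric coefficient 1).
#'
#' The production form `f` (non-increasing) and uptake form `U` (increasing)
#' are pluggable; the defaults mirror the colimitation model's kinetics:
#' `f(R) = b * ell / (ell + R)` and Michaelis-Menten `U(R) = a * R / (d + R)`.
#' Shape constraints (`f' <= 0`, `U' > 0`, `g1' >= 0`) are assumptions of the
#' model, not consequences of any formula, so they are validated numerically
#' on a grid of `grid_n` points over `[0, R_max]`; a violation is a
#' configuration error.
#'
#' @param mu external resource input rate.
#' @param rho resource washout rate.
#' @param alpha privatization fraction in `[0, 1]`.
#' @param gamma production cost per unit resource produced, in `[0, 1]`.
#' @param delta cell death / washout rate.
#' @param f,U production and uptake functions of signature
#'   `function(R, pars)`; defaults as described above.
#' @param f_params,U_params parameter lists passed to `f` and `U`.
#' @param R_max,grid_n range and resolution of the numerical shape check.
#' @return An object of class `sr_spec`.
#' @examples
#' spec <- single_resource_spec(alpha = 0.8, gamma = 0.3)
#' sr_growth(spec, R = 1, strain = 1)
#' @export
single_resource_spec <- function(mu = 0.5, rho = 0.1, alpha = 0.875,
                                 gamma = 0.4, delta = 0.4,
                                 f = NULL, U = NULL,
                                 f_params = list(b = 1, ell = 3),
                                 U_params = list(a = 3, d = 2),
                                 R_max = 100, grid_n = 1000) {
  stopifnot(mu >= 0, rho >= 0, delta >= 0,
            alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  if (is.null(f)) f <- function(R, pars) pars$ell * pars$b / (pars$ell + R)
  if (is.null(U)) U <- function(R, pars) pars$a * R / (pars$d + R)
  spec <- structure(
    list(mu = mu, rho = rho, alpha = alpha, gamma = gamma, delta = delta,
         f = f, U = U, f_params = f_params, U_params = U_params,
         R_max = R_max),
    class = "sr_spec")
  grid <- seq(0, R_max, length.out = grid_n)
  fv <- spec$f(grid, f_params)
  Uv <- spec$U(grid, U_params)
  if (any(!is.finite(fv)) || any(fv < 0) || any(!is.finite(Uv)) || any(Uv < 0)) {
    stop("f and U must be finite and non-negative on [0, R_max]")
  }
  tol <- 1e-10
  if (any(diff(fv) > tol)) stop("f(R) must be non-increasing")
  if (any(diff(Uv) < -tol)) stop("U(R) must be increasing")
  g1 <- (alpha - gamma) * fv + Uv
  if (any(diff(g1) < -tol)) {
    stop("g1(R) must be non-decreasing (resource must never inhibit producer growth)")
  }
  spec
}

#' @rdname single_resource_spec
#' @param R resource concentration (vectorized).
#' @param strain 1 (producer) or 2 (non-producer).
#' @export
sr_growth <- function(spec, R, strain) {
  stopifnot(inherits(spec, "sr_spec"), strain %in% c(1, 2))
  U <- spec$U(R, spec$U_params)
  if (strain == 1) (spec$alpha - spec$gamma) * spec$f(R, spec$f_params) + U else U
}

#' Right-hand side of the single-resource model
#'
#' @param t time (unused; deSolve compatibility).
#' @param state numeric vector `c(R, x1, x2)`.
#' @param spec an [single_resource_spec()] object.
#' @return List of one numeric vector: `c(dR, dx1, dx2)`.
#' @export
rhs_single_resource <- function(t = 0, state, spec) {
  stopifnot(length(state) == 3)
  R <- max(state[1], 0)
  x1 <- state[2]
  x2 <- state[3]
  fR <- spec$f(R, spec$f_params)
  UR <- spec$U(R, spec$U_params)
  dR <- spec$mu - spec$rho * R + (1 - spec$alpha) * fR * x1 - UR * (x1 + x2)
  dx1 <- x1 * ((spec$alpha - spec$gamma) * fR + UR - spec$delta)
  dx2 <- x2 * (UR - spec$delta)
  list(c(dR, dx1, dx2))
}

#' Single-strain resource equilibrium R*
#'
#' The resource concentration at which a strain's growth `g_i(R)` exactly
#' balances mortality `delta`; by the R* rule, the strain with the lower
#' `R*` excludes the other in pairwise competition (provided production is
#' still active at the loser's equilibrium). For the non-producer with
#' Michaelis-Menten uptake this is the closed form `d * delta / (a - delta)`.
#'
#' @param spec an [single_resource_spec()] object.
#' @param strain 1 (producer) or 2 (non-producer).
#' @return The root `R*`, or `NA` with a `"reason"` attribute if growth never
#'   reaches `delta` on the search bracket (strain not viable).
#' @export
sr_rstar <- function(spec, strain) {
  g <- function(R) sr_growth(spec, R, strain) - spec$delta
  if (g(0) >= 0) return(0)
  root <- scan_uniroot(g, lower = 1e-12, upper = 1e6)
  if (is.na(root)) {
    return(structure(NA_real_, reason = "growth never balances delta: not viable"))
  }
  root
}

#' Resource concentration at which production halts
#'
#' The smallest `R` with `f(R) = 0`. For asymptotically decaying production
#' forms (such as the default) production never fully halts and the function
#' returns `Inf`.
#'
#' @param spec an [single_resource_spec()] object.
#' @param tol production below `tol` counts as halted.
#' @return Smallest root of `f`, or `Inf`.
#' @export
sr_production_halt <- function(spec, tol = 1e-12) {
  fv <- function(R) spec$f(R, spec$f_params)
  if (fv(0) <= tol) return(0)
  if (fv(spec$R_max) > tol) return(Inf)
  stats::uniroot(function(R) fv(R) - tol, c(0, spec$R_max), tol = 1e-10)$root
}

#' Integrate the single-resource model and classify the outcome
#'
#' Integrates `c(R, x1, x2)` with steady-state early exit and the same
#' status classification as [integrate_to_equilibrium()] (densities below
#' `1e-8` are extinct; any state component above `1e6` is unbounded, which
#' this model can genuinely reach when `alpha > gamma`).
#'
#' @param spec an [single_resource_spec()] object.
#' @param init initial state `c(R, x1, x2)`.
#' @param horizon integration horizon in model time units.
#' @return List with `state` (final state), `time`, `status` and `converged`.
#' @export
sr_integrate <- function(spec, init = c(spec$mu / max(spec$rho, 1e-12), 0.3, 0.3),
                         horizon = 1e5) {
  integrate_rhs(function(t, y, ignored) rhs_single_resource(t, y, spec),
                init, horizon, n_dens = 2)
}
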