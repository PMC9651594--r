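#' Facultative production and uptake kinetics
#'
#' The per-capita rate functions of the colimitation model. Production rates
#' decrease monotonically with the extracellular concentration of the product
#' (cells facultatively shut production down as the resource becomes
#' plentiful), reaching half their maximum at the half-inhibition constant.
#' Uptake follows saturating Michaelis-Menten (type II) kinetics with a
#' half-saturation constant.
#'
#' All four functions accept `Inf` concentrations and return the analytic
#' limit (production 0, uptake at its maximum).
#'
#' @param N,S extracellular fixed-nitrogen / siderophore concentration
#'   (non-negative; vectorized).
#' @param b,q maximum fixation / siderophore production rate.
#' @param ell,m half-inhibition constants for fixation / siderophore
#'   production.
#' @param a,u maximum nitrogen / siderophore uptake rates.
#' @param d,p half-saturation constants for nitrogen / siderophore uptake.
#' @return Per-capita rate(s), same length as the concentration argument.
#' @examples
#' fixation_rate(N = 3, b = 2, ell = 3)  # half-maximum: 1
#' nitrogen_uptake(N = 2, a = 3, d = 2)  # half-maximum: 1.5
#' @name kinetics
NULL

check_conc <- function(x, what) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("'", what, "' must be non-negative (got ",
         paste(utils::head(x[is.na(x) | x < 0], 3), collapse = ", "), ")")
  }
  invisible(x)
}

#' @rdname kinetics
#' @export
fixation_rate <- function(N, b, ell) {
  check_conc(N, "N")
  stopifnot(b >= 0, ell >= 0)
  ifelse(is.infinite(N), 0, ifelse(ell + N > 0, ell * b / (ell + N), b))
}

#' @rdname kinetics
#' @export
siderophore_production_rate <- function(S, q, m) {
  check_conc(S, "S")
  stopifnot(q >= 0, m >= 0)
  ifelse(is.infinite(S), 0, ifelse(m + S > 0, m * q / (m + S), q))
}

#' @rdname kinetics
#' @export
nitrogen_uptake <- function(N, a, d) {
  check_conc(N, "N")
  stopifnot(a >= 0, d >= 0)
  ifelse(is.infinite(N), a, ifelse(d + N > 0, a * N / (d + N), 0))
}

#' @rdname kinetics
#' @export
siderophore_uptake <- function(S, u, p) {
  check_conc(S, "S")
  stopifnot(u >= 0, p >= 0)
  ifelse(is.infinite(S), u, ifelse(p + S > 0, u * S / (p + S), 0))
}

#' Total nitrogen acquisition rate
#'
#' Cells acquire fixed nitrogen through two channels: the privatized share
#' `alpha` of their own fixation, and uptake from the shared pool:
#' `eta(N) = alpha * f_N(N) + U_N(N)`.
#'
#' @param N fixed-nitrogen concentration (vectorized; `Inf` allowed).
#' @param params a [colim_params()] object (strain-realized, i.e. `b` is the
#'   strain's own fixation maximum).
#' @return Nitrogen acquisition rate(s).
#' @examples
#' nitrogen_acquisition(1, colim_params(b = 2))  # 0.875 * 1.5 + 1 = 2.3125
#' @export
nitrogen_acquisition <- function(N, params) {
  params$alpha * fixation_rate(N, params$b, params$ell) +
    nitrogen_uptake(N, params$a, params$d)
}

#' Siderophore-dependent half-saturation for growth on nitrogen
#'
#' Biochemically dependent colimitation: the half-saturation constant of
#' growth on acquired nitrogen is set by siderophore (iron) uptake,
#' `h(S) = (r / c) * (U_S(S) + k_S) / U_S(S)`. With unlimited siderophore
#' uptake it approaches `(r / c) * (1 + k_S / u)`; when uptake equals `k_S`
#' it has doubled relative to the uptake-unlimited value `r / c`; with no
#' siderophore uptake it diverges, shutting growth off entirely.
#'
#' @param S siderophore concentration (vectorized; `Inf` allowed).
#' @param params a [colim_params()] object.
#' @return Half-saturation value(s); `Inf` at `S = 0` (for `k_S > 0`), by
#'   construction rather than as an error.
#' @export
half_saturation <- function(S, params) {
  US <- siderophore_uptake(S, params$u, params$p)
  base <- params$r / params$c
  ifelse(US > 0, base * (US + params$k_S) / US,
         if (params$k_S > 0) Inf else base)
}

#' Colimited growth rate
#'
#' Growth increases with the nitrogen acquisition rate `eta` and saturates at
#' the maximum rate `r`, with the half-saturation point set by siderophore
#' uptake: `G(S, N) = r * eta(N) / (eta(N) + h(S))`.
#'
#' @inheritParams nitrogen_acquisition
#' @param S siderophore concentration (`Inf` allowed).
#' @return Growth rate(s) in `[0, r)`.
#' @export
colimited_growth <- function(S, N, params) {
  eta <- nitrogen_acquisition(N, params)
  h <- half_saturation(S, params)
  ifelse(is.infinite(h), 0,
         ifelse(eta + h > 0, params$r * eta / (eta + h), 0))
}

#' Net per-capita growth rate of a strain
#'
#' Colimited growth minus the production costs and mortality:
#' `G(S, N) - gamma * f_N(N) - beta * f_S(S) - delta`. A strain is at
#' (resource) equilibrium exactly where this is zero; the zero set in the
#' `(S, N)` plane is the strain's ZNGI.
#'
#' @inheritParams colimited_growth
#' @return Net per-capita growth rate(s).
#' @examples
#' st <- derive_strains(colim_params(b = 1))
#' # two strains differing only in siderophore production differ in growth by
#' # exactly the production cost beta * f_S(S):
#' per_capita_growth(0.5, 1, st$Full) - per_capita_growth(0.5, 1, st$LOFS)
#' @export
per_capita_growth <- function(S, N, params) {
  colimited_growth(S, N, params) -
    params$gamma * fixation_rate(N, params$b, params$ell) -
    params$beta * siderophore_production_rate(S, params$q, params$m) -
    params$delta
}

#' Sensitivity of growth to nitrogen acquisition
#'
#' The partial derivative of the colimited growth rate with respect to the
#' nitrogen acquisition rate, evaluated at resource concentrations
#' `(S, N)`: `r * h(S) / (eta(N) + h(S))^2`. This is the marginal growth
#' return on one extra unit of acquired nitrogen, and is the quantity that
#' weights the private benefit of fixation in the privatization bounds
#' (see [privatization_bound()]). Both arguments accept `Inf`, evaluated via
#' the analytic limits of the kinetics (`eta(Inf) = a`,
#' `h(Inf) = (r / c) * (1 + k_S / u)`).
#'
#' @inheritParams colimited_growth
#' @return Sensitivity value(s) (dimensionless rate per rate); 0 where
#'   `h = Inf` would shut growth off entirely.
#' @export
growth_sensitivity <- function(S, N, params) {
  eta <- nitrogen_acquisition(N, params)
  h <- half_saturation(S, params)
  ifelse(is.infinite(h), 0, params$r * h / (eta + h)^2)
}

#' Right-hand side of the colimitation model
#'
#' Dynamics of the state `(N, S, x_1, ..., x_n)`: resources receive external
#' supply, wash out at rate `rho`, and are modified by the cells (leaked
#' fixation minus uptake for N; production minus uptake for S); each strain
#' grows at its net per-capita rate.
#'
#' @param state numeric state vector `c(N, S, x...)` with one density per
#'   strain.
#' @param strains list of strain-realized [colim_params()] objects (as from
#'   [derive_strains()]); the shared environmental parameters (`mu_N`,
#'   `mu_S`, `rho`, `alpha`, ...) are taken from the first element. May be
#'   empty for a cell-free environment.
#' @param t time (unused; present for deSolve compatibility).
#' @return List of one numeric vector: the state derivative, as expected by
#'   [deSolve::ode()].
#' @export
rhs_colimitation <- function(t = 0, state, strains) {
  n <- length(strains)
  if (length(state) != 2 + n) stop("state must have length 2 + n strains")
  check_conc(state, "state")
  N <- state[1]
  S <- state[2]
  x <- state[seq_len(n) + 2]
  env <- if (n > 0) strains[[1]] else NULL
  dN <- if (n > 0) env$mu_N - env$rho * N else 0
  dS <- if (n > 0) env$mu_S - env$rho * S else 0
  dx <- numeric(n)
  for (i in seq_len(n)) {
    pr <- strains[[i]]
    fN <- fixation_rate(N, pr$b, pr$ell)
    fS <- siderophore_production_rate(S, pr$q, pr$m)
    UN <- nitrogen_uptake(N, pr$a, pr$d)
    US <- siderophore_uptake(S, pr$u, pr$p)
    dN <- dN + x[i] * ((1 - pr$alpha) * fN - UN)
    dS <- dS + x[i] * (fS - US)
    dx[i] <- x[i] * per_capita_growth(S, N, pr)
  }
  list(c(dN, dS, dx))
}

# Internal fast path used by the integrator: same maths as rhs_colimitation
# but without argument checking, on a pre-flattened parameter list.
rhs_colim_fast <- function(t, y, pl) {
  N <- max(y[1], 0)
  S <- max(y[2], 0)
  x <- y[-(1:2)]
  fN <- if (pl$ell + N > 0) pl$ell * pl$bvec / (pl$ell + N) else pl$bvec
  fS <- if (pl$m + S > 0) pl$m * pl$qvec / (pl$m + S) else pl$qvec
  UN <- if (pl$d + N > 0) pl$a * N / (pl$d + N) else 0
  US <- if (pl$p + S > 0) pl$u * S / (pl$p + S) else 0
  eta <- pl$alpha * fN + UN
  if (US > 0) {
    h <- (pl$r / pl$c) * (US + pl$k_S) / US
    G <- pl$r * eta / (eta + h)
  } else if (pl$k_S > 0) {
    G <- rep(0, length(eta))
  } else {
    h <- pl$r / pl$c
    G <- pl$r * eta / (eta + h)
  }
  g <- G - pl$gamma * fN - pl$beta * fS - pl$delta
  dN <- pl$mu_N - pl$rho * N + sum(x * ((1 - pl$alpha) * fN - UN))
  dS <- pl$mu_S - pl$rho * S + sum(x * (fS - US))
  list(c(dN, dS, x * g))
}

flatten_strains <- function(strains) {
  env <- strains[[1]]
  pl <- env[param_names()]
  pl$bvec <- vapply(strains, function(s) s$b, numeric(1))
  pl$qvec <- vapply(strains, function(s) s$q, numeric(1))
  pl
}
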