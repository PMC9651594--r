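set_trait <- function(params, trait, value) {
  stopifnot(trait %in% c("b", "q", "alpha"))
  if (trait == "alpha") stopifnot(value >= 0, value <= 1) else stopifnot(value >= 0)
  params[[trait]] <- value
  params
}

#' Fitness gradient of a production trait
#'
#' The derivative of the invasion growth rate with respect to the invader's
#' trait value, evaluated at the resident's equilibrium (central finite
#' difference with relative step `step`; one-sided at trait bounds).
#' Positive gradients mean selection for higher trait values. Supported
#' traits: maximum fixation rate `"b"`, maximum siderophore production
#' `"q"`, and privatization `"alpha"`.
#'
#' @param params base [colim_params()] (the resident's parameters other than
#'   the trait).
#' @param trait one of `"b"`, `"q"`, `"alpha"`.
#' @param value resident trait value (the resident must be viable there).
#' @param step relative finite-difference step.
#' @return The fitness gradient (rate per trait unit); `NA` with a
#'   `"status"` attribute if the resident is not at a viable equilibrium.
#' @export
fitness_gradient <- function(params, trait, value, step = 1e-4) {
  resident <- set_trait(params, trait, value)
  eq <- integrate_to_equilibrium(resident)
  if (eq$status != "viable_equilibrium") {
    return(structure(NA_real_, status = eq$status))
  }
  gI <- function(v) {
    invasion_growth_rate(set_trait(params, trait, v), eq)
  }
  h <- step * max(abs(value), 1)
  hi <- value + h
  lo <- value - h
  if (trait == "alpha") hi <- min(hi, 1)
  lo <- max(lo, 0)
  (gI(hi) - gI(lo)) / (hi - lo)
}

#' Pairwise invasibility plot (PIP) grid
#'
#' For every viable resident trait value on the grid, integrates the
#' resident to equilibrium and evaluates the invasion growth rate of every
#' invader trait value there. The diagonal is zero up to the equilibrium
#' tolerance; non-viable residents are marked.
#'
#' @inheritParams fitness_gradient
#' @param grid trait values used for both residents (columns) and invaders
#'   (rows).
#' @return A list of class `pip_grid`: `trait`, `grid`, `growth` (invader x
#'   resident matrix of invasion growth rates, NA columns for non-viable
#'   residents), `resident_status`.
#' @export
compute_pip <- function(params, trait, grid = seq(0, 2, length.out = 41)) {
  growth <- matrix(NA_real_, nrow = length(grid), ncol = length(grid))
  status <- character(length(grid))
  for (j in seq_along(grid)) {
    resident <- set_trait(params, trait, grid[j])
    eq <- integrate_to_equilibrium(resident)
    status[j] <- eq$status
    if (eq$status != "viable_equilibrium") next
    growth[, j] <- vapply(grid, function(v) {
      invasion_growth_rate(set_trait(params, trait, v), eq)
    }, numeric(1))
  }
  structure(list(trait = trait, grid = grid, growth = growth,
                 resident_status = status),
            class = "pip_grid")
}

#' Locate the evolutionarily stable strategy of a production trait
#'
#' Scans the fitness gradient over a trait grid, refines sign changes by
#' bisection, and classifies the evolutionary regime: `"loss_of_trait"`
#' (gradient negative throughout the viable range, so the trait erodes to
#' 0), `"interior_ESS"` (a gradient root that no grid invader can invade),
#' or `"no_stable_equilibrium"` (selection pushes the trait into values
#' where the resident's ecological dynamics are unbounded).
#'
#' @inheritParams fitness_gradient
#' @param range trait search interval.
#' @param n_grid scan resolution.
#' @param invader_grid trait values used for the uninvasibility check.
#' @return A list of class `ess_result`: `trait`, `ess_value`, `regime`,
#'   `gradient` (data.frame of the scan), `uninvasible` (logical, for the
#'   located ESS), `resident_eq`.
#' @export
find_ess <- function(params, trait, range = c(0, 2), n_grid = 21,
                     invader_grid = NULL) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  gr <- vapply(grid, function(v) {
    g <- fitness_gradient(params, trait, v)
    c(g, if (is.na(g)) NA else 0)
  }, numeric(2))[1, ]
  stat <- vapply(grid, function(v) {
    eq <- integrate_to_equilibrium(set_trait(params, trait, v))
    eq$status
  }, character(1))
  scan <- data.frame(value = grid, gradient = gr, status = stat)
  viable <- stat == "viable_equilibrium"
  if (!any(viable)) {
    return(structure(list(trait = trait, ess_value = NA_real_,
                          regime = "no_stable_equilibrium", gradient = scan,
                          uninvasible = NA, resident_eq = NULL),
                     class = "ess_result"))
  }
  if (is.null(invader_grid)) invader_grid <- grid
  finish <- function(value, regime) {
    resident <- set_trait(params, trait, value)
    eq <- integrate_to_equilibrium(resident)
    uninv <- if (eq$status == "viable_equilibrium") {
      inv <- vapply(invader_grid, function(v) {
        invasion_growth_rate(set_trait(params, trait, v), eq)
      }, numeric(1))
      all(inv <= 1e-7)
    } else {
      # trait loss can drive the population itself extinct (evolutionary
      # suicide); there is no resident environment left to invade
      NA
    }
    structure(list(trait = trait, ess_value = value, regime = regime,
                   gradient = scan, uninvasible = uninv, resident_eq = eq),
              class = "ess_result")
  }
  vg <- which(viable & !is.na(gr))
  # interior root: gradient sign change from + to - between viable nodes
  for (k in seq_along(vg)[-1]) {
    j0 <- vg[k - 1]
    j1 <- vg[k]
    if (j1 == j0 + 1 && gr[j0] > 0 && gr[j1] <= 0) {
      root <- bisect_gradient(params, trait, grid[j0], grid[j1])
      return(finish(root, "interior_ESS"))
    }
  }
  top <- max(vg)
  if (gr[top] > 0) {
    # selection pushes upward past the last viable resident
    if (top < n_grid && stat[top + 1] == "unbounded") {
      return(structure(list(trait = trait, ess_value = NA_real_,
                            regime = "no_stable_equilibrium", gradient = scan,
                            uninvasible = NA, resident_eq = NULL),
                       class = "ess_result"))
    }
    return(finish(grid[top], "interior_ESS"))
  }
  # gradient negative throughout: trait is lost
  finish(0, "loss_of_trait")
}

bisect_gradient <- function(params, trait, lo, hi, iter = 40, tol = 1e-6) {
  glo <- fitness_gradient(params, trait, lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    gm <- fitness_gradient(params, trait, mid)
    if (is.na(gm)) return(mid)
    if (gm > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' @export
print.ess_result <- function(x, ...) {
  cat("ESS for trait '", x$trait, "': regime ", x$regime, sep = "")
  if (!is.na(x$ess_value)) cat(", value ", format(x$ess_value), sep = "")
  cat("\n")
  invisible(x)
}

# N on the ZNGI of a strain, with the envelope conventions: +Inf when the
# strain cannot grow at any N for this S, 0 when it grows even at N = 0.
envelope_N <- function(S, pr) {
  if (per_capita_growth(S, Inf, pr) <= 0) return(Inf)
  if (per_capita_growth(S, 0, pr) >= 0) return(0)
  monotone_root(function(N) per_capita_growth(S, N, pr))
}

#' ZNGI envelope over a trait family
#'
#' Computes the family of ZNGIs obtained by varying one production trait and
#' keeps, for each siderophore concentration, the outermost member (the
#' lowest nitrogen requirement). A resident sitting at a point of this
#' geometrical envelope is uninvasible by every other trait value in the
#' family, so the envelope labels each resource environment with its ESS
#' trait. Impact vectors of the winning trait are attached at each point.
#'
#' @inheritParams fitness_gradient
#' @param values trait grid defining the family.
#' @param S_grid siderophore grid; defaults to a log-spaced grid above the
#'   family's common `S*`.
#' @param n default grid size.
#' @return A data.frame of class `zngi_envelope`: columns `S`, `N`,
#'   `trait_value`, `I_S`, `I_N`.
#' @export
zngi_envelope <- function(params, trait = "b",
                          values = seq(0, 2, length.out = 41),
                          S_grid = NULL, n = 120) {
  fam <- lapply(values, function(v) set_trait(params, trait, v))
  if (is.null(S_grid)) {
    sstars <- vapply(fam, asymptote_sstar, numeric(1))
    base <- min(sstars, na.rm = TRUE)
    S_grid <- base + exp(seq(log(1e-3), log(1e3), length.out = n))
  }
  rows <- lapply(S_grid, function(s) {
    Ns <- vapply(fam, function(pr) envelope_N(s, pr), numeric(1))
    j <- which.min(Ns)
    if (!is.finite(Ns[j])) return(NULL)
    iv <- impact_vector(s, Ns[j], fam[[j]])
    data.frame(S = s, N = Ns[j], trait_value = values[j],
               I_S = iv[["I_S"]], I_N = iv[["I_N"]])
  })
  out <- do.call(rbind, rows)
  structure(out, trait = trait, values = values,
            class = c("zngi_envelope", "data.frame"))
}

#' Critical N:S ratio for the onset of fixation along the envelope
#'
#' Moving along the ZNGI envelope from the siderophore-limited end (high
#' N:S) toward the nitrogen-limited end (low N:S), the ESS fixation rate
#' transitions from 0 to positive. This function locates that transition by
#' bisection in the siderophore coordinate and returns the equilibrium
#' N:S ratio there. Environments with a higher N:S ratio than the critical
#' value select for complete loss of fixation.
#'
#' @param params base [colim_params()]; `alpha` and `gamma` in it control
#'   where the transition sits.
#' @param values fixation-rate grid defining the trait family.
#' @param n envelope scan resolution.
#' @return A list: `ratio` (critical N:S; `NA` if the ESS is 0 or positive
#'   along the entire envelope, see `reason`), `S`, `N` at the transition,
#'   and the scanned `envelope`.
#' @export
critical_ns_ratio <- function(params, values = seq(0, 2, length.out = 41),
                              n = 120) {
  env <- zngi_envelope(params, "b", values, n = n)
  pos <- env$trait_value > values[2] / 2   # positive beyond grid resolution
  if (all(pos)) {
    return(list(ratio = NA_real_, reason = "fixation positive along entire envelope",
                envelope = env))
  }
  if (!any(pos)) {
    return(list(ratio = NA_real_, reason = "loss of fixation along entire envelope",
                envelope = env))
  }
  # envelope is ordered by S: zero-trait at low S, positive at high S
  flip <- which(diff(pos) != 0)[1]
  lo <- env$S[flip]
  hi <- env$S[flip + 1]
  fam <- lapply(values, function(v) set_trait(params, "b", v))
  argmin_pos <- function(s) {
    Ns <- vapply(fam, function(pr) envelope_N(s, pr), numeric(1))
    values[which.min(Ns)] > values[2] / 2
  }
  plo <- argmin_pos(lo)
  for (i in 1:30) {
    mid <- sqrt(lo * hi)
    if (argmin_pos(mid) == plo) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  Sc <- sqrt(lo * hi)
  Ns <- vapply(fam, function(pr) envelope_N(Sc, pr), numeric(1))
  Nc <- min(Ns)
  list(ratio = Nc / Sc, S = Sc, N = Nc, envelope = env)
}
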