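#' Parameters of the nitrogen/siderophore colimitation model
#'
#' Constructs the 18-parameter vector of the colimitation model. Defaults are
#' the values used throughout the adaptive-dynamics analyses; the maximum
#' fixation rate `b` is the evolving trait and has no canonical default, so it
#' defaults to 1 and is normally set explicitly (or sampled, see
#' [sample_parameters()]).
#'
#' @param mu_S,mu_N siderophore and fixed-nitrogen input rates (resource per
#'   unit time) from sources external to the community.
#' @param rho resource washout/decay rate (per unit time), shared by both
#'   resources.
#' @param alpha privatization of fixed nitrogen: the fraction of fixed N a
#'   producing cell retains for its own growth; `1 - alpha` is leaked into the
#'   shared pool. In `[0, 1]`.
#' @param gamma per-unit-rate growth cost of nitrogen fixation.
#' @param delta per-capita cell death / washout rate.
#' @param b maximum nitrogen fixation rate (realized at N = 0).
#' @param ell fixation half-inhibition constant: the N concentration at which
#'   fixation runs at half its maximum.
#' @param a maximum nitrogen uptake rate.
#' @param d nitrogen uptake half-saturation constant.
#' @param q maximum siderophore production rate (realized at S = 0).
#' @param m siderophore production half-inhibition constant.
#' @param u maximum siderophore uptake rate.
#' @param p siderophore uptake half-saturation constant.
#' @param beta per-unit-rate growth cost of siderophore production.
#' @param r maximum per-capita cell growth rate.
#' @param k_S strength of colimitation: the siderophore uptake rate at which
#'   the effective half-saturation for growth on N doubles.
#' @param c siderophore affinity: scales how cheaply siderophore uptake buys
#'   down the half-saturation for growth on nitrogen.
#'
#' @return An object of class `colim_params`: a named list of the 18
#'   parameters, with an optional `strain` attribute (see [derive_strains()]).
#' @examples
#' pars <- colim_params(b = 1.5)
#' pars$alpha
#' @export
colim_params <- function(mu_S = 0.001, mu_N = 0.9, rho = 0.1, alpha = 0.875,
                         gamma = 0.4, delta = 0.4, b = 1, ell = 3, a = 3,
                         d = 2, q = 1.75, m = 1, u = 1, p = 1.85, beta = 0.4,
                         r = 2, k_S = 0.1, c = 1.25) {
  pars <- list(mu_S = mu_S, mu_N = mu_N, rho = rho, alpha = alpha,
               gamma = gamma, delta = delta, b = b, ell = ell, a = a, d = d,
               q = q, m = m, u = u, p = p, beta = beta, r = r, k_S = k_S,
               c = c)
  validate_colim_params(pars)
  structure(pars, class = "colim_params")
}

#' @export
print.colim_params <- function(x, ...) {
  lab <- attr(x, "strain")
  cat("Colimitation model parameters",
      if (!is.null(lab)) paste0(" [strain: ", lab, "]"), "\n", sep = "")
  print(unlist(x), ...)
  invisible(x)
}

validate_colim_params <- function(pars) {
  nm <- param_names()
  if (!all(nm %in% names(pars))) {
    stop("missing parameters: ", paste(setdiff(nm, names(pars)), collapse = ", "))
  }
  vals <- unlist(pars[nm])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all parameters must be finite and non-negative")
  }
  for (fr in c("alpha", "gamma", "beta", "rho")) {
    if (pars[[fr]] > 1) stop("'", fr, "' must lie in [0, 1]")
  }
  invisible(pars)
}

#' Canonical parameter order of the colimitation model
#'
#' The fixed name order used for config files, sampling and CSV export.
#' @return Character vector of the 18 parameter names.
#' @export
param_names <- function() {
  c("mu_S", "mu_N", "rho", "alpha", "gamma", "delta", "b", "ell", "a", "d",
    "q", "m", "u", "p", "beta", "r", "k_S", "c")
}

#' Sampling ranges of the colimitation model parameters
#'
#' The uniform sampling intervals used by the random-parameter screens, one
#' per model parameter.
#'
#' @return Named list of length-2 numeric vectors `c(lower, upper)`.
#' @examples
#' param_ranges()$alpha
#' @export
param_ranges <- function() {
  list(mu_S = c(0, 1), mu_N = c(0, 1), rho = c(0, 1), alpha = c(0, 1),
       gamma = c(0, 1), delta = c(0.001, 0.5), b = c(0, 2), ell = c(0, 2),
       a = c(0.1, 2), d = c(0, 2), q = c(0, 2), m = c(0, 2), u = c(0.1, 2),
       p = c(0, 2), beta = c(0, 1), r = c(0.1, 2), k_S = c(0, 0.5),
       c = c(0.1, 2))
}

#' Derive the four loss-of-function strain variants of a parameter set
#'
#' Every base parameter set defines four strains that share all parameters
#' except the two production maxima: Full (fixes nitrogen and produces
#' siderophores), LOFN (`b = 0`), LOFS (`q = 0`) and LOFB (`b = q = 0`).
#'
#' @param params a [colim_params()] object (the Full strain's parameters).
#' @return Named list of four `colim_params` objects (`Full`, `LOFN`, `LOFS`,
#'   `LOFB`), each carrying a `strain` attribute.
#' @examples
#' st <- derive_strains(colim_params(b = 1.2))
#' st$LOFN$b  # 0
#' @export
derive_strains <- function(params) {
  stopifnot(inherits(params, "colim_params"))
  mk <- function(label, b, q) {
    out <- params
    out$b <- b
    out$q <- q
    attr(out, "strain") <- label
    out
  }
  list(Full = mk("Full", params$b, params$q),
       LOFN = mk("LOFN", 0, params$q),
       LOFS = mk("LOFS", params$b, 0),
       LOFB = mk("LOFB", 0, 0))
}

#' @rdname derive_strains
#' @export
strain_labels <- function() c("Full", "LOFN", "LOFS", "LOFB")

#' Read or write a parameter set as a flat JSON config file
#'
#' Parameter files are flat JSON objects keyed by the canonical parameter
#' names (see [param_names()]). Unknown keys are rejected.
#'
#' @param path file path.
#' @param params a [colim_params()] object.
#' @return `read_params()` returns a `colim_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter keys in ", path, ": ", paste(unknown, collapse = ", "))
  }
  do.call(colim_params, as.list(raw))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "colim_params"))
  jsonlite::write_json(params[param_names()], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
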