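#' Monotone nitrogen-acquisition constraint on parameter sets
#'
#' For realism, a strain's total nitrogen acquisition
#' `eta(N) = alpha * f_N(N) + U_N(N)` must never decrease as environmental
#' fixed nitrogen increases: rising uptake must at least compensate the
#' facultative shutdown of fixation. The derivative condition
#' `a * d / (d + N)^2 >= alpha * b * ell / (ell + N)^2` for all `N >= 0`
#' reduces to the closed form `alpha * b <= a * min(d / ell, ell / d)`
#' (the worst case sits at `N = 0` or `N -> Inf`). Both the closed form and
#' a dense-grid numerical check are provided; the grid check is the
#' authority if they ever disagree.
#'
#' @param params a [colim_params()] object (or a named list/row with fields
#'   `alpha`, `b`, `a`, `d`, `ell`).
#' @param method `"closed_form"` (default) or `"grid"`.
#' @param N_max,n grid range and resolution for the numerical check.
#' @return Logical: does the parameter set satisfy the constraint?
#' @examples
#' acquisition_constraint(colim_params(b = 0.1))
#' @export
acquisition_constraint <- function(params, method = c("closed_form", "grid"),
                            N_max = 100, n = 2001) {
  method <- match.arg(method)
  alpha <- params$alpha; b <- params$b; a <- params$a
  d <- params$d; ell <- params$ell
  if (method == "closed_form") {
    lhs <- alpha * b
    bound <- if (ell <= 0 || d <= 0) 0 else a * min(d / ell, ell / d)
    return(lhs <= bound + 1e-12)
  }
  N <- seq(0, N_max, length.out = n)
  deta <- a * d / (d + N)^2 - alpha * b * ell / (ell + N)^2
  all(deta >= -1e-10)
}

#' Draw constrained random parameter sets for the colimitation model
#'
#' The synthetic parameter generator behind all screens: independent uniform
#' draws of the 18 parameters over their sampling ranges
#' ([param_ranges()]), rejecting draws that violate the nitrogen-acquisition
#' monotonicity constraint ([acquisition_constraint()]; about half of raw draws are
#' accepted at the default ranges). Draw order follows [param_names()], so
#' batches are fully reproducible from the seed.
#'
#' Note that rejection induces correlations among the accepted parameters
#' (in particular, accepted `alpha * b` is stochastically smaller than under
#' the raw uniforms), so the realized distribution is not the product of the
#' marginal uniforms.
#'
#' @param n number of accepted parameter sets required.
#' @param seed integer RNG seed.
#' @param ranges named list of sampling intervals (defaults to
#'   [param_ranges()]).
#' @param chunk raw draws per rejection round.
#' @return An object of class `sample_batch`: list with `params` (data.frame
#'   of accepted sets, one row each, columns in canonical order plus
#'   `draw`), `seed`, `n_requested`, `n_accepted`, `n_raw`, and
#'   `acceptance_fraction`.
#' @examples
#' batch <- sample_parameters(5, seed = 1)
#' batch$acceptance_fraction
#' @export
sample_parameters <- function(n, seed, ranges = param_ranges(), chunk = 4096) {
  stopifnot(n >= 1, is.numeric(seed))
  n <- as.integer(n)
  nm <- param_names()
  stopifnot(setequal(names(ranges), nm))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  acc <- list()
  n_acc <- 0L
  n_raw <- 0L
  probe_done <- FALSE
  while (n_acc < n) {
    draws <- vapply(nm, function(p) {
      stats::runif(chunk, ranges[[p]][1], ranges[[p]][2])
    }, numeric(chunk))
    draws <- as.data.frame(draws)
    bound <- draws$a * pmin(draws$d / draws$ell, draws$ell / draws$d)
    bound[is.na(bound)] <- 0
    keep <- draws$alpha * draws$b <= bound + 1e-12
    n_raw <- n_raw + chunk
    if (!probe_done && mean(keep) < 0.01) {
      stop("acceptance fraction below 1% on the probe batch; ",
           "check the sampling ranges")
    }
    probe_done <- TRUE
    kept <- draws[keep, , drop = FALSE]
    if (nrow(kept) > 0) {
      kept$draw <- n_raw - chunk + which(keep)
      acc[[length(acc) + 1]] <- kept
      n_acc <- n_acc + nrow(kept)
    }
  }
  params <- do.call(rbind, acc)
  # trim the final chunk so exactly n sets are returned while the raw-draw
  # count remains the number actually needed to reach the n-th acceptance
  params <- params[seq_len(n), , drop = FALSE]
  n_raw <- params$draw[n]
  rownames(params) <- NULL
  structure(list(params = params, seed = seed, n_requested = n,
                 n_accepted = n, n_raw = n_raw,
                 acceptance_fraction = n / n_raw, ranges = ranges),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat("Constrained parameter batch: ", x$n_accepted, " accepted / ",
      x$n_raw, " raw draws (", round(100 * x$acceptance_fraction, 1),
      "%), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Extract one parameter set from a batch
#'
#' @param batch a `sample_batch` from [sample_parameters()], or a data.frame
#'   of parameter rows.
#' @param i row index.
#' @return A [colim_params()] object.
#' @export
batch_params <- function(batch, i) {
  df <- if (inherits(batch, "sample_batch")) batch$params else batch
  do.call(colim_params, as.list(df[i, param_names()]))
}

#' Write a parameter batch as CSV
#'
#' One row per accepted set: the 18 parameters in canonical order plus the
#' raw draw index and the seed.
#'
#' @param batch a `sample_batch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(batch, path) {
  df <- batch$params
  df$seed <- batch$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
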