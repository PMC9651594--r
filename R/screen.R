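#' Monoculture viability screen over a parameter batch
#'
#' For every accepted parameter set and each of the four strain variants as
#' sole resident, integrates the model under the standard protocol (initial
#' conditions 0.3, horizon `1e5`, extinction threshold `1e-8` on final
#' density) and records the outcome. Trajectories that hit the
#' unbounded-growth cap are counted as viable (their final density is above
#' threshold) but flagged, since classification is by final density alone.
#'
#' @param batch a `sample_batch` from [sample_parameters()], or its `params`
#'   data.frame.
#' @param strains which strain variants to screen (default all four).
#' @param horizon integration horizon.
#' @param progress print a progress note every 500 sets.
#' @return A data.frame of class `screen_result` with one row per
#'   (set, strain): columns `set`, `strain`, `status`, `viable`,
#'   `unbounded`, `converged`, `N_star`, `S_star`, `x_star`.
#' @export
viability_screen <- function(batch, strains = strain_labels(),
                             horizon = 1e5, progress = FALSE) {
  df <- if (inherits(batch, "sample_batch")) batch$params else batch
  nset <- nrow(df)
  rows <- vector("list", nset * length(strains))
  k <- 0L
  for (i in seq_len(nset)) {
    base <- batch_params(df, i)
    sv <- derive_strains(base)
    for (lab in strains) {
      eq <- integrate_to_equilibrium(sv[[lab]], horizon = horizon)
      k <- k + 1L
      rows[[k]] <- data.frame(
        set = i, strain = lab, status = eq$status,
        viable = eq$status %in% c("viable_equilibrium", "unbounded"),
        unbounded = eq$status == "unbounded",
        converged = eq$converged,
        N_star = eq$resources[["N"]], S_star = eq$resources[["S"]],
        x_star = if (length(eq$density) > 0) eq$density[1] else NA_real_)
    }
    if (progress && i %% 500 == 0) message("screened ", i, "/", nset, " sets")
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out$strain <- factor(out$strain, levels = strain_labels())
  class(out) <- c("screen_result", "data.frame")
  attr(out, "batch_seed") <- if (inherits(batch, "sample_batch")) batch$seed else NA
  out
}

#' Invasion screen on top of a viability screen
#'
#' For every viable resident in a viability screen, evaluates the invasion
#' growth rate of each of the other three strain variants derived from the
#' same parameter set, at the resident's screened equilibrium (the final
#' integration state, per the screening protocol). Invasion succeeds when
#' the growth rate exceeds `tie_tol`.
#'
#' @param screen a `screen_result` from [viability_screen()].
#' @param batch the `sample_batch` the screen was computed from.
#' @param tie_tol tie tolerance on the invasion growth rate.
#' @return A data.frame with one row per (set, viable resident, invader):
#'   columns `set`, `resident`, `invader`, `growth`, `success`.
#' @export
invasibility_screen <- function(screen, batch, tie_tol = 1e-9) {
  df <- if (inherits(batch, "sample_batch")) batch$params else batch
  viable <- screen[screen$viable, , drop = FALSE]
  rows <- vector("list", nrow(viable) * 3L)
  k <- 0L
  for (j in seq_len(nrow(viable))) {
    i <- viable$set[j]
    res_lab <- as.character(viable$strain[j])
    sv <- derive_strains(batch_params(df, i))
    eqres <- c(S = viable$S_star[j], N = viable$N_star[j])
    for (lab in setdiff(strain_labels(), res_lab)) {
      g <- per_capita_growth(eqres[["S"]], eqres[["N"]], sv[[lab]])
      k <- k + 1L
      rows[[k]] <- data.frame(set = i, resident = res_lab, invader = lab,
                              growth = g, success = g > tie_tol)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out$resident <- factor(out$resident, levels = strain_labels())
  out$invader <- factor(out$invader, levels = strain_labels())
  out
}

#' Summarize a screen as the viability / invasibility percentage table
#'
#' Columns are residents; the first row is the percentage of parameter sets
#' for which that resident is viable, and the remaining rows are the
#' percentage of viable-resident parameter sets successfully invaded by each
#' invader variant (diagonal entries are blank).
#'
#' @param screen a `screen_result` from [viability_screen()].
#' @param invasions the output of [invasibility_screen()].
#' @param digits decimals in the percentage table.
#' @return A list with `percent` (5 x 4 data.frame of percentages) and
#'   `counts` (successes and denominators).
#' @export
screen_summary <- function(screen, invasions, digits = 1) {
  labs <- strain_labels()
  nset <- length(unique(screen$set))
  pv <- vapply(labs, function(l) {
    mean(screen$viable[screen$strain == l])
  }, numeric(1))
  pct <- matrix(NA_real_, nrow = 5, ncol = 4,
                dimnames = list(c("% Viable", paste("vs", labs, "invader")),
                                labs))
  cnt_num <- cnt_den <- matrix(NA_real_, nrow = 5, ncol = 4,
                               dimnames = dimnames(pct))
  pct[1, ] <- 100 * pv
  cnt_num[1, ] <- round(pv * nset)
  cnt_den[1, ] <- nset
  for (res in labs) {
    for (inv in setdiff(labs, res)) {
      sel <- invasions$resident == res & invasions$invader == inv
      pct[paste("vs", inv, "invader"), res] <- 100 * mean(invasions$success[sel])
      cnt_num[paste("vs", inv, "invader"), res] <- sum(invasions$success[sel])
      cnt_den[paste("vs", inv, "invader"), res] <- sum(sel)
    }
  }
  list(percent = as.data.frame(round(pct, digits)),
       counts = list(successes = cnt_num, denominators = cnt_den))
}

#' Bin screen outcomes by one focal parameter
#'
#' Splits the focal parameter's sampling range into evenly spaced intervals
#' and reports the per-interval proportion of viable parameter sets (for one
#' strain) or of successful invasions (for one resident/invader pair),
#' together with counts so confidence intervals can be computed downstream.
#' Empty bins get `NA` proportions.
#'
#' @param screen a `screen_result` ([viability_screen()]) or an invasion
#'   data.frame ([invasibility_screen()]).
#' @param batch the `sample_batch` the screen came from.
#' @param focal focal parameter name.
#' @param strain strain label (viability binning).
#' @param resident,invader strain labels (invasion binning; both given
#'   switches to invasion mode).
#' @param n_bins number of intervals.
#' @return A data.frame with columns `bin`, `lower`, `upper`, `n`,
#'   `successes`, `proportion`.
#' @export
bin_by_parameter <- function(screen, batch, focal, strain = NULL,
                             resident = NULL, invader = NULL, n_bins = 100) {
  df <- if (inherits(batch, "sample_batch")) batch$params else batch
  rng <- (if (inherits(batch, "sample_batch")) batch$ranges else param_ranges())[[focal]]
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  if (!is.null(resident) && !is.null(invader)) {
    sel <- screen$resident == resident & screen$invader == invader
    val <- df[[focal]][screen$set[sel]]
    outcome <- screen$success[sel]
  } else {
    stopifnot(!is.null(strain))
    sel <- screen$strain == strain
    val <- df[[focal]][screen$set[sel]]
    outcome <- screen$viable[sel]
  }
  bin <- pmin(pmax(findInterval(val, edges, rightmost.closed = TRUE), 1), n_bins)
  n <- tabulate(bin, n_bins)
  succ <- vapply(seq_len(n_bins), function(k) sum(outcome[bin == k]), numeric(1))
  data.frame(bin = seq_len(n_bins), lower = edges[-length(edges)],
             upper = edges[-1], n = n, successes = succ,
             proportion = ifelse(n > 0, succ / n, NA_real_))
}

#' Invasion-probability lattice over privatization and fixation cost
#'
#' Lays a `k x k` lattice over the `(alpha, gamma)` unit square and, at each
#' node, computes the probability of successful invasion among the
#' viable-resident parameter sets lying within a disk of given radius around
#' the node. Nodes whose disks contain no viable sets are reported `NA`.
#'
#' @param invasions invasion data.frame from [invasibility_screen()].
#' @param batch the `sample_batch`.
#' @param resident,invader strain labels selecting the pair.
#' @param k lattice size per axis.
#' @param radius disk radius.
#' @return A data.frame with columns `alpha`, `gamma`, `n`, `probability`.
#' @export
alpha_gamma_lattice <- function(invasions, batch, resident, invader,
                                k = 50, radius = 0.05) {
  df <- if (inherits(batch, "sample_batch")) batch$params else batch
  sel <- invasions$resident == resident & invasions$invader == invader
  av <- df$alpha[invasions$set[sel]]
  gv <- df$gamma[invasions$set[sel]]
  succ <- invasions$success[sel]
  nodes <- expand.grid(alpha = seq(0, 1, length.out = k),
                       gamma = seq(0, 1, length.out = k))
  res <- t(vapply(seq_len(nrow(nodes)), function(i) {
    inside <- (av - nodes$alpha[i])^2 + (gv - nodes$gamma[i])^2 <= radius^2
    n <- sum(inside)
    c(n, if (n > 0) mean(succ[inside]) else NA_real_)
  }, numeric(2)))
  nodes$n <- res[, 1]
  nodes$probability <- res[, 2]
  nodes
}
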