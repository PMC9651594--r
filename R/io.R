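#' Export ZNGI curves and impact vectors as tidy CSV
#'
#' One row per sampled isocline point, with the strain label and the impact
#' vector evaluated at the point (columns `strain`, `S`, `N`, `I_S`, `I_N`).
#'
#' @param zngis a `zngi` data.frame from [trace_zngi()] or a list of them.
#' @param strains the matching strain-realized [colim_params()] objects (a
#'   single object or list).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_zngi_csv <- function(zngis, strains, path) {
  if (inherits(zngis, "zngi")) zngis <- list(zngis)
  if (inherits(strains, "colim_params")) strains <- list(strains)
  stopifnot(length(zngis) == length(strains))
  rows <- mapply(function(z, pr) {
    iv <- t(vapply(seq_len(nrow(z)), function(i) {
      if (is.na(z$N[i])) return(c(NA_real_, NA_real_))
      impact_vector(z$S[i], z$N[i], pr)
    }, numeric(2)))
    lab <- attr(z, "strain") %||% attr(pr, "strain") %||% "strain"
    data.frame(strain = lab, S = z$S, N = z$N, I_S = iv[, 1], I_N = iv[, 2])
  }, zngis, strains, SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export pairwise competition outcomes as CSV
#'
#' One row per ordered strain pair and parameter set, with the invader's
#' growth rate at the resident equilibrium, the classification, and the
#' number of located coexistence points.
#'
#' @param outcomes list of `competition_outcome` objects
#'   ([classify_pairwise()]).
#' @param path output file path.
#' @param set optional parameter-set identifiers (recycled).
#' @return `path`, invisibly.
#' @export
export_pairwise_csv <- function(outcomes, path, set = seq_along(outcomes)) {
  rows <- mapply(function(oc, id) {
    data.frame(set = id, resident = oc$pair[1], invader = oc$pair[2],
               G_invader = oc$invasion[["B_at_A"]],
               classification = oc$classification,
               n_coexistence_points = nrow(oc$coexistence))
  }, outcomes, set, SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run one analysis step from a configuration, writing artifacts to disk
#'
#' The programmatic entry point behind the command-line wrapper
#' (`inst/cli/privgoods.R`). Each subcommand is a thin layer over the
#' package functions; results are written as CSV plus a JSON run summary
#' (config, seed, package version, timings) so every artifact is
#' reproducible from its provenance record.
#'
#' Subcommands: `sample` (parameter batch), `viability`, `invade`, `screen-table`
#' (the full viability/invasibility percentage table), `zngi`, `supplymap`,
#' `pairwise`, `pip`, `ess`, `ess-map`, `envelope`, `critical-ratio`,
#' `sr-demo` (single-resource R* and competition demo).
#'
#' @param subcommand one of the names above.
#' @param config named list: `seed`, `n`, `out_dir`, `params` (path to a
#'   JSON parameter file or a named list of overrides of the defaults), and
#'   subcommand-specific entries (`trait`, `resident`, `invader`, `grid_n`).
#' @return Invisible list of the paths written.
#' @export
run_analysis <- function(subcommand, config = list()) {
  known <- c("sample", "viability", "invade", "screen-table", "zngi", "supplymap",
             "pairwise", "pip", "ess", "ess-map", "envelope",
             "critical-ratio", "sr-demo")
  if (!subcommand %in% known) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  cfg <- config
  cfg$seed <- cfg$seed %||% 1L
  cfg$n <- cfg$n %||% 200L
  if (cfg$n < 1) stop("config 'n' must be at least 1")
  cfg$out_dir <- cfg$out_dir %||% "."
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- if (is.character(cfg$params)) {
    read_params(cfg$params)
  } else if (is.list(cfg$params)) {
    do.call(colim_params, cfg$params)
  } else {
    colim_params()
  }
  t0 <- Sys.time()
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    paths <<- c(paths, path)
    path
  }
  need_screen <- subcommand %in% c("viability", "invade", "screen-table")
  if (subcommand == "sample") {
    batch <- sample_parameters(cfg$n, cfg$seed)
    emit("batch.csv", function(p) write_batch_csv(batch, p))
  } else if (need_screen) {
    batch <- sample_parameters(cfg$n, cfg$seed)
    emit("batch.csv", function(p) write_batch_csv(batch, p))
    screen <- viability_screen(batch)
    emit("viability.csv", function(p) utils::write.csv(screen, p, row.names = FALSE))
    if (subcommand %in% c("invade", "screen-table")) {
      inv <- invasibility_screen(screen, batch)
      emit("invasions.csv", function(p) utils::write.csv(inv, p, row.names = FALSE))
      if (subcommand == "screen-table") {
        tb <- screen_summary(screen, inv)
        emit("screen_table.csv", function(p) utils::write.csv(tb$percent, p))
        emit("screen_table_counts.csv", function(p) {
          utils::write.csv(as.data.frame(tb$counts$denominators), p)
        })
      }
    }
  } else if (subcommand == "zngi") {
    sv <- derive_strains(pars)
    zs <- lapply(sv, trace_zngi)
    emit("zngi.csv", function(p) export_zngi_csv(zs, sv, p))
  } else if (subcommand == "supplymap") {
    sv <- derive_strains(pars)
    rows <- lapply(names(sv), function(lab) {
      mp <- map_supply_to_equilibrium(sv[[lab]])
      data.frame(strain = lab, S = mp$resources[["S"]], N = mp$resources[["N"]],
                 x = mp$density, status = mp$status,
                 matched = isTRUE(mp$matched))
    })
    emit("supplymap.csv", function(p) {
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    })
  } else if (subcommand == "pairwise") {
    sv <- derive_strains(pars)
    combos <- utils::combn(strain_labels(), 2, simplify = FALSE)
    ocs <- lapply(combos, function(cb) classify_pairwise(sv[[cb[1]]], sv[[cb[2]]]))
    emit("pairwise.csv", function(p) export_pairwise_csv(ocs, p))
  } else if (subcommand == "pip") {
    trait <- cfg$trait %||% "b"
    pip <- compute_pip(pars, trait,
                       grid = seq(0, 2, length.out = cfg$grid_n %||% 41))
    emit(paste0("pip_", trait, ".csv"), function(p) {
      m <- pip$growth
      dimnames(m) <- list(invader = signif(pip$grid, 6),
                          resident = signif(pip$grid, 6))
      utils::write.csv(sign(m), p)
    })
  } else if (subcommand == "ess") {
    trait <- cfg$trait %||% "b"
    ess <- find_ess(pars, trait)
    emit(paste0("ess_", trait, ".csv"), function(p) {
      utils::write.csv(ess$gradient, p, row.names = FALSE)
    })
    emit(paste0("ess_", trait, ".json"), function(p) {
      jsonlite::write_json(list(trait = ess$trait, ess_value = ess$ess_value,
                                regime = ess$regime,
                                uninvasible = ess$uninvasible),
                           p, auto_unbox = TRUE, digits = NA)
    })
  } else if (subcommand == "ess-map") {
    agrid <- seq(0.05, 0.95, length.out = cfg$grid_n %||% 7)
    ggrid <- seq(0.05, 0.95, length.out = cfg$grid_n %||% 7)
    rows <- lapply(agrid, function(av) {
      do.call(rbind, lapply(ggrid, function(gv) {
        pp <- pars
        pp$alpha <- av
        pp$gamma <- gv
        ess <- find_ess(pp, "b", n_grid = 11)
        data.frame(alpha = av, gamma = gv, ess_b = ess$ess_value,
                   regime = ess$regime)
      }))
    })
    emit("ess_map.csv", function(p) {
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    })
  } else if (subcommand == "envelope") {
    env <- zngi_envelope(pars, cfg$trait %||% "b")
    emit("envelope.csv", function(p) utils::write.csv(env, p, row.names = FALSE))
  } else if (subcommand == "critical-ratio") {
    cr <- critical_ns_ratio(pars)
    emit("critical_ratio.json", function(p) {
      jsonlite::write_json(list(ratio = cr$ratio, S = cr$S %||% NA,
                                N = cr$N %||% NA,
                                reason = cr$reason %||% NA),
                           p, auto_unbox = TRUE, digits = NA)
    })
  } else if (subcommand == "sr-demo") {
    spec <- single_resource_spec(alpha = pars$alpha, gamma = pars$gamma,
                                 delta = pars$delta)
    eq <- sr_integrate(spec)
    demo <- data.frame(R1_star = sr_rstar(spec, 1), R2_star = sr_rstar(spec, 2),
                       winner = c("producer", "non-producer",
                                  "unresolved")[sr_winner(eq)],
                       status = eq$status)
    emit("sr_demo.csv", function(p) utils::write.csv(demo, p, row.names = FALSE))
  }
  summary <- list(subcommand = subcommand, seed = cfg$seed, n = cfg$n,
                  params = pars[param_names()],
                  package_version = as.character(utils::packageVersion("privgoods")),
                  elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  artifacts = paths)
  sp <- file.path(cfg$out_dir, paste0("run_", gsub("-", "_", subcommand), ".json"))
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, sp))
}

# 1 producer, 2 non-producer, 3 unresolved
sr_winner <- function(eq) {
  x <- eq$state[2:3]
  if (eq$status == "unbounded") {
    return(if (x[1] >= x[2]) 1L else 2L)
  }
  alive <- x >= 1e-8
  if (alive[1] && !alive[2]) 1L else if (alive[2] && !alive[1]) 2L else 3L
}
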