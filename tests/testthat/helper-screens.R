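# Shared fixtures, built in code. The large screen used by the
# reproduction tests is computed once per test run and cached.

.pg_cache <- new.env(parent = emptyenv())

# canonical screening experiment: n accepted sets, all four strains
cached_screen <- function(n = 2000, seed = 101) {
  key <- paste0("screen_", n, "_", seed)
  if (!is.null(.pg_cache[[key]])) return(.pg_cache[[key]])
  batch <- sample_parameters(n, seed = seed)
  screen <- viability_screen(batch)
  invasions <- invasibility_screen(screen, batch)
  out <- list(batch = batch, screen = screen, invasions = invasions,
              table = screen_summary(screen, invasions))
  .pg_cache[[key]] <- out
  out
}

# a small batch for unit-level tests
small_batch <- function(n = 40, seed = 7) {
  key <- paste0("batch_", n, "_", seed)
  if (is.null(.pg_cache[[key]])) .pg_cache[[key]] <- sample_parameters(n, seed = seed)
  .pg_cache[[key]]
}

# random single-resource spec with valid shape constraints and both strains
# viable; NULL when the draw is invalid
random_sr_spec <- function() {
  b <- runif(1, 0.2, 2)
  ell <- runif(1, 0.5, 3)
  a <- runif(1, 0.5, 3)
  d <- runif(1, 0.5, 3)
  alpha <- runif(1)
  gamma <- runif(1)
  delta <- runif(1, 0.05, 0.45)
  mu <- runif(1, 0.05, 1)
  rho <- runif(1, 0.05, 1)
  # shape constraint for the default Monod-type forms
  if (abs(alpha - gamma) * b > a * min(d / ell, ell / d)) return(NULL)
  if (delta >= a * 0.9) return(NULL)
  tryCatch(
    single_resource_spec(mu = mu, rho = rho, alpha = alpha, gamma = gamma,
                         delta = delta, f_params = list(b = b, ell = ell),
                         U_params = list(a = a, d = d)),
    error = function(e) NULL)
}

cross2 <- function(v, w) v[[1]] * w[[2]] - v[[2]] * w[[1]]

set_trait_pg <- function(params, value, trait = "b") {
  privgoods:::set_trait(params, trait, value)
}
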