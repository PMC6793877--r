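# Shared fixtures: small simulated datasets and an enumeration-based
# grid-search oracle for the likelihood optimum, independent of the
# package's optimiser.

eff_grid_1rep <- function(seed = 101) build_effort_grid(1, seed = seed)

quick_eff_choices <- function(model_name = "no_sensitivity_linear",
                              params = c(lambda = 1.2, mu = 0.52),
                              seed = 202, n_repetitions = 3) {
  simulate_choices(build_effort_grid(n_repetitions, seed = seed),
                   choice_model(model_name), params, seed = seed + 1)
}

# Dense grid search over the free-parameter box, refined twice around the
# running minimum. Pure enumeration; shares only the NLL definition with
# the fit path, never the optimiser.
grid_search_nll <- function(choices, model, n_points = 400, n_refine = 2) {
  free <- model$free
  lower <- vapply(model$bounds, `[`, numeric(1), 1)
  upper <- vapply(model$bounds, `[`, numeric(1), 2)
  lo <- lower
  hi <- upper
  best <- NULL
  for (stage in seq_len(1 + n_refine)) {
    axes <- lapply(seq_along(free), function(j) seq(lo[j], hi[j], length.out = n_points))
    pts <- as.matrix(expand.grid(axes))
    vals <- apply(pts, 1, function(p)
      negative_log_likelihood(choices, model, stats::setNames(p, free)))
    k <- which.min(vals)
    best <- list(par = stats::setNames(pts[k, ], free), value = vals[k])
    step <- (hi - lo) / (n_points - 1)
    lo <- pmax(lower, pts[k, ] - 2 * step)
    hi <- pmin(upper, pts[k, ] + 2 * step)
  }
  best
}
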