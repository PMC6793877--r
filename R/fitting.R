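# Per-subject maximum-likelihood estimation.
#
# The likelihood surface is optimised with a derivative-free simplex search
# on a logistic transform of the parameters (so the box bounds are respected
# without penalty terms), restarted from multiple uniform draws within the
# bounds; one-parameter models use bounded Brent search directly. Repeated
# presentations of the same lottery are aggregated to binomial counts before
# optimisation, which changes nothing in the likelihood but cuts its cost.

make_nll <- function(choices, model) {
  cols <- if (model$domain == "effort") c("b_gain", "b_loss") else c("usd_gain", "usd_loss")
  if (!all(c(cols, "response") %in% names(choices))) {
    abort(paste0("`choices` must carry columns ",
                 paste(c(cols, "response"), collapse = ", "), "."))
  }
  if (!all(choices$response %in% c(0, 1))) {
    abort("`choices$response` must contain only 0 and 1.")
  }
  agg <- choices %>%
    group_by(dplyr::across(dplyr::all_of(cols))) %>%
    summarise(n_acc = sum(.data$response), n_tot = n(), .groups = "drop")
  n_rej <- agg$n_tot - agg$n_acc
  n_acc <- agg$n_acc
  lot <- agg[cols]
  function(free_values) {
    p <- full_params(model, stats::setNames(free_values, model$free))
    du <- lottery_utility(lot, model, p) - sure_bet_utility(model, p)
    pr <- clamp_prob(plogis(p[["mu"]] * du))
    -sum(n_acc * log(pr) + n_rej * log1p(-pr))
  }
}

# Restart initial points. Away from the region where mu matches the utility
# scale, the clamped likelihood is nearly flat (choices are predicted
# deterministically), and a simplex started there stalls. So mu is drawn
# log-uniformly across its bounds, the value/encoding parameters uniformly,
# and the first restart is pinned at neutral valuation (alpha = lambda =
# gamma = 1) with mu set to the reciprocal median |dU| -- a start inside the
# informative basin for any outcome scale.
draw_starts <- function(choices, model, n_restarts, lower, upper) {
  k <- model$n_params
  mu_i <- match("mu", model$free)
  starts <- matrix(runif(n_restarts * k, lower, upper), ncol = k, byrow = TRUE)
  mu_lo <- max(lower[mu_i], 1e-3)
  starts[, mu_i] <- exp(runif(n_restarts, log(mu_lo), log(upper[mu_i])))
  neutral <- stats::setNames(rep(1, k), model$free)
  du <- lottery_utility(choices, model, full_params(model, neutral)) -
    sure_bet_utility(model, full_params(model, neutral))
  scale <- median(abs(du[du != 0]))
  mu0 <- if (is.finite(scale) && scale > 0) 1 / scale else 1
  starts[1, ] <- pmin(pmax(neutral, lower + 1e-6), upper - 1e-6)
  starts[1, mu_i] <- min(max(mu0, mu_lo), upper[mu_i] * (1 - 1e-6))
  starts
}

#' Fit one subject's choices by maximum likelihood
#'
#' Minimises the Bernoulli negative log-likelihood of a subject's
#' accept/reject responses under a candidate model, using bounded
#' multi-restart derivative-free optimisation (Nelder-Mead simplex on a
#' logistic bound transform; Brent search for single-parameter models).
#' Restart initial points are random draws within the bounds (log-uniform
#' for the scale parameter `mu`, uniform otherwise), plus one start at
#' neutral valuation with `mu` matched to the utility scale; the returned
#' fit is the best restart.
#'
#' @param choices Tibble of one subject's trials (outcome columns plus
#'   `response` in \{0, 1\}).
#' @param model A [choice_model()].
#' @param n_restarts Number of random restarts (default 20; single-parameter
#'   models use one deterministic bounded search).
#' @param seed Optional integer seed making the restart draws reproducible.
#' @return An object of class `lottery_fit`: estimates (free and fixed
#'   parameters), `neg_ll`, `aic = 2 * n_params + 2 * neg_ll`, `n_trials`,
#'   restart bookkeeping and a convergence flag. Use [tidy()] / [glance()]
#'   to extract tibbles.
#' @examples
#' g <- build_effort_grid(1, seed = 1)
#' ch <- simulate_choices(g, choice_model("no_loss_aversion_linear"),
#'                        c(mu = 0.4), seed = 2)
#' fit <- fit_subject(ch, choice_model("no_loss_aversion_linear"), seed = 3)
#' glance(fit)
#' @export
fit_subject <- function(choices, model, n_restarts = 20, seed = NULL) {
  stopifnot(inherits(model, "choice_model"), n_restarts >= 1)
  if (nrow(choices) == 0) abort("`choices` is empty.")
  nll <- make_nll(choices, model)
  lower <- vapply(model$bounds, `[`, numeric(1), 1)
  upper <- vapply(model$bounds, `[`, numeric(1), 2)
  k <- model$n_params

  if (k == 1L) {
    opt <- optim(mean(c(lower, upper)), function(x) nll(x),
                 method = "Brent", lower = lower, upper = upper,
                 control = list(maxit = 2000))
    # Brent's interior search can stop a tolerance away from a boundary
    # optimum; check the endpoints explicitly.
    cand <- c(opt$par, lower, upper)
    vals <- c(opt$value, nll(lower), nll(upper))
    pick <- which.min(vals)
    restarts <- tibble(
      restart = 1L, neg_ll = vals[pick], converged = opt$convergence == 0
    )
    best_par <- stats::setNames(cand[pick], model$free)
    best <- 1L
  } else {
    starts <- if (is.null(seed)) {
      draw_starts(choices, model, n_restarts, lower, upper)
    } else {
      withr::with_seed(seed, draw_starts(choices, model, n_restarts, lower, upper))
    }
    runs <- lapply(seq_len(n_restarts), function(i) {
      z0 <- to_unbounded(starts[i, ], lower, upper)
      opt <- tryCatch(
        optim(z0, function(z) nll(from_unbounded(z, lower, upper)),
              method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-8)),
        error = function(e) NULL
      )
      if (is.null(opt)) return(list(value = Inf, par = rep(NA_real_, k), conv = FALSE))
      list(value = opt$value, par = from_unbounded(opt$par, lower, upper),
           conv = opt$convergence == 0)
    })
    values <- vapply(runs, `[[`, numeric(1), "value")
    restarts <- tibble(
      restart = seq_len(n_restarts), neg_ll = values,
      converged = vapply(runs, `[[`, logical(1), "conv")
    )
    best <- which.min(values)
    best_par <- stats::setNames(runs[[best]]$par, model$free)
  }

  estimate <- full_params(model, best_par)
  neg_ll <- restarts$neg_ll[best]
  structure(
    list(
      model = model,
      estimate = estimate,
      free = best_par,
      neg_ll = neg_ll,
      aic = 2 * model$n_params + 2 * neg_ll,
      n_trials = nrow(choices),
      n_restarts = nrow(restarts),
      best_restart = best,
      converged = isTRUE(restarts$converged[best]) && is.finite(neg_ll),
      restarts = restarts
    ),
    class = "lottery_fit"
  )
}

#' @export
print.lottery_fit <- function(x, ...) {
  cat("<lottery_fit> model:", x$model$name, "\n")
  est <- x$free
  cat("  estimates: ",
      paste(names(est), "=", formatC(est, digits = 4, format = "g"), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  neg_ll = %.4f | AIC = %.4f | n = %d trials | %s\n",
              x$neg_ll, x$aic, x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname fit_subject
#' @param x A `lottery_fit` object.
#' @param ... Unused.
#' @export
tidy.lottery_fit <- function(x, ...) {
  free <- names(x$free)
  all_par <- intersect(.param_order, union(names(x$estimate), free))
  tibble(
    term = all_par,
    estimate = unname(x$estimate[all_par]),
    fixed = !all_par %in% free,
    lower = vapply(all_par, function(p)
      if (p %in% free) x$model$bounds[[p]][1] else NA_real_, numeric(1)),
    upper = vapply(all_par, function(p)
      if (p %in% free) x$model$bounds[[p]][2] else NA_real_, numeric(1))
  )
}

#' @rdname fit_subject
#' @export
glance.lottery_fit <- function(x, ...) {
  tibble(
    model = x$model$name, n_params = x$model$n_params,
    neg_ll = x$neg_ll, aic = x$aic, n_trials = x$n_trials,
    n_restarts = x$n_restarts, best_restart = x$best_restart,
    converged = x$converged
  )
}

#' Fit every subject under every candidate model
#'
#' Applies [fit_subject()] over the cross product of subjects in `choices`
#' and models in `models`. Per-cell seeds are derived deterministically from
#' the master seed and the (subject, model) labels, so adding or removing a
#' model leaves the other cells' results unchanged.
#'
#' @param choices Tibble of trials for one or more subjects (must carry
#'   `subject_id`).
#' @param models A named list of [choice_model()] objects (e.g.
#'   [eff_model_space()]), or a single model.
#' @param n_restarts Restarts per fit (default 20).
#' @param seed Master integer seed.
#' @return A tibble with one row per subject x model: parameter estimates
#'   (`alpha`, `lambda`, `gamma`, `mu`, fixed values filled in), `n_params`,
#'   `neg_ll`, `aic`, `n_trials`, `converged`.
#' @export
fit_cohort <- function(choices, models, n_restarts = 20, seed = 1) {
  if (inherits(models, "choice_model")) models <- stats::setNames(list(models), models$name)
  if (!"subject_id" %in% names(choices)) abort("`choices` must carry `subject_id`.")
  subjects <- unique(choices$subject_id)
  grid <- tidyr::expand_grid(subject_id = subjects, model = names(models))
  purrr::pmap_dfr(grid, function(subject_id, model) {
    m <- models[[model]]
    sub <- choices[choices$subject_id == subject_id, , drop = FALSE]
    fit <- fit_subject(sub, m, n_restarts = n_restarts,
                       seed = derive_seed(seed, subject_id, model))
    tibble(
      subject_id = subject_id, model = model,
      alpha = fit$estimate[["alpha"]], lambda = fit$estimate[["lambda"]],
      gamma = fit$estimate[["gamma"]], mu = fit$estimate[["mu"]],
      n_params = m$n_params, neg_ll = fit$neg_ll, aic = fit$aic,
      n_trials = fit$n_trials, converged = fit$converged
    )
  })
}
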