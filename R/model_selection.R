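# Group-level random-effects Bayesian model selection.
#
# Model frequencies r in the population are given a Dirichlet prior with unit
# counts; each subject's model assignment is a latent categorical variable.
# A variational scheme alternates (i) subject-wise assignment
# responsibilities computed from the subject's log-evidence plus the digamma
# of the Dirichlet counts and (ii) Dirichlet count updates from the summed
# responsibilities. Exceedance probabilities are estimated by sampling the
# posterior Dirichlet; the Bayesian omnibus risk compares the free energy of
# the random-effects model against the null of equal frequencies, and
# protects the exceedance probabilities by blending with 1/K.

#' AIC approximation to the log model evidence
#'
#' The per-subject marginal likelihood of each candidate is approximated from
#' its maximum-likelihood fit as `log evidence = -AIC / 2`.
#'
#' @param aic Numeric vector of AIC values, or a fit tibble from
#'   [fit_cohort()] (with columns `aic`, and then also `subject_id`,
#'   `model`).
#' @return A numeric vector (or the tibble with a `log_evidence` column
#'   added).
#' @export
log_evidence_from_aic <- function(aic) {
  if (is.data.frame(aic)) {
    if (!"aic" %in% names(aic)) abort("Fit table must have an `aic` column.")
    return(mutate(aic, log_evidence = -.data$aic / 2))
  }
  -aic / 2
}

# Fit tibble (subject_id x model) -> subjects x models evidence matrix.
evidence_matrix <- function(fits) {
  if (is.matrix(fits)) return(fits)
  need <- c("subject_id", "model", "aic")
  if (!all(need %in% names(fits))) {
    abort("`fits` must be a matrix or a fit tibble with subject_id, model, aic.")
  }
  wide <- fits %>%
    mutate(log_evidence = -.data$aic / 2) %>%
    select("subject_id", "model", "log_evidence") %>%
    tidyr::pivot_wider(names_from = "model", values_from = "log_evidence")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$subject_id)
  m
}

#' Random-effects Bayesian model selection
#'
#' Given per-subject log model evidences (here: `-AIC/2` from maximum
#' likelihood fits), estimates the posterior Dirichlet over population model
#' frequencies, the expected frequencies, exceedance probabilities (xp),
#' Bayesian omnibus risk (BOR; the posterior probability that observed
#' frequency differences arose by chance, from the free-energy comparison
#' with the equal-frequency null) and protected exceedance probabilities
#' `pxp = (1 - BOR) * xp + BOR / K`.
#'
#' @param evidence A subjects x models matrix of log evidences, or a fit
#'   tibble from [fit_cohort()] (AICs are converted internally).
#' @param n_samples Dirichlet draws used to estimate xp (default 1e5).
#' @param seed Optional seed for the xp sampler.
#' @param max_iter,tol Variational iteration cap (default 500) and
#'   convergence tolerance on the Dirichlet counts.
#' @return An object of class `bms_result` with fields `alpha` (posterior
#'   Dirichlet counts), `expected_freq`, `xp`, `pxp`, `bor`, `models`,
#'   `n_subjects`, and free energies `F_rfx`, `F_null`. [tidy()] gives a
#'   per-model tibble, [glance()] a one-row summary, [select_winner()] the
#'   highest-pxp model.
#' @export
rfx_bms <- function(evidence, n_samples = 1e5, seed = NULL,
                    max_iter = 500, tol = 1e-10) {
  L <- evidence_matrix(evidence)
  if (!all(is.finite(L))) abort("Log evidences must all be finite.")
  K <- ncol(L)
  N <- nrow(L)
  if (K < 2) abort("Need at least 2 models.")
  models <- colnames(L) %||% paste0("model", seq_len(K))

  # Per-subject constants cancel in the responsibilities and shift both free
  # energies equally; remove them up front for numerical headroom.
  shift <- apply(L, 1, max)
  Ln <- L - shift

  alpha0 <- rep(1, K)
  alpha <- alpha0
  g <- matrix(1 / K, N, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ln_u <- sweep(Ln, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(ln_u - apply(ln_u, 1, max))
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) warn("rfx_bms: variational updates did not converge; results use the last iterate.")

  expected_freq <- alpha / sum(alpha)
  xp <- dirichlet_exceedance(alpha, n_samples = n_samples, seed = seed)

  # Free energy (ELBO) of the random-effects model ...
  e_ln_r <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * e_ln_r)
  F_rfx <- sum(g * sweep(Ln, 2, e_ln_r, `+`)) - sum(xlogx(g)) - kl_dir
  # ... versus the null that all frequencies equal 1/K.
  F_null <- sum(apply(Ln, 1, function(l) log(mean(exp(l - max(l)))) + max(l)))

  bor <- 1 / (1 + exp(F_rfx - F_null))
  pxp <- (1 - bor) * xp + bor / K

  structure(
    list(
      alpha = stats::setNames(alpha, models),
      expected_freq = stats::setNames(expected_freq, models),
      xp = stats::setNames(xp, models),
      pxp = stats::setNames(pxp, models),
      bor = bor,
      models = models,
      n_subjects = N,
      n_samples = n_samples,
      F_rfx = F_rfx + sum(shift),
      F_null = F_null + sum(shift),
      n_iter = it,
      converged = converged
    ),
    class = "bms_result"
  )
}

# P(model k has the largest frequency) under Dirichlet(alpha), by sampling.
dirichlet_exceedance <- function(alpha, n_samples = 1e5, seed = NULL) {
  K <- length(alpha)
  draw <- function() {
    g <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    winners <- max.col(g, ties.method = "first")
    tabulate(winners, nbins = K) / n_samples
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> ", x$n_subjects, " subjects x ", length(x$models),
      " models\n", sep = "")
  print(tidy(x), n = length(x$models))
  cat(sprintf("Bayesian omnibus risk: %.3g\n", x$bor))
  invisible(x)
}

#' @rdname rfx_bms
#' @param x A `bms_result`.
#' @param ... Unused.
#' @export
tidy.bms_result <- function(x, ...) {
  tibble(
    model = x$models,
    alpha = unname(x$alpha),
    expected_freq = unname(x$expected_freq),
    xp = unname(x$xp),
    pxp = unname(x$pxp)
  )
}

#' @rdname rfx_bms
#' @export
glance.bms_result <- function(x, ...) {
  w <- select_winner(x)
  tibble(
    n_subjects = x$n_subjects, n_models = length(x$models),
    winner = w$model, winner_pxp = w$pxp, bor = x$bor,
    converged = x$converged
  )
}

#' Select the winning model from a BMS result
#'
#' The winner is the model with the highest protected exceedance
#' probability; exact ties are broken toward the lowest index and flagged.
#'
#' @param bms A `bms_result` from [rfx_bms()].
#' @return A one-row tibble: `model`, `index`, `pxp`, `bor`, `tie`.
#' @export
select_winner <- function(bms) {
  stopifnot(inherits(bms, "bms_result"))
  idx <- unname(which.max(bms$pxp))
  tie <- sum(bms$pxp == bms$pxp[idx]) > 1
  if (tie) warn("select_winner: exact tie on pxp; returning the lowest index.")
  tibble(model = bms$models[idx], index = idx,
         pxp = unname(bms$pxp[idx]), bor = bms$bor, tie = tie)
}

#' Parameter priors for the confusion analysis
#'
#' `anchor_param_prior()` (the default in [confusion_analysis()]) draws each
#' generating parameter from the population model of the synthetic cohort
#' generator: log-normal around the model's anchor medians with IQR-matched
#' spread (see [default_param_anchors()]). `uniform_param_prior()` instead
#' draws uniformly over each free parameter's fitting bounds, except `mu`,
#' drawn log-uniformly so that runs are not dominated by uninformative
#' random-choice subjects; note that box-uniform value/encoding parameters
#' place most mass on behaviourally degenerate subjects (deterministic
#' corner boundaries that several encodings reproduce exactly), under which
#' no model space is fully identifiable.
#'
#' @param task Task whose anchors parameterise the draws.
#' @return A function `(model, n)` returning an n-row tibble of parameter
#'   draws (free parameters only).
#' @export
anchor_param_prior <- function(task = "EFF") {
  force(task)
  function(model, n) {
    draw_subject_params(model, n, distribution = "lognormal",
                        task = task)[model$free]
  }
}

#' @rdname anchor_param_prior
#' @param mu_range Range of the log-uniform `mu` draw.
#' @export
uniform_param_prior <- function(mu_range = c(0.01, 20)) {
  force(mu_range)
  function(model, n) {
    draws <- lapply(model$free, function(par) {
      if (par == "mu") {
        exp(runif(n, log(mu_range[1]), log(mu_range[2])))
      } else {
        b <- model$bounds[[par]]
        runif(n, b[1], b[2])
      }
    })
    stats::setNames(as_tibble(draws, .name_repair = "minimal"), model$free)
  }
}

#' Monte-Carlo model confusion analysis
#'
#' Tests model identifiability: for each generating model, repeatedly draw a
#' cohort of subject parameters from the prior, simulate their lottery
#' choices on the design, fit every candidate model, run [rfx_bms()], and
#' record which model wins. A model space is identifiable when each
#' generating model recovers itself on the diagonal of the resulting
#' confusion matrix.
#'
#' @param models Named list of candidate [choice_model()]s.
#' @param design A lottery design tibble ([build_effort_grid()] or
#'   [build_financial_grid()]).
#' @param n_subjects Simulated subjects per run (default 20).
#' @param n_mc Monte-Carlo repetitions per generating model (default 8).
#' @param prior Parameter sampler `(model, n)`; default
#'   [anchor_param_prior()] for the design's task. See
#'   [uniform_param_prior()] for the box-uniform alternative.
#' @param generating Names of the generating models (default: all of
#'   `models`; restricting this computes selected rows of the matrix).
#' @param n_restarts Restarts per fit (default 20).
#' @param seed Master seed.
#' @return An object of class `confusion_result`: `matrix` (generating x
#'   selected win counts), `runs` (per-run winner tibble), `pxp` (list of
#'   per-run pxp vectors). `tidy()` returns the long count table.
#' @export
confusion_analysis <- function(models, design, n_subjects = 20, n_mc = 8,
                               prior = NULL,
                               generating = names(models),
                               n_restarts = 20, seed = 1) {
  stopifnot(length(models) >= 2, all(generating %in% names(models)))
  if (is.null(prior)) prior <- anchor_param_prior(task = design$task[1])
  runs <- purrr::map_dfr(generating, function(gen) {
    purrr::map_dfr(seq_len(n_mc), function(run) {
      run_seed <- derive_seed(seed, "confusion", gen, run)
      cohort <- withr::with_seed(run_seed, {
        pars <- prior(models[[gen]], n_subjects)
        purrr::map_dfr(seq_len(n_subjects), function(s) {
          simulate_choices(design, models[[gen]], as.list(pars[s, ])) %>%
            mutate(subject_id = sprintf("sim%02d", s), .before = 1)
        })
      })
      fits <- tryCatch(
        fit_cohort(cohort, models, n_restarts = n_restarts,
                   seed = derive_seed(run_seed, "fit")),
        error = function(e) NULL
      )
      if (is.null(fits)) {
        warn(paste0("confusion_analysis: fitting failed for generator '", gen,
                    "', run ", run, "; run excluded."))
        return(tibble(generating = gen, run = run, selected = NA_character_,
                      pxp = list(NULL)))
      }
      bms <- rfx_bms(fits, seed = derive_seed(run_seed, "bms"))
      tibble(generating = gen, run = run,
             selected = select_winner(bms)$model, pxp = list(bms$pxp))
    })
  })
  ok <- !is.na(runs$selected)
  mat <- matrix(0L, nrow = length(generating), ncol = length(models),
                dimnames = list(generating, names(models)))
  if (any(ok)) {
    tab <- table(runs$generating[ok], runs$selected[ok])
    mat[rownames(tab), colnames(tab)] <- tab
  }
  structure(
    list(matrix = mat, runs = runs[c("generating", "run", "selected")],
         pxp = runs$pxp, n_mc = n_mc, n_subjects = n_subjects),
    class = "confusion_result"
  )
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("<confusion_result> ", x$n_mc, " runs x ", x$n_subjects,
      " subjects per generating model\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' @rdname confusion_analysis
#' @param x A `confusion_result`.
#' @param ... Unused.
#' @export
tidy.confusion_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE)) %>%
    rename(generating = "Var1", selected = "Var2", n_wins = "Freq")
}
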