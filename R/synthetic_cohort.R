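# Synthetic cohorts: subjects with known parameters, Bernoulli choices from
# the logistic rule on a lottery design. Stands in for (undeposited) subject
# data in recovery and identifiability studies.

# Across-subject medians and interquartile ranges of the fitted parameters,
# per task and candidate model, used as default anchors for the
# heterogeneity model. A q25 of 0 is kept as reported; the log-normal spread
# then falls back to the median-to-q75 distance.
param_anchor_table <- function() {
  tribble_anchor <- function(task, model, term, median, q25, q75) {
    tibble(task = task, model = model, term = term,
           median = median, q25 = q25, q75 = q75)
  }
  bind_rows(
    # EFF task
    tribble_anchor("EFF", "symmetric_linear", "lambda", 1.17, 0.98, 1.31),
    tribble_anchor("EFF", "symmetric_linear", "alpha", 0.84, 0.67, 1.09),
    tribble_anchor("EFF", "symmetric_linear", "mu", 1.08, 0.37, 2.25),
    tribble_anchor("EFF", "symmetric_quadratic", "lambda", 0.64, 0.48, 0.80),
    tribble_anchor("EFF", "symmetric_quadratic", "alpha", 0.76, 0.52, 1.14),
    tribble_anchor("EFF", "symmetric_quadratic", "mu", 0.11, 0.004, 0.63),
    tribble_anchor("EFF", "no_sensitivity_linear", "lambda", 1.20, 0.95, 1.30),
    tribble_anchor("EFF", "no_sensitivity_linear", "mu", 0.52, 0.33, 0.69),
    tribble_anchor("EFF", "no_sensitivity_quadratic", "lambda", 0.55, 0.43, 0.62),
    tribble_anchor("EFF", "no_sensitivity_quadratic", "mu", 0.012, 0.008, 0.014),
    tribble_anchor("EFF", "no_loss_aversion_linear", "mu", 0.40, 0.25, 0.62),
    tribble_anchor("EFF", "no_loss_aversion_quadratic", "mu", 0.003, 0.002, 0.004),
    tribble_anchor("EFF", "zero_reference", "gamma", 1.24, 1.00, 1.33),
    tribble_anchor("EFF", "zero_reference", "mu", 0.21, 0.10, 0.67),
    tribble_anchor("EFF", "hybrid", "lambda", 0.71, 0.14, 0.99),
    tribble_anchor("EFF", "hybrid", "gamma", 1.61, 1.21, 4.21),
    tribble_anchor("EFF", "hybrid", "mu", 0.064, 0.00, 0.338),
    # EFF2 (repeated session)
    tribble_anchor("EFF2", "symmetric_linear", "lambda", 1.36, 1.14, 2.15),
    tribble_anchor("EFF2", "symmetric_linear", "alpha", 0.97, 0.67, 1.23),
    tribble_anchor("EFF2", "symmetric_linear", "mu", 0.78, 0.24, 2.57),
    tribble_anchor("EFF2", "symmetric_quadratic", "lambda", 0.89, 0.61, 0.97),
    tribble_anchor("EFF2", "symmetric_quadratic", "alpha", 0.65, 0.31, 0.96),
    tribble_anchor("EFF2", "symmetric_quadratic", "mu", 0.22, 0.016, 2.58),
    tribble_anchor("EFF2", "no_sensitivity_linear", "lambda", 1.53, 1.17, 1.77),
    tribble_anchor("EFF2", "no_sensitivity_linear", "mu", 0.49, 0.33, 0.68),
    tribble_anchor("EFF2", "no_sensitivity_quadratic", "lambda", 0.73, 0.52, 0.88),
    tribble_anchor("EFF2", "no_sensitivity_quadratic", "mu", 0.012, 0.008, 0.017),
    tribble_anchor("EFF2", "no_loss_aversion_linear", "mu", 0.30, 0.27, 0.59),
    tribble_anchor("EFF2", "no_loss_aversion_quadratic", "mu", 0.005, 0.003, 0.009),
    tribble_anchor("EFF2", "zero_reference", "gamma", 1.50, 1.12, 1.80),
    tribble_anchor("EFF2", "zero_reference", "mu", 0.06, 0.03, 0.29),
    tribble_anchor("EFF2", "hybrid", "lambda", 0.75, 0.55, 0.90),
    tribble_anchor("EFF2", "hybrid", "gamma", 2.11, 1.20, 2.86),
    tribble_anchor("EFF2", "hybrid", "mu", 0.01, 0.001, 0.65),
    # FIN task
    tribble_anchor("FIN", "fin_symmetric", "lambda", 1.52, 1.13, 2.37),
    tribble_anchor("FIN", "fin_symmetric", "alpha", 0.74, 0.35, 0.87),
    tribble_anchor("FIN", "fin_symmetric", "mu", 1.24, 0.49, 10.85),
    tribble_anchor("FIN", "fin_no_sensitivity", "lambda", 1.87, 1.22, 3.01),
    tribble_anchor("FIN", "fin_no_sensitivity", "mu", 0.18, 0.16, 0.39),
    tribble_anchor("FIN", "fin_no_loss_aversion", "mu", 0.10, 0.05, 0.11),
    tribble_anchor("FIN", "fin_large_money_reference", "gamma", 0.002, 0.00, 0.71),
    tribble_anchor("FIN", "fin_large_money_reference", "mu", 1.54e4, 1.98, 2.55e4),
    tribble_anchor("FIN", "fin_hybrid", "lambda", 0.901, 0.74, 1.10),
    tribble_anchor("FIN", "fin_hybrid", "gamma", 0.001, 0.001, 0.70),
    tribble_anchor("FIN", "fin_hybrid", "mu", 2.02e4, 2.24, 3.5e4)
  )
}

#' Default parameter anchors for a model
#'
#' Across-subject median and interquartile range for each free parameter of
#' a candidate model, representative of the study population the synthetic
#' generator emulates. These anchor the cohort heterogeneity model and the
#' generating values used in recovery checks.
#'
#' @param model A [choice_model()] or model name.
#' @param task `"EFF"`, `"EFF2"` or `"FIN"`.
#' @return A tibble with columns `term`, `median`, `q25`, `q75`.
#' @examples
#' default_param_anchors("hybrid", "EFF")
#' @export
default_param_anchors <- function(model, task = c("EFF", "EFF2", "FIN")) {
  task <- match.arg(task)
  name <- if (inherits(model, "choice_model")) model$name else model
  out <- param_anchor_table() %>%
    filter(.data$task == !!task, .data$model == name) %>%
    select("term", "median", "q25", "q75")
  if (nrow(out) == 0) {
    abort(paste0("No parameter anchors for model '", name, "' in task ", task, "."))
  }
  out
}

#' Draw per-subject generating parameters
#'
#' Draws one parameter set per subject. `distribution = "point"` returns the
#' anchor medians for every subject. `distribution = "lognormal"` draws each
#' parameter from a log-normal with median equal to the anchor median and
#' log-scale spread chosen so the interquartile range matches the anchor IQR
#' (when the reported q25 is 0 or the median is 0, the spread falls back to
#' the median-to-q75 distance, and a zero median falls back to a point
#' mass). Draws outside the model's fitting bounds are rejection-resampled
#' (up to 1000 attempts each).
#'
#' @param model A [choice_model()].
#' @param n_subjects Number of subjects.
#' @param anchors Anchor tibble (`term`, `median`, `q25`, `q75`), by default
#'   [default_param_anchors()] for the model in task `task`.
#' @param distribution `"lognormal"` (default) or `"point"`.
#' @param task Task used to look up default anchors.
#' @param seed Optional seed.
#' @return Tibble with `subject_id` and one column per free parameter.
#' @export
draw_subject_params <- function(model, n_subjects,
                                anchors = NULL,
                                distribution = c("lognormal", "point"),
                                task = "EFF", seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(model, "choice_model"), n_subjects >= 1)
  if (is.null(anchors)) anchors <- default_param_anchors(model, task)
  missing <- setdiff(model$free, anchors$term)
  if (length(missing)) {
    abort(paste0("Anchors missing for parameter(s): ", paste(missing, collapse = ", ")))
  }
  do_draw <- function() {
    cols <- lapply(model$free, function(par) {
      a <- anchors[anchors$term == par, ]
      if (distribution == "point" || a$median == 0) {
        rep(a$median, n_subjects)
      } else {
        sdlog <- lognormal_spread(a$median, a$q25, a$q75)
        b <- model$bounds[[par]]
        draw_bounded_lognormal(n_subjects, meanlog = log(a$median),
                               sdlog = sdlog, lower = b[1], upper = b[2])
      }
    })
    stats::setNames(as_tibble(cols, .name_repair = "minimal"), model$free)
  }
  pars <- if (is.null(seed)) do_draw() else withr::with_seed(seed, do_draw())
  dplyr::bind_cols(tibble(subject_id = sprintf("sim%03d", seq_len(n_subjects))), pars)
}

# sdlog matching the target IQR: for a log-normal, q75/q25 = exp(2 * 0.6745 * s).
lognormal_spread <- function(m, q25, q75) {
  z75 <- stats::qnorm(0.75)
  if (q25 > 0) log(q75 / q25) / (2 * z75) else log(q75 / m) / z75
}

draw_bounded_lognormal <- function(n, meanlog, sdlog, lower, upper,
                                   max_tries = 1000) {
  out <- rlnorm(n, meanlog, sdlog)
  for (i in seq_len(max_tries)) {
    bad <- out < lower | out > upper
    if (!any(bad)) return(out)
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  abort("Could not draw parameters within bounds after 1000 resamples.")
}

#' Simulate lottery choices for one parameter set
#'
#' One Bernoulli draw per design trial with the model's logistic acceptance
#' probability. Optionally annotates each choice's reported strength
#' (strong/weak, by thresholding |dU| at its within-subject median -- purely
#' cosmetic, never used in fitting) and a response time (a decreasing noisy
#' function of |dU|, for schema completeness only; this is not a model of
#' observed response times).
#'
#' @param design Lottery design tibble ([build_effort_grid()] or
#'   [build_financial_grid()]).
#' @param model A [choice_model()].
#' @param params Named list/vector of the model's free parameters.
#' @param seed Optional seed.
#' @param annotate If `TRUE` (default) add `strength` and `rt_ms` columns.
#' @return The design tibble with `response` (1 = accept), and optionally
#'   `strength`, `rt_ms`.
#' @export
simulate_choices <- function(design, model, params, seed = NULL, annotate = TRUE) {
  p_full <- full_params(model, params)
  du <- lottery_utility(design, model, p_full) - sure_bet_utility(model, p_full)
  prob <- plogis(p_full[["mu"]] * du)
  do_sim <- function() {
    out <- design %>% mutate(response = rbinom(n(), 1, prob))
    if (annotate) {
      thr <- median(abs(du))
      out <- out %>% mutate(
        strength = ifelse(abs(du) > thr, "strong", "weak"),
        rt_ms = 900 + 2600 * exp(-abs(du) / (thr + 1e-9)) *
          exp(rnorm(n(), 0, 0.25))
      )
    }
    out
  }
  if (is.null(seed)) do_sim() else withr::with_seed(seed, do_sim())
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws `n_subjects` parameter sets (see [draw_subject_params()]) and
#' simulates each subject's choices on the design, with a per-subject
#' randomised trial order.
#'
#' @inheritParams draw_subject_params
#' @param design Lottery design for one subject; each subject gets an
#'   independently shuffled trial order of the same trials.
#' @param seed Master seed (subject-level seeds are derived from it).
#' @return A list with `choices` (all subjects' trials; `subject_id` first)
#'   and `ground_truth` (one row per subject: the generating parameters).
#' @examples
#' g <- build_effort_grid(seed = 1)
#' coh <- generate_cohort(3, choice_model("hybrid"), g,
#'                        distribution = "point", seed = 7)
#' nrow(coh$choices) # 3 * 363
#' @export
generate_cohort <- function(n_subjects, model, design,
                            anchors = NULL,
                            distribution = c("lognormal", "point"),
                            task = NULL, seed = 1) {
  distribution <- match.arg(distribution)
  task <- task %||% design$task[1]
  pars <- draw_subject_params(model, n_subjects, anchors = anchors,
                              distribution = distribution, task = task,
                              seed = derive_seed(seed, "params"))
  choices <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    sid <- pars$subject_id[s]
    sdesign <- shuffle_trials(design, derive_seed(seed, "order", sid))
    simulate_choices(sdesign, model, as.list(pars[s, model$free]),
                     seed = derive_seed(seed, "choice", sid)) %>%
      mutate(subject_id = sid, .before = 1)
  })
  list(choices = choices, ground_truth = pars)
}
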