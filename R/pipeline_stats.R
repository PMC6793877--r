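# Descriptive and inferential summaries of choice behaviour: rejection
# matrices over the gain x loss grid, Mann-Kendall monotonicity of the
# marginal rejection curves, subjective-value tables per effort condition,
# loss/gain valuation ratios, and parameter comparison reports.

# The gain/loss level columns of a choices tibble (percent for effort
# tasks, dollars for the financial task).
level_cols <- function(choices) {
  if (all(c("gain_pct", "loss_pct") %in% names(choices))) {
    c(gain = "gain_pct", loss = "loss_pct")
  } else if (all(c("usd_gain", "usd_loss") %in% names(choices))) {
    c(gain = "usd_gain", loss = "usd_loss")
  } else {
    abort("`choices` must carry gain_pct/loss_pct or usd_gain/usd_loss.")
  }
}

#' Rejection-frequency matrix over the lottery grid
#'
#' For every (gain level, loss level) cell, the fraction of presentations
#' that were rejected, averaged over repetitions and subjects, with the
#' across-subject dispersion of the per-subject cell rates. Cells absent
#' from the data are returned as `NA`, never imputed.
#'
#' @param choices Choices tibble (one or more subjects; a `subject_id`
#'   column is optional for a single subject).
#' @return A tibble with one row per grid cell: gain level, loss level,
#'   `n_trials`, `n_reject`, `rejection_rate`, `sd_subjects` (NA with a
#'   single subject).
#' @seealso [rejection_marginals()], [plot_rejection_matrix()]
#' @export
rejection_matrix <- function(choices) {
  cols <- level_cols(choices)
  if (!"subject_id" %in% names(choices)) choices$subject_id <- "s1"
  per_subject <- choices %>%
    group_by(.data$subject_id,
             dplyr::across(dplyr::all_of(unname(cols)))) %>%
    summarise(n_trials = n(), n_reject = sum(1 - .data$response),
              rate = .data$n_reject / .data$n_trials, .groups = "drop")
  cells <- per_subject %>%
    group_by(dplyr::across(dplyr::all_of(unname(cols)))) %>%
    summarise(
      n_trials = sum(.data$n_trials), n_reject = sum(.data$n_reject),
      rejection_rate = .data$n_reject / .data$n_trials,
      sd_subjects = if (dplyr::n() > 1) sd(.data$rate) else NA_real_,
      .groups = "drop"
    )
  # complete grid, flagging unobserved cells as NA
  full <- tidyr::expand_grid(
    !!cols[["gain"]] := sort(unique(choices[[cols[["gain"]]]])),
    !!cols[["loss"]] := sort(unique(choices[[cols[["loss"]]]]))
  )
  left_join(full, cells, by = unname(cols)) %>%
    arrange(.data[[cols[["gain"]]]], .data[[cols[["loss"]]]])
}

#' Marginal rejection curves
#'
#' Mean rejection frequency as a function of the gain level (averaged over
#' loss levels) and of the loss level (averaged over gain levels) -- the
#' curves whose monotonicity is tested with [mann_kendall_trend()].
#'
#' @inheritParams rejection_matrix
#' @return A tibble with `margin` (`"gain"`/`"loss"`), `level`, and
#'   `rejection_rate`.
#' @export
rejection_marginals <- function(choices) {
  cells <- rejection_matrix(choices)
  cols <- level_cols(choices)
  marg <- function(which) {
    cells %>%
      group_by(level = .data[[cols[[which]]]]) %>%
      summarise(rejection_rate = mean(.data$rejection_rate, na.rm = TRUE),
                .groups = "drop") %>%
      mutate(margin = which, .before = 1)
  }
  bind_rows(marg("gain"), marg("loss"))
}

#' Mann-Kendall trend test
#'
#' Tests the monotonicity of a sequence: `S = sum_{i<j} sign(x_j - x_i)`,
#' with the tie-corrected normal approximation
#' `var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie-group
#' sizes `t`), continuity correction, and a two-sided p-value. A constant
#' sequence gives S = 0, p = 1.
#'
#' @param x Numeric sequence (ordered by the covariate, e.g. loss level);
#'   length >= 4.
#' @return A one-row tibble: `n`, `s`, `var_s`, `z`, `p_value`.
#' @examples
#' mann_kendall_trend(1:11) # S = 55
#' @export
mann_kendall_trend <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) abort("Mann-Kendall test needs a sequence of length >= 4.")
  if (anyNA(x)) abort("`x` must not contain NA.")
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  }
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- if (var_s == 0) 1 else 2 * pnorm(-abs(z))
  tibble(n = n, s = s, var_s = var_s, z = z, p_value = min(p, 1))
}

#' Subjective value by gain/loss condition
#'
#' Evaluates a fitted model's subjective value at each nonzero condition:
#' for effort models, the ten |db| levels 3.5 ... 35 N·s/m on either side of
#' the 35 N·s/m reference; for money models, the ten |$| levels 10 ... 100.
#'
#' @param model A [choice_model()].
#' @param params Named list/vector of the model's free parameters.
#' @return A tibble with `condition` (|db| or |$|), `domain`
#'   (`"gain"`/`"loss"`), the physical outcome, and `sv`.
#' @export
sv_by_condition <- function(model, params) {
  p <- full_params(model, params)
  if (model$domain == "effort") {
    d <- seq(3.5, 35, by = 3.5)
    out <- bind_rows(
      tibble(condition = d, domain = "gain", outcome = 35 - d),
      tibble(condition = d, domain = "loss", outcome = 35 + d)
    )
  } else {
    d <- seq(10, 100, by = 10)
    out <- bind_rows(
      tibble(condition = d, domain = "gain", outcome = d),
      tibble(condition = d, domain = "loss", outcome = -d)
    )
  }
  x <- encode_outcome(out$outcome, model, gamma = p[["gamma"]])
  out %>% mutate(sv = arm_value(x, model, p))
}

#' Mean loss/gain valuation ratio
#'
#' For each nonzero condition, |SV(loss)| / |SV(gain)| at the matched
#' distance from the reference, averaged over conditions. Equals 1 exactly
#' under symmetric valuation (lambda = 1, gamma = 1); values above 1 mean
#' losses are valued more steeply than equivalent gains.
#'
#' @inheritParams sv_by_condition
#' @return A scalar ratio.
#' @export
loss_gain_ratio <- function(model, params) {
  sv <- sv_by_condition(model, params)
  wide <- sv %>%
    select("condition", "domain", "sv") %>%
    tidyr::pivot_wider(names_from = "domain", values_from = "sv")
  if (any(wide$gain == 0)) abort("Zero gain-side subjective value; ratio undefined.")
  mean(abs(wide$loss) / abs(wide$gain))
}

#' Compare parameter estimates to unity or between tasks
#'
#' One-sample mode (`y = NULL`): Shapiro-Wilk normality check and a Wilcoxon
#' signed-rank test of the estimates against `null_value`. Paired mode:
#' Shapiro-Wilk on the paired differences, paired Wilcoxon signed-rank test,
#' Pearson correlation between the two estimate vectors, and the count of
#' subjects with consistent directionality (both estimates on the same side
#' of `null_value`).
#'
#' @param x Numeric vector of per-subject estimates.
#' @param y Optional second vector, paired with `x` (same subjects).
#' @param null_value Reference value (default 1, symmetric valuation).
#' @return A one-row tibble of test results.
#' @export
compare_parameters <- function(x, y = NULL, null_value = 1) {
  x <- as.numeric(x)
  if (is.null(y)) {
    if (length(x) < 3) abort("Need at least 3 estimates.")
    sw <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    if (all(x == null_value)) {
      return(tibble(
        comparison = paste0("one-sample vs ", null_value), n = length(x),
        median_x = median(x), median_y = NA_real_,
        shapiro_p = sw, wilcoxon_v = 0, wilcoxon_p = 1,
        pearson_r = NA_real_, pearson_p = NA_real_, n_consistent = NA_integer_
      ))
    }
    wt <- suppressWarnings(wilcox.test(x, mu = null_value, exact = FALSE))
    return(tibble(
      comparison = paste0("one-sample vs ", null_value), n = length(x),
      median_x = median(x), median_y = NA_real_,
      shapiro_p = sw, wilcoxon_v = unname(wt$statistic),
      wilcoxon_p = wt$p.value,
      pearson_r = NA_real_, pearson_p = NA_real_,
      n_consistent = NA_integer_
    ))
  }
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must be paired (same length).")
  if (length(x) < 3) abort("Need at least 3 pairs.")
  d <- x - y
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  wt <- if (all(d == 0)) {
    list(statistic = c(V = 0), p.value = 1)
  } else {
    suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
  }
  ct <- if (sd(x) == 0 || sd(y) == 0) {
    list(estimate = NA_real_, p.value = NA_real_)
  } else {
    cor.test(x, y)
  }
  tibble(
    comparison = "paired", n = length(x),
    median_x = median(x), median_y = median(y),
    shapiro_p = sw, wilcoxon_v = unname(wt$statistic), wilcoxon_p = wt$p.value,
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    n_consistent = sum(sign(x - null_value) == sign(y - null_value))
  )
}

#' Two-way repeated-measures ANOVA on subjective valuations
#'
#' Report-stage delegation to `stats::aov`: within-subject effects of domain
#' (gain vs loss), condition (|db| level), and their interaction on
#' per-subject subjective values.
#'
#' @param sv_table Tibble with columns `subject_id`, `domain`, `condition`,
#'   `sv` (e.g. [sv_by_condition()] evaluated per subject's fit).
#' @return A tidy tibble of the ANOVA table (term, df, statistic, p.value).
#' @export
sv_anova <- function(sv_table) {
  need <- c("subject_id", "domain", "condition", "sv")
  if (!all(need %in% names(sv_table))) {
    abort(paste0("`sv_table` needs columns ", paste(need, collapse = ", "), "."))
  }
  dat <- sv_table %>%
    mutate(subject_id = factor(.data$subject_id),
           domain = factor(.data$domain),
           condition = factor(.data$condition),
           sv_mag = abs(.data$sv))
  fit <- aov(sv_mag ~ domain * condition + Error(subject_id / (domain * condition)),
             data = dat)
  purrr::map_dfr(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    tibble(
      term = trimws(rownames(tab)),
      df = tab$Df,
      statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
      p_value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_
    )
  }) %>% filter(.data$term != "Residuals")
}
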