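#' Convert a displayed effort percentage to a damping coefficient
#'
#' The effort task displays outcomes as signed percentages of effort relative
#' to a reference resistance of 35 N·s/m: negative percentages are reductions
#' in effort (gains, down to -100% = no resistance), positive percentages are
#' increases (losses, up to +100% = 70 N·s/m). The mapping is linear,
#' `b = 35 * (1 + pct / 100)`, i.e. 3.5 N·s/m per 10% step.
#'
#' @param percent_shown Signed percentage(s); must be multiples of 10 in
#'   \[-100, 100\].
#' @return Damping coefficient(s) in N·s/m, in \[0, 70\].
#' @examples
#' percent_to_b(c(-100, 0, 50)) # 0, 35, 52.5
#' @seealso [b_to_percent()], [build_effort_grid()]
#' @export
percent_to_b <- function(percent_shown) {
  check_on_percent_grid(percent_shown)
  35 * (1 + percent_shown / 100)
}

#' Convert a damping coefficient back to its displayed percentage
#'
#' Exact inverse of [percent_to_b()] on the 21-level grid
#' (0, 3.5, 7, ..., 70 N·s/m).
#'
#' @param b Damping coefficient(s), N·s/m, on the 3.5 N·s/m grid in \[0, 70\].
#' @return Signed percentage(s), multiples of 10 in \[-100, 100\].
#' @export
b_to_percent <- function(b) {
  pct <- 100 * (b / 35 - 1)
  pct_round <- round(pct / 10) * 10
  bad <- is.na(b) | abs(pct - pct_round) > 1e-9 | pct_round < -100 | pct_round > 100
  if (any(bad)) {
    abort(paste0(
      "`b` must lie on the resistance grid 0, 3.5, 7, ..., 70 N·s/m; ",
      "offending value(s): ", paste(b[bad], collapse = ", ")
    ))
  }
  pct_round
}

check_on_percent_grid <- function(pct, what = "percent_shown") {
  bad <- is.na(pct) | pct %% 10 != 0 | pct < -100 | pct > 100
  if (any(bad)) {
    abort(paste0(
      "`", what, "` must be a multiple of 10 between -100 and 100 ",
      "(the displayed 10% gain/loss grid); offending value(s): ",
      paste(pct[bad], collapse = ", ")
    ))
  }
  invisible(pct)
}

check_on_dollar_grid <- function(usd, what = "usd") {
  bad <- is.na(usd) | usd %% 10 != 0 | usd < -100 | usd > 100
  if (any(bad)) {
    abort(paste0(
      "`", what, "` must be a multiple of $10 between -$100 and $100 ",
      "(the $10-step lottery grid); offending value(s): ",
      paste(usd[bad], collapse = ", ")
    ))
  }
  invisible(usd)
}

#' Build the effort lottery design
#'
#' Constructs the full factorial grid of 50:50 effort gambles: 11 gain levels
#' (0 to 100% less effort, stored as `gain_pct` in \{-100, ..., 0\}) crossed
#' with 11 loss levels (`loss_pct` in \{0, ..., 100\}), each pair repeated
#' `n_repetitions` times, in a per-subject randomised trial order. Every
#' lottery offers a 50% chance of the gain arm and a 50% chance of the loss
#' arm, against the sure option of reaching at the reference resistance
#' (35 N·s/m, the 0% level). The default 3 repetitions give the 363-trial
#' session design.
#'
#' @param n_repetitions Number of times each of the 121 unique lotteries is
#'   presented (default 3).
#' @param seed Optional integer seed controlling the trial-order shuffle; the
#'   set of trials is the same for every seed, only their order changes.
#' @param task Task label, `"EFF"` (default) or `"EFF2"` (the repeated
#'   session uses the identical design).
#' @return A tibble with one row per trial: `trial_index`, `task`,
#'   `gain_pct`, `loss_pct`, `b_gain`, `b_loss`, `repetition`.
#' @examples
#' g <- build_effort_grid(seed = 1)
#' nrow(g) # 363
#' @export
build_effort_grid <- function(n_repetitions = 3, seed = NULL, task = c("EFF", "EFF2")) {
  task <- match.arg(task)
  stopifnot(n_repetitions >= 1)
  cells <- tidyr::expand_grid(
    gain_pct = seq(-100, 0, by = 10),
    loss_pct = seq(0, 100, by = 10)
  )
  grid <- tidyr::expand_grid(repetition = seq_len(n_repetitions), cells) %>%
    mutate(
      task = task,
      b_gain = percent_to_b(.data$gain_pct),
      b_loss = percent_to_b(.data$loss_pct)
    )
  grid <- shuffle_trials(grid, seed)
  grid %>%
    select("trial_index", "task", "gain_pct", "loss_pct",
           "b_gain", "b_loss", "repetition")
}

#' Build the financial lottery design
#'
#' The monetary analogue of [build_effort_grid()]: 11 dollar gains
#' (`usd_gain` in \{0, 10, ..., 100\}) crossed with 11 dollar losses
#' (`usd_loss` in \{-100, ..., 0\}), each repeated `n_repetitions` times in
#' randomised order. The sure option is $0 (keep the endowment unchanged).
#'
#' @inheritParams build_effort_grid
#' @return A tibble with one row per trial: `trial_index`, `task`,
#'   `usd_gain`, `usd_loss`, `repetition`.
#' @export
build_financial_grid <- function(n_repetitions = 3, seed = NULL) {
  stopifnot(n_repetitions >= 1)
  cells <- tidyr::expand_grid(
    usd_gain = seq(0, 100, by = 10),
    usd_loss = seq(-100, 0, by = 10)
  )
  grid <- tidyr::expand_grid(repetition = seq_len(n_repetitions), cells) %>%
    mutate(task = "FIN")
  grid <- shuffle_trials(grid, seed)
  grid %>%
    select("trial_index", "task", "usd_gain", "usd_loss", "repetition")
}

shuffle_trials <- function(grid, seed) {
  perm <- if (is.null(seed)) {
    sample.int(nrow(grid))
  } else {
    withr::with_seed(seed, sample.int(nrow(grid)))
  }
  grid[perm, , drop = FALSE] %>%
    mutate(trial_index = row_number())
}

# Which outcome columns a task's data carries.
outcome_cols <- function(task) {
  if (task %in% c("EFF", "EFF2")) c("b_gain", "b_loss") else c("usd_gain", "usd_loss")
}
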