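# Trial-level choice data interchange: a plain CSV dialect with one row per
# trial. Effort tasks carry gain_pct/loss_pct (and derivable b_gain/b_loss);
# the financial task carries usd_gain/usd_loss. Validation is collective:
# all malformed rows are reported together with their row numbers.

#' Read and validate a choice-record CSV
#'
#' Expected columns: `subject_id`, `task` (EFF/EFF2/FIN), `trial_index`,
#' the task's outcome levels (`gain_pct` in \{-100..0\} and `loss_pct` in
#' \{0..100\}, or `usd_gain` in \{0..100\} and `usd_loss` in \{-100..0\},
#' all multiples of 10), `response` (1 = accept, 0 = reject), and optional
#' `strength` and `rt_ms`. For effort tasks the damping-coefficient columns
#' `b_gain`/`b_loss` are recomputed from the percentages.
#'
#' @param path CSV file path.
#' @return A validated tibble of choice records.
#' @export
read_choices <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_choices(df)
}

#' @rdname read_choices
#' @param choices A choices tibble (as produced by [generate_cohort()] or
#'   [read_choices()]).
#' @export
validate_choices <- function(choices) {
  if (nrow(choices) == 0) abort("Choice file contains no rows.")
  problems <- character()
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(
        msg, " (rows ", paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ")"
      ))
    }
  }
  for (col in c("subject_id", "task", "response")) {
    if (!col %in% names(choices)) {
      problems <- c(problems, paste0("missing required column `", col, "`"))
    }
  }
  if (length(problems)) abort(paste0("Invalid choice data: ",
                                     paste(problems, collapse = "; ")))

  note(which(!choices$task %in% c("EFF", "EFF2", "FIN")),
       "task must be EFF, EFF2 or FIN")
  resp <- suppressWarnings(as.numeric(choices$response))
  note(which(is.na(resp) | !resp %in% c(0, 1)),
       "response must be 0 (reject) or 1 (accept)")
  choices$response <- resp

  is_eff <- choices$task %in% c("EFF", "EFF2")
  if (any(is_eff)) {
    for (col in c("gain_pct", "loss_pct")) {
      if (!col %in% names(choices)) {
        problems <- c(problems, paste0("missing `", col, "` for effort-task rows"))
        next
      }
      v <- choices[[col]]
      rng <- if (col == "gain_pct") c(-100, 0) else c(0, 100)
      bad <- is_eff & (is.na(v) | v %% 10 != 0 | v < rng[1] | v > rng[2])
      note(which(bad), paste0(
        "`", col, "` must be a multiple of 10 in [", rng[1], ", ", rng[2],
        "] (the displayed 10% gain/loss grid)"
      ))
    }
  }
  if (any(!is_eff)) {
    for (col in c("usd_gain", "usd_loss")) {
      if (!col %in% names(choices)) {
        problems <- c(problems, paste0("missing `", col, "` for FIN rows"))
        next
      }
      v <- choices[[col]]
      rng <- if (col == "usd_gain") c(0, 100) else c(-100, 0)
      bad <- !is_eff & (is.na(v) | v %% 10 != 0 | v < rng[1] | v > rng[2])
      note(which(bad), paste0(
        "`", col, "` must be a multiple of $10 in [", rng[1], ", ", rng[2], "]"
      ))
    }
  }
  if (length(problems)) {
    abort(paste0("Invalid choice data: ", paste(problems, collapse = "; ")))
  }
  if (any(is_eff) && all(c("gain_pct", "loss_pct") %in% names(choices))) {
    choices$b_gain <- ifelse(is_eff, 35 * (1 + choices$gain_pct / 100),
                             choices$b_gain %||% NA_real_)
    choices$b_loss <- ifelse(is_eff, 35 * (1 + choices$loss_pct / 100),
                             choices$b_loss %||% NA_real_)
  }
  as_tibble(choices)
}

#' @rdname read_choices
#' @export
write_choices <- function(choices, path) {
  readr::write_csv(choices, path)
  invisible(path)
}

# Serialize a fit table / BMS result for the report bundle.
write_fits <- function(fits, path) {
  readr::write_csv(fits, path)
  invisible(path)
}

write_bms_json <- function(bms, path) {
  jsonlite::write_json(
    list(
      models = bms$models,
      alpha = unname(bms$alpha),
      expected_freq = unname(bms$expected_freq),
      xp = unname(bms$xp),
      pxp = unname(bms$pxp),
      bor = bms$bor,
      winner = select_winner(bms)$model,
      n_subjects = bms$n_subjects
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

write_manifest <- function(path, config) {
  config$r_version <- as.character(getRversion())
  config$package_version <- as.character(utils::packageVersion("effortvalue"))
  config$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
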