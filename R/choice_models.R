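# Candidate prospect-theory choice models.
#
# Every model is built from three pieces:
#   1. an outcome encoding X: the physical resistance b (N·s/m) or a dollar
#      amount is mapped to a signed subjective input, zero at the reference
#      (b = 35 N·s/m or $0) for reference-dependent encodings;
#   2. a value function SV(X) = X^alpha for X > 0, -lambda * (-X)^alpha for
#      X < 0 (SV(0) = 0), with alpha the value sensitivity and lambda the
#      loss-aversion coefficient;
#   3. a logistic choice rule P(accept) = 1 / (1 + exp(-mu * (U_lot - U_sure)))
#      where U_lot = 0.5 SV(X+) + 0.5 SV(X-) is the 50:50 gamble's utility and
#      mu the choice stochasticity (mu = 0 is random choice).

.default_bounds <- list(
  alpha = c(0, 10), lambda = c(0, 10), gamma = c(0, 10), mu = c(0, 20)
)
.param_order <- c("alpha", "lambda", "gamma", "mu")

#' Construct a candidate choice model
#'
#' Builds one member of the model space by name. Effort-task candidates
#' (tasks `EFF`/`EFF2`; outcomes are damping coefficients with reference
#' 35 N·s/m):
#' \describe{
#'   \item{`symmetric_linear` / `symmetric_quadratic`}{free `alpha`, `lambda`,
#'     `mu`; encoding X = -(b - 35) resp. X = -(b^2 - 35^2).}
#'   \item{`no_sensitivity_linear` / `no_sensitivity_quadratic`}{`alpha` fixed
#'     to 1; free `lambda`, `mu`.}
#'   \item{`no_loss_aversion_linear` / `no_loss_aversion_quadratic`}{`alpha` and
#'     `lambda` fixed to 1; free `mu`.}
#'   \item{`zero_reference`}{all effort treated as a loss, X = b^gamma valued
#'     as -X; free `gamma`, `mu`.}
#'   \item{`hybrid`}{reference-dependent loss aversion on a nonlinear absolute
#'     encoding, X = -(b^gamma - 35^gamma) with `alpha` fixed to 1; free
#'     `lambda`, `gamma`, `mu`.}
#' }
#' Financial-task candidates (task `FIN`; outcomes are signed dollars):
#' \describe{
#'   \item{`fin_symmetric`}{free `alpha`, `lambda`, `mu`; X = $.}
#'   \item{`fin_no_sensitivity`}{free `lambda`, `mu`.}
#'   \item{`fin_no_loss_aversion`}{free `mu`.}
#'   \item{`fin_large_money_reference`}{all outcomes framed as gains by
#'     translating dollars by +$100; X = ($ + 100)^gamma valued linearly
#'     against the translated $100 sure bet; free `gamma`, `mu`.}
#'   \item{`fin_hybrid`}{X = sign($) |$|^gamma with `alpha` fixed to 1; free
#'     `lambda`, `gamma`, `mu`.}
#' }
#'
#' Free parameters are bounded: alpha, lambda, gamma in \[0, 10\] and mu in
#' \[0, 20\], except the two power-of-money encodings
#' (`fin_large_money_reference`, `fin_hybrid`) where gamma near 0 compresses
#' X to order 1 and mu is allowed \[0, 1e5\].
#'
#' @param name Model name (see Details).
#' @return An object of class `choice_model`: a list with `name`, `domain`
#'   (`"effort"` or `"money"`), `encoding`, `fixed` (named fixed parameters),
#'   `free` (free parameter names), `bounds`, and `n_params`.
#' @examples
#' choice_model("hybrid")
#' @export
choice_model <- function(name) {
  defs <- model_definitions()
  if (!name %in% names(defs)) {
    abort(paste0(
      "Unknown model '", name, "'. Available: ",
      paste(names(defs), collapse = ", ")
    ))
  }
  def <- defs[[name]]
  free <- intersect(.param_order, def$free)
  bounds <- .default_bounds[free]
  if (!is.null(def$bounds)) bounds <- modifyList(bounds, def$bounds[intersect(names(def$bounds), free)])
  structure(
    list(
      name = name,
      label = def$label,
      domain = def$domain,
      encoding = def$encoding,
      fixed = def$fixed,
      free = free,
      bounds = bounds,
      n_params = length(free)
    ),
    class = "choice_model"
  )
}

model_definitions <- function() {
  list(
    symmetric_linear = list(
      label = "Symmetric sensitivity, X = Δb", domain = "effort",
      encoding = "effort_delta", fixed = c(gamma = 1),
      free = c("alpha", "lambda", "mu")
    ),
    symmetric_quadratic = list(
      label = "Symmetric sensitivity, X = Δ(b²)", domain = "effort",
      encoding = "effort_delta", fixed = c(gamma = 2),
      free = c("alpha", "lambda", "mu")
    ),
    no_sensitivity_linear = list(
      label = "No sensitivity, X = Δb", domain = "effort",
      encoding = "effort_delta", fixed = c(alpha = 1, gamma = 1),
      free = c("lambda", "mu")
    ),
    no_sensitivity_quadratic = list(
      label = "No sensitivity, X = Δ(b²)", domain = "effort",
      encoding = "effort_delta", fixed = c(alpha = 1, gamma = 2),
      free = c("lambda", "mu")
    ),
    no_loss_aversion_linear = list(
      label = "No loss aversion, X = Δb", domain = "effort",
      encoding = "effort_delta", fixed = c(alpha = 1, lambda = 1, gamma = 1),
      free = "mu"
    ),
    no_loss_aversion_quadratic = list(
      label = "No loss aversion, X = Δ(b²)", domain = "effort",
      encoding = "effort_delta", fixed = c(alpha = 1, lambda = 1, gamma = 2),
      free = "mu"
    ),
    zero_reference = list(
      label = "Zero-effort reference, X = b^γ", domain = "effort",
      encoding = "effort_absolute", fixed = c(alpha = 1, lambda = 1),
      free = c("gamma", "mu")
    ),
    hybrid = list(
      label = "Loss aversion + encoding, X = Δ(b^γ)", domain = "effort",
      encoding = "effort_delta", fixed = c(alpha = 1),
      free = c("lambda", "gamma", "mu")
    ),
    fin_symmetric = list(
      label = "Symmetric sensitivity, X = $", domain = "money",
      encoding = "money_signed", fixed = c(gamma = 1),
      free = c("alpha", "lambda", "mu")
    ),
    fin_no_sensitivity = list(
      label = "No sensitivity, X = $", domain = "money",
      encoding = "money_signed", fixed = c(alpha = 1, gamma = 1),
      free = c("lambda", "mu")
    ),
    fin_no_loss_aversion = list(
      label = "No loss aversion, X = $", domain = "money",
      encoding = "money_signed", fixed = c(alpha = 1, lambda = 1, gamma = 1),
      free = "mu"
    ),
    fin_large_money_reference = list(
      label = "Large-money reference, X = ($+100)^γ", domain = "money",
      encoding = "money_translated", fixed = c(alpha = 1, lambda = 1),
      free = c("gamma", "mu"),
      bounds = list(mu = c(0, 1e5))
    ),
    fin_hybrid = list(
      label = "Loss aversion + encoding, X = sign($)|$|^γ", domain = "money",
      encoding = "money_signed", fixed = c(alpha = 1),
      free = c("lambda", "gamma", "mu"),
      bounds = list(mu = c(0, 1e5))
    )
  )
}

#' @export
print.choice_model <- function(x, ...) {
  cat("<choice_model> ", x$name, " (", x$label, ")\n", sep = "")
  cat("  domain:  ", x$domain, "\n", sep = "")
  cat("  free:    ", paste(x$free, collapse = ", "),
      " (", x$n_params, " parameter", if (x$n_params > 1) "s", ")\n", sep = "")
  if (length(x$fixed)) {
    cat("  fixed:   ", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' The candidate model spaces
#'
#' `eff_model_space()` returns the eight effort-task candidates (the three
#' nested value models each under linear and quadratic encodings, the
#' zero-effort-reference model, and the hybrid loss-aversion + encoding
#' model). `fin_model_space()` returns the five financial-task candidates.
#'
#' @return A named list of [choice_model()] objects.
#' @export
eff_model_space <- function() {
  nm <- c("symmetric_linear", "symmetric_quadratic",
          "no_sensitivity_linear", "no_sensitivity_quadratic",
          "no_loss_aversion_linear", "no_loss_aversion_quadratic",
          "zero_reference", "hybrid")
  stats::setNames(lapply(nm, choice_model), nm)
}

#' @rdname eff_model_space
#' @export
fin_model_space <- function() {
  nm <- c("fin_symmetric", "fin_no_sensitivity", "fin_no_loss_aversion",
          "fin_large_money_reference", "fin_hybrid")
  stats::setNames(lapply(nm, choice_model), nm)
}

# Merge free-parameter values with a model's fixed parameters into the full
# (alpha, lambda, gamma, mu) vector used by the value machinery.
full_params <- function(model, params) {
  params <- unlist(params)
  out <- c(alpha = 1, lambda = 1, gamma = 1, mu = NA_real_)
  out[names(model$fixed)] <- model$fixed
  out[names(params)] <- params
  missing <- setdiff(model$free, names(params))
  if (length(missing)) {
    abort(paste0("Missing value(s) for free parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

# Signed power with 0^g := 0 so the b = 0 and $0 arms are defined for all
# exponents.
pow0 <- function(x, g) ifelse(x == 0, 0, x^g)

#' Encode an outcome as a subjective input X
#'
#' Applies a model's outcome encoding. Effort outcomes are damping
#' coefficients `b` (N·s/m); reference-dependent encodings return
#' X = -(b^gamma - 35^gamma), so reduced effort gives X > 0 and increased
#' effort X < 0, and the reference maps to 0. The zero-reference encoding
#' returns X = b^gamma (interpreted in the loss domain). Money encodings act
#' on signed dollars: X = sign($)|$|^gamma, or ($ + 100)^gamma for the
#' translated large-money reference.
#'
#' @param outcome Numeric vector of outcomes (damping coefficients or signed
#'   dollars).
#' @param model A [choice_model()].
#' @param gamma Encoding exponent; required if the model's `gamma` is free,
#'   ignored otherwise.
#' @return Numeric vector X.
#' @export
encode_outcome <- function(outcome, model, gamma = NULL) {
  g <- resolve_gamma(model, gamma)
  switch(model$encoding,
    effort_delta = 35^g - pow0(outcome, g),
    effort_absolute = pow0(outcome, g),
    money_signed = sign(outcome) * pow0(abs(outcome), g),
    money_translated = pow0(outcome + 100, g),
    abort(paste0("Unknown encoding: ", model$encoding))
  )
}

resolve_gamma <- function(model, gamma) {
  if ("gamma" %in% names(model$fixed)) return(model$fixed[["gamma"]])
  if (is.null(gamma)) {
    abort(paste0("Model '", model$name,
                 "' has a free encoding exponent; supply `gamma`."))
  }
  gamma
}

#' Prospect-theory subjective value
#'
#' `SV(X) = X^alpha` for X > 0, `-lambda * (-X)^alpha` for X < 0, and 0 at
#' X = 0 (the continuous extension, so alpha = 0 still gives SV(0) = 0).
#'
#' @param x Encoded outcome(s) X.
#' @param params Named vector/list with `alpha` and `lambda` (both >= 0);
#'   missing entries default to 1.
#' @return Numeric vector of subjective values.
#' @examples
#' subjective_value(c(-10, 0, 10), c(alpha = 1, lambda = 1.52))
#' @export
subjective_value <- function(x, params = c(alpha = 1, lambda = 1)) {
  params <- unlist(params)
  alpha <- if ("alpha" %in% names(params)) params[["alpha"]] else 1
  lambda <- if ("lambda" %in% names(params)) params[["lambda"]] else 1
  if (alpha < 0 || lambda < 0) abort("`alpha` and `lambda` must be >= 0.")
  ifelse(x > 0, x^alpha, ifelse(x < 0, -lambda * (-x)^alpha, 0))
}

# Value applied on the lottery arms. The zero-reference (and any pure
# loss-domain) encoding values every outcome as -X.
arm_value <- function(x, model, params) {
  if (model$encoding == "effort_absolute") return(-x)
  if (model$encoding == "money_translated") return(x)  # linear on encoded gains
  subjective_value(x, params)
}

#' Utility of a 50:50 lottery
#'
#' `U_lot = 0.5 SV(X+) + 0.5 SV(X-)`, the probability-weighted subjective
#' value of the gamble's gain and loss arms. With `alpha = 1` this is the
#' classic mixed-gamble utility `0.5 X+ - 0.5 lambda (-X-)`.
#'
#' @param data A tibble of lotteries with the task's outcome columns
#'   (`b_gain`/`b_loss` for effort, `usd_gain`/`usd_loss` for money).
#' @param model A [choice_model()].
#' @param params Named vector/list giving the model's free parameters (and
#'   optionally overriding none of the fixed ones).
#' @return Numeric vector, one utility per row of `data`.
#' @export
lottery_utility <- function(data, model, params) {
  p <- full_params(model, params)
  cols <- if (model$domain == "effort") c("b_gain", "b_loss") else c("usd_gain", "usd_loss")
  if (!all(cols %in% names(data))) {
    abort(paste0("`data` must carry columns ", paste(cols, collapse = ", "),
                 " for a ", model$domain, "-domain model."))
  }
  xg <- encode_outcome(data[[cols[1]]], model, gamma = p[["gamma"]])
  xl <- encode_outcome(data[[cols[2]]], model, gamma = p[["gamma"]])
  0.5 * arm_value(xg, model, p) + 0.5 * arm_value(xl, model, p)
}

#' Utility of the sure option
#'
#' The utility of rejecting the lottery: reaching at the reference resistance
#' (effort tasks) or keeping $0 (financial task). Zero for all
#' reference-dependent encodings; `-(35^gamma)` for the zero-effort-reference
#' model (the sure bet is itself effortful); `(100)^gamma` for the
#' translated large-money reference (the $0 sure bet translates to $100).
#'
#' @inheritParams lottery_utility
#' @return A scalar utility.
#' @export
sure_bet_utility <- function(model, params) {
  p <- full_params(model, params)
  switch(model$encoding,
    effort_delta = 0,
    money_signed = 0,
    effort_absolute = -(35^p[["gamma"]]),
    money_translated = pow0(100, p[["gamma"]])
  )
}

#' Logistic acceptance probability
#'
#' `P(accept) = 1 / (1 + exp(-mu * (U_lot - U_sure)))`. `mu = 0` gives
#' random choice (P = 0.5 everywhere); large `mu` approaches deterministic
#' utility maximisation. Computed via `plogis()`, numerically stable for
#' arbitrarily large `|mu * dU|`.
#'
#' @param u_lot Lottery utility (vector).
#' @param u_sure Sure-option utility (scalar or vector).
#' @param mu Choice stochasticity, >= 0.
#' @return Acceptance probabilities in \[0, 1\].
#' @export
accept_probability <- function(u_lot, u_sure = 0, mu) {
  if (any(mu < 0)) abort("`mu` must be >= 0.")
  plogis(mu * (u_lot - u_sure))
}

# All per-trial acceptance probabilities for a model + parameter vector.
trial_probabilities <- function(data, model, params) {
  p <- full_params(model, params)
  du <- lottery_utility(data, model, p) - sure_bet_utility(model, p)
  plogis(p[["mu"]] * du)
}

#' Bernoulli negative log-likelihood of observed choices
#'
#' `-sum(r_i log P_i + (1 - r_i) log(1 - P_i))` over trials, where `r_i = 1`
#' is acceptance and `P_i` the model's acceptance probability. Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` before taking logs so the likelihood
#' stays finite under near-deterministic parameters.
#'
#' @param choices Tibble of trials with the task's outcome columns and a
#'   `response` column in \{0, 1\}.
#' @inheritParams lottery_utility
#' @return A non-negative scalar.
#' @examples
#' g <- build_effort_grid(1, seed = 1)
#' g$response <- rep(c(0, 1), length.out = nrow(g))
#' negative_log_likelihood(g, choice_model("no_loss_aversion_linear"), c(mu = 0.4))
#' @export
negative_log_likelihood <- function(choices, model, params) {
  if (nrow(choices) == 0) abort("`choices` is empty.")
  r <- choices$response
  if (is.null(r) || !all(r %in% c(0, 1))) {
    abort("`choices$response` must contain only 0 (reject) and 1 (accept).")
  }
  p <- clamp_prob(trial_probabilities(choices, model, params))
  -sum(r * log(p) + (1 - r) * log1p(-p))
}
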