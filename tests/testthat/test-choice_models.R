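test_that("model spaces have the catalogued sizes and parameter counts", {
  eff <- eff_model_space()
  fin <- fin_model_space()
  expect_length(eff, 8)
  expect_length(fin, 5)
  n_par <- vapply(eff, `[[`, integer(1), "n_params")
  expect_equal(unname(n_par), c(3L, 3L, 2L, 2L, 1L, 1L, 2L, 3L))
  expect_equal(unname(vapply(fin, `[[`, integer(1), "n_params")),
               c(3L, 2L, 1L, 2L, 3L))
  expect_error(choice_model("nope"), "Unknown model")
})

test_that("outcome encodings respect the sign convention and reference", {
  hybrid <- choice_model("hybrid")
  expect_equal(encode_outcome(35, hybrid, gamma = 1.61), 0)
  lin <- choice_model("no_sensitivity_linear")
  expect_equal(encode_outcome(0, lin), 35)
  expect_equal(encode_outcome(70, lin), -35)
  quad <- choice_model("no_sensitivity_quadratic")
  expect_equal(encode_outcome(70, quad), -(70^2 - 35^2)) # -3675
  # zero-effort reference: all outcomes positive, loss-domain interpretation
  zr <- choice_model("zero_reference")
  expect_equal(encode_outcome(c(0, 35, 70), zr, gamma = 1), c(0, 35, 70))
  # money: signed power and translation
  finh <- choice_model("fin_hybrid")
  expect_equal(encode_outcome(c(-100, 0, 100), finh, gamma = 0.5),
               c(-10, 0, 10))
  lmr <- choice_model("fin_large_money_reference")
  expect_equal(encode_outcome(c(-100, 0, 100), lmr, gamma = 1), c(0, 100, 200))
  expect_error(encode_outcome(35, hybrid), "free encoding exponent")
})

test_that("subjective value is a two-part power function, zero at zero", {
  expect_equal(subjective_value(10, c(alpha = 1, lambda = 5)), 10)
  expect_equal(subjective_value(-10, c(alpha = 1, lambda = 1.52)), -15.2)
  expect_equal(subjective_value(-10, c(alpha = 1, lambda = 1)), -10)
  expect_equal(subjective_value(0, c(alpha = 0, lambda = 2)), 0)
  x <- seq(-20, 20, by = 2.5)
  expect_equal(subjective_value(x, c(alpha = 1, lambda = 1)), x)
  expect_error(subjective_value(1, c(alpha = -1, lambda = 1)), ">= 0")
})

test_that("lottery utility is the half-half subjective value of both arms", {
  lin <- choice_model("no_sensitivity_linear")
  sym <- tibble::tibble(b_gain = 25, b_loss = 45) # X+ = 10, X- = -10
  expect_equal(lottery_utility(sym, lin, c(lambda = 1, mu = 1)), 0)
  expect_equal(lottery_utility(sym, lin, c(lambda = 2, mu = 1)), -5)
  ref <- tibble::tibble(b_gain = 35, b_loss = 35)
  hybrid <- choice_model("hybrid")
  expect_equal(lottery_utility(ref, hybrid, c(lambda = 3, gamma = 2.4, mu = 1)), 0)
  # alpha = lambda = 1, linear: utility equals the expected value in db units
  nolav <- choice_model("no_loss_aversion_linear")
  g <- eff_grid_1rep()
  ev <- 0.5 * (35 - g$b_gain) + 0.5 * (35 - g$b_loss)
  expect_equal(lottery_utility(g, nolav, c(mu = 1)), ev)
})

test_that("sure-bet utility is zero unless the reference is shifted", {
  expect_equal(sure_bet_utility(choice_model("hybrid"),
                                c(lambda = 1, gamma = 1.61, mu = 1)), 0)
  expect_equal(sure_bet_utility(choice_model("fin_symmetric"),
                                c(alpha = 1, lambda = 1, mu = 1)), 0)
  expect_equal(sure_bet_utility(choice_model("zero_reference"),
                                c(gamma = 1, mu = 1)), -35)
  expect_equal(sure_bet_utility(choice_model("zero_reference"),
                                c(gamma = 2, mu = 1)), -1225)
  expect_equal(sure_bet_utility(choice_model("fin_large_money_reference"),
                                c(gamma = 1, mu = 1)), 100)
})

test_that("logistic choice rule: random at mu = 0, deterministic in the limit", {
  expect_equal(accept_probability(c(-50, 0, 50), 0, mu = 0), rep(0.5, 3))
  expect_equal(accept_probability(7, 7, mu = 3), 0.5)
  expect_equal(accept_probability(1, 0, mu = 1e6), 1)
  expect_equal(accept_probability(-1, 0, mu = 1e6), 0)
  # stable far beyond |mu * dU| = 700
  expect_equal(accept_probability(-1000, 0, mu = 10), 0)
  expect_true(is.finite(accept_probability(1000, 0, mu = 10)))
  du <- seq(-30, 30, by = 5)
  p <- accept_probability(du, 0, mu = 0.3)
  expect_true(all(diff(p) > 0))
  expect_error(accept_probability(1, 0, mu = -1), ">= 0")
})

test_that("negative log-likelihood matches the explicit Bernoulli product", {
  lin <- choice_model("no_sensitivity_linear")
  g <- eff_grid_1rep()[1:10, ]
  g$response <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1)
  params <- c(lambda = 1.3, mu = 0.4)
  # brute-force oracle: per-trial product of Bernoulli terms
  p <- accept_probability(lottery_utility(g, lin, params), 0, params[["mu"]])
  lik <- 1
  for (i in 1:10) lik <- lik * p[i]^g$response[i] * (1 - p[i])^(1 - g$response[i])
  expect_equal(negative_log_likelihood(g, lin, params), -log(lik))
})

test_that("likelihood limiting cases and additivity hold", {
  lin <- choice_model("no_sensitivity_linear")
  g <- eff_grid_1rep()
  g$response <- rep(c(0, 1), length.out = nrow(g))
  expect_equal(negative_log_likelihood(g, lin, c(lambda = 1.5, mu = 0)),
               nrow(g) * log(2))
  # single accepted trial at P = 0.9
  one <- tibble::tibble(b_gain = 35, b_loss = 35, response = 1)
  mu <- 1
  one$b_gain <- 35 - qlogis(0.9) / 0.5 # X+ = logit(0.9)/0.5, X- = 0
  nolav <- choice_model("no_loss_aversion_linear")
  expect_equal(negative_log_likelihood(one, nolav, c(mu = 1)), -log(0.9))
  # duplicating every trial doubles the value
  expect_equal(
    negative_log_likelihood(dplyr::bind_rows(g, g), lin, c(lambda = 1.5, mu = 0.3)),
    2 * negative_log_likelihood(g, lin, c(lambda = 1.5, mu = 0.3))
  )
  expect_error(negative_log_likelihood(g[0, ], lin, c(lambda = 1, mu = 1)), "empty")
  g$response[1] <- 2
  expect_error(negative_log_likelihood(g, lin, c(lambda = 1, mu = 1)), "0.*1")
  # finite under near-deterministic parameters
  g$response[1] <- 1
  expect_true(is.finite(negative_log_likelihood(g, lin, c(lambda = 10, mu = 20))))
})

test_that("acceptance is monotone in each arm for delta-encoded models", {
  set.seed(42)
  for (name in c("symmetric_linear", "symmetric_quadratic", "hybrid")) {
    m <- choice_model(name)
    for (rep in 1:5) {
      params <- c(alpha = runif(1, 0.3, 2), lambda = runif(1, 0.2, 3),
                  gamma = runif(1, 0.5, 2.5), mu = runif(1, 0.01, 1))
      losses <- tibble::tibble(b_gain = 21, b_loss = seq(35, 70, by = 3.5))
      p_loss <- accept_probability(lottery_utility(losses, m, params), 0,
                                   params[["mu"]])
      expect_true(all(diff(p_loss) <= 1e-12))
      gains <- tibble::tibble(b_gain = seq(35, 0, by = -3.5), b_loss = 49)
      p_gain <- accept_probability(lottery_utility(gains, m, params), 0,
                                   params[["mu"]])
      expect_true(all(diff(p_gain) >= -1e-12))
    }
  }
})

test_that("hybrid with gamma = 1 is observationally a linear no-sensitivity model", {
  g <- eff_grid_1rep()
  for (lambda in c(0.5, 1, 2.3)) {
    u_h <- lottery_utility(g, choice_model("hybrid"),
                           c(lambda = lambda, gamma = 1, mu = 0.5))
    u_l <- lottery_utility(g, choice_model("no_sensitivity_linear"),
                           c(lambda = lambda, mu = 0.5))
    expect_equal(u_h, u_l)
  }
})
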