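test_that("point-mass parameter draws return the anchor medians exactly", {
  m <- choice_model("hybrid")
  pars <- draw_subject_params(m, 4, distribution = "point", task = "EFF", seed = 1)
  expect_equal(nrow(pars), 4)
  expect_true(all(pars$lambda == 0.71))
  expect_true(all(pars$gamma == 1.61))
  expect_true(all(pars$mu == 0.064))
})

test_that("log-normal draws match the target median and respect bounds", {
  m <- choice_model("no_sensitivity_linear")
  anchors <- tibble::tibble(term = c("lambda", "mu"),
                            median = c(1.2, 0.5), q25 = c(0.9, 0.3),
                            q75 = c(1.6, 0.8))
  pars <- draw_subject_params(m, 1e4, anchors = anchors,
                              distribution = "lognormal", seed = 2)
  expect_lt(abs(median(pars$lambda) - 1.2) / 1.2, 0.05)
  expect_lt(abs(median(pars$mu) - 0.5) / 0.5, 0.05)
  # IQR-matched spread
  expect_lt(abs(diff(quantile(pars$lambda, c(0.25, 0.75))) - 0.7), 0.07)
  expect_true(all(pars$lambda >= 0 & pars$lambda <= 10))
  expect_true(all(pars$mu >= 0 & pars$mu <= 20))
  # determinism
  pars2 <- draw_subject_params(m, 1e4, anchors = anchors,
                               distribution = "lognormal", seed = 2)
  expect_identical(pars, pars2)
})

test_that("simulated choices follow the generative acceptance probabilities", {
  g <- build_effort_grid(1, seed = 3)
  m <- choice_model("no_loss_aversion_linear")
  # mu = 0: random choice
  ch0 <- simulate_choices(g, m, c(mu = 0), seed = 4)
  p_hat <- mean(ch0$response)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(g)))
  # deterministic limit: accept exactly the positive-dU lotteries
  chd <- simulate_choices(g, m, c(mu = 1e6), seed = 5)
  du <- lottery_utility(g, m, c(mu = 1)) # mu only scales dU
  off <- du != 0
  expect_equal(chd$response[off], as.integer(du[off] > 0))
})

test_that("empirical acceptance converges to the model probability per lottery", {
  m <- choice_model("hybrid")
  params <- c(lambda = 0.71, gamma = 1.61, mu = 0.064)
  design <- build_effort_grid(1, seed = 6)
  big <- dplyr::bind_rows(replicate(1000, design, simplify = FALSE))
  ch <- simulate_choices(big, m, params, seed = 7, annotate = FALSE)
  p_true <- accept_probability(lottery_utility(design, m, params), 0,
                               params[["mu"]])
  emp <- ch |>
    dplyr::group_by(gain_pct, loss_pct) |>
    dplyr::summarise(rate = mean(response), .groups = "drop") |>
    dplyr::arrange(gain_pct, loss_pct)
  key <- order(design$gain_pct, design$loss_pct)
  se <- sqrt(p_true[key] * (1 - p_true[key]) / 1000)
  expect_true(all(abs(emp$rate - p_true[key]) <= pmax(3 * se, 5e-3)))
})

test_that("generated rejection frequencies are monotone in the expected directions", {
  g <- build_effort_grid(3, seed = 8)
  coh <- generate_cohort(10, choice_model("hybrid"), g,
                         distribution = "point", seed = 9)
  marg <- rejection_marginals(coh$choices)
  loss <- dplyr::filter(marg, margin == "loss") |> dplyr::arrange(level)
  gain <- dplyr::filter(marg, margin == "gain") |> dplyr::arrange(level)
  expect_lt(mann_kendall_trend(loss$rejection_rate)$s * -1, 0) # increasing
  expect_gt(mann_kendall_trend(gain$rejection_rate)$s, 0) # rejection falls as gain grows
})

test_that("cohorts have the right shape, schema and ground truth", {
  g <- build_effort_grid(3, seed = 10)
  coh <- generate_cohort(20, choice_model("hybrid"), g,
                         distribution = "point", seed = 11)
  expect_equal(nrow(coh$choices), 20 * 363)
  expect_equal(nrow(coh$ground_truth), 20)
  expect_true(all(c("subject_id", "gain_pct", "loss_pct", "response",
                    "strength", "rt_ms") %in% names(coh$choices)))
  gf <- build_financial_grid(1, seed = 12)
  cohf <- generate_cohort(2, choice_model("fin_symmetric"), gf,
                          distribution = "point", task = "FIN", seed = 13)
  expect_true(all(c("usd_gain", "usd_loss") %in% names(cohf$choices)))
  expect_false("gain_pct" %in% names(cohf$choices))
  # same seed, same cohort
  coh2 <- generate_cohort(20, choice_model("hybrid"), g,
                          distribution = "point", seed = 11)
  expect_identical(coh$choices, coh2$choices)
})
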