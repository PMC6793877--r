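test_that("AIC-based log evidence is -AIC/2", {
  expect_equal(log_evidence_from_aic(0), 0)
  expect_equal(log_evidence_from_aic(c(10, -4)), c(-5, 2))
  # equal fits, 3 vs 1 parameters: evidence difference is -2
  aic3 <- 2 * 3 + 2 * 50
  aic1 <- 2 * 1 + 2 * 50
  expect_equal(log_evidence_from_aic(aic3) - log_evidence_from_aic(aic1), -2)
  fits <- tibble::tibble(subject_id = "s1", model = "m", aic = 4)
  expect_equal(log_evidence_from_aic(fits)$log_evidence, -2)
})

test_that("equal evidences give uniform frequencies and high omnibus risk", {
  L <- matrix(-100, nrow = 20, ncol = 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  bms <- rfx_bms(L, seed = 1)
  expect_equal(unname(bms$expected_freq), rep(1 / 6, 6))
  expect_equal(unname(bms$xp), rep(1 / 6, 6), tolerance = 0.02)
  # pxp inherits only Monte-Carlo noise from the xp sampler here
  expect_equal(unname(bms$pxp), rep(1 / 6, 6), tolerance = 1e-3)
  expect_gt(bms$bor, 0.9)
})

test_that("a dominant model takes pxp ~ 1 and drives omnibus risk to 0", {
  L <- matrix(0, nrow = 12, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  L[, 2] <- 10 # better by 10 log-units in every subject
  bms <- rfx_bms(L, seed = 2)
  expect_gt(bms$pxp[["b"]], 0.99)
  expect_lt(bms$bor, 1e-3)
  w <- select_winner(bms)
  expect_equal(w$model, "b")
  expect_equal(w$index, 2L)
  expect_false(w$tie)
})

test_that("the pxp blending identity holds exactly", {
  set.seed(3)
  L <- matrix(rnorm(15 * 4, sd = 2), nrow = 15,
              dimnames = list(NULL, paste0("m", 1:4)))
  bms <- rfx_bms(L, seed = 4)
  K <- 4
  expect_equal(unname(bms$pxp),
               unname((1 - bms$bor) * bms$xp + bms$bor / K))
  expect_equal(sum(bms$expected_freq), 1)
  expect_equal(sum(bms$xp), 1, tolerance = 1e-12)
  expect_equal(sum(bms$pxp), 1, tolerance = 1e-12)
  expect_true(all(bms$alpha >= 1))
})

test_that("permuting the model order permutes the deterministic outputs", {
  set.seed(5)
  L <- matrix(rnorm(10 * 3, sd = 3), nrow = 10,
              dimnames = list(NULL, c("a", "b", "c")))
  perm <- c(3, 1, 2)
  bms1 <- rfx_bms(L, seed = 6)
  bms2 <- rfx_bms(L[, perm], seed = 6)
  expect_equal(unname(bms2$alpha), unname(bms1$alpha[perm]))
  expect_equal(unname(bms2$expected_freq), unname(bms1$expected_freq[perm]))
  expect_equal(bms2$bor, bms1$bor)
  expect_equal(unname(bms2$xp), unname(bms1$xp[perm]), tolerance = 0.01)
})

test_that("per-subject constants in the evidence do not change the result", {
  set.seed(7)
  L <- matrix(rnorm(8 * 3), nrow = 8, dimnames = list(NULL, c("a", "b", "c")))
  shifted <- L + matrix(rnorm(8, sd = 50), nrow = 8, ncol = 3)
  bms1 <- rfx_bms(L, seed = 8)
  bms2 <- rfx_bms(shifted, seed = 8)
  expect_equal(bms1$alpha, bms2$alpha)
  expect_equal(bms1$xp, bms2$xp)
  expect_equal(bms1$bor, bms2$bor, tolerance = 1e-8)
})

test_that("single-subject two-model exceedance matches the Beta tail", {
  L <- matrix(c(1.3, 0), nrow = 1, dimnames = list(NULL, c("a", "b")))
  n_samples <- 1e5
  bms <- rfx_bms(L, n_samples = n_samples, seed = 9)
  a <- unname(bms$alpha)
  xp_exact <- 1 - pbeta(0.5, a[1], a[2])
  se <- sqrt(xp_exact * (1 - xp_exact) / n_samples)
  expect_lt(abs(bms$xp[["a"]] - xp_exact), 3 * se)
})

test_that("exact pxp ties break to the lowest index with a flag", {
  bms <- structure(
    list(pxp = c(m1 = 0.4, m2 = 0.4, m3 = 0.2), models = c("m1", "m2", "m3"),
         bor = 0.1),
    class = "bms_result"
  )
  expect_warning(w <- select_winner(bms), "tie")
  expect_equal(w$model, "m1")
  expect_true(w$tie)
})

test_that("a clearly separable two-model space is identified on the diagonal", {
  models <- eff_model_space()[c("no_sensitivity_linear", "no_sensitivity_quadratic")]
  design <- build_effort_grid(3, seed = 10)
  # point priors at each model's typical fitted values keep the runs cheap
  prior <- function(model, n) {
    anchors <- default_param_anchors(model, "EFF")
    tibble::as_tibble(stats::setNames(
      lapply(model$free, function(p) rep(anchors$median[anchors$term == p], n)),
      model$free
    ))
  }
  conf <- confusion_analysis(models, design, n_subjects = 6, n_mc = 2,
                             prior = prior, n_restarts = 6, seed = 11)
  expect_equal(unname(rowSums(conf$matrix)), c(2L, 2L))
  expect_equal(unname(diag(conf$matrix)), c(2L, 2L))
  td <- tidy(conf)
  expect_equal(sum(td$n_wins), 4L)
})
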