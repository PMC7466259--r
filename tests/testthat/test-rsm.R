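test_that("a noise-free quadratic surface is recovered exactly", {
  des <- build_bbd(paper_factors(), n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
  set.seed(5)
  beta <- stats::rnorm(10)
  y <- oracle_predict(beta, coded)
  m <- fit_full_quadratic(des, y)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-9)
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 0, tolerance = 1e-12)
  # predictions are exact on the training points
  expect_equal(predict(m, coded), y, tolerance = 1e-9)
  # reduced model keeps everything when all terms are active (p ~ 0)
  expect_equal(coef(reduce_model(m, alpha = 0.05)), coef(m))
})

test_that("coefficients agree with an independent normal-equations solve", {
  des <- build_bbd(paper_factors(), n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
  set.seed(17)
  for (i in 1:25) {
    y <- random_quadratic_response(coded, sd = stats::runif(1, 0.05, 1))
    m <- fit_full_quadratic(des, y)
    X <- oracle_X(coded)
    beta_ne <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(m$coefficients), unname(drop(beta_ne)), tolerance = 1e-9)
  }
})

test_that("the intercept equals the center-replicate mean on any BBD data", {
  # the center-run indicator 1 - (x1^2 + x2^2 + x3^2)/2 lies in the model
  # span, so the fitted value at the center equals the center mean
  set.seed(23)
  for (i in 1:100) {
    nc <- sample(2:5, 1)
    des <- build_bbd(paper_factors(), n_center = nc,
                     seed = sample.int(1e6, 1))
    coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
    y <- random_quadratic_response(coded, sd = stats::runif(1, 0, 2))
    m <- fit_full_quadratic(des, y)
    expect_equal(unname(m$coefficients["constant"]),
                 mean(y[des$points$is_center]), tolerance = 1e-9)
  }
})

test_that("fit metrics behave: adjusted R2 below R2, reduction never raises refit R2, permutation invariance", {
  des <- build_bbd(paper_factors(), n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
  set.seed(31)
  y <- random_quadratic_response(coded, sd = 0.5)
  m <- fit_full_quadratic(des, y)
  expect_lte(m$r2_adj, m$r2)
  expect_gte(m$r2, 0); expect_lte(m$r2, 1)
  expect_true(all(m$p_values >= 0 & m$p_values <= 1))
  red <- reduce_model(m, alpha = 0.2)
  expect_lte(red$r2, m$r2 + 1e-12)

  perm <- sample(nrow(coded))
  m_perm <- fit_full_quadratic(coded[perm, ], y[perm])
  expect_equal(m_perm$coefficients, m$coefficients, tolerance = 1e-9)
  expect_equal(m_perm$r2, m$r2, tolerance = 1e-12)
})

test_that("a single active factor is the only one flagged significant", {
  des <- build_bbd(paper_factors(), n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
  set.seed(41)
  y <- 2 * coded[, 3] + stats::rnorm(nrow(coded), 0, 0.01)
  m <- fit_full_quadratic(des, y)
  expect_lt(m$p_values["x3"], 0.05)
  expect_true(all(m$p_values[setdiff(names(m$p_values), c("constant", "x3"))] > 0.05))
})

test_that("published responses reproduce the printed coefficient summaries", {
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  fit <- infer_run_assignment(t2, t3$coefficients, factors = paper_factors())
  models <- fit_all_responses(fit$design, t2)

  constants <- vapply(models, function(m) m$coefficients[["constant"]], numeric(1))
  expect_equal(round(constants[c("Rs1-2", "Rs2-3", "Rs4-5", "Rs5-6", "Rs7-8")], 3),
               c(`Rs1-2` = 3.092, `Rs2-3` = 1.297, `Rs4-5` = 2.594,
                 `Rs5-6` = 0.000, `Rs7-8` = 0.877))
  # the Rs4-5 constant is the plain mean of the three center replicates
  expect_equal(constants[["Rs4-5"]], mean(c(2.6014, 2.6402, 2.5400)), tolerance = 1e-9)
  # prediction at the center point returns the intercept
  expect_equal(predict(models[["Rs4-5"]], c(0, 0, 0)), constants[["Rs4-5"]])

  # pH terms drive the BEN-SOR separation, as the printed ANOVA flags
  m23 <- models[["Rs2-3"]]
  expect_lt(m23$p_values["x3"], 0.05)
  expect_lt(m23$p_values["x3x3"], 0.05)

  # the sole significant term for Rs1-2 is the quadratic pH term
  m12 <- models[["Rs1-2"]]
  sig <- names(m12$p_values)[m12$p_values < 0.05]
  expect_equal(setdiff(sig, "constant"), "x3x3")
  red <- reduce_model(m12, alpha = 0.05)
  expect_setequal(names(coef(red)), c("constant", "x3x3"))

  # alpha = 1 keeps the full model
  expect_equal(coef(reduce_model(m12, alpha = 1)), coef(m12))
})

test_that("degenerate and invalid fits are handled explicitly", {
  des <- build_bbd(paper_factors(), n_center = 3)
  expect_error(fit_full_quadratic(des, rep(1, 10)), "length")
  # collapsing the design to a single point is rank-deficient
  flat <- matrix(0, 15, 3)
  expect_error(fit_full_quadratic(flat, rnorm(15)), "singular")
})
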