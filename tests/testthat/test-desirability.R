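test_that("individual desirability anchors, ramps and directions", {
  g <- desirability_goal("y", "maximize", low = 1, high = 3)
  expect_equal(d_individual(c(1, 3, 2, 0, 5), g), c(0, 1, 0.5, 0, 1))
  gm <- desirability_goal("y", "minimize", low = 1, high = 3)
  expect_equal(d_individual(c(1, 3, 2), gm), c(1, 0, 0.5))
  gt <- desirability_goal("y", "target", low = 0, high = 4, target = 1)
  expect_equal(d_individual(c(0, 1, 2.5, 4), gt), c(0, 1, 0.5, 0))
  gs <- desirability_goal("y", "maximize", low = 0, high = 1, shape = 2)
  expect_equal(d_individual(0.5, gs), 0.25)
  expect_error(desirability_goal("y", "maximize", 3, 1), "less than")
  expect_error(desirability_goal("y", "maximize", 0, 1, impact = 7), "impact")
})

test_that("composite desirability is the impact-weighted geometric mean", {
  expect_equal(composite_desirability(c(0.25, 1), c(1, 3)), 0.25^(1 / 4))
  expect_equal(composite_desirability(rep(1, 5), rep(3, 5)), 1)
  expect_equal(composite_desirability(c(0.9, 0, 0.8), c(3, 3, 1)), 0)
  expect_error(composite_desirability(numeric(0), integer(0)), "no desirabilities")
  expect_error(composite_desirability(c(0.5, 1.2), c(1, 1)), "0, 1")
})

test_that("composite properties: bounds, equal-value identity, monotonicity", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    d <- stats::runif(k)
    imp <- sample(1:5, k, replace = TRUE)
    D <- composite_desirability(d, imp)
    expect_gte(D, 0); expect_lte(D, 1)
    # equal d values compose to that value whatever the impacts
    expect_equal(composite_desirability(rep(d[1], k), imp), d[1])
    # raising one component never lowers the composite
    j <- sample(k, 1)
    d2 <- d; d2[j] <- min(1, d2[j] + stats::runif(1, 0, 1 - d2[j]))
    expect_gte(composite_desirability(d2, imp), D - 1e-12)
  }
})

test_that("the optimizer finds the vertex of a concave single-response surface", {
  des <- build_bbd(paper_factors(), n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])
  vertex <- c(0.3, -0.4, 0.6)
  y <- -((coded[, 1] - vertex[1])^2 + (coded[, 2] - vertex[2])^2 +
           (coded[, 3] - vertex[3])^2)
  m <- fit_full_quadratic(des, y, response_name = "y")
  g <- list(y = desirability_goal("y", "maximize", low = -3, high = 0))
  opt <- optimize_desirability(list(y = m), g, grid_n = 41)
  expect_equal(unname(opt$coded_optimum), vertex, tolerance = 1e-4)
  # doubling the lattice moves the polished optimum by less than one coarse cell
  opt2 <- optimize_desirability(list(y = m), g, grid_n = 81)
  expect_lt(max(abs(opt2$coded_optimum - opt$coded_optimum)), 2 / 40)
})

test_that("ties on a constant surface resolve to the lexicographically smallest point", {
  des <- build_bbd(paper_factors(), n_center = 3)
  y <- rep(2, 15)
  m <- suppressWarnings(fit_full_quadratic(des, y, response_name = "y"))
  g <- list(y = desirability_goal("y", "maximize", low = 0, high = 4))
  opt <- optimize_desirability(list(y = m), g, grid_n = 11, polish = FALSE)
  expect_equal(unname(opt$coded_optimum), c(-1, -1, -1))
  expect_equal(opt$composite_D, 0.5)
})

test_that("an everywhere-undesirable surface is flagged", {
  des <- build_bbd(paper_factors(), n_center = 3)
  m <- suppressWarnings(fit_full_quadratic(des, rep(10, 15), response_name = "y"))
  g <- list(y = desirability_goal("y", "minimize", low = 0, high = 1))
  opt <- optimize_desirability(list(y = m), g, grid_n = 11)
  expect_true(opt$all_zero)
  expect_equal(opt$composite_D, 0)
})

test_that("default goals encode the separation objective", {
  t2 <- load_fixture("table2")
  goals <- default_goals(t2)
  expect_setequal(names(goals), c(paste0("Rs", 1:7, "-", 2:8), "time"))
  expect_equal(goals[["time"]]$direction, "minimize")
  expect_equal(goals[["time"]]$impact, 1L)
  expect_equal(goals[["time"]]$low, 14.7)
  expect_equal(goals[["time"]]$high, 25.4)
  rs <- goals[["Rs1-2"]]
  expect_equal(rs$direction, "maximize")
  expect_equal(rs$impact, 3L)
  expect_equal(c(rs$low, rs$high), c(0, 1.5))
  obs <- default_goals(t2, rs_anchors = "observed")[["Rs1-2"]]
  expect_equal(c(obs$low, obs$high), c(0, 3.438))
})
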