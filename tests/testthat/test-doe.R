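test_that("a 3-factor BBD has the canonical edge set plus center replicates", {
  fac <- paper_factors()
  des <- build_bbd(fac, n_center = 3)
  pts <- des$points
  expect_equal(nrow(pts), 15L)
  expect_equal(sum(pts$is_center), 3L)

  edges <- as.matrix(pts[!pts$is_center, c("x1", "x2", "x3")])
  expect_equal(nrow(unique(edges)), 12L)
  # each edge point has exactly two coordinates at +/-1 and one at 0
  expect_true(all(rowSums(edges != 0) == 2))
  expect_true(all(edges %in% c(-1, 0, 1)))

  des0 <- build_bbd(fac, n_center = 0)
  expect_equal(nrow(des0$points), 12L)
  expect_false(any(des0$points$is_center))

  expect_error(build_bbd(fac[1:2]), "3 factors")
})

test_that("coded columns are balanced and pairwise orthogonal", {
  for (nc in c(0, 3, 5)) {
    m <- as.matrix(build_bbd(paper_factors(), n_center = nc)$points[, c("x1", "x2", "x3")])
    expect_equal(colSums(m), c(x1 = 0, x2 = 0, x3 = 0))
    expect_equal(colSums(m != 0), c(x1 = 8, x2 = 8, x3 = 8))
    expect_equal(unname(crossprod(m)[lower.tri(diag(3))]), rep(0, 3))
  }
})

test_that("run-order randomization is deterministic in the seed and leaves the point set intact", {
  fac <- paper_factors()
  a <- build_bbd(fac, n_center = 3, seed = 42)
  b <- build_bbd(fac, n_center = 3, seed = 42)
  c <- build_bbd(fac, n_center = 3, seed = 7)
  expect_identical(a$points, b$points)
  expect_false(identical(a$points, c$points))
  key <- function(d) sort(do.call(paste, as.data.frame(d$points[, c("x1", "x2", "x3")])))
  expect_identical(key(a), key(c))
})

test_that("uncode maps coded levels to factor units and code inverts it", {
  fac <- paper_factors()
  expect_equal(uncode(c(0.69, 0, 0), fac)[1], 8.45)  # printed as 8.5%
  expect_equal(uncode(c(0, 0, 0.88), fac)[3], 6.76)  # printed as pH 6.7
  expect_equal(uncode(c(0, 0, 0), fac), c(5, 80, 5))

  set.seed(11)
  pts <- matrix(stats::runif(60, -1, 1), ncol = 3)
  expect_equal(code(uncode(pts, fac), fac), pts, tolerance = 1e-12)
})

test_that("run assignment is recovered from responses generated at a known permutation", {
  fac <- paper_factors()
  des <- build_bbd(fac, n_center = 3)
  coded <- as.matrix(des$points[, c("x1", "x2", "x3")])

  set.seed(101)
  betas <- replicate(4, stats::rnorm(10), simplify = FALSE)
  coef_tab <- data.frame(term = c("constant", "x1", "x2", "x3", "x1x1", "x1x2",
                                  "x1x3", "x2x2", "x2x3", "x3x3"))
  for (j in seq_along(betas)) coef_tab[[paste0("y", j)]] <- betas[[j]]

  perm <- c(sample(which(!des$points$is_center)), which(des$points$is_center))
  resp <- data.frame(run = seq_len(15))
  for (j in seq_along(betas)) {
    resp[[paste0("y", j)]] <- oracle_predict(betas[[j]], coded[perm, ])
  }
  out <- infer_run_assignment(resp, coef_tab, center_runs = 13:15)
  expect_equal(as.matrix(out$design$points[, c("x1", "x2", "x3")]),
               coded[perm, ], ignore_attr = TRUE)
  expect_lt(out$cost, 1e-16)

  # identity case: responses already in canonical order
  resp_id <- data.frame(run = seq_len(15))
  for (j in seq_along(betas)) resp_id[[paste0("y", j)]] <- oracle_predict(betas[[j]], coded)
  out_id <- infer_run_assignment(resp_id, coef_tab, center_runs = 13:15)
  expect_equal(as.matrix(out_id$design$points[, c("x1", "x2", "x3")]), coded,
               ignore_attr = TRUE)

  # permuting input rows (run labels travel with their rows) gives the same mapping
  shuf <- sample(15)
  out_shuf <- infer_run_assignment(resp[shuf, ], coef_tab, center_runs = 13:15)
  expect_equal(out_shuf$design$points, out$design$points)
})

test_that("center-run detection finds the replicate triple in the published responses", {
  out <- infer_run_assignment(load_fixture("table2"),
                              load_fixture("table3")$coefficients)
  expect_equal(out$center_runs, c(4L, 5L, 12L))
})
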