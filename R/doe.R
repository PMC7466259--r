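#' Define an experimental factor
#'
#' A factor is described by its uncoded low and high levels; coded levels
#' -1, 0 and +1 map to low, midpoint and high respectively.
#'
#' @param name Factor name, e.g. `"%B initial"`.
#' @param low,high Uncoded low/high levels; `low < high` is required.
#' @param units Unit label (informational).
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pH", 3, 7, units = "pH")
#' @export
factor_spec <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("factor_spec: 'low' must be strictly less than 'high'", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high, units = units),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s: [%g, %g] %s\n", x$name, x$low, x$high, x$units))
  invisible(x)
}

check_factors <- function(factors) {
  if (!is.list(factors) || !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  }
  factors
}

# canonical 12-point edge set for a 3-factor Box-Behnken design:
# blocks (x1,x2), (x1,x3), (x2,x3), each block in (-,-), (-,+), (+,-), (+,+)
bbd_edge_points <- function() {
  pm <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  rbind(
    cbind(pm[, 1], pm[, 2], 0),
    cbind(pm[, 1], 0, pm[, 2]),
    cbind(0, pm[, 1], pm[, 2])
  )
}

#' Build a three-level Box-Behnken design
#'
#' Generates the 12 edge-midpoint combinations of a 3-factor Box-Behnken
#' design (every pair of factors at the four (+/-1, +/-1) settings with the
#' third factor at its center) plus `n_center` center replicates. The
#' canonical ordering lists the (x1,x2), (x1,x3), (x2,x3) blocks followed
#' by the center points; a randomized run order is derived from `seed`
#' without affecting the analysis, which is order-invariant.
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of center replicates (non-negative).
#' @param seed Integer seed for run-order randomization, or `NULL` to keep
#'   the canonical order.
#' @return An object of class `bbd_design`: a list with elements `factors`,
#'   `points` (data frame with columns `run`, `x1`, `x2`, `x3`,
#'   `is_center`, coded units), `n_center` and `seed`.
#' @examples
#' fac <- list(factor_spec("%B initial", 0, 10, "%"),
#'             factor_spec("%B end", 60, 100, "%"),
#'             factor_spec("pH", 3, 7))
#' build_bbd(fac, n_center = 3)
#' @export
build_bbd <- function(factors, n_center = 3, seed = NULL) {
  check_factors(factors)
  if (length(factors) != 3L) {
    stop("build_bbd: exactly 3 factors are required for this design", call. = FALSE)
  }
  n_center <- as.integer(n_center)
  stopifnot(n_center >= 0L)
  edges <- bbd_edge_points()
  coded <- rbind(edges, matrix(0, nrow = n_center, ncol = 3))
  n <- nrow(coded)
  ord <- seq_len(n)
  if (!is.null(seed)) {
    ord <- local({
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(as.integer(seed))
      sample.int(n)
    })
  }
  pts <- data.frame(
    run = seq_len(n),
    x1 = coded[ord, 1], x2 = coded[ord, 2], x3 = coded[ord, 3]
  )
  pts$is_center <- pts$x1 == 0 & pts$x2 == 0 & pts$x3 == 0
  structure(list(factors = factors, points = pts, n_center = n_center,
                 seed = seed),
            class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (%d edge + %d center)\n",
              nrow(x$points), nrow(x$points) - x$n_center, x$n_center))
  for (f in x$factors) print(f)
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bbd_design <- function(x, ...) x$points

#' Convert coded factor levels to uncoded units and back
#'
#' `uncode()` maps coded values (-1 at `low`, +1 at `high`) to natural
#' factor units via `center + coded * half_range`; `code()` is its inverse.
#' Both accept a numeric vector (one point) or a matrix/data frame with one
#' column per factor.
#'
#' @param x Coded (for `uncode`) or uncoded (for `code`) values.
#' @param factors List of [factor_spec()], one per column of `x`.
#' @return Numeric vector or matrix in the other scale.
#' @examples
#' fac <- list(factor_spec("%B initial", 0, 10),
#'             factor_spec("%B end", 60, 100),
#'             factor_spec("pH", 3, 7))
#' uncode(c(0.69, 0.49, 0.88), fac)
#' @export
uncode <- function(x, factors) {
  check_factors(factors)
  lows <- vapply(factors, `[[`, numeric(1), "low")
  highs <- vapply(factors, `[[`, numeric(1), "high")
  ctr <- (lows + highs) / 2
  half <- (highs - lows) / 2
  if (is.null(dim(x))) {
    stopifnot(length(x) == length(factors), all(is.finite(x)))
    return(ctr + x * half)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(factors))
  sweep(sweep(x, 2, half, `*`), 2, ctr, `+`)
}

#' @rdname uncode
#' @export
code <- function(x, factors) {
  check_factors(factors)
  lows <- vapply(factors, `[[`, numeric(1), "low")
  highs <- vapply(factors, `[[`, numeric(1), "high")
  ctr <- (lows + highs) / 2
  half <- (highs - lows) / 2
  if (is.null(dim(x))) {
    stopifnot(length(x) == length(factors))
    return((x - ctr) / half)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(factors))
  sweep(sweep(x, 2, ctr, `-`), 2, half, `/`)
}

# exact minimum-cost bijection between n runs and n candidate settings by
# dynamic programming over subsets; ties resolved so that the earliest run
# receives the lowest-index (lexicographically smallest) setting.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) {
    stop("solve_assignment: cost matrix must be square", call. = FALSE)
  }
  if (n > 20L) stop("solve_assignment: too many runs for exact search", call. = FALSE)
  ns <- bitwShiftL(1L, n)
  f <- rep(Inf, ns)           # f[S+1]: min cost of assigning last popcount(S) runs to settings S
  f[1] <- 0
  popcnt <- integer(ns)
  for (s in 1:(ns - 1L)) popcnt[s + 1L] <- popcnt[bitwShiftR(s, 1) + 1L] + bitwAnd(s, 1L)
  ord <- order(popcnt)
  bit <- bitwShiftL(1L, 0:(n - 1L))
  for (s in ord) {
    S <- s - 1L
    m <- popcnt[s]
    if (m == 0L) next
    run <- n - m + 1L                      # first of the trailing runs covered by S
    js <- which(bitwAnd(S, bit) != 0L)
    vals <- cost[run, js] + f[(S - bit[js]) + 1L]
    f[s] <- min(vals)
  }
  # forward reconstruction, preferring the smallest setting index on ties
  S <- ns - 1L
  assign_to <- integer(n)
  tol <- 1e-9
  for (run in seq_len(n)) {
    js <- which(bitwAnd(S, bit) != 0L)
    vals <- cost[run, js] + f[(S - bit[js]) + 1L]
    j <- js[which(vals <= min(vals) + tol)[1L]]
    assign_to[run] <- j
    S <- S - bit[j]
  }
  list(assignment = assign_to, cost = f[ns])
}

#' Recover the run-to-combination assignment of a Box-Behnken experiment
#'
#' When a published response table lists runs without their factor
#' settings, the assignment of the 12 edge runs to the 12 edge
#' combinations can be recovered by matching observed responses against
#' predictions of the published response-surface models. The cost of
#' pairing run r with combination c is the sum over responses of the
#' squared difference between the observed response and the model
#' prediction at c; the minimum-cost bijection is found exactly.
#'
#' @param responses A response table (data frame) with a `run` column and
#'   one numeric column per response; `"FOP"` markers are encoded as 0.
#' @param models Named list of [quadratic_model] objects (one per response
#'   column used) or a coefficient matrix as returned by
#'   `load_fixture("table3")$coefficients`.
#' @param center_runs Integer vector of run ids known to be center
#'   replicates, or `NULL` to detect them as the triple of mutually most
#'   similar rows.
#' @param factors Optional list of [factor_spec()] attached to the
#'   returned design.
#' @param n_center Number of center points expected (default 3).
#' @return A list with `design` (a `bbd_design` whose points are in run
#'   order, carrying the recovered coded settings), `center_runs`, and
#'   `cost` (total squared prediction error of the optimal bijection).
#' @export
infer_run_assignment <- function(responses, models, center_runs = NULL,
                                 factors = NULL, n_center = 3L) {
  y <- fop_encode(responses)
  run_ids <- if ("run" %in% names(responses)) as.integer(responses$run) else seq_len(nrow(y))
  resp_names <- colnames(y)
  if (is.matrix(models) || is.data.frame(models)) {
    models <- models_from_coefficients(models)
  }
  use <- intersect(resp_names, names(models))
  if (length(use) == 0L) stop("no response columns match the supplied models", call. = FALSE)
  y <- y[, use, drop = FALSE]

  n <- nrow(y)
  if (is.null(center_runs)) {
    center_runs <- detect_center_runs(y, run_ids, n_center)
  }
  edge_idx <- which(!(run_ids %in% center_runs))
  combos <- bbd_edge_points()
  if (length(edge_idx) != nrow(combos)) {
    stop(sprintf("assignment is not square: %d edge runs vs %d combinations",
                 length(edge_idx), nrow(combos)), call. = FALSE)
  }
  pred <- vapply(use, function(nm) predict(models[[nm]], combos), numeric(nrow(combos)))
  cost <- matrix(0, length(edge_idx), nrow(combos))
  for (i in seq_along(edge_idx)) {
    d <- sweep(pred, 2, as.numeric(y[edge_idx[i], use]), `-`)
    cost[i, ] <- rowSums(d^2)
  }
  # order edge runs by run id so the tie-break applies to the lowest run first
  o <- order(run_ids[edge_idx])
  sol <- solve_assignment(cost[o, , drop = FALSE])

  coded <- matrix(0, n, 3)
  coded[edge_idx[o], ] <- combos[sol$assignment, , drop = FALSE]
  pts <- data.frame(run = run_ids, x1 = coded[, 1], x2 = coded[, 2],
                    x3 = coded[, 3])
  pts <- pts[order(pts$run), , drop = FALSE]
  rownames(pts) <- NULL
  pts$is_center <- pts$run %in% center_runs
  design <- structure(list(factors = factors, points = pts,
                           n_center = length(center_runs), seed = NULL),
                      class = "bbd_design")
  list(design = design, center_runs = sort(center_runs), cost = sol$cost)
}

# the center replicates are the triple of rows with the smallest total
# pairwise distance after scaling each response to unit range
detect_center_runs <- function(y, run_ids, n_center = 3L) {
  rng <- apply(y, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  z <- sweep(y, 2, rng, `/`)
  d <- as.matrix(stats::dist(z))
  combs <- utils::combn(nrow(z), n_center)
  tot <- apply(combs, 2, function(ix) sum(d[ix, ix]) / 2)
  sort(run_ids[combs[, which.min(tot)]])
}
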