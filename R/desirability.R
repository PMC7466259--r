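#' Define a desirability goal for one response
#'
#' Derringer-style one-sided transforms: for `maximize`, d(y) is 0 at or
#' below `low`, 1 at or above `high`, and `((y - low)/(high - low))^shape`
#' between; `minimize` is the mirror image; `target` ramps up to 1 at
#' `target` and back down to 0 at `high`.
#'
#' @param response_name Name of the response the goal applies to.
#' @param direction One of `"maximize"`, `"minimize"`, `"target"`.
#' @param low,high Anchor range (`low < high`).
#' @param target Target value (required for `direction = "target"`).
#' @param shape Positive exponent of the ramp (1 = linear).
#' @param impact Integer importance weight in 1..5 (3 is the customary
#'   default; the composite raises d to this power).
#' @return A `desirability_goal` object.
#' @export
desirability_goal <- function(response_name, direction = c("maximize", "minimize", "target"),
                              low, high, target = NA_real_, shape = 1, impact = 3) {
  direction <- match.arg(direction)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("desirability_goal: 'low' must be strictly less than 'high'", call. = FALSE)
  }
  if (!is.numeric(shape) || shape <= 0) {
    stop("desirability_goal: 'shape' must be positive", call. = FALSE)
  }
  impact <- as.integer(impact)
  if (is.na(impact) || impact < 1L || impact > 5L) {
    stop("desirability_goal: 'impact' must be an integer in 1..5", call. = FALSE)
  }
  if (direction == "target" && (!is.finite(target) || target <= low || target >= high)) {
    stop("desirability_goal: 'target' must lie inside (low, high)", call. = FALSE)
  }
  structure(list(response_name = response_name, direction = direction,
                 low = low, high = high, target = target,
                 shape = shape, impact = impact),
            class = "desirability_goal")
}

#' Individual desirability of a response value
#'
#' @param y Response value(s).
#' @param goal A [desirability_goal()].
#' @return Desirability in \[0, 1\], vectorized over `y`.
#' @export
d_individual <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  ramp <- function(v) pmin(1, pmax(0, v))^goal$shape
  switch(goal$direction,
    maximize = ramp((y - goal$low) / (goal$high - goal$low)),
    minimize = ramp((goal$high - y) / (goal$high - goal$low)),
    target = {
      up <- ramp((y - goal$low) / (goal$target - goal$low))
      down <- ramp((goal$high - y) / (goal$high - goal$target))
      ifelse(y <= goal$target, up, down)
    }
  )
}

#' Importance-weighted composite desirability
#'
#' The geometric mean of the individual desirabilities weighted by their
#' impact coefficients: `D = (prod d_i^impact_i)^(1/sum impact_i)`. Any
#' zero desirability annihilates the composite.
#'
#' @param d_values Numeric vector of individual desirabilities in \[0, 1\]
#'   (or a matrix, one column per response, composited row-wise).
#' @param impacts Integer impact coefficients, same length as the number
#'   of responses.
#' @return Composite desirability in \[0, 1\].
#' @examples
#' composite_desirability(c(0.25, 1), c(1, 3))  # 0.25^(1/4)
#' @export
composite_desirability <- function(d_values, impacts) {
  if (length(d_values) == 0L) stop("composite_desirability: no desirabilities given", call. = FALSE)
  if (is.null(dim(d_values))) d_values <- matrix(d_values, nrow = 1)
  if (ncol(d_values) != length(impacts)) {
    stop("composite_desirability: impacts do not match responses", call. = FALSE)
  }
  if (any(d_values < -1e-12 | d_values > 1 + 1e-12)) {
    stop("composite_desirability: desirabilities must lie in [0, 1]", call. = FALSE)
  }
  d_values <- pmin(pmax(d_values, 0), 1)  # argument order keeps the dim attribute
  w <- as.numeric(impacts)
  # log-scale accumulation; any zero d gives D = 0
  lg <- log(d_values)
  lg[d_values == 0] <- -Inf
  D <- exp(as.vector(lg %*% w) / sum(w))
  D[!is.finite(D)] <- 0
  D
}

#' Default goal set for separation optimization
#'
#' One `maximize` goal per resolution column (impact 3) and one
#' `minimize` goal for analysis time (impact 1, anchored at the observed
#' time range). Resolution anchors come in two conventions:
#' `"separation"` (the default) ramps desirability linearly from 0 at
#' `Rs = 0` (fully overlapped) to 1 at `Rs = 1.5`, the complete-separation
#' threshold — additional resolution beyond baseline separation earns no
#' further desirability; `"observed"` anchors each resolution at its
#' observed range over the experiment (`"FOP"` encoded as 0), the
#' convention of generic response-surface software.
#'
#' @param responses Response table with Rs columns and a `time` column.
#' @param rs_impact,time_impact Impact coefficients (defaults 3 and 1).
#' @param rs_anchors `"separation"` (ramp over \[0, 1.5\]) or
#'   `"observed"` (per-column observed range).
#' @return Named list of [desirability_goal()] objects, one per response
#'   column.
#' @export
default_goals <- function(responses, rs_impact = 3, time_impact = 1,
                          rs_anchors = c("separation", "observed")) {
  rs_anchors <- match.arg(rs_anchors)
  y <- fop_encode(responses)
  stats::setNames(lapply(colnames(y), function(nm) {
    rng <- range(y[, nm])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # degenerate constant column
    if (nm == "time") {
      desirability_goal(nm, "minimize", rng[1], rng[2], impact = time_impact)
    } else if (rs_anchors == "separation") {
      desirability_goal(nm, "maximize", 0, 1.5, impact = rs_impact)
    } else {
      desirability_goal(nm, "maximize", rng[1], rng[2], impact = rs_impact)
    }
  }), colnames(y))
}

# composite desirability of model predictions at coded points (matrix)
composite_at <- function(points, models, goals) {
  D <- matrix(NA_real_, nrow(points), length(models))
  for (j in seq_along(models)) {
    pred <- predict(models[[j]], points)
    D[, j] <- d_individual(pred, goals[[j]])
  }
  composite_desirability(D, vapply(goals, `[[`, integer(1), "impact"))
}

#' Multi-response optimization over the coded factor cube
#'
#' Maximizes the composite desirability of the fitted response-surface
#' models over \eqn{[-1,1]^3}: a deterministic scan of a `grid_n`^3
#' lattice followed by a Nelder-Mead polish started from the best lattice
#' cell. Ties on the lattice resolve to the lexicographically smallest
#' coded point.
#'
#' @param models Named list of `quadratic_model` objects.
#' @param goals Named list of [desirability_goal()], one per model (names
#'   must match).
#' @param grid_n Lattice points per axis (default 201).
#' @param factors Optional list of [factor_spec()] used to report the
#'   optimum in natural units.
#' @param polish Run the local polish after the grid scan (default TRUE).
#' @return An `mro_result`: `coded_optimum`, `uncoded_optimum` (if
#'   `factors` given), `composite_D`, `per_response` (predicted value and
#'   individual desirability at the optimum), and `all_zero` flag set when
#'   the desirability surface vanishes everywhere on the lattice.
#' @export
optimize_desirability <- function(models, goals, grid_n = 201, factors = NULL,
                                  polish = TRUE) {
  stopifnot(length(models) > 0, grid_n >= 2)
  if (is.null(names(goals)) || !setequal(names(goals), names(models))) {
    stop("optimize_desirability: goals must be named after the models", call. = FALSE)
  }
  goals <- goals[names(models)]
  g <- seq(-1, 1, length.out = grid_n)
  slice <- as.matrix(expand.grid(x3 = g, x2 = g))[, 2:1]  # x2 varies slowest within a slice
  best_D <- -Inf; best_pt <- c(-1, -1, -1)
  tie_tol <- 1e-12
  for (x1 in g) {  # x1 slowest: scan order is lexicographic in (x1, x2, x3)
    pts <- cbind(x1, slice)
    D <- composite_at(pts, models, goals)
    mx <- max(D)
    if (mx > best_D + tie_tol) {  # ties (within numerical fuzz) keep the earliest point
      best_D <- mx
      best_pt <- pts[which(D >= mx - tie_tol)[1L], ]
    }
  }
  all_zero <- best_D <= 0
  if (polish && !all_zero) {
    obj <- function(p) {
      pen <- sum(pmax(0, abs(p) - 1)^2)
      -composite_at(matrix(pmin(1, pmax(-1, p)), 1), models, goals) + 1e3 * pen
    }
    opt <- stats::optim(best_pt, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    cand <- pmin(1, pmax(-1, opt$par))
    cand_D <- composite_at(matrix(cand, 1), models, goals)
    if (cand_D > best_D + tie_tol) { best_D <- cand_D; best_pt <- cand }
  }
  per <- lapply(names(models), function(nm) {
    pred <- predict(models[[nm]], best_pt)
    list(predicted = pred, d = d_individual(pred, goals[[nm]]))
  })
  names(per) <- names(models)
  structure(list(
    coded_optimum = stats::setNames(as.numeric(best_pt), c("x1", "x2", "x3")),
    uncoded_optimum = if (!is.null(factors)) {
      stats::setNames(uncode(as.numeric(best_pt), factors),
                      vapply(factors, `[[`, character(1), "name"))
    },
    composite_D = max(best_D, 0),
    per_response = per,
    all_zero = all_zero,
    grid_n = grid_n
  ), class = "mro_result")
}

#' @export
print.mro_result <- function(x, ...) {
  cat("Multi-response desirability optimum\n")
  cat("  coded:  ", paste(sprintf("%s = %.3f", names(x$coded_optimum), x$coded_optimum),
                          collapse = ", "), "\n")
  if (!is.null(x$uncoded_optimum)) {
    cat("  uncoded:", paste(sprintf("%s = %.2f", names(x$uncoded_optimum), x$uncoded_optimum),
                            collapse = ", "), "\n")
  }
  cat(sprintf("  composite D = %.4f%s\n", x$composite_D,
              if (x$all_zero) " (desirability vanishes on the whole cube)" else ""))
  invisible(x)
}
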