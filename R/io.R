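#' Read and write designs and response tables
#'
#' Comma-separated, UTF-8, header row required. A design file carries
#' columns `run`, `x1_coded`, `x2_coded`, `x3_coded`, `x1`, `x2`, `x3`,
#' `is_center`; a response file carries `run`, the Rs columns (the
#' literal string `"FOP"` is the only non-numeric token permitted) and
#' `time`. Write-then-read reproduces the object exactly, FOP markers
#' included.
#'
#' @param design A `bbd_design`.
#' @param path File path.
#' @name design_io
NULL

#' @rdname design_io
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bbd_design"))
  coded <- design_coded(design)
  un <- uncode(coded, design$factors)
  out <- data.frame(run = design$points$run,
                    x1_coded = coded[, 1], x2_coded = coded[, 2], x3_coded = coded[, 3],
                    x1 = un[, 1], x2 = un[, 2], x3 = un[, 3],
                    is_center = design$points$is_center)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname design_io
#' @param factors List of [factor_spec()] to attach (the file stores only
#'   levels).
#' @export
read_design <- function(path, factors) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run", "x1_coded", "x2_coded", "x3_coded", "is_center")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("read_design: missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  pts <- data.frame(run = as.integer(tab$run), x1 = tab$x1_coded,
                    x2 = tab$x2_coded, x3 = tab$x3_coded,
                    is_center = as.logical(tab$is_center))
  structure(list(factors = factors, points = pts,
                 n_center = sum(pts$is_center), seed = NULL),
            class = "bbd_design")
}

#' @rdname design_io
#' @param responses Response table data frame (`run`, Rs columns, `time`).
#' @export
write_response_table <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname design_io
#' @export
read_response_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(tab) == 0L) stop("read_response_table: empty response table", call. = FALSE)
  if (!"run" %in% names(tab)) stop("read_response_table: missing 'run' column", call. = FALSE)
  tab$run <- as.integer(tab$run)
  if ("time" %in% names(tab)) tab$time <- as.numeric(tab$time)
  rs_cols <- setdiff(names(tab), c("run", "time"))
  for (nm in rs_cols) {
    bad <- !(toupper(trimws(tab[[nm]])) == "FOP" |
               !is.na(suppressWarnings(as.numeric(tab[[nm]]))))
    if (any(bad)) {
      stop(sprintf("read_response_table: non-numeric, non-FOP cell in column '%s', row %d",
                   nm, which(bad)[1]), call. = FALSE)
    }
  }
  tab
}

#' Run the full design-fit-optimize pipeline
#'
#' Fits the full second-order model to every response column, flags the
#' significant terms at `alpha`, runs the importance-weighted
#' desirability optimization over the coded cube, and classifies the
#' predicted resolutions at the optimum. Deterministic: the same inputs
#' give the same report.
#'
#' @param responses Response table (`run`, Rs columns with optional
#'   `"FOP"`, `time`).
#' @param design A `bbd_design` whose points are in run order; default
#'   the canonical 15-run design on `factors`.
#' @param factors List of three [factor_spec()]; default the built-in
#'   factor ranges (`load_fixture("table1")`).
#' @param alpha Significance level for term flags.
#' @param fop_value Numeric encoding of FOP cells.
#' @param rs_impact,time_impact Desirability impact coefficients.
#' @param rs_anchors Resolution anchor convention, see [default_goals()].
#' @param grid_n Optimizer lattice density per axis.
#' @param use_reduced Optimize the alpha-reduced models instead of the
#'   full ones (default FALSE: full models).
#' @return A `pipeline_report`: `models`, `coefficients`
#'   ([coefficients_table()] layout), `significant` (logical matrix),
#'   `optimum` (an `mro_result`), `predicted_at_optimum` with separation
#'   classes, and the configuration used.
#' @export
run_pipeline <- function(responses, design = NULL, factors = load_fixture("table1"),
                         alpha = 0.05, fop_value = 0, rs_impact = 3,
                         time_impact = 1, rs_anchors = c("separation", "observed"),
                         grid_n = 201, use_reduced = FALSE) {
  if (is.null(dim(responses)) || nrow(responses) == 0L) {
    stop("run_pipeline: empty response table", call. = FALSE)
  }
  if (is.null(design)) design <- build_bbd(factors, n_center = nrow(responses) - 12L)
  if (nrow(design$points) != nrow(responses)) {
    stop("run_pipeline: design and response table sizes differ", call. = FALSE)
  }
  models <- fit_all_responses(design, responses, fop_value = fop_value)
  goals <- default_goals(responses, rs_impact = rs_impact,
                         time_impact = time_impact, rs_anchors = rs_anchors)
  opt_models <- if (use_reduced) lapply(models, reduce_model, alpha = alpha) else models
  optimum <- optimize_desirability(opt_models, goals, grid_n = grid_n,
                                   factors = design$factors)
  sig <- vapply(models, function(m) m$p_values[quadratic_terms[-1]] < alpha,
                logical(9))
  rownames(sig) <- quadratic_terms[-1]
  pred <- vapply(models, function(m) predict(m, optimum$coded_optimum), numeric(1))
  cls <- ifelse(names(pred) == "time", NA_character_,
                classify_separation(pmax(0, pred)))
  structure(list(
    models = models,
    coefficients = coefficients_table(models, digits = NULL),
    significant = sig,
    optimum = optimum,
    predicted_at_optimum = data.frame(
      response = names(pred), predicted = unname(pred), class = unname(cls)
    ),
    config = list(alpha = alpha, fop_value = fop_value, rs_impact = rs_impact,
                  time_impact = time_impact, rs_anchors = match.arg(rs_anchors),
                  grid_n = grid_n, use_reduced = use_reduced)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Separation-optimization pipeline: %d fitted responses\n",
              length(x$models)))
  print(coefficients_table(x$models, digits = 3), row.names = FALSE)
  print(x$optimum)
  cat("Predicted responses at the optimum:\n")
  print(transform(x$predicted_at_optimum, predicted = round(predicted, 3)),
        row.names = FALSE)
  invisible(x)
}
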