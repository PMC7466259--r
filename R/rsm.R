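quadratic_terms <- c("constant", "x1", "x2", "x3",
                     "x1x1", "x1x2", "x1x3", "x2x2", "x2x3", "x3x3")

# model matrix of the full second-order polynomial on coded factors,
# columns in the canonical term order above
quadratic_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == 3L)
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cbind(constant = 1, x1 = x1, x2 = x2, x3 = x3,
        x1x1 = x1^2, x1x2 = x1 * x2, x1x3 = x1 * x3,
        x2x2 = x2^2, x2x3 = x2 * x3, x3x3 = x3^2)
}

design_coded <- function(design) {
  if (inherits(design, "bbd_design")) {
    as.matrix(design$points[, c("x1", "x2", "x3")])
  } else {
    m <- as.matrix(design)
    stopifnot(ncol(m) == 3L)
    m
  }
}

#' Fit the full second-order response-surface polynomial
#'
#' Fits, by ordinary least squares on coded factor levels, the 10-term
#' second-order model
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'       \sum_{i<j} \beta_{ij} x_i x_j}
#' to one response column of a designed experiment. `"FOP"` cells (fully
#' overlapped peaks) are encoded as `fop_value` before fitting. Per-term
#' two-sided p-values come from the t statistics of the fit; the
#' goodness-of-fit summaries are \eqn{R^2}, adjusted \eqn{R^2}, the
#' residual standard error and the mean absolute error, all computed on
#' the training data.
#'
#' @param design A [build_bbd()] design (or a 3-column coded matrix).
#' @param y Response vector, numeric or character with `"FOP"` markers.
#' @param response_name Label stored with the model.
#' @param fop_value Numeric encoding of FOP cells (default 0).
#' @param terms Character subset of the 10 canonical terms to retain
#'   (always including `"constant"`); default is the full model.
#' @return A `quadratic_model`: coefficients, p-values, `r2`, `r2_adj`,
#'   `se`, `mae`, `n_obs`, `df_resid`, and the data used (for refits).
#' @export
fit_full_quadratic <- function(design, y, response_name = "y", fop_value = 0,
                               terms = quadratic_terms) {
  coded <- design_coded(design)
  y <- fop_encode(y, value = fop_value)
  if (length(y) != nrow(coded)) {
    stop("fit_full_quadratic: response length does not match the design", call. = FALSE)
  }
  terms <- union("constant", terms)
  X <- quadratic_model_matrix(coded)[, quadratic_terms[quadratic_terms %in% terms], drop = FALSE]
  p <- ncol(X)
  if (nrow(X) < p + 1L) {
    stop("fit_full_quadratic: too few observations for the requested terms", call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("fit_full_quadratic: singular fit; the design does not support the model", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  n <- length(y)
  df_resid <- n - p
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  r2_adj <- if (sst > 0) 1 - (1 - r2) * (n - 1) / df_resid else 1
  se <- sqrt(sse / df_resid)
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta_se <- sqrt(diag(XtXinv) * se^2)
  degenerate <- FALSE
  if (se == 0) {
    # interpolating fit: report p = 0 for nonzero coefficients, 1 otherwise
    degenerate <- TRUE
    pvals <- ifelse(abs(beta) > 0, 0, 1)
  } else {
    tstat <- beta / beta_se
    pvals <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  }
  structure(list(
    response_name = response_name,
    coefficients = beta,
    p_values = pvals,
    std_errors = beta_se,
    r2 = r2, r2_adj = r2_adj, se = se, mae = mean(abs(res)),
    n_obs = n, df_resid = df_resid,
    degenerate = degenerate,
    coded = coded, y = y, fop_value = fop_value
  ), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Second-order model for %s (n = %d, residual df = %d)\n",
              x$response_name, x$n_obs, x$df_resid))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    p_value = signif(x$p_values, 3))
  tab$signif <- ifelse(x$p_values < 0.05, "*", "")
  print(tab)
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  SE = %.4f  MAE = %.4f\n",
              x$r2, x$r2_adj, x$se, x$mae))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' Predict from a fitted second-order model
#'
#' @param object A `quadratic_model`.
#' @param newdata Coded point (length-3 vector) or matrix with 3 columns.
#'   Points outside the \[-1, 1\] cube are extrapolations and trigger a
#'   warning.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (any(abs(newdata) > 1 + 1e-8)) {
    warning("predict: point outside the coded [-1, 1] cube (extrapolation)")
  }
  X <- quadratic_model_matrix(newdata)
  keep <- names(object$coefficients)
  drop(X[, keep, drop = FALSE] %*% object$coefficients)
}

#' Refit keeping only significant terms
#'
#' Retains the intercept plus every term with `p < alpha` and refits by
#' least squares. Model hierarchy is deliberately not enforced: a
#' quadratic term may be kept without its linear parent, as is common in
#' single-pass significance filtering.
#'
#' @param model A full `quadratic_model` (must carry its training data).
#' @param alpha Significance level in (0, 1).
#' @return The reduced `quadratic_model` (possibly intercept-only).
#' @export
reduce_model <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "quadratic_model"), alpha > 0, alpha <= 1)
  if (alpha >= 1) return(model)
  keep <- names(model$coefficients)[model$p_values < alpha]
  keep <- union("constant", keep)
  if (setequal(keep, names(model$coefficients))) return(model)
  fit_full_quadratic(model$coded, model$y, response_name = model$response_name,
                     fop_value = model$fop_value, terms = keep)
}

#' Fit all response columns of a designed experiment
#'
#' @param design A [build_bbd()] design (points in run order).
#' @param responses Response table with a `run` column and one column per
#'   response; `"FOP"` markers allowed.
#' @param fop_value Numeric encoding of FOP cells.
#' @return Named list of `quadratic_model` objects.
#' @export
fit_all_responses <- function(design, responses, fop_value = 0) {
  y <- fop_encode(responses, value = fop_value)
  stats::setNames(lapply(colnames(y), function(nm) {
    fit_full_quadratic(design, y[, nm], response_name = nm, fop_value = fop_value)
  }), colnames(y))
}

#' Tabulate fitted models in the standard coefficients layout
#'
#' Rows: the 10 polynomial terms, then `R2`, `R2_adj`, `SE`, `MAE`;
#' columns: one per response.
#'
#' @param models Named list of `quadratic_model` objects.
#' @param digits Rounding applied to the table (default 3 for
#'   coefficients, 4 for fit metrics); `NULL` for full precision.
#' @return A data frame with a `term` column.
#' @export
coefficients_table <- function(models, digits = 3) {
  stopifnot(length(models) > 0)
  col <- function(m) {
    b <- stats::setNames(rep(0, 10), quadratic_terms)
    b[names(m$coefficients)] <- m$coefficients
    if (!is.null(digits)) b <- round(b, digits)
    fitm <- c(R2 = m$r2, R2_adj = m$r2_adj, SE = m$se, MAE = m$mae)
    if (!is.null(digits)) fitm <- round(fitm, digits + 1)
    c(b, fitm)
  }
  out <- data.frame(term = c(quadratic_terms, "R2", "R2_adj", "SE", "MAE"))
  for (nm in names(models)) out[[nm]] <- col(models[[nm]])
  out
}

# build light-weight prediction-only models from a printed coefficient
# table (term x response), e.g. the published coefficient matrix
models_from_coefficients <- function(tab) {
  tab <- as.data.frame(tab)
  if ("term" %in% names(tab)) {
    rownames(tab) <- tab$term
    tab$term <- NULL
  }
  missing <- setdiff(quadratic_terms, rownames(tab))
  if (length(missing)) {
    stop("coefficient table lacks terms: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::setNames(lapply(names(tab), function(nm) {
    structure(list(response_name = nm,
                   coefficients = stats::setNames(as.numeric(tab[quadratic_terms, nm]),
                                                  quadratic_terms),
                   p_values = rep(NA_real_, 10)),
              class = "quadratic_model")
  }), names(tab))
}
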