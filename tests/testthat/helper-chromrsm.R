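# shared fixtures and small independent oracles used across test files

paper_factors <- function() {
  list(factor_spec("%B initial", 0, 10, "%"),
       factor_spec("%B end", 60, 100, "%"),
       factor_spec("pH", 3, 7, "pH"))
}

# independent model-matrix oracle for the 10-term second-order polynomial
# (kept separate from the package's own construction on purpose)
oracle_X <- function(coded) {
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cbind(1, x1, x2, x3, x1^2, x1 * x2, x1 * x3, x2^2, x2 * x3, x3^2)
}

# evaluate a coefficient column (canonical term order) at coded points
oracle_predict <- function(beta, coded) drop(oracle_X(coded) %*% beta)

# random full-quadratic response surface on a design, plus iid noise
random_quadratic_response <- function(coded, sd = 0.1) {
  beta <- stats::rnorm(10)
  oracle_predict(beta, coded) + stats::rnorm(nrow(coded), 0, sd)
}
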