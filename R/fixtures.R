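#' Embedded study fixtures
#'
#' Returns the data tables of the published method-development study that
#' the package reproduces computationally: the factor ranges
#' (`"table1"`), the 15-run response table with FOP markers (`"table2"`),
#' the printed coefficient matrix with fit metrics and significance flags
#' (`"table3"`), the real-sample additive concentrations (`"table5b"`),
#' and the NADFC concentration limits (`"limits"`).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table5b"`,
#'   `"limits"`.
#' @return `"table1"`: list of three [factor_spec()]. `"table2"`: data
#'   frame with `run`, seven character `Rs` columns (literal `"FOP"`
#'   allowed) and numeric `time`. `"table3"`: list with `coefficients`
#'   (term x response data frame), `fit` (R2/R2_adj/SE/MAE rows) and
#'   `significant` (logical flags). `"table5b"`: long data frame
#'   (`sample`, `analyte`, `concentration`, `sd`). `"limits"`: named
#'   numeric vector.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table5b", "limits")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "chromrsm")
  switch(name,
    table1 = {
      tab <- utils::read.csv(path("table1_factors.csv"), stringsAsFactors = FALSE,
                             check.names = FALSE)
      lapply(seq_len(nrow(tab)), function(i) {
        factor_spec(tab$name[i], tab$low[i], tab$high[i], tab$units[i])
      })
    },
    table2 = {
      tab <- utils::read.csv(path("table2_responses.csv"), stringsAsFactors = FALSE,
                             check.names = FALSE, colClasses = "character")
      tab$run <- as.integer(tab$run)
      tab$time <- as.numeric(tab$time)
      tab
    },
    table3 = {
      tab <- utils::read.csv(path("table3_coefficients.csv"), stringsAsFactors = FALSE,
                             check.names = FALSE)
      sig <- utils::read.csv(path("table3_significant.csv"), stringsAsFactors = FALSE,
                             check.names = FALSE)
      coefs <- tab[tab$term %in% quadratic_terms, , drop = FALSE]
      fit <- tab[!(tab$term %in% quadratic_terms), , drop = FALSE]
      rownames(coefs) <- rownames(fit) <- NULL
      list(coefficients = coefs, fit = fit, significant = sig)
    },
    table5b = utils::read.csv(path("table5b_concentrations.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(sample = "character")),
    limits = nadfc_limits()
  )
}
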