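#' Construct a chromatographic peak
#'
#' @param analyte Analyte identifier. A merged (co-eluting) peak carries
#'   the identifiers of its members joined by `"+"`.
#' @param t Retention time, minutes (`t >= 0`).
#' @param w Base width, minutes (`w > 0`); the tangent/baseline width,
#'   equal to 4 standard deviations for a Gaussian peak.
#' @param area,height Signal area and height, arbitrary units.
#' @return A `peak` object.
#' @export
peak <- function(analyte, t, w, area = 1, height = NA_real_) {
  if (!is.finite(t) || t < 0) stop("peak: retention time must be >= 0", call. = FALSE)
  if (!is.finite(w) || w <= 0) stop("peak: base width must be positive", call. = FALSE)
  structure(list(analyte = as.character(analyte), t = as.numeric(t),
                 w = as.numeric(w), area = as.numeric(area),
                 height = as.numeric(height)),
            class = "peak")
}

#' Assemble peaks into a chromatogram
#'
#' Peaks are sorted by retention time; duplicate analyte identifiers are
#' rejected.
#'
#' @param peaks List of [peak()] objects.
#' @param run_id Integer run identifier.
#' @param metadata Optional list of factor settings used for the run.
#' @return A `chromatogram` object; `as.data.frame()` gives the peak table.
#' @export
chromatogram <- function(peaks, run_id = NA_integer_, metadata = list()) {
  stopifnot(is.list(peaks), all(vapply(peaks, inherits, logical(1), "peak")))
  ts <- vapply(peaks, `[[`, numeric(1), "t")
  peaks <- peaks[order(ts)]
  ids <- vapply(peaks, `[[`, character(1), "analyte")
  if (anyDuplicated(ids)) stop("chromatogram: duplicate analyte identifiers", call. = FALSE)
  structure(list(peaks = peaks, run_id = run_id, metadata = metadata),
            class = "chromatogram")
}

#' @export
as.data.frame.chromatogram <- function(x, ...) {
  data.frame(
    analyte = vapply(x$peaks, `[[`, character(1), "analyte"),
    t_min = vapply(x$peaks, `[[`, numeric(1), "t"),
    w_min = vapply(x$peaks, `[[`, numeric(1), "w"),
    area = vapply(x$peaks, `[[`, numeric(1), "area"),
    height = vapply(x$peaks, `[[`, numeric(1), "height")
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram (run %s): %d peaks\n",
              ifelse(is.na(x$run_id), "-", x$run_id), length(x$peaks)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Resolution between two adjacent peaks
#'
#' `Rs = (t2 - t1) / (0.5 (w1 + w2))`: the retention-time difference of
#' the pair relative to their average baseline width. `Rs >= 1.5` is
#' baseline (complete) separation.
#'
#' @param first,second [peak()] objects, `second` eluting at or after
#'   `first`.
#' @return The dimensionless resolution (0 for coincident peaks).
#' @examples
#' resolution(peak("A", 5.0, 1.0), peak("B", 6.5, 1.0))  # 1.5
#' @export
resolution <- function(first, second) {
  stopifnot(inherits(first, "peak"), inherits(second, "peak"))
  if (second$t < first$t) {
    stop("resolution: peaks must be given in elution order", call. = FALSE)
  }
  denom <- 0.5 * (first$w + second$w)
  if (!is.finite(denom) || denom <= 0) {
    stop("resolution: combined peak width must be positive", call. = FALSE)
  }
  (second$t - first$t) / denom
}

#' Classify a separation by its resolution
#'
#' `full` separation at `Rs >= 1.5`, `acceptable` (about 98% separated)
#' for `1.0 <= Rs < 1.5`, `poor` below 1.0.
#'
#' @param rs Non-negative resolution value(s).
#' @return Character vector in `{"full", "acceptable", "poor"}`.
#' @export
classify_separation <- function(rs) {
  rs <- as.numeric(rs)
  if (any(!is.finite(rs)) || any(rs < 0)) {
    stop("classify_separation: resolution must be non-negative", call. = FALSE)
  }
  ifelse(rs >= 1.5, "full", ifelse(rs >= 1.0, "acceptable", "poor"))
}

#' Extract the optimization responses from a chromatogram
#'
#' Computes the resolution of every adjacent peak pair in elution order
#' plus the analysis time (retention time of the last peak). Pairs that
#' cannot be distinguished are reported as the marker string `"FOP"`
#' (fully overlapped peaks): either both analytes sit in one merged peak
#' (identifier joined by `"+"`), or their resolution falls below
#' `fop_threshold`.
#'
#' @param chrom A [chromatogram()].
#' @param fop_threshold Resolution below which a pair is reported as FOP
#'   (default 0.2).
#' @param analyte_order Optional character vector giving the expected
#'   elution order of individual analytes; when supplied, response cells
#'   are produced for each adjacent pair in this order (so pairs hidden
#'   inside a merged peak are reported FOP). Defaults to the order of the
#'   peaks as they stand.
#' @return A one-row data frame: columns `Rs1-2`, ..., plus `time`
#'   (minutes). Rs columns are character so that `"FOP"` can be carried;
#'   use [fop_encode()] to obtain numbers.
#' @export
response_row <- function(chrom, fop_threshold = 0.2, analyte_order = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(chrom$peaks) == 0L) stop("response_row: empty chromatogram", call. = FALSE)
  peaks <- chrom$peaks
  if (is.null(analyte_order)) {
    members <- lapply(peaks, function(p) strsplit(p$analyte, "+", fixed = TRUE)[[1]])
    analyte_order <- unlist(members)
  }
  n <- length(analyte_order)
  if (n < 2L) stop("response_row: at least two analytes are required", call. = FALSE)
  # map every analyte to the peak containing it
  peak_of <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(vapply(peaks, function(p) {
      analyte_order[i] %in% strsplit(p$analyte, "+", fixed = TRUE)[[1]]
    }, logical(1)))
    if (length(hit) != 1L) {
      stop(sprintf("response_row: analyte '%s' not found exactly once", analyte_order[i]),
           call. = FALSE)
    }
    peak_of[i] <- hit
  }
  cells <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    p1 <- peak_of[i]; p2 <- peak_of[i + 1L]
    if (p1 == p2) {
      cells[i] <- "FOP"
    } else {
      rs <- resolution(peaks[[min(p1, p2)]], peaks[[max(p1, p2)]])
      cells[i] <- if (rs < fop_threshold) "FOP" else as.character(rs)
    }
  }
  out <- as.data.frame(as.list(cells), stringsAsFactors = FALSE)
  names(out) <- paste0("Rs", seq_len(n - 1L), "-", 2:n)
  out$time <- max(vapply(peaks, `[[`, numeric(1), "t"))
  out
}

#' Encode FOP markers numerically
#'
#' Converts the character response columns of a response table to numeric,
#' replacing `"FOP"` (fully overlapped peaks) cells by `value`. The
#' default 0 reflects that a fully overlapped pair has no measurable
#' separation.
#'
#' @param responses Response table (data frame, possibly with a `run`
#'   column, which is dropped) or vector.
#' @param value Numeric stand-in for FOP cells (default 0).
#' @return Numeric matrix (or vector) of responses.
#' @export
fop_encode <- function(responses, value = 0) {
  enc <- function(v) {
    v <- as.character(v)
    v[toupper(trimws(v)) == "FOP"] <- as.character(value)
    as.numeric(v)
  }
  if (is.null(dim(responses))) return(enc(responses))
  responses <- as.data.frame(responses)
  responses <- responses[, setdiff(names(responses), "run"), drop = FALSE]
  out <- vapply(responses, enc, numeric(nrow(responses)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(responses),
                                     dimnames = list(NULL, names(responses)))
  out
}
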