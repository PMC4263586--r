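# Cell-index computation and trace normalization.
#
# The cell index summarizes the frequency-dependent electrode resistance of
# a well: CI = max over measured frequencies f of R_cell(f)/R_b(f) - 1,
# where R_b is the background (no cells) resistance. More attached cells
# raise R_cell and hence CI; an empty well gives CI = 0. The index is not
# clamped at zero: backgrounds recorded with cells already present can
# legitimately yield negative values.

#' Compute the cell index from an electrode resistance spectrum pair
#'
#' @param r_background Background resistances (ohms), electrode without
#'   cells, one per measured frequency.
#' @param r_cell Resistances with cells present, same length.
#' @param frequencies Optional frequency labels (Hz), same length; only
#'   checked for length, the index depends on the resistance ratios alone.
#' @return Dimensionless cell index: `max(r_cell / r_background - 1)`.
#' @export
#' @examples
#' compute_cell_index(c(10, 20), c(15, 50)) # max(0.5, 1.5) = 1.5
compute_cell_index <- function(r_background, r_cell, frequencies = NULL) {
  r_background <- as.numeric(r_background)
  r_cell <- as.numeric(r_cell)
  if (length(r_background) < 1L ||
      length(r_background) != length(r_cell)) {
    stop("r_background and r_cell must be non-empty and of equal length")
  }
  if (!is.null(frequencies) &&
      length(frequencies) != length(r_background)) {
    stop("frequencies must match the resistance vectors in length")
  }
  if (any(r_background <= 0) || any(r_cell <= 0)) {
    stop("electrode resistances must be positive")
  }
  max(r_cell / r_background - 1)
}

#' Reference time for normalization: last grid point at or before first dose
#'
#' Trace normalization references the last recorded point before compound
#' addition; a dose time coinciding with a grid point references that point.
#'
#' @param plate An [rtca_plate()] (or anything with `times` and
#'   `dose_times`).
#' @return Reference time in hours.
#' @export
default_reference_time <- function(plate) {
  times <- plate$times
  first_dose <- min(plate$dose_times)
  ok <- times <= first_dose
  if (!any(ok)) {
    stop("no grid point at or before the first dose time (",
         first_dose, " h)")
  }
  max(times[ok])
}

#' Normalize a cell-index trace to a reference time point
#'
#' Divides every value by the value at `reference_time`, so the normalized
#' cell index is exactly 1 there. Wells whose reference cell index falls
#' below `quality_floor` (instrument guidance: a pre-dose CI of at least
#' 0.5) are flagged degenerate via the `"degenerate"` attribute; a
#' non-positive reference value is an error, never a silent drop.
#'
#' @param trace An [rtca_trace()].
#' @param reference_time A time on the trace grid; default the last point
#'   at or before the trace's dose time.
#' @param quality_floor Minimum acceptable reference cell index before the
#'   well is flagged (default 0.5).
#' @return An `rtca_trace` with normalized values, attributes
#'   `reference_time`, `normalized = TRUE` and logical `degenerate`.
#' @export
#' @examples
#' tr <- rtca_trace(c(0, 16, 40), c(1, 2, 3), dose_time = 16)
#' normalize_trace(tr, 16)$values # 0.5 1.0 1.5
normalize_trace <- function(trace, reference_time = NULL,
                            quality_floor = 0.5) {
  stopifnot(inherits(trace, "rtca_trace"))
  if (is.null(reference_time)) {
    if (is.null(trace$dose_time)) {
      stop("reference_time required for a trace without a dose time")
    }
    reference_time <- default_reference_time(
      list(times = trace$times, dose_times = trace$dose_time))
  }
  idx <- which(trace$times == reference_time)
  if (length(idx) != 1L) {
    stop("reference_time ", reference_time,
         " is not a grid point of the trace")
  }
  ref <- trace$values[idx]
  if (ref <= 0) {
    stop("degenerate well ", trace$well, ": reference cell index ", ref,
         " is not positive; cannot normalize")
  }
  out <- trace
  out$values <- trace$values / ref
  attr(out, "reference_time") <- reference_time
  attr(out, "normalized") <- TRUE
  attr(out, "degenerate") <- ref < quality_floor
  if (attr(out, "degenerate")) {
    warning("well ", trace$well, ": reference cell index ",
            format(ref), " below quality floor ", quality_floor)
  }
  out
}

#' Normalize every trace of a plate
#'
#' @param plate An [rtca_plate()].
#' @param reference_time Reference time; default
#'   [default_reference_time()] of the plate (last point before first
#'   dose).
#' @param quality_floor Degenerate-well threshold, see
#'   [normalize_trace()].
#' @return An `rtca_plate` of normalized values with attributes
#'   `reference_time` and `degenerate_wells` (character vector; these wells
#'   are flagged, not dropped).
#' @export
normalize_plate <- function(plate, reference_time = NULL,
                            quality_floor = 0.5) {
  stopifnot(inherits(plate, "rtca_plate"))
  if (is.null(reference_time)) reference_time <- default_reference_time(plate)
  idx <- which(plate$times == reference_time)
  if (length(idx) != 1L) {
    stop("reference_time ", reference_time, " is not on the plate grid")
  }
  refs <- plate$values[idx, ]
  bad <- colnames(plate$values)[refs <= 0]
  if (length(bad)) {
    stop("degenerate well(s) with non-positive reference cell index: ",
         paste(bad, collapse = ", "))
  }
  out <- plate
  out$values <- sweep(plate$values, 2L, refs, "/")
  attr(out, "reference_time") <- reference_time
  attr(out, "normalized") <- TRUE
  attr(out, "degenerate_wells") <-
    colnames(plate$values)[refs < quality_floor]
  out
}

#' Replicate mean and standard deviation of traces
#'
#' @param traces List of [rtca_trace()] objects on one shared time grid
#'   (length >= 2).
#' @return List with `times`, `mean`, `sd` (sample standard deviation,
#'   n - 1 denominator) and `n`.
#' @export
summarize_replicates <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L) {
    stop("need at least 2 replicate traces")
  }
  grids <- lapply(traces, `[[`, "times")
  if (!all(vapply(grids[-1L], function(g) identical(g, grids[[1L]]),
                  logical(1)))) {
    stop("replicate traces are not on a shared time grid")
  }
  mat <- vapply(traces, `[[`, numeric(length(grids[[1L]])), "values")
  list(times = grids[[1L]],
       mean = rowMeans(mat),
       sd = apply(mat, 1L, stats::sd),
       n = length(traces))
}
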