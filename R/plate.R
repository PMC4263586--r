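# ---- well addresses ---------------------------------------------------------

VALID_ROWS <- LETTERS[1:8]
WELL_ROLES <- c("treated", "vehicle_control", "positive_control", "blank")

#' Format a well address
#'
#' Wells on a 96-well E-plate are addressed by row letter A--H and column
#' 1--12; the canonical string form zero-pads the column ("B07").
#'
#' @param row Row letter, one of \code{"A"}--\code{"H"}.
#' @param column Column number, 1--12.
#' @return Canonical well string, e.g. \code{"B07"}.
#' @export
#' @examples
#' well_address("B", 7)
well_address <- function(row, column) {
  row <- toupper(as.character(row))
  column <- as.integer(column)
  if (!all(row %in% VALID_ROWS)) {
    stop("well row must be one of A-H, got: ",
         paste(setdiff(row, VALID_ROWS), collapse = ", "))
  }
  if (any(is.na(column)) || any(column < 1L) || any(column > 12L)) {
    stop("well column must be an integer in 1-12")
  }
  sprintf("%s%02d", row, column)
}

#' Validate well address strings
#'
#' @param wells Character vector of well addresses.
#' @return The canonical form of `wells`, invisibly erroring on invalid input.
#' @export
check_wells <- function(wells) {
  ok <- grepl("^[A-H](0[1-9]|1[0-2])$", wells)
  if (!all(ok)) {
    stop("invalid well address(es): ", paste(wells[!ok], collapse = ", "))
  }
  wells
}

# ---- cell-index traces ------------------------------------------------------

#' Construct a cell-index trace
#'
#' A trace is one well's cell-index time series, with time in hours since
#' cell seeding and an optional compound-addition time.
#'
#' @param times Numeric vector of hours since seeding, strictly increasing,
#'   length >= 2.
#' @param values Numeric cell-index values, same length as `times`.
#' @param well Well address string (default `"A01"`).
#' @param dose_time Hours since seeding of compound addition, or `NULL` for
#'   wells that are never dosed. When present it must lie within the time
#'   range of the trace.
#' @return An object of class `rtca_trace`.
#' @export
#' @examples
#' tr <- rtca_trace(c(0, 16, 40), c(1, 2, 3), dose_time = 16)
rtca_trace <- function(times, values, well = "A01", dose_time = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) stop("trace needs at least 2 timepoints")
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (any(diff(times) <= 0)) stop("non-increasing time grid in trace")
  if (anyNA(times) || anyNA(values)) stop("trace contains NA")
  check_wells(well)
  if (!is.null(dose_time)) {
    dose_time <- as.numeric(dose_time)
    if (dose_time < times[1L] || dose_time > times[length(times)]) {
      stop("dose_time ", dose_time, " outside trace time range for well ", well)
    }
  }
  structure(list(well = well, times = times, values = values,
                 dose_time = dose_time),
            class = "rtca_trace")
}

#' @export
print.rtca_trace <- function(x, ...) {
  cat(sprintf("<rtca_trace> well %s: %d points, %.2f-%.2f h%s\n",
              x$well, length(x$times), x$times[1L],
              x$times[length(x$times)],
              if (is.null(x$dose_time)) "" else
                sprintf(", dosed at %.2f h", x$dose_time)))
  invisible(x)
}

# ---- plate experiments ------------------------------------------------------

#' Construct a plate experiment
#'
#' Bundles one E-plate run: a shared time grid, a matrix of cell-index values
#' (one column per well), the plate layout, and the compound-addition
#' time(s). Multiple dose times support repeat-dosing designs; trace
#' normalization always references the first one.
#'
#' @param times Shared time grid, hours since seeding, strictly increasing.
#' @param values Numeric matrix, `length(times)` rows, one named column per
#'   well.
#' @param layout Data frame with columns `well`, `role`, `compound_id`,
#'   `concentration_uM`, `replicate_index`.
#' @param dose_times Numeric vector of compound-addition times (hours), one
#'   per administration.
#' @param plate_id Plate identifier string.
#' @return An object of class `rtca_plate`.
#' @export
rtca_plate <- function(times, values, layout, dose_times,
                       plate_id = "plate1") {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(times) < 2L) stop("plate needs at least 2 timepoints")
  if (any(diff(times) <= 0)) stop("non-increasing time grid")
  if (nrow(values) != length(times)) {
    stop("values must have one row per timepoint")
  }
  if (ncol(values) < 1L) stop("no traces in plate")
  if (is.null(colnames(values))) stop("trace columns must be named by well")
  check_wells(colnames(values))
  layout <- as.data.frame(layout, stringsAsFactors = FALSE)
  req <- c("well", "role", "compound_id", "concentration_uM",
           "replicate_index")
  missing_cols <- setdiff(req, names(layout))
  if (length(missing_cols)) {
    stop("layout lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_wells(layout$well)
  if (anyDuplicated(layout$well)) {
    stop("duplicated well(s) in layout: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role)) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  }
  orphan <- setdiff(colnames(values), layout$well)
  if (length(orphan)) {
    stop("trace well(s) absent from layout: ",
         paste(orphan, collapse = ", "))
  }
  missing_trace <- setdiff(layout$well, colnames(values))
  if (length(missing_trace)) {
    stop("layout well(s) absent from time-series data: ",
         paste(missing_trace, collapse = ", "))
  }
  needs_cmpd <- layout$role %in% c("treated", "positive_control")
  if (any(needs_cmpd & (is.na(layout$compound_id) |
                        is.na(layout$concentration_uM)))) {
    stop("treated/positive_control wells need compound_id and concentration")
  }
  veh <- layout$role == "vehicle_control"
  if (any(veh & (!is.na(layout$compound_id) |
                 !is.na(layout$concentration_uM)))) {
    stop("vehicle_control wells must not carry compound_id or concentration")
  }
  if (any(layout$role == "treated") && !any(veh)) {
    stop("at least one vehicle_control well is required when treated wells exist")
  }
  dose_times <- as.numeric(dose_times)
  if (length(dose_times) < 1L) stop("at least one dose time required")
  if (any(dose_times < times[1L]) || any(dose_times > times[length(times)])) {
    stop("dose time(s) outside the recorded time range")
  }
  structure(list(plate_id = plate_id, times = times, values = values,
                 layout = layout, dose_times = sort(dose_times)),
            class = "rtca_plate")
}

#' Extract one well's trace from a plate
#'
#' @param plate An `rtca_plate`.
#' @param well Well address string.
#' @return An `rtca_trace` carrying the plate's first dose time.
#' @export
get_trace <- function(plate, well) {
  stopifnot(inherits(plate, "rtca_plate"))
  if (!well %in% colnames(plate$values)) {
    stop("well ", well, " not present in plate ", plate$plate_id)
  }
  rtca_trace(plate$times, plate$values[, well], well = well,
             dose_time = plate$dose_times[1L])
}

#' @export
print.rtca_plate <- function(x, ...) {
  cat(sprintf("<rtca_plate> %s: %d wells x %d timepoints (%.1f-%.1f h)\n",
              x$plate_id, ncol(x$values), length(x$times),
              x$times[1L], x$times[length(x$times)]))
  cat(sprintf("  dose at %s h; roles: %s\n",
              paste(format(x$dose_times), collapse = ", "),
              paste(sprintf("%s=%d", names(table(x$layout$role)),
                            as.integer(table(x$layout$role))),
                    collapse = " ")))
  invisible(x)
}

#' @export
summary.rtca_plate <- function(object, ...) {
  lay <- object$layout
  treated <- lay[lay$role == "treated", , drop = FALSE]
  cmpds <- sort(unique(treated$compound_id))
  cat(sprintf("Plate %s\n", object$plate_id))
  print(object)
  if (length(cmpds)) {
    cat("  compounds:", paste(cmpds, collapse = ", "), "\n")
    conc <- sort(unique(treated$concentration_uM))
    cat("  concentrations (uM):", paste(format(conc), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot replicate-mean traces of a plate
#'
#' Draws the vehicle-control mean and, for one compound, the replicate-mean
#' trace per concentration, with the first dose time marked.
#'
#' @param x An `rtca_plate`.
#' @param compound_id Compound to plot; default the first treated compound.
#' @param normalized Normalize traces to the last pre-dose point first?
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rtca_plate <- function(x, compound_id = NULL, normalized = TRUE, ...) {
  lay <- x$layout
  if (is.null(compound_id)) {
    cand <- lay$compound_id[lay$role == "treated"]
    if (!length(cand)) stop("no treated wells to plot")
    compound_id <- cand[1L]
  }
  plate <- if (normalized) normalize_plate(x) else x
  veh <- lay$well[lay$role == "vehicle_control"]
  sel <- lay[lay$role == "treated" & lay$compound_id == compound_id, ,
             drop = FALSE]
  if (!nrow(sel)) stop("compound ", compound_id, " not on plate")
  concs <- sort(unique(sel$concentration_uM))
  series <- vapply(concs, function(cc) {
    rowMeans(plate$values[, sel$well[sel$concentration_uM == cc],
                          drop = FALSE])
  }, numeric(length(plate$times)))
  ctrl <- rowMeans(plate$values[, veh, drop = FALSE])
  graphics::matplot(plate$times, cbind(ctrl, series), type = "l", lty = 1,
                    col = seq_len(length(concs) + 1L),
                    xlab = "time since seeding (h)",
                    ylab = if (normalized) "normalized cell index"
                           else "cell index",
                    main = compound_id, ...)
  graphics::abline(v = x$dose_times[1L], lty = 3)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_len(length(concs) + 1L),
                   legend = c("vehicle", paste0(format(concs), " uM")))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a plate experiment from CSV files
#'
#' The time-series file has a first column `time_h` (decimal hours) and one
#' column per well named by its address ("A01".."H12"), one row per
#' timepoint. The layout file has columns `well`, `role`, `compound_id`,
#' `concentration_uM`, `replicate_index` and, in its first data row's
#' optional `dose_times` column, a `;`-separated list of dose times.
#'
#' @param timeseries_path Path to the time-series CSV.
#' @param layout_path Path to the layout CSV.
#' @param dose_times Dose time(s) in hours; overrides any `dose_times`
#'   column in the layout file.
#' @param plate_id Plate identifier; defaults to the time-series file name.
#' @return A validated [rtca_plate()].
#' @export
read_plate <- function(timeseries_path, layout_path, dose_times = NULL,
                       plate_id = NULL) {
  if (!file.exists(timeseries_path)) {
    stop("time-series file not found: ", timeseries_path)
  }
  if (!file.exists(layout_path)) {
    stop("layout file not found: ", layout_path)
  }
  ts <- utils::read.csv(timeseries_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(ts)[1L] != "time_h") {
    stop("malformed header in ", timeseries_path,
         ": first column must be 'time_h', got '", names(ts)[1L], "'")
  }
  if (ncol(ts) < 2L) stop("no trace columns in ", timeseries_path)
  times <- as.numeric(ts$time_h)
  if (anyNA(times)) {
    stop("non-numeric time value in ", timeseries_path, " at line ",
         which(is.na(times))[1L] + 1L)
  }
  if (any(diff(times) <= 0)) {
    stop("non-increasing time column in ", timeseries_path, " at line ",
         which(diff(times) <= 0)[1L] + 2L)
  }
  values <- as.matrix(ts[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  lay <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  if (!"well" %in% names(lay)) {
    stop("malformed header in ", layout_path, ": no 'well' column")
  }
  lay$compound_id[lay$compound_id %in% c("", "NA")] <- NA_character_
  if (is.null(dose_times)) {
    if ("dose_times" %in% names(lay)) {
      dose_times <- as.numeric(strsplit(as.character(lay$dose_times[1L]),
                                        ";", fixed = TRUE)[[1L]])
      lay$dose_times <- NULL
    } else {
      stop("dose_times not given and no dose_times column in ", layout_path)
    }
  }
  if (is.null(plate_id)) {
    plate_id <- sub("\\.[^.]*$", "", basename(timeseries_path))
  }
  rtca_plate(times, values, lay, dose_times, plate_id = plate_id)
}

#' Write a plate experiment to CSV files
#'
#' Inverse of [read_plate()]: values are written with 12 significant digits
#' so a round trip reproduces the plate to better than 1e-9 relative
#' tolerance, and layout fields exactly.
#'
#' @param plate An `rtca_plate`.
#' @param timeseries_path Output path for the time-series CSV.
#' @param layout_path Output path for the layout CSV.
#' @return Invisibly, the plate.
#' @export
write_plate <- function(plate, timeseries_path, layout_path) {
  stopifnot(inherits(plate, "rtca_plate"))
  if (ncol(plate$values) == 0L) stop("no traces to write")
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  ts <- data.frame(time_h = fmt(plate$times), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (w in colnames(plate$values)) ts[[w]] <- fmt(plate$values[, w])
  utils::write.csv(ts, timeseries_path, row.names = FALSE, quote = FALSE)
  lay <- plate$layout
  lay$dose_times <- c(paste(fmt(plate$dose_times), collapse = ";"),
                      rep("", nrow(lay) - 1L))
  utils::write.csv(lay, layout_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(plate)
}

#' Read compound reference labels
#'
#' Labels CSV columns: `compound_id`, `genotoxic_reference`
#' (true/false/empty) and `mechanism_reference` (one of calcium_modulator,
#' antimitotic, dna_damaging, nuclear_receptor, none, or empty).
#'
#' @param path Path to the labels CSV.
#' @return Data frame with typed columns.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "genotoxic_reference", "mechanism_reference")
  miss <- setdiff(req, names(lab))
  if (length(miss)) {
    stop("labels file lacks column(s): ", paste(miss, collapse = ", "))
  }
  g <- tolower(trimws(as.character(lab$genotoxic_reference)))
  lab$genotoxic_reference <- ifelse(g %in% c("true", "1"), TRUE,
                                    ifelse(g %in% c("false", "0"), FALSE, NA))
  m <- trimws(as.character(lab$mechanism_reference))
  m[m == ""] <- NA_character_
  valid <- c("calcium_modulator", "antimitotic", "dna_damaging",
             "nuclear_receptor", "none")
  bad <- setdiff(stats::na.omit(unique(m)), valid)
  if (length(bad)) {
    stop("unknown mechanism label(s): ", paste(bad, collapse = ", "))
  }
  lab$mechanism_reference <- m
  if (anyDuplicated(lab$compound_id)) {
    stop("duplicated compound_id in labels file")
  }
  lab
}
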