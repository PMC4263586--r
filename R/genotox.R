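# Genotoxicity decision rule on normalized impedance traces.
#
# A concentration is scored positive when the treated/control cell-index
# ratio (i) rises above control early after dosing and (ii) subsequently
# falls to at least 50 percent mortality (ratio <= 0.5) within 48 h of
# exposure. Both clauses must hold at the same concentration; a compound is
# positive when any tested concentration is. Concentrations that satisfy
# the elevation clause and approach, but do not reach, 50 percent mortality
# are reported as equivocal and scored negative.

#' Apply the genotoxicity rule to one compound
#'
#' @param treated_by_conc Named list of replicate-mean normalized
#'   [rtca_trace()] objects, names the tested concentrations (uM).
#' @param control Replicate-mean normalized control trace on the same grid.
#' @param dose_time Compound-addition time (h); default the control trace's
#'   dose time.
#' @param rules An [rtca_rules()]; uses `elevation_margin`,
#'   `elevation_window`, `mortality_window`, `mortality_ratio` and
#'   `equivocal_band`.
#' @param compound_id Identifier recorded on the call.
#' @return Object of class `genotox_call`: `compound_id`, `positive`,
#'   `equivocal`, `evidence_concentration` (lowest positive concentration,
#'   `NA` when negative), `peak_excess` (largest post-dose ratio over all
#'   concentrations) and `min_relative_48h` (smallest ratio within the
#'   mortality window over all concentrations).
#' @export
call_genotoxicity <- function(treated_by_conc, control, dose_time = NULL,
                              rules = rtca_rules(),
                              compound_id = "compound") {
  if (!length(treated_by_conc)) stop("no concentrations supplied")
  stopifnot(inherits(control, "rtca_trace"))
  if (is.null(dose_time)) dose_time <- control$dose_time
  if (is.null(dose_time)) stop("dose_time required")
  tmax <- max(control$times)
  if (dose_time + rules$mortality_window > tmax + 1e-9) {
    stop("mortality window (", rules$mortality_window,
         " h post-dose) exceeds the recorded trace extent")
  }
  concs <- as.numeric(names(treated_by_conc))
  if (anyNA(concs)) stop("treated_by_conc names must be concentrations")
  pos_conc <- c()
  equivocal <- FALSE
  peak_excess <- -Inf
  min_rel_48 <- Inf
  for (i in seq_along(concs)) {
    tr <- treated_by_conc[[i]]
    stopifnot(inherits(tr, "rtca_trace"))
    if (!identical(tr$times, control$times)) {
      stop("treated and control traces are not on a shared grid")
    }
    post <- tr$times > dose_time
    rs <- .ratio_series(tr$times[post], tr$values[post],
                        control$values[post])
    u <- rs$times - dose_time
    peak_excess <- max(peak_excess, max(rs$ratio))
    within48 <- u <= rules$mortality_window
    if (any(within48)) {
      min_rel_48 <- min(min_rel_48, min(rs$ratio[within48]))
    }
    elev <- which(u <= rules$elevation_window &
                    rs$ratio > 1 + rules$elevation_margin)
    if (!length(elev)) next
    after <- which(seq_along(u) > elev[1L] & within48)
    if (!length(after)) next
    bottom <- min(rs$ratio[after])
    if (bottom <= rules$mortality_ratio) {
      pos_conc <- c(pos_conc, concs[i])
    } else if (bottom <= rules$mortality_ratio + rules$equivocal_band) {
      equivocal <- TRUE
    }
  }
  positive <- length(pos_conc) > 0L
  structure(list(compound_id = compound_id, positive = positive,
                 equivocal = !positive && equivocal,
                 evidence_concentration =
                   if (positive) min(pos_conc) else NA_real_,
                 peak_excess = peak_excess,
                 min_relative_48h = min_rel_48),
            class = "genotox_call")
}

#' @export
print.genotox_call <- function(x, ...) {
  verdict <- if (x$positive) "POSITIVE" else if (x$equivocal) {
    "negative (equivocal)"
  } else "negative"
  cat(sprintf("<genotox_call> %s: %s", x$compound_id, verdict))
  if (x$positive) {
    cat(sprintf(" at %g uM", x$evidence_concentration))
  }
  cat(sprintf(" [peak %.2f, min(48h) %.2f]\n", x$peak_excess,
              x$min_relative_48h))
  invisible(x)
}

#' Apply the genotoxicity rule to every compound on a plate
#'
#' @param plate An [rtca_plate()].
#' @param rules An [rtca_rules()].
#' @return Data frame of class `rtca_genotox` with one row per compound:
#'   `compound_id`, `positive`, `equivocal`, `evidence_concentration_uM`,
#'   `peak_excess`, `min_relative_48h`.
#' @export
genotox_plate <- function(plate, rules = rtca_rules()) {
  pm <- .plate_means(plate, rules)
  rows <- lapply(names(pm$treated), function(cid) {
    g <- call_genotoxicity(pm$treated[[cid]], pm$control, pm$dose_time,
                           rules, compound_id = cid)
    data.frame(compound_id = cid, positive = g$positive,
               equivocal = g$equivocal,
               evidence_concentration_uM = g$evidence_concentration,
               peak_excess = g$peak_excess,
               min_relative_48h = g$min_relative_48h,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rtca_genotox", "data.frame")
  out
}

#' Confusion counts with predictivity percentages
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `rtca_confusion` with `sensitivity`
#'   (100 tp/(tp+fn)), `specificity` (100 tn/(tn+fp)) and `concordance`
#'   (100 (tp+tn)/n), each rounded to 1 decimal; a metric with an empty
#'   denominator is `NA` (not applicable), never a division by zero.
#' @export
#' @examples
#' confusion_summary(tp = 14, fp = 2, tn = 50, fn = 15)
confusion_summary <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n = tp + fp + tn + fn,
                 sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 concordance = pct(tp + tn, tp + fp + tn + fn)),
            class = "rtca_confusion")
}

#' @export
print.rtca_confusion <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not applicable" else sprintf("%.1f%%", v)
  cat(sprintf(
    "<rtca_confusion> n=%d (tp=%d fp=%d tn=%d fn=%d)\n  sensitivity %s, specificity %s, concordance %s\n",
    x$n, x$tp, x$fp, x$tn, x$fn, fmt(x$sensitivity), fmt(x$specificity),
    fmt(x$concordance)))
  invisible(x)
}

#' Evaluate genotoxicity predictivity against reference labels
#'
#' Equivocal calls are reported separately but scored negative. With a
#' grouping, per-group summaries are returned alongside the pooled one;
#' pooled counts always equal the per-group sums.
#'
#' @param calls Data frame with `compound_id`, `positive` and optionally
#'   `equivocal` (e.g. [genotox_plate()] output).
#' @param labels Data frame with `compound_id` and `genotoxic_reference`
#'   (logical).
#' @param grouping Optional named vector or data frame
#'   (`compound_id`, `group`) assigning compounds to projects.
#' @return List with `pooled` ([confusion_summary()]), `groups` (named list
#'   of summaries, present when `grouping` is given) and `n_equivocal`.
#' @export
evaluate_predictivity <- function(calls, labels, grouping = NULL) {
  calls <- as.data.frame(calls)
  m <- match(calls$compound_id, labels$compound_id)
  if (anyNA(m)) {
    stop("no genotoxicity label for compound(s): ",
         paste(calls$compound_id[is.na(m)], collapse = ", "))
  }
  truth <- labels$genotoxic_reference[m]
  if (anyNA(truth)) {
    stop("missing genotoxic_reference for compound(s): ",
         paste(calls$compound_id[is.na(truth)], collapse = ", "))
  }
  pred <- calls$positive
  count <- function(sel) {
    confusion_summary(tp = sum(sel & pred & truth),
                      fp = sum(sel & pred & !truth),
                      tn = sum(sel & !pred & !truth),
                      fn = sum(sel & !pred & truth))
  }
  all_sel <- rep(TRUE, nrow(calls))
  out <- list(pooled = count(all_sel),
              n_equivocal = if ("equivocal" %in% names(calls)) {
                sum(calls$equivocal)
              } else 0L)
  if (!is.null(grouping)) {
    if (is.data.frame(grouping)) {
      g <- grouping$group[match(calls$compound_id, grouping$compound_id)]
    } else {
      g <- grouping[calls$compound_id]
    }
    if (anyNA(g)) stop("grouping does not cover every called compound")
    out$groups <- lapply(split(seq_len(nrow(calls)), g), function(idx) {
      sel <- all_sel & seq_len(nrow(calls)) %in% idx
      count(sel)
    })
  }
  out
}
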