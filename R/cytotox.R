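# Endpoint cytotoxicity: percent viability relative to vehicle controls for
# the impedance readout (normalized cell index) and an orthogonal
# fluorescence viability readout, their cross-readout correlation, and LC50
# by two-point bracketing linear regression around the 50 percent crossing.

#' Endpoint percent viability relative to vehicle controls
#'
#' For the impedance readout, uses the normalized cell index at
#' `endpoint_time`; the vehicle-control replicate mean is set to 100
#' percent. For the fluorescence readout, supply per-well endpoint signals.
#'
#' @param plate An [rtca_plate()].
#' @param endpoint_time Endpoint (hours since seeding); default the last
#'   recorded time. Must be a grid point.
#' @param readout `"impedance"` or `"fluorescence"`.
#' @param fluorescence Data frame with columns `well` and `signal`
#'   (endpoint fluorescence per well); required for that readout.
#' @return Data frame with `compound_id`, `concentration_uM`, `readout`,
#'   `percent_of_control`.
#' @export
endpoint_viability <- function(plate, endpoint_time = NULL,
                               readout = c("impedance", "fluorescence"),
                               fluorescence = NULL) {
  stopifnot(inherits(plate, "rtca_plate"))
  readout <- match.arg(readout)
  if (is.null(endpoint_time)) endpoint_time <- max(plate$times)
  lay <- plate$layout
  veh <- lay$well[lay$role == "vehicle_control"]
  if (!length(veh)) stop("no vehicle-control wells on plate")
  if (readout == "impedance") {
    nplate <- normalize_plate(plate)
    idx <- which(nplate$times == endpoint_time)
    if (length(idx) != 1L) {
      stop("endpoint_time ", endpoint_time, " is not on the plate grid")
    }
    signal <- nplate$values[idx, ]
  } else {
    if (is.null(fluorescence)) {
      stop("fluorescence readout requires a well/signal table")
    }
    if (!all(c("well", "signal") %in% names(fluorescence))) {
      stop("fluorescence table needs columns 'well' and 'signal'")
    }
    signal <- fluorescence$signal[match(colnames(plate$values),
                                        fluorescence$well)]
    names(signal) <- colnames(plate$values)
    if (anyNA(signal[lay$well[lay$role != "blank"]])) {
      stop("fluorescence signal missing for some non-blank wells")
    }
  }
  ctrl <- mean(signal[veh])
  if (is.na(ctrl) || ctrl <= 0) {
    stop("vehicle-control mean signal is not positive; cannot express ",
         "percent of control")
  }
  treated <- lay[lay$role == "treated", , drop = FALSE]
  combos <- unique(treated[, c("compound_id", "concentration_uM")])
  combos <- combos[order(combos$compound_id, combos$concentration_uM), ,
                   drop = FALSE]
  pct <- mapply(function(cid, cc) {
    wells <- treated$well[treated$compound_id == cid &
                            treated$concentration_uM == cc]
    100 * mean(signal[wells]) / ctrl
  }, combos$compound_id, combos$concentration_uM)
  data.frame(compound_id = combos$compound_id,
             concentration_uM = combos$concentration_uM,
             readout = readout, percent_of_control = as.numeric(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-readout correlation of percent-viability values
#'
#' Pearson product-moment correlation of matched (compound, concentration)
#' percent-of-control pairs, reported as a percentage.
#'
#' @param impedance,fluorescence Data frames as returned by
#'   [endpoint_viability()] (or any with `compound_id`,
#'   `concentration_uM`, `percent_of_control`).
#' @return List with `correlation_pct` (Pearson r x 100, 1 decimal; `NA`
#'   when fewer than 3 matched pairs or a readout has zero variance) and
#'   `n_pairs`.
#' @export
cross_readout_correlation <- function(impedance, fluorescence) {
  key <- function(d) paste(d$compound_id, d$concentration_uM, sep = "@")
  ki <- key(impedance)
  kf <- key(fluorescence)
  shared <- intersect(ki, kf)
  x <- impedance$percent_of_control[match(shared, ki)]
  y <- fluorescence$percent_of_control[match(shared, kf)]
  if (length(shared) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(correlation_pct = NA_real_, n_pairs = length(shared)))
  }
  list(correlation_pct = round(100 * stats::cor(x, y), 1),
       n_pairs = length(shared))
}

#' LC50 by bracketing two-point linear regression
#'
#' Selects the adjacent dose pair whose viabilities straddle 50 percent
#' (when several pairs straddle, the one nearest 50 by summed absolute
#' deviation; ties go to the lowest doses), fits y = a x + b through those
#' two points on the linear concentration scale, and solves for y = 50. A
#' dose at exactly 50 percent viability is itself the LC50. When every
#' viability stays above 50 the LC50 is reported as beyond the top dose;
#' when the lowest dose already kills more than half the cells it is
#' reported as below the lowest dose.
#'
#' @param doses Tested concentrations (uM), strictly increasing, length
#'   >= 2.
#' @param viability Percent viability at each dose (control = 100).
#' @param readout Readout label carried on the result.
#' @param compound_id Compound label carried on the result.
#' @param log_scale Fit on log10(concentration) instead of the linear
#'   scale.
#' @return Object of class `rtca_lc50`: `lc50` (uM, `NA` when flagged),
#'   `flag` (`"ok"`, `"exact"`, `"> top dose"`, `"< lowest dose"`),
#'   `bracketing_pair` (two-row data frame), `slope_a`, `intercept_b`.
#' @export
#' @examples
#' compute_lc50(c(1, 10), c(80, 20)) # 5.5 uM
compute_lc50 <- function(doses, viability, readout = "impedance",
                         compound_id = "compound", log_scale = FALSE) {
  doses <- as.numeric(doses)
  viability <- as.numeric(viability)
  if (length(doses) < 2L) stop("need at least 2 dose-viability points")
  if (length(doses) != length(viability)) {
    stop("doses and viability must have equal length")
  }
  if (any(duplicated(doses))) stop("non-monotone duplicate doses")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (log_scale && any(doses <= 0)) {
    stop("log-scale fit requires positive doses")
  }
  res <- structure(list(compound_id = compound_id, readout = readout,
                        lc50 = NA_real_, flag = NA_character_,
                        bracketing_pair = NULL, slope_a = NA_real_,
                        intercept_b = NA_real_, log_scale = log_scale),
                   class = "rtca_lc50")
  exact <- which(viability == 50)
  if (length(exact)) {
    i <- exact[1L]
    res$lc50 <- doses[i]
    res$flag <- "exact"
    res$bracketing_pair <- data.frame(concentration_uM = doses[i],
                                      viability_pct = viability[i])
    return(res)
  }
  if (viability[1L] < 50) {
    res$flag <- "< lowest dose"
    return(res)
  }
  straddle <- which((viability[-length(viability)] - 50) *
                      (viability[-1L] - 50) < 0)
  if (!length(straddle)) {
    res$flag <- if (all(viability > 50)) "> top dose" else "< lowest dose"
    return(res)
  }
  dev <- abs(viability[straddle] - 50) + abs(viability[straddle + 1L] - 50)
  i <- straddle[which.min(dev)]  # which.min takes the first (lowest doses) on ties
  x <- if (log_scale) log10(doses) else doses
  a <- (viability[i + 1L] - viability[i]) / (x[i + 1L] - x[i])
  b <- viability[i] - a * x[i]
  xc <- (50 - b) / a
  res$lc50 <- if (log_scale) 10^xc else xc
  res$flag <- "ok"
  res$slope_a <- a
  res$intercept_b <- b
  res$bracketing_pair <- data.frame(
    concentration_uM = doses[c(i, i + 1L)],
    viability_pct = viability[c(i, i + 1L)])
  res
}

#' @export
print.rtca_lc50 <- function(x, ...) {
  lab <- switch(x$flag,
                "ok" = sprintf("%.4g uM", x$lc50),
                "exact" = sprintf("%.4g uM (tested dose at exactly 50%%)",
                                  x$lc50),
                "> top dose" = "> top dose tested",
                "< lowest dose" = "< lowest dose tested")
  cat(sprintf("<rtca_lc50> %s [%s]: LC50 %s\n", x$compound_id, x$readout,
              lab))
  invisible(x)
}

#' Endpoint cytotoxicity report for a plate
#'
#' Computes percent viability per compound and concentration (impedance
#' and, when supplied, fluorescence), the LC50 per compound and readout,
#' and the cross-readout correlation.
#'
#' @param plate An [rtca_plate()].
#' @param endpoint_time Endpoint in hours; default the last recorded time.
#' @param fluorescence Optional well/signal table for the orthogonal
#'   readout.
#' @param log_scale Passed to [compute_lc50()].
#' @return List with `viability` (long data frame), `lc50` (data frame with
#'   `compound_id`, `readout`, `lc50_uM`, `lc50_flag`) and
#'   `correlation_pct` (`NA` without a fluorescence readout).
#' @export
cytotox_report <- function(plate, endpoint_time = NULL, fluorescence = NULL,
                           log_scale = FALSE) {
  imp <- endpoint_viability(plate, endpoint_time, "impedance")
  via <- imp
  correlation <- NA_real_
  flu <- NULL
  if (!is.null(fluorescence)) {
    flu <- endpoint_viability(plate, endpoint_time, "fluorescence",
                              fluorescence = fluorescence)
    via <- rbind(imp, flu)
    correlation <- cross_readout_correlation(imp, flu)$correlation_pct
  }
  lc_rows <- list()
  for (tab in list(imp, flu)) {
    if (is.null(tab)) next
    for (cid in unique(tab$compound_id)) {
      sub <- tab[tab$compound_id == cid, , drop = FALSE]
      sub <- sub[order(sub$concentration_uM), , drop = FALSE]
      r <- compute_lc50(sub$concentration_uM, sub$percent_of_control,
                        readout = sub$readout[1L], compound_id = cid,
                        log_scale = log_scale)
      lc_rows[[length(lc_rows) + 1L]] <- data.frame(
        compound_id = cid, readout = sub$readout[1L], lc50_uM = r$lc50,
        lc50_flag = r$flag, stringsAsFactors = FALSE)
    }
  }
  list(viability = via, lc50 = do.call(rbind, lc_rows),
       correlation_pct = correlation)
}
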