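# Rule-based classification of time-dependent cell response profiles
# (TCRPs). Replaces by-eye comparison of normalized impedance curves with
# explicit, configurable shape rules over a small set of curve features.

#' Classification rule thresholds
#'
#' Every threshold used by the shape classifier and the genotoxicity caller
#' lives here. All ratios are treated/control normalized-cell-index ratios;
#' times are hours post-dose.
#'
#' @param slope_threshold Minimum magnitude of the early negative ratio
#'   slope (per hour) for the rapid calcium-modulator drop.
#' @param mortality_ratio Treated/control ratio at or below which cells are
#'   counted as >= 50 percent dead (0.5, matching controls set to 100
#'   percent).
#' @param elevation_margin Fractional excess over control required to call
#'   the ratio "elevated" (default 0.10, i.e. ratio > 1.1).
#' @param flat_threshold Maximum flatness statistic (residual sd of the
#'   post-dose trace after linear detrending, relative to the dose-time
#'   level) for the antimitotic call.
#' @param growth_margin Minimum control endpoint/dose-time growth factor
#'   required before "treated stays flat" is informative.
#' @param time_to_min_max Latest ratio-minimum time (h post-dose) still
#'   compatible with the rapid calcium-modulator drop (default 10).
#' @param persistence_min Minimum fraction of the post-dose grid with an
#'   elevated ratio for the nuclear-receptor call.
#' @param persistence_margin Excess over 1 a ratio must show to count as
#'   elevated in the persistence feature (default 0: any point above
#'   control counts).
#' @param antimitotic_band Allowed treated endpoint/dose-time ratio band for
#'   the growth-arrest call.
#' @param elevation_window Post-dose window (h) in which the genotoxicity
#'   rule looks for elevation above control.
#' @param mortality_window Post-dose window (h) in which >= 50 percent
#'   mortality must be reached (default 48).
#' @param equivocal_band Width of the near-miss band above
#'   `mortality_ratio` reported as equivocal.
#' @param early_window Window (h post-dose) for the early-slope feature.
#' @param endpoint_offset Endpoint used by the shape features, hours
#'   post-dose (default 48).
#' @param exclude_degenerate Exclude wells flagged for a reference cell
#'   index below `quality_floor` from replicate means?
#' @param quality_floor Minimum acceptable pre-dose cell index.
#' @return Named list of class `rtca_rules`.
#' @export
rtca_rules <- function(slope_threshold = 0.15, mortality_ratio = 0.5,
                       elevation_margin = 0.10, flat_threshold = 0.15,
                       growth_margin = 1.5, time_to_min_max = 10,
                       persistence_min = 0.8, persistence_margin = 0,
                       antimitotic_band = c(0.7, 1.3),
                       elevation_window = 24, mortality_window = 48,
                       equivocal_band = 0.05, early_window = 2,
                       endpoint_offset = 48, exclude_degenerate = TRUE,
                       quality_floor = 0.5) {
  structure(list(slope_threshold = slope_threshold,
                 mortality_ratio = mortality_ratio,
                 elevation_margin = elevation_margin,
                 flat_threshold = flat_threshold,
                 growth_margin = growth_margin,
                 time_to_min_max = time_to_min_max,
                 persistence_min = persistence_min,
                 persistence_margin = persistence_margin,
                 antimitotic_band = antimitotic_band,
                 elevation_window = elevation_window,
                 mortality_window = mortality_window,
                 equivocal_band = equivocal_band,
                 early_window = early_window,
                 endpoint_offset = endpoint_offset,
                 exclude_degenerate = exclude_degenerate,
                 quality_floor = quality_floor),
            class = "rtca_rules")
}

# treated/control ratio with undefined points (control <= 0) dropped
.ratio_series <- function(times, treated, control) {
  ok <- control > 0
  list(times = times[ok], ratio = treated[ok] / control[ok],
       n_undefined = sum(!ok))
}

#' Extract shape features from a treated/control trace pair
#'
#' Works on replicate-mean normalized traces sharing one grid. Ratios are
#' treated/control; points where the control is non-positive are excluded
#' from every feature window.
#'
#' @param treated,control Normalized [rtca_trace()] objects (replicate
#'   means) on a shared grid.
#' @param dose_time Compound-addition time (h); defaults to the treated
#'   trace's dose time.
#' @param rules An [rtca_rules()] configuration.
#' @return Object of class `tcrp_features`: `early_slope` (steepest
#'   negative central-difference slope of the ratio in the first
#'   `early_window` hours post-dose), `time_to_min` (h post-dose of the
#'   ratio minimum), `min_relative`, `peak_relative_0_12h`,
#'   `endpoint_relative` (ratio at `endpoint_offset` h post-dose),
#'   `flatness`, `elevation_persistence`, `endpoint_vs_dose` (treated
#'   endpoint over treated dose-time level) and `control_growth` (same for
#'   the control).
#' @export
extract_features <- function(treated, control, dose_time = NULL,
                             rules = rtca_rules()) {
  stopifnot(inherits(treated, "rtca_trace"), inherits(control, "rtca_trace"))
  if (!identical(treated$times, control$times)) {
    stop("treated and control traces are not on a shared grid")
  }
  if (is.null(dose_time)) dose_time <- treated$dose_time
  if (is.null(dose_time) || !dose_time %in% treated$times) {
    stop("dose_time must be a grid point of the traces")
  }
  t <- treated$times
  post <- t > dose_time
  if (sum(post) < 3L) stop("too few post-dose timepoints")
  rs <- .ratio_series(t[post], treated$values[post], control$values[post])
  if (length(rs$ratio) < 3L) {
    stop("control non-positive at nearly all post-dose points")
  }
  u <- rs$times - dose_time

  # steepest negative ratio slope in the early window, central differences
  early <- which(u <= rules$early_window)
  early_slope <- 0
  if (length(early) >= 3L) {
    i <- early[-c(1L, length(early))]
    slopes <- (rs$ratio[i + 1L] - rs$ratio[i - 1L]) /
      (rs$times[i + 1L] - rs$times[i - 1L])
    early_slope <- min(slopes, 0)
  }

  i_min <- which.min(rs$ratio)
  peak_idx <- u > 0 & u <= 12
  endpoint_target <- dose_time + rules$endpoint_offset
  i_end <- which.min(abs(rs$times - min(endpoint_target, max(rs$times))))

  # flatness: residual sd of the treated post-dose values around a linear
  # trend, relative to the treated level at dose time
  dose_idx <- which(t == dose_time)
  level <- treated$values[dose_idx]
  tv <- treated$values[post]
  fit <- stats::lm.fit(cbind(1, t[post]), tv)
  flatness <- stats::sd(fit$residuals) / abs(level)

  end_grid <- which.min(abs(t - min(endpoint_target, max(t))))
  structure(list(
    early_slope = early_slope,
    time_to_min = u[i_min],
    min_relative = rs$ratio[i_min],
    peak_relative_0_12h = if (any(peak_idx)) max(rs$ratio[peak_idx]) else NA_real_,
    endpoint_relative = rs$ratio[i_end],
    flatness = flatness,
    elevation_persistence = mean(rs$ratio > 1 + rules$persistence_margin),
    endpoint_vs_dose = treated$values[end_grid] / level,
    control_growth = control$values[end_grid] / control$values[dose_idx],
    n_undefined = rs$n_undefined
  ), class = "tcrp_features")
}

.rule_match <- function(f, class, rules) {
  switch(class,
    dna_damaging =
      !is.na(f$peak_relative_0_12h) &&
      f$peak_relative_0_12h >= 1 + rules$elevation_margin &&
      f$endpoint_relative <= rules$mortality_ratio,
    calcium_modulator =
      f$time_to_min <= rules$time_to_min_max &&
      f$early_slope <= -rules$slope_threshold &&
      f$min_relative <= rules$mortality_ratio,
    nuclear_receptor =
      f$elevation_persistence >= rules$persistence_min &&
      f$endpoint_relative >= 1 + rules$elevation_margin,
    antimitotic =
      f$flatness <= rules$flat_threshold &&
      f$endpoint_vs_dose >= rules$antimitotic_band[1L] &&
      f$endpoint_vs_dose <= rules$antimitotic_band[2L] &&
      f$control_growth >= rules$growth_margin,
    cytotoxic =
      f$min_relative <= rules$mortality_ratio &&
      f$time_to_min > rules$time_to_min_max,
    stop("unknown class ", class))
}

# precedence when several rules match at one concentration
CLASS_PRECEDENCE <- c("dna_damaging", "calcium_modulator",
                      "nuclear_receptor", "antimitotic", "cytotoxic")

#' Classify a compound's response signature across concentrations
#'
#' Concentrations are scanned from highest to lowest; the first
#' concentration whose features match a class rule determines the call
#' (reference signatures appear at high dose, while a first-match scan
#' still catches responses present at a single intermediate dose). On a
#' multi-match at one concentration the precedence is DNA damaging >
#' calcium modulator > nuclear receptor > antimitotic > cytotoxic.
#'
#' @param features_by_conc Named list of [extract_features()] results;
#'   names are the tested concentrations (uM).
#' @param rules An [rtca_rules()].
#' @return List with `assigned_class` (one of the four mechanism classes,
#'   `"cytotoxic"`, or `"none"`) and `evidence_concentration` (uM, `NA`
#'   when no rule fired).
#' @export
classify_signature <- function(features_by_conc, rules = rtca_rules()) {
  if (!length(features_by_conc)) stop("no concentrations to classify")
  concs <- as.numeric(names(features_by_conc))
  if (anyNA(concs)) stop("features_by_conc names must be concentrations")
  for (i in order(concs, decreasing = TRUE)) {
    f <- features_by_conc[[i]]
    for (cl in CLASS_PRECEDENCE) {
      if (.rule_match(f, cl, rules)) {
        return(list(assigned_class = cl, evidence_concentration = concs[i]))
      }
    }
  }
  list(assigned_class = "none", evidence_concentration = NA_real_)
}

# replicate-mean normalized traces per compound/concentration, plus the
# vehicle-control mean; degenerate wells optionally excluded
.plate_means <- function(plate, rules) {
  nplate <- normalize_plate(plate, quality_floor = rules$quality_floor)
  degen <- attr(nplate, "degenerate_wells")
  usable <- function(wells) {
    if (rules$exclude_degenerate) wells <- setdiff(wells, degen)
    wells
  }
  lay <- plate$layout
  veh <- usable(lay$well[lay$role == "vehicle_control"])
  if (!length(veh)) stop("no usable vehicle-control wells")
  d <- plate$dose_times[1L]
  mk <- function(wells) {
    rtca_trace(nplate$times,
               rowMeans(nplate$values[, wells, drop = FALSE]),
               well = wells[1L], dose_time = d)
  }
  control <- mk(veh)
  treated <- lay[lay$role == "treated", , drop = FALSE]
  by_cmpd <- list()
  for (cid in unique(treated$compound_id)) {
    sub <- treated[treated$compound_id == cid, , drop = FALSE]
    concs <- sort(unique(sub$concentration_uM))
    means <- list()
    for (cc in concs) {
      wells <- usable(sub$well[sub$concentration_uM == cc])
      if (length(wells)) means[[as.character(cc)]] <- mk(wells)
    }
    by_cmpd[[cid]] <- means
  }
  list(control = control, treated = by_cmpd, dose_time = d)
}

#' Classify every compound on a plate
#'
#' Normalizes the plate, averages replicates, extracts shape features per
#' concentration and applies [classify_signature()].
#'
#' @param plate An [rtca_plate()].
#' @param rules An [rtca_rules()].
#' @param model_id Cellular model identifier recorded on the calls
#'   (defaults to the plate id).
#' @param references Optional reference table with `compound_id` and
#'   `mechanism_reference`; adds a 0/1 `score` column.
#' @return Data frame of class `rtca_calls`: `compound_id`, `model_id`,
#'   `assigned_class`, `evidence_concentration_uM` (and `score`).
#' @export
classify_plate <- function(plate, rules = rtca_rules(),
                           model_id = plate$plate_id, references = NULL) {
  pm <- .plate_means(plate, rules)
  out <- list()
  for (cid in names(pm$treated)) {
    feats <- lapply(pm$treated[[cid]], extract_features,
                    control = pm$control, dose_time = pm$dose_time,
                    rules = rules)
    call <- classify_signature(feats, rules)
    out[[cid]] <- data.frame(compound_id = cid, model_id = model_id,
                             assigned_class = call$assigned_class,
                             evidence_concentration_uM =
                               call$evidence_concentration,
                             stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  if (!is.null(references)) {
    ref_col <- if ("mechanism_reference" %in% names(references)) {
      "mechanism_reference"
    } else "archetype"
    m <- match(calls$compound_id, references$compound_id)
    if (anyNA(m)) {
      stop("no reference mechanism for compound(s): ",
           paste(calls$compound_id[is.na(m)], collapse = ", "))
    }
    calls$score <- as.integer(calls$assigned_class == references[[ref_col]][m])
  }
  class(calls) <- c("rtca_calls", "data.frame")
  calls
}

#' Per-model and combined success percentages from a 0/1 score matrix
#'
#' @param score_matrix Matrix or data frame of 0/1 reproduction scores,
#'   one row per compound, one column per cellular model.
#' @return List with `per_model` (named percentages, 1 decimal),
#'   `combined` (percentage of compounds scoring 1 in at least one model)
#'   and `n_compounds`.
#' @export
#' @examples
#' signature_success(cbind(m1 = c(1, 1, 0), m2 = c(1, 0, 0)))
signature_success <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (!all(m %in% c(0, 1))) stop("scores must be 0 or 1")
  if (!nrow(m)) stop("empty score matrix")
  per_model <- round(100 * colSums(m) / nrow(m), 1)
  combined <- round(100 * sum(apply(m, 1L, max)) / nrow(m), 1)
  list(per_model = per_model, combined = combined, n_compounds = nrow(m))
}

#' Score signature reproduction against reference mechanisms
#'
#' Each call scores 1 when its assigned class equals the compound's
#' reference mechanism. Per model, success is the percentage of compounds
#' scoring 1; combined success counts a compound once it scores 1 in at
#' least one model.
#'
#' @param calls Data frame of calls (e.g. rbind of [classify_plate()]
#'   results for several cellular models) with `compound_id`, `model_id`
#'   and `assigned_class` or a precomputed `score`.
#' @param references Data frame with `compound_id` and
#'   `mechanism_reference`; required when `calls` has no `score` column.
#' @return List with `per_model`, `combined`, `n_compounds` (as
#'   [signature_success()]) plus the underlying `score_matrix`.
#' @export
score_reproduction <- function(calls, references = NULL) {
  calls <- as.data.frame(calls)
  if (!"score" %in% names(calls)) {
    if (is.null(references)) {
      stop("references required when calls carry no score column")
    }
    m <- match(calls$compound_id, references$compound_id)
    if (anyNA(m)) {
      stop("no reference mechanism for compound(s): ",
           paste(unique(calls$compound_id[is.na(m)]), collapse = ", "))
    }
    calls$score <- as.integer(calls$assigned_class ==
                                references$mechanism_reference[m])
  }
  cmpds <- unique(calls$compound_id)
  models <- unique(calls$model_id)
  sm <- matrix(0L, nrow = length(cmpds), ncol = length(models),
               dimnames = list(cmpds, models))
  for (i in seq_len(nrow(calls))) {
    sm[calls$compound_id[i], calls$model_id[i]] <- calls$score[i]
  }
  res <- signature_success(sm)
  res$score_matrix <- sm
  res
}
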