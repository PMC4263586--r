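# Seeded generator of synthetic plate experiments.
#
# Each well follows a parametric archetype of the characteristic impedance
# response shapes: logistic control growth; gradual exponential cell-index
# decline (cytotoxic); rapid drop bottoming out 5-10 h after dosing (calcium
# modulator); growth arrest with a flat/wavy cell index (antimitotic);
# elevation above control over ~12 h followed by an apoptotic decline below
# half of control within 48 h (DNA damaging / genotoxic); and sustained
# elevation above control (nuclear receptor). Effect magnitude scales with
# Hill occupancy h(c) = c^s / (c^s + potency^s). Noise is multiplicative
# log-normal with marginal sd `noise_sd` and exponential temporal
# autocorrelation (Ornstein-Uhlenbeck on the log scale), so traces are
# smooth the way real impedance recordings are.

ARCHETYPES <- c("control", "cytotoxic", "calcium_modulator", "antimitotic",
                "dna_damaging", "nuclear_receptor")
MECHANISM_CLASSES <- c("calcium_modulator", "antimitotic", "dna_damaging",
                       "nuclear_receptor")

# deterministic per-well RNG substream: hashing (plate_id, well) means
# adding a compound never perturbs other wells' draws
.well_seed <- function(seed, plate_id, well) {
  s <- paste(plate_id, well, sep = "/")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 2654435) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# log-scale OU noise: marginal N(0, sd^2), corr(dt) = exp(-dt/tau)
.ou_noise <- function(times, sd, tau = 1) {
  n <- length(times)
  if (sd <= 0) return(rep(0, n))
  eps <- numeric(n)
  eps[1L] <- stats::rnorm(1L, 0, sd)
  if (n > 1L) {
    phi <- exp(-diff(times) / tau)
    innov <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) eps[i] <- phi[i - 1L] * eps[i - 1L] + innov[i - 1L]
  }
  eps
}

#' Logistic growth parameters for control wells
#'
#' @param K Plateau cell index (> 0), default 4.
#' @param r Growth rate per hour (> 0), default 0.2.
#' @param t0 Logistic midpoint in hours since seeding, default 18 (so cells
#'   are in mid-exponential growth at a typical overnight dose time).
#' @return List of growth parameters.
#' @export
growth_params <- function(K = 4, r = 0.2, t0 = 18) {
  if (K <= 0) stop("logistic plateau K must be positive")
  if (r <= 0) stop("growth rate r must be positive")
  list(K = K, r = r, t0 = t0)
}

.logistic <- function(times, g) g$K / (1 + exp(-g$r * (times - g$t0)))

#' Archetype parameters for a simulated compound
#'
#' @param archetype One of `"control"`, `"cytotoxic"`,
#'   `"calcium_modulator"`, `"antimitotic"`, `"dna_damaging"`,
#'   `"nuclear_receptor"`.
#' @param potency Hill midpoint (uM) of the concentration-effect curve.
#' @param hill_slope Hill slope (> 0).
#' @param effect_delay Hours post-dose at which the calcium-modulator drop
#'   bottoms out (the field-reported window is 5--10 h).
#' @param decline_rate Exponential decline rate per hour (cytotoxic decline;
#'   DNA-damaging post-peak apoptotic decline).
#' @param elevation_factor Peak treated/control ratio for the DNA-damaging
#'   and nuclear-receptor archetypes (>= 1).
#' @param wobble_amplitude Amplitude (cell-index units) of the antimitotic
#'   "wavy" term.
#' @param wobble_period Period (hours) of the wavy term (> 0).
#' @param rise_time Hours over which the elevated archetypes climb to their
#'   peak ratio (default 12).
#' @param drop_depth Fractional cell-index loss at the calcium-modulator
#'   minimum (0--1).
#' @param drop_tau Time constant (h) of the rapid calcium-modulator drop.
#' @param recovery_rate Slow post-minimum ratio recovery (per hour) making
#'   the calcium-modulator minimum unique.
#' @return An object of class `archetype_params`.
#' @export
archetype_params <- function(archetype, potency = 3, hill_slope = 1.5,
                             effect_delay = 7, decline_rate = NULL,
                             elevation_factor = 1.5, wobble_amplitude = 0.3,
                             wobble_period = 24, rise_time = 12,
                             drop_depth = 0.95, drop_tau = 1,
                             recovery_rate = 0.01) {
  archetype <- match.arg(archetype, ARCHETYPES)
  if (is.null(decline_rate)) {
    decline_rate <- if (archetype == "dna_damaging") 0.10 else 0.08
  }
  if (potency <= 0) stop("potency must be positive")
  if (hill_slope <= 0) stop("hill_slope must be positive")
  if (effect_delay < 0) stop("effect_delay must be non-negative")
  if (decline_rate < 0) stop("decline_rate must be non-negative")
  if (elevation_factor < 1) stop("elevation_factor must be >= 1")
  if (wobble_amplitude < 0) stop("wobble_amplitude must be non-negative")
  if (wobble_period <= 0) stop("wobble_period must be positive")
  if (drop_depth <= 0 || drop_depth > 1) stop("drop_depth must be in (0, 1]")
  if (drop_tau <= 0) stop("drop_tau must be positive")
  structure(list(archetype = archetype, potency = potency,
                 hill_slope = hill_slope, effect_delay = effect_delay,
                 decline_rate = decline_rate,
                 elevation_factor = elevation_factor,
                 wobble_amplitude = wobble_amplitude,
                 wobble_period = wobble_period, rise_time = rise_time,
                 drop_depth = drop_depth, drop_tau = drop_tau,
                 recovery_rate = recovery_rate),
            class = "archetype_params")
}

.hill <- function(conc, params) {
  if (conc <= 0) return(0)
  cs <- conc^params$hill_slope
  cs / (cs + params$potency^params$hill_slope)
}

# noise-free treated mean on the grid; equals the control mean before dosing
.archetype_mean <- function(times, dose_time, params, occupancy, growth) {
  ctrl <- .logistic(times, growth)
  if (params$archetype == "control" || occupancy == 0) return(ctrl)
  u <- times - dose_time
  post <- u > 0
  h <- occupancy
  out <- ctrl
  up <- u[post]
  out[post] <- switch(
    params$archetype,
    cytotoxic = ctrl[post] *
      ((1 - h) + h * exp(-params$decline_rate * up)),
    calcium_modulator = {
      rho <- 1 - params$drop_depth * (1 - exp(-up / params$drop_tau))
      late <- up > params$effect_delay
      rho_min <- 1 - params$drop_depth *
        (1 - exp(-params$effect_delay / params$drop_tau))
      rho[late] <- pmin(1, rho_min + params$recovery_rate *
                             (up[late] - params$effect_delay))
      ctrl[post] * ((1 - h) + h * rho)
    },
    antimitotic = {
      level <- .logistic(dose_time, growth)
      frozen <- level + params$wobble_amplitude *
        sin(2 * pi * up / params$wobble_period)
      (1 - h) * ctrl[post] + h * frozen
    },
    dna_damaging = {
      e <- params$elevation_factor
      rho <- ifelse(up <= params$rise_time,
                    1 + (e - 1) * up / params$rise_time,
                    e * exp(-params$decline_rate * (up - params$rise_time)))
      ctrl[post] * ((1 - h) + h * rho)
    },
    nuclear_receptor = {
      e <- params$elevation_factor
      rho <- 1 + (e - 1) * pmin(1, up / params$rise_time)
      ctrl[post] * ((1 - h) + h * rho)
    },
    stop("unhandled archetype ", params$archetype))
  out
}

#' Simulate a vehicle-control well
#'
#' Noise-free mean is logistic growth `K / (1 + exp(-r (t - t0)))`; noisy
#' values multiply the mean by correlated log-normal noise. Identical seeds
#' reproduce identical traces.
#'
#' @param times Time grid (hours since seeding), strictly increasing.
#' @param growth [growth_params()].
#' @param noise_sd Marginal sd of the log-scale noise (0 = noise-free).
#' @param noise_tau Correlation time (h) of the noise.
#' @param seed Integer seed.
#' @param well Well address for the returned trace.
#' @param dose_time Optional dose time recorded on the trace (controls
#'   receive vehicle at the same moment compounds are added).
#' @return An [rtca_trace()].
#' @export
simulate_control <- function(times, growth = growth_params(),
                             noise_sd = 0.05, noise_tau = 1, seed = 1,
                             well = "A01", dose_time = NULL) {
  mean_ci <- .logistic(times, growth)
  eps <- .with_seed(seed, .ou_noise(times, noise_sd, noise_tau))
  rtca_trace(times, mean_ci * exp(eps), well = well, dose_time = dose_time)
}

#' Simulate a compound-treated well
#'
#' Before `dose_time` the mean equals the control mean; afterwards it
#' follows the compound's archetype kinetics scaled by Hill occupancy at
#' `concentration`. Zero concentration reproduces the control exactly.
#'
#' @param times Time grid (hours since seeding).
#' @param dose_time Compound-addition time; must be a grid point.
#' @param concentration Concentration in uM (>= 0).
#' @param archetype An [archetype_params()].
#' @param growth [growth_params()] of the underlying cell model.
#' @inheritParams simulate_control
#' @return An [rtca_trace()] with `dose_time` set.
#' @export
simulate_treated <- function(times, dose_time, concentration, archetype,
                             growth = growth_params(), noise_sd = 0.05,
                             noise_tau = 1, seed = 1, well = "A01") {
  stopifnot(inherits(archetype, "archetype_params"))
  if (!dose_time %in% times) stop("dose_time must be a grid point")
  if (concentration < 0) stop("concentration must be non-negative")
  h <- .hill(concentration, archetype)
  mean_ci <- .archetype_mean(times, dose_time, archetype, h, growth)
  eps <- .with_seed(seed, .ou_noise(times, noise_sd, noise_tau))
  rtca_trace(times, mean_ci * exp(eps), well = well, dose_time = dose_time)
}

#' Simulation design for a plate experiment
#'
#' Defaults mirror a standard screening run: seeding at t = 0, dosing at
#' 18 h, recording every 10 min for the first 2 h post-dose and every
#' 30 min otherwise up to 72 h; dose ladder 0.1/1/10/100 uM; treated wells
#' in triplicate, six vehicle controls, and detergent positive controls in
#' duplicate at three concentrations.
#'
#' @param dose_time Compound-addition time (h).
#' @param duration Total recording time (h); must leave >= 48 h post-dose
#'   for the downstream mortality window.
#' @param pre_interval Pre-dose sampling interval (h).
#' @param fast_interval Post-dose fast sampling interval (h), default 10
#'   min.
#' @param fast_window Length of the fast-sampling window (h), default 2.
#' @param interval Routine sampling interval (h), default 30 min.
#' @param dose_ladder Tested concentrations (uM), increasing.
#' @param n_treated,n_vehicle,n_positive Replicate counts.
#' @param positive_concentrations Detergent positive-control concentrations
#'   (fraction w/v).
#' @param noise_sd,noise_tau Log-normal noise parameters.
#' @param growth [growth_params()].
#' @param include_positive_controls Add the positive-control wells?
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(dose_time = 18, duration = 72,
                              pre_interval = 0.5, fast_interval = 1 / 6,
                              fast_window = 2, interval = 0.5,
                              dose_ladder = c(0.1, 1, 10, 100),
                              n_treated = 3, n_vehicle = 6, n_positive = 2,
                              positive_concentrations =
                                c(0.00125, 0.0025, 0.005),
                              noise_sd = 0.05, noise_tau = 1,
                              growth = growth_params(t0 = dose_time),
                              include_positive_controls = TRUE) {
  if (any(diff(dose_ladder) <= 0)) stop("dose_ladder must be increasing")
  if (n_treated < 1 || n_vehicle < 1) stop("replicate counts must be >= 1")
  if (duration <= dose_time) stop("duration must exceed dose_time")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(dose_time = dose_time, duration = duration,
                 pre_interval = pre_interval, fast_interval = fast_interval,
                 fast_window = fast_window, interval = interval,
                 dose_ladder = dose_ladder, n_treated = n_treated,
                 n_vehicle = n_vehicle, n_positive = n_positive,
                 positive_concentrations = positive_concentrations,
                 noise_sd = noise_sd, noise_tau = noise_tau,
                 growth = growth,
                 include_positive_controls = include_positive_controls),
            class = "simulation_design")
}

#' Time grid of a simulation design
#'
#' @param design A [simulation_design()].
#' @return Strictly increasing grid (hours since seeding) containing the
#'   dose time.
#' @export
design_grid <- function(design) {
  d <- design$dose_time
  pre <- seq(0, d, by = design$pre_interval)
  fast <- d + seq(design$fast_interval, design$fast_window,
                  by = design$fast_interval)
  slow_start <- d + design$fast_window + design$interval
  slow <- if (slow_start <= design$duration) {
    seq(slow_start, design$duration, by = design$interval)
  } else numeric(0)
  grid <- round(sort(unique(c(pre, fast, slow))), 6)
  grid
}

#' Simulate a whole plate experiment
#'
#' Lays out vehicle controls, optional positive controls and each
#' compound's dose ladder in replicate on a 96-well plate, simulates every
#' well, and returns the plate together with the ground-truth label table
#' (DNA-damaging compounds are the genotoxic positives).
#'
#' @param design A [simulation_design()].
#' @param compounds Named list of [archetype_params()]; names are the
#'   compound ids.
#' @param seed Master integer seed. Per-well substreams are derived by
#'   hashing (plate id, well), so adding a compound does not perturb the
#'   other wells' draws.
#' @param plate_id Plate identifier.
#' @return List with `plate` (an [rtca_plate()]) and `truth` (data frame
#'   `compound_id`, `archetype`, `mechanism_reference`,
#'   `genotoxic_reference`).
#' @export
simulate_plate <- function(design, compounds, seed = 1,
                           plate_id = "simplate") {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(names(compounds)) || any(names(compounds) == "")) {
    stop("compounds must be a named list (names are compound ids)")
  }
  n_cmpd_wells <- length(compounds) * length(design$dose_ladder) *
    design$n_treated
  n_pos <- if (design$include_positive_controls) {
    design$n_positive * length(design$positive_concentrations)
  } else 0L
  n_wells <- n_cmpd_wells + design$n_vehicle + n_pos
  if (n_wells > 96L) {
    stop("plate capacity exceeded: design needs ", n_wells, " wells (max 96)")
  }
  all_wells <- as.vector(t(outer(VALID_ROWS, 1:12, well_address)))
  rows <- list()
  k <- 0L
  take <- function(n) {
    w <- all_wells[(k + 1L):(k + n)]
    k <<- k + n
    w
  }
  for (i in seq_len(design$n_vehicle)) {
    rows[[length(rows) + 1L]] <- data.frame(
      well = take(1L), role = "vehicle_control", compound_id = NA_character_,
      concentration_uM = NA_real_, replicate_index = i,
      stringsAsFactors = FALSE)
  }
  if (design$include_positive_controls) {
    for (pc in design$positive_concentrations) {
      for (i in seq_len(design$n_positive)) {
        rows[[length(rows) + 1L]] <- data.frame(
          well = take(1L), role = "positive_control",
          compound_id = "triton_x100", concentration_uM = pc,
          replicate_index = i, stringsAsFactors = FALSE)
      }
    }
  }
  for (cid in names(compounds)) {
    for (conc in design$dose_ladder) {
      for (i in seq_len(design$n_treated)) {
        rows[[length(rows) + 1L]] <- data.frame(
          well = take(1L), role = "treated", compound_id = cid,
          concentration_uM = conc, replicate_index = i,
          stringsAsFactors = FALSE)
      }
    }
  }
  layout <- do.call(rbind, rows)
  grid <- design_grid(design)
  d <- design$dose_time
  triton <- archetype_params("cytotoxic", potency = 1e-6, hill_slope = 1,
                             decline_rate = 0.6)
  values <- matrix(NA_real_, nrow = length(grid), ncol = nrow(layout),
                   dimnames = list(NULL, layout$well))
  for (j in seq_len(nrow(layout))) {
    w <- layout$well[j]
    ws <- .well_seed(seed, plate_id, w)
    tr <- switch(
      layout$role[j],
      vehicle_control = simulate_control(
        grid, design$growth, design$noise_sd, design$noise_tau,
        seed = ws, well = w, dose_time = d),
      positive_control = simulate_treated(
        grid, d, layout$concentration_uM[j], triton, design$growth,
        design$noise_sd, design$noise_tau, seed = ws, well = w),
      treated = simulate_treated(
        grid, d, layout$concentration_uM[j],
        compounds[[layout$compound_id[j]]], design$growth,
        design$noise_sd, design$noise_tau, seed = ws, well = w))
    values[, j] <- tr$values
  }
  truth <- data.frame(
    compound_id = names(compounds),
    archetype = vapply(compounds, `[[`, character(1), "archetype"),
    stringsAsFactors = FALSE, row.names = NULL)
  truth$mechanism_reference <- ifelse(truth$archetype %in% MECHANISM_CLASSES,
                                      truth$archetype, "none")
  truth$genotoxic_reference <- truth$archetype == "dna_damaging"
  list(plate = rtca_plate(grid, values, layout, dose_times = d,
                          plate_id = plate_id),
       truth = truth)
}

#' Draw random archetype parameters within documented ranges
#'
#' Potency is log-uniform over 0.32--10 uM (so the top of the default dose
#' ladder sits at >= 90 percent occupancy), Hill slope uniform 1--2, and
#' per-archetype shape parameters vary within the ranges stated in the
#' methods vignette. Call inside an established RNG state.
#'
#' @param archetype Mechanism class (or `"cytotoxic"`/`"control"`).
#' @return An [archetype_params()].
#' @export
draw_archetype_params <- function(archetype) {
  archetype <- match.arg(archetype, ARCHETYPES)
  base <- list(potency = 10^stats::runif(1, -0.5, 1),
               hill_slope = stats::runif(1, 1, 2))
  extra <- switch(archetype,
    control = list(),
    cytotoxic = list(decline_rate = stats::runif(1, 0.05, 0.12)),
    calcium_modulator = list(effect_delay = stats::runif(1, 5, 9.5),
                             drop_depth = stats::runif(1, 0.9, 0.98),
                             drop_tau = stats::runif(1, 0.5, 1.5)),
    antimitotic = list(wobble_amplitude = stats::runif(1, 0.1, 0.4),
                       wobble_period = stats::runif(1, 18, 30)),
    dna_damaging = list(elevation_factor = stats::runif(1, 1.3, 1.8),
                        decline_rate = stats::runif(1, 0.08, 0.15)),
    nuclear_receptor = list(elevation_factor = stats::runif(1, 1.3, 1.8)))
  do.call(archetype_params, c(list(archetype = archetype), base, extra))
}

#' Simulate a panel of compounds across plates
#'
#' Draws `n_per_class` compounds per archetype with randomized parameters,
#' packs them onto plates of at most `compounds_per_plate` compounds
#' (sharing vehicle controls within a plate), and simulates each plate.
#'
#' @param n_per_class Compounds per archetype class.
#' @param classes Archetype classes to include.
#' @param design Base [simulation_design()]; its `noise_sd` applies.
#' @param seed Master seed.
#' @param compounds_per_plate Compounds per simulated plate.
#' @return List with `plates` (list of [rtca_plate()]) and `truth` (pooled
#'   ground-truth table).
#' @export
simulate_mechanism_panel <- function(n_per_class = 50,
                                     classes = MECHANISM_CLASSES,
                                     design = simulation_design(),
                                     seed = 1, compounds_per_plate = 5) {
  specs <- .with_seed(seed, {
    out <- list()
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        out[[sprintf("%s_%03d", cl, i)]] <- draw_archetype_params(cl)
      }
    }
    out[sample(length(out))]   # shuffle so plates mix classes
  })
  # skip positive controls on panel plates to fit more compounds
  design$include_positive_controls <- FALSE
  idx <- split(seq_along(specs),
               ceiling(seq_along(specs) / compounds_per_plate))
  plates <- vector("list", length(idx))
  truths <- vector("list", length(idx))
  for (p in seq_along(idx)) {
    sim <- simulate_plate(design, specs[idx[[p]]],
                          seed = (seed + 7919 * p) %% 2147483647,
                          plate_id = sprintf("panel%03d", p))
    plates[[p]] <- sim$plate
    truths[[p]] <- sim$truth
  }
  list(plates = plates, truth = do.call(rbind, truths))
}

#' Simulate a shared-latent dual-readout endpoint experiment
#'
#' One latent endpoint viability per (compound, dose) drives both the
#' impedance and the fluorescence percent-of-control readout, each observed
#' with independent multiplicative log-normal noise. Used to exercise the
#' cross-readout correlation computation.
#'
#' @param n_compounds Number of compounds.
#' @param doses Dose ladder (uM).
#' @param noise_sd Per-readout log-normal sd (default 0.05).
#' @param seed Integer seed.
#' @return Data frame with `compound_id`, `concentration_uM`, `latent`,
#'   `impedance_pct`, `fluorescence_pct`.
#' @export
simulate_dual_readout <- function(n_compounds = 50,
                                  doses = c(0.1, 1, 10, 100),
                                  noise_sd = 0.05, seed = 1) {
  .with_seed(seed, {
    rows <- vector("list", n_compounds)
    for (i in seq_len(n_compounds)) {
      potency <- 10^stats::runif(1, -0.5, 1.5)
      slope <- stats::runif(1, 1, 2)
      emax <- stats::runif(1, 0.6, 1)
      occ <- doses^slope / (doses^slope + potency^slope)
      latent <- pmax(0, 1 - emax * occ)
      rows[[i]] <- data.frame(
        compound_id = sprintf("cmpd_%03d", i), concentration_uM = doses,
        latent = latent,
        impedance_pct = 100 * latent *
          exp(stats::rnorm(length(doses), 0, noise_sd)),
        fluorescence_pct = 100 * latent *
          exp(stats::rnorm(length(doses), 0, noise_sd)),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
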