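# Shared fixture builders. All synthetic, generated in code at test time.

# a tiny hand-built plate: 2 treated wells (one compound, one dose),
# 2 vehicle wells, linear growth, dosing at 2 h
toy_plate <- function(treated_factor = 0.5, n_time = 9, duration = 8,
                      dose_time = 2) {
  times <- seq(0, duration, length.out = n_time)
  ctrl <- 1 + times          # growing control
  trt <- ifelse(times <= dose_time, ctrl, ctrl * treated_factor)
  values <- cbind(A01 = ctrl, A02 = ctrl * 1.02, B01 = trt, B02 = trt * 0.98)
  layout <- data.frame(
    well = c("A01", "A02", "B01", "B02"),
    role = c("vehicle_control", "vehicle_control", "treated", "treated"),
    compound_id = c(NA, NA, "cmpdX", "cmpdX"),
    concentration_uM = c(NA, NA, 10, 10),
    replicate_index = c(1, 2, 1, 2),
    stringsAsFactors = FALSE)
  rtca_plate(times, values, layout, dose_times = dose_time,
             plate_id = "toy")
}

# normalized trace pair (control flat at 1) with a prescribed post-dose
# treated/control ratio profile; `ratio_fun` maps hours post-dose to ratio
ratio_pair <- function(ratio_fun, dose_time = 18, duration = 72, by = 1) {
  times <- seq(0, duration, by = by)
  control <- rtca_trace(times, rep(1, length(times)),
                        well = "A01", dose_time = dose_time)
  u <- pmax(0, times - dose_time)
  treated <- rtca_trace(times, ifelse(u > 0, ratio_fun(u), 1),
                        well = "B01", dose_time = dose_time)
  list(treated = treated, control = control)
}

# piecewise-linear interpolation helper for ratio profiles
pwl <- function(u_knots, r_knots) {
  function(u) stats::approx(u_knots, r_knots, xout = u, rule = 2)$y
}
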