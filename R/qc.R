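FLOW_CLASSES <- c("excellent", "good", "fair", "passable", "poor", "very_poor")

#' Carr's compressibility index
#'
#' `CI% = 100 * (tapped - bulk) / tapped`. Lower values indicate better
#' powder flow (less consolidation on tapping). Vectorized.
#'
#' @param bulk_density,tapped_density Densities in the same units;
#'   `tapped_density >= bulk_density > 0`.
#' @return Carr's index in percent.
#' @export
#' @examples
#' carr_index(0.42, 0.50)  # 16
carr_index <- function(bulk_density, tapped_density) {
  if (any(bulk_density <= 0) || any(tapped_density <= 0)) {
    dk_stop_argument("densities must be > 0")
  }
  if (any(bulk_density > tapped_density)) {
    dk_stop_argument("bulk density cannot exceed tapped density")
  }
  100 * (tapped_density - bulk_density) / tapped_density
}

#' Angle of repose of a poured powder cone
#'
#' `theta = atan(height / radius)` in degrees. Lower angles indicate
#' better flow. Vectorized.
#'
#' @param height,radius Cone height and base radius, same length unit;
#'   both > 0.
#' @return Angle in degrees.
#' @export
#' @examples
#' angle_of_repose(1, sqrt(3))  # 30
angle_of_repose <- function(height, radius) {
  if (any(height <= 0) || any(radius <= 0)) {
    dk_stop_argument("`height` and `radius` must be > 0")
  }
  atan(height / radius) * 180 / pi
}

#' Classify powder flowability from the angle of repose
#'
#' Step classification on compendial-style bands, with the excellent band
#' extended to 30 degrees: <= 30 excellent; (30, 35\] good; (35, 40\]
#' fair; (40, 45\] passable; > 45 poor. Vectorized.
#'
#' @param angle Angle(s) of repose in degrees, in (0, 90).
#' @return Character vector of flowability classes.
#' @export
classify_angle <- function(angle) {
  if (any(angle <= 0 | angle >= 90)) {
    dk_stop_argument("`angle` must lie in (0, 90) degrees")
  }
  vapply(angle, function(a) {
    if (a <= 30) "excellent"
    else if (a <= 35) "good"
    else if (a <= 40) "fair"
    else if (a <= 45) "passable"
    else "poor"
  }, character(1))
}

#' Classify powder flowability from Carr's index
#'
#' Step classification on compendial-style bands: <= 10 excellent;
#' (10, 15\] good; (15, 20\] fair; (20, 25\] passable; (25, 31\] poor;
#' > 31 very poor. Vectorized.
#'
#' @param ci Carr's index value(s) in percent, in \[0, 100).
#' @return Character vector of flowability classes.
#' @export
classify_ci <- function(ci) {
  if (any(ci < 0 | ci >= 100)) {
    dk_stop_argument("`ci` must lie in [0, 100) percent")
  }
  vapply(ci, function(x) {
    if (x <= 10) "excellent"
    else if (x <= 15) "good"
    else if (x <= 20) "fair"
    else if (x <= 25) "passable"
    else if (x <= 31) "poor"
    else "very_poor"
  }, character(1))
}

#' Tablet friability result
#'
#' Percentage weight loss under standardized tumbling,
#' `100 * (initial - final) / initial`, with the robustness verdict:
#' tablets that fracture or lose more than 1% of their weight fail. A
#' final mass slightly above the initial one (weighing noise) is clamped
#' to zero loss with a warning.
#'
#' @param initial_mass,final_mass Total tablet mass before/after the test;
#'   > 0.
#' @param fractured Did any tablet fracture during the test?
#' @return An object of class `friability_result` with fields
#'   `weight_loss` (%), `fractured`, `passed`.
#' @export
#' @examples
#' friability(6500, 6495)  # 0.077% loss, passed
friability <- function(initial_mass, final_mass, fractured = FALSE) {
  if (initial_mass <= 0 || final_mass <= 0) {
    dk_stop_argument("masses must be > 0")
  }
  if (final_mass > initial_mass) {
    warning("final mass exceeds initial mass; weight loss clamped at 0")
    final_mass <- initial_mass
  }
  loss <- 100 * (initial_mass - final_mass) / initial_mass
  structure(
    list(weight_loss = loss, fractured = isTRUE(fractured),
         passed = friability_verdict(loss, fractured)),
    class = "friability_result"
  )
}

#' @export
print.friability_result <- function(x, ...) {
  cat(sprintf("<friability_result> weight loss %.2f%%, %sfractured: %s\n",
              x$weight_loss, if (x$fractured) "" else "not ",
              if (x$passed) "Passed" else "Failed"))
  invisible(x)
}

#' @rdname friability
#' @param weight_loss Percentage weight loss (when applying the rule to an
#'   already-computed loss).
#' @return `friability_verdict()`: logical, `TRUE` iff not fractured and
#'   weight loss <= 1%. Vectorized.
#' @export
friability_verdict <- function(weight_loss, fractured) {
  !as.logical(fractured) & (is.na(weight_loss) | weight_loss <= 1)
}

#' Powder flow rate through an orifice
#'
#' `mass / time` in g/s, from a timed discharge through an orifice.
#'
#' @param mass Discharged mass in g; >= 0.
#' @param time Discharge time in s; > 0.
#' @return Flow rate in g/s.
#' @export
flow_rate <- function(mass, time) {
  if (any(time <= 0)) dk_stop_argument("`time` must be > 0")
  if (any(mass < 0)) dk_stop_argument("`mass` must be >= 0")
  mass / time
}

#' Powder QC summary with flowability classification
#'
#' Summarizes replicate powder measurements per formulation as mean and
#' standard deviation of flow rate, angle of repose and Carr's index, and
#' classifies flowability from the replicate means (classification of the
#' mean, matching the mean-plus-minus-SD presentation of flowability
#' tables).
#'
#' @param measurements Data frame of replicate rows with columns
#'   `formulation_id`, `bulk_density`, `tapped_density`, `cone_height`,
#'   `cone_radius`, `flow_mass_g`, `flow_time_s`.
#' @return A tibble with one row per formulation: mean and SD of each
#'   metric plus `angle_inference` and `ci_inference` classes.
#' @export
qc_report <- function(measurements) {
  required <- c("formulation_id", "bulk_density", "tapped_density",
                "cone_height", "cone_radius", "flow_mass_g", "flow_time_s")
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0) {
    dk_stop_format(sprintf("missing required column(s): %s",
                           paste(missing, collapse = ", ")))
  }
  groups <- split(measurements,
                  factor(measurements$formulation_id,
                         levels = unique(measurements$formulation_id)))
  rows <- lapply(groups, function(g) {
    fr <- flow_rate(g$flow_mass_g, g$flow_time_s)
    ang <- angle_of_repose(g$cone_height, g$cone_radius)
    ci <- carr_index(g$bulk_density, g$tapped_density)
    tibble(
      formulation_id = g$formulation_id[1],
      n = nrow(g),
      flow_rate_mean = mean(fr), flow_rate_sd = sd_or_zero(fr),
      angle_mean = mean(ang), angle_sd = sd_or_zero(ang),
      ci_mean = mean(ci), ci_sd = sd_or_zero(ci),
      angle_inference = classify_angle(mean(ang)),
      ci_inference = classify_ci(mean(ci))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)
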