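#' Dissolution profile objects
#'
#' A `dissolution_profile` is the basic data object consumed by all profile
#' comparisons and kinetic fits: a time series of cumulative percent of the
#' labeled dose released, sampled at strictly increasing times (minutes),
#' optionally annotated with the pH of the dissolution medium at each
#' sampling point (two-stage gastric/intestinal protocols change the medium
#' pH part-way through the run).
#'
#' Invariants enforced by the constructor:
#' * `times` strictly increasing, first time >= 0;
#' * `release` in \[0, 110\] (cumulative release may overshoot 100% slightly
#'   because of analytical noise; beyond 110 is treated as a data error);
#' * `ph`, when given, has one value per point.
#'
#' @param formulation_id Character label of the formulation.
#' @param times Numeric vector of sampling times in minutes.
#' @param release Numeric vector of cumulative % of dose released, same
#'   length as `times`.
#' @param ph Optional numeric vector of medium pH per sampling point.
#' @param stages Optional data frame with columns `start_time` and `pH`
#'   describing medium changes; used to derive `ph` when `ph` is missing.
#'   Must be sorted by `start_time` with the first stage starting at 0. A
#'   sample taken exactly at a changeover time belongs to the outgoing
#'   stage (the aliquot is drawn before the medium is modified).
#' @param replicate_id Optional replicate label.
#'
#' @return An object of class `dissolution_profile`.
#' @seealso [read_profiles()], [write_profiles()], [simulate_profile()]
#' @export
#' @examples
#' dissolution_profile("F-8", times = c(15, 30, 60), release = c(5, 9, 16))
dissolution_profile <- function(formulation_id, times, release, ph = NULL,
                                stages = NULL, replicate_id = NA_character_) {
  times <- as.numeric(times)
  release <- as.numeric(release)
  if (length(times) != length(release)) {
    dk_stop_validation("`times` and `release` must have the same length")
  }
  if (length(times) > 0 && times[1] < 0) {
    dk_stop_validation("first sampling time must be >= 0")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    dk_stop_validation(sprintf(
      "sampling times of profile '%s' must be strictly increasing", formulation_id))
  }
  if (any(release < 0 | release > 110)) {
    dk_stop_validation(sprintf(
      "release values of profile '%s' must lie in [0, 110]", formulation_id))
  }
  if (!is.null(stages)) {
    stages <- as.data.frame(stages)
    if (!all(c("start_time", "pH") %in% names(stages))) {
      dk_stop_validation("`stages` needs columns start_time and pH")
    }
    if (nrow(stages) == 0 || stages$start_time[1] != 0) {
      dk_stop_validation("first stage must start at time 0")
    }
    if (is.unsorted(stages$start_time, strictly = TRUE)) {
      dk_stop_validation("`stages` must be sorted by start_time")
    }
    if (is.null(ph) && length(times) > 0) {
      # sample at a changeover time belongs to the outgoing stage
      idx <- findInterval(times, stages$start_time, left.open = TRUE)
      idx[idx == 0L] <- 1L
      ph <- stages$pH[idx]
    }
  }
  if (!is.null(ph)) {
    ph <- as.numeric(ph)
    if (length(ph) != length(times)) {
      dk_stop_validation("`ph` must have one value per sampling point")
    }
  }
  structure(
    list(
      formulation_id = as.character(formulation_id),
      replicate_id = as.character(replicate_id),
      times = times,
      release = release,
      ph = ph
    ),
    class = "dissolution_profile"
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  rep_lab <- if (is.na(x$replicate_id)) "" else sprintf(" (replicate %s)", x$replicate_id)
  cat(sprintf("<dissolution_profile> %s%s: %d points", x$formulation_id,
              rep_lab, length(x$times)))
  if (length(x$times) > 0) {
    cat(sprintf(", t = %g..%g min, release %.1f..%.1f%%",
                min(x$times), max(x$times), min(x$release), max(x$release)))
  }
  cat("\n")
  if (!is.null(x$ph)) {
    st <- profile_stages(x)
    cat(sprintf("  stages: %s\n",
                paste(sprintf("pH %.3g from %g min", st$pH, st$start_time),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.dissolution_profile <- function(x, ...) {
  tibble(
    formulation_id = x$formulation_id,
    replicate = x$replicate_id,
    time_min = x$times,
    release_pct = x$release,
    pH = if (is.null(x$ph)) NA_real_ else x$ph
  )
}

#' Medium stages of a profile
#'
#' Reconstructs the (start_time, pH) stage table from the per-point pH
#' annotation. A new stage is recorded as starting at the last sampling
#' time of the previous pH run, since the medium is modified immediately
#' after that aliquot is drawn.
#'
#' @param profile A [dissolution_profile()].
#' @return A tibble with columns `start_time` (minutes) and `pH`; a single
#'   row with `pH = NA` when the profile carries no pH annotation.
#' @export
profile_stages <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (is.null(profile$ph) || length(profile$ph) == 0) {
    return(tibble(start_time = 0, pH = NA_real_))
  }
  runs <- rle(profile$ph)
  ends <- cumsum(runs$lengths)
  starts <- c(0, profile$times[ends[-length(ends)]])
  tibble(start_time = starts, pH = runs$values)
}

#' Read dissolution profiles from a CSV file
#'
#' Expects a UTF-8 comma-separated file with a header row and columns
#' `formulation_id`, `time_min`, `release_pct`; columns `replicate` and
#' `pH` are optional (a missing pH column yields single-stage profiles).
#' One profile is returned per (formulation_id, replicate) group, rows
#' sorted by time within each group.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector remapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(time_min = "t", release_pct = "Q")`.
#' @return A list of [dissolution_profile()] objects.
#' @export
read_profiles <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    dk_stop_argument(sprintf("file '%s' does not exist", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      hit <- match(dialect[[canon]], names(df))
      if (!is.na(hit)) names(df)[hit] <- canon
    }
  }
  required <- c("formulation_id", "time_min", "release_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    dk_stop_format(sprintf("missing required column(s): %s",
                           paste(missing, collapse = ", ")))
  }
  if (!"replicate" %in% names(df)) df$replicate <- NA_character_
  has_ph <- "pH" %in% names(df) && !all(is.na(df$pH))

  key <- paste(df$formulation_id, df$replicate, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  lapply(groups, function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    if (anyDuplicated(g$time_min)) {
      dk_stop_validation(sprintf(
        "duplicated sampling times for formulation '%s' replicate '%s'",
        g$formulation_id[1], g$replicate[1]))
    }
    dissolution_profile(
      formulation_id = g$formulation_id[1],
      times = g$time_min,
      release = g$release_pct,
      ph = if (has_ph) g$pH else NULL,
      replicate_id = g$replicate[1]
    )
  }) |> unname()
}

#' Write dissolution profiles to a CSV file
#'
#' Writes the canonical dialect (`formulation_id,replicate,time_min,
#' release_pct,pH`) at full double precision so that
#' `read_profiles(write_profiles(x))` reproduces times and release values
#' exactly. An empty collection produces a header-only file.
#'
#' @param profiles A list of [dissolution_profile()] objects (a single
#'   profile is accepted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, as_tibble)
  df <- if (length(rows) == 0) {
    tibble(formulation_id = character(), replicate = character(),
           time_min = numeric(), release_pct = numeric(), pH = numeric())
  } else {
    do.call(rbind, rows)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Calibration line for absorbance-to-concentration conversion
#'
#' A linear (Beer-Lambert range) calibration mapping UV absorbance to drug
#' concentration: `concentration = slope * absorbance + intercept`, in
#' mg/mL per absorbance unit.
#'
#' @param slope Concentration per absorbance unit (mg/mL/AU); must be > 0.
#' @param intercept Concentration offset (mg/mL), default 0.
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept = 0) {
  if (!is.numeric(slope) || length(slope) != 1 || slope <= 0) {
    dk_stop_argument("calibration `slope` must be a single positive number")
  }
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_line")
}

#' Convert absorbance readings to cumulative % release
#'
#' Applies a linear calibration to raw absorbance readings and scales by
#' the dilution factor, vessel volume and labeled dose:
#' `release_i = (slope * A_i + intercept) * dilution_factor * vessel_volume
#' / dose * 100`.
#'
#' By default no correction is applied for drug removed in sampled
#' aliquots. When `sample_volume > 0` the standard cumulative correction is
#' applied: the drug mass withdrawn with each earlier aliquot is added back
#' to later readings, i.e.
#' `Q_i = base_i + (sample_volume / vessel_volume) * sum(base_j, j < i)`.
#'
#' @param absorbances Numeric vector of absorbance readings (AU), in
#'   sampling order.
#' @param calibration A [calibration_line()].
#' @param dilution_factor Dilution applied before reading; >= 1.
#' @param vessel_volume Dissolution vessel volume in mL.
#' @param dose Labeled dose in mg.
#' @param sample_volume Aliquot volume withdrawn per sample in mL; 0
#'   disables the withdrawal correction (the default).
#' @return Numeric vector of cumulative % release.
#' @export
#' @examples
#' cal <- calibration_line(slope = 0.08)
#' absorbance_to_release(1.0, cal, dilution_factor = 1,
#'                       vessel_volume = 900, dose = 80)  # 90%
absorbance_to_release <- function(absorbances, calibration, dilution_factor = 1,
                                  vessel_volume, dose, sample_volume = 0) {
  stopifnot(inherits(calibration, "calibration_line"))
  if (!is.numeric(dose) || dose <= 0) dk_stop_argument("`dose` must be > 0")
  if (!is.numeric(vessel_volume) || vessel_volume <= 0) {
    dk_stop_argument("`vessel_volume` must be > 0")
  }
  if (dilution_factor < 1) dk_stop_argument("`dilution_factor` must be >= 1")
  if (sample_volume < 0 || sample_volume >= vessel_volume) {
    dk_stop_argument("`sample_volume` must be in [0, vessel_volume)")
  }
  conc <- calibration$slope * absorbances + calibration$intercept
  base <- conc * dilution_factor * vessel_volume / dose * 100
  if (sample_volume > 0 && length(base) > 1) {
    prior <- c(0, cumsum(base)[-length(base)])
    base <- base + sample_volume / vessel_volume * prior
  }
  base
}
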