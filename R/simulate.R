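#' Two-stage sustained-release sampling schedule
#'
#' The standard sampling grid for a 24 h two-stage dissolution run:
#' every 15 min during the 2 h gastric stage (pH 1.2), then every 2 h up
#' to 24 h in the intestinal stage (pH 7.4) — 8 + 11 = 19 sampling times.
#'
#' @param stage1_interval Sampling interval during stage 1, minutes.
#' @param changeover Medium changeover time, minutes.
#' @param stage2_interval Sampling interval during stage 2, minutes.
#' @param total Total run length, minutes.
#' @return Numeric vector of sampling times in minutes (the time-zero
#'   point is not sampled).
#' @export
#' @examples
#' two_stage_schedule()  # 15, 30, ..., 120, 240, ..., 1440
two_stage_schedule <- function(stage1_interval = 15, changeover = 120,
                               stage2_interval = 120, total = 1440) {
  c(seq(stage1_interval, changeover, by = stage1_interval),
    seq(changeover + stage2_interval, total, by = stage2_interval))
}

# Noise-free model curves on the % release scale.
release_curve <- function(model, params, times) {
  model <- match.arg(model, KINETIC_MODELS)
  k <- params$k
  if (is.null(k) || !is.finite(k) || k < 0) {
    dk_stop_argument(sprintf("model '%s' needs a non-negative rate constant `k`", model))
  }
  switch(model,
    zero_order = k * times,
    first_order = 100 * (1 - exp(-k * times)),
    higuchi = k * sqrt(times),
    korsmeyer_peppas = {
      n <- params$n
      if (is.null(n) || !is.finite(n) || n <= 0) {
        dk_stop_argument("korsmeyer_peppas needs a positive exponent `n`")
      }
      k * times^n
    }
  )
}

# Shared noising/clipping: clip the noise-free curve at `cap`, add i.i.d.
# Gaussian noise, clamp to the physical range, optionally project onto
# non-decreasing curves (cumulative release cannot decrease).
noisy_release <- function(base, noise_sd, cap, monotone) {
  y <- pmin(base, cap)
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  y <- pmin(pmax(y, 0), cap + 5 * noise_sd, 110)  # 110 = hard validity bound
  if (monotone) y <- cummax(y)
  y
}

#' Simulate replicate dissolution profiles from a kinetics model
#'
#' Generates in-silico dissolution experiments with the statistical
#' structure the analysis assumes: a noise-free curve from one release
#' model evaluated on the sampling schedule, clipped at `cap` (the labeled
#' dose), plus independent additive Gaussian measurement noise per point
#' and replicate, optionally projected onto non-decreasing curves. Points
#' are annotated pH 1.2 up to the changeover time and pH 7.4 after it,
#' emulating the two-stage gastric/intestinal protocol.
#'
#' Replicate `r` draws from a stream seeded by the r-th value derived from
#' the root seed, so requesting more replicates never changes earlier
#' ones, and a fixed seed reproduces the data exactly.
#'
#' @param model One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param params Named list of model parameters: `k` (rate constant in the
#'   model's units) and, for Korsmeyer-Peppas, the exponent `n`.
#' @param schedule Sampling times in minutes; default
#'   [two_stage_schedule()].
#' @param noise_sd Standard deviation of the additive measurement noise on
#'   the % release scale; >= 0.
#' @param cap Maximum release (% of dose) of the noise-free curve; in
#'   (0, 110], default 100.
#' @param monotone Project each noised replicate onto a non-decreasing
#'   curve? Default `FALSE`.
#' @param n_replicates Number of replicates; >= 1.
#' @param seed Root seed (integer) for reproducibility; `NULL` uses the
#'   current RNG state.
#' @param formulation_id Label for the generated profiles.
#' @param changeover pH changeover time in minutes for the stage
#'   annotation.
#' @return A list of `n_replicates` [dissolution_profile()] objects with
#'   `replicate_id` `"R1"`, `"R2"`, ...
#' @export
#' @examples
#' sim <- simulate_profile("higuchi", list(k = 6.5), noise_sd = 1,
#'                         n_replicates = 3, seed = 42)
#' sim[[1]]
simulate_profile <- function(model, params, schedule = two_stage_schedule(),
                             noise_sd = 0, cap = 100, monotone = FALSE,
                             n_replicates = 1, seed = NULL,
                             formulation_id = "SIM", changeover = 120) {
  if (length(schedule) < 1 || is.unsorted(schedule, strictly = TRUE)) {
    dk_stop_argument("`schedule` must be strictly increasing")
  }
  if (noise_sd < 0) dk_stop_argument("`noise_sd` must be >= 0")
  if (cap <= 0 || cap > 110) dk_stop_argument("`cap` must lie in (0, 110]")
  if (n_replicates < 1) dk_stop_argument("`n_replicates` must be >= 1")
  base <- release_curve(model, params, schedule)
  ph <- ifelse(schedule <= changeover, 1.2, 7.4)
  rep_seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    y <- if (is.null(rep_seeds)) {
      noisy_release(base, noise_sd, cap, monotone)
    } else {
      with_seed(rep_seeds[r], noisy_release(base, noise_sd, cap, monotone))
    }
    dissolution_profile(formulation_id, schedule, y, ph = ph,
                        replicate_id = sprintf("R%d", r))
  })
}

#' Simulate a two-stage dissolution profile with a kinetics change
#'
#' Models a medium change that alters the release kinetics: stage-1
#' kinetics up to the changeover time, then stage-2 kinetics continuing
#' additively from the release level reached at changeover, so the curve
#' is continuous there (the medium change is a buffer addition, not a
#' tablet transfer, so no release jump occurs):
#' `Q(t) = Q1(t)` for `t <= changeover`,
#' `Q(t) = Q1(changeover) + Q2(t - changeover)` after.
#'
#' @param model1,params1 Stage-1 model and parameters (see
#'   [simulate_profile()]).
#' @param model2,params2 Stage-2 model and parameters.
#' @param changeover Changeover time in minutes; must be one of the
#'   schedule times.
#' @inheritParams simulate_profile
#' @return A list of [dissolution_profile()] objects.
#' @export
simulate_two_stage_profile <- function(model1, params1, model2, params2,
                                       changeover = 120,
                                       schedule = two_stage_schedule(),
                                       noise_sd = 0, cap = 100,
                                       monotone = FALSE, n_replicates = 1,
                                       seed = NULL, formulation_id = "SIM2") {
  if (!any(abs(schedule - changeover) < 1e-9)) {
    dk_stop_argument("`changeover` must be one of the schedule times")
  }
  if (length(schedule) < 1 || is.unsorted(schedule, strictly = TRUE)) {
    dk_stop_argument("`schedule` must be strictly increasing")
  }
  base1 <- release_curve(model1, params1, pmin(schedule, changeover))
  at_change <- release_curve(model1, params1, changeover)
  elapsed2 <- pmax(schedule - changeover, 0)
  base2 <- at_change + release_curve(model2, params2, elapsed2)
  base <- ifelse(schedule <= changeover, base1, base2)
  ph <- ifelse(schedule <= changeover, 1.2, 7.4)
  rep_seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    y <- if (is.null(rep_seeds)) {
      noisy_release(base, noise_sd, cap, monotone)
    } else {
      with_seed(rep_seeds[r], noisy_release(base, noise_sd, cap, monotone))
    }
    dissolution_profile(formulation_id, schedule, y, ph = ph,
                        replicate_id = sprintf("R%d", r))
  })
}

#' Simulate replicate powder QC measurements
#'
#' Generates noised triplicate-style measurements of bulk and tapped
#' density and of the poured-cone geometry, as inputs for the powder flow
#' metrics ([carr_index()], [angle_of_repose()]). Noise is multiplicative
#' Gaussian with coefficient of variation `noise_cv` per measurement;
#' `noise_cv = 0` returns the true values exactly.
#'
#' @param true_bulk_density,true_tapped_density Densities in g/mL;
#'   tapped >= bulk > 0.
#' @param cone_height,cone_radius Poured-cone geometry, same length unit.
#' @param noise_cv Coefficient of variation of the measurement noise;
#'   >= 0.
#' @param n_replicates Number of replicate measurements.
#' @param seed Seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return A tibble with columns `replicate`, `bulk_density`,
#'   `tapped_density`, `cone_height`, `cone_radius`.
#' @export
simulate_powder_measurements <- function(true_bulk_density, true_tapped_density,
                                         cone_height, cone_radius,
                                         noise_cv = 0, n_replicates = 3,
                                         seed = NULL) {
  if (true_bulk_density <= 0 || true_tapped_density <= 0) {
    dk_stop_argument("densities must be > 0")
  }
  if (true_tapped_density < true_bulk_density) {
    dk_stop_argument("tapped density must be >= bulk density")
  }
  if (noise_cv < 0) dk_stop_argument("`noise_cv` must be >= 0")
  truth <- c(true_bulk_density, true_tapped_density, cone_height, cone_radius)
  rep_seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    draw <- function() truth * pmax(1 + rnorm(4, sd = noise_cv), 1e-6)
    v <- if (noise_cv == 0) truth
         else if (is.null(rep_seeds)) draw()
         else with_seed(rep_seeds[r], draw())
    tibble(replicate = r, bulk_density = v[1], tapped_density = v[2],
           cone_height = v[3], cone_radius = v[4])
  })
  do.call(rbind, rows)
}
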