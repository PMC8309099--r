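#' @rdname analyze_profile
#' @format NULL
#' @name kinetic-models
NULL

KINETIC_MODELS <- c("zero_order", "first_order", "higuchi", "korsmeyer_peppas")

# Parsimony preference used only to break exact ties in model selection:
# fewer assumptions / fewer effective parameters first.
MODEL_PARSIMONY <- c(zero_order = 1, first_order = 2, higuchi = 3,
                     korsmeyer_peppas = 4)

#' Truncate a profile to the first 60% of drug release
#'
#' The Higuchi and Korsmeyer-Peppas models are short-time approximations,
#' valid only over roughly the first 60% of cumulative release; fits of
#' those models therefore use only points with release <= 60%. The first
#' point exceeding 60% (and everything after it) is dropped. The input
#' profile is not modified.
#'
#' @param profile A [dissolution_profile()].
#' @return A new [dissolution_profile()] containing only the points at
#'   <= 60% release (possibly zero points; downstream fits then refuse).
#' @export
truncate_to_60 <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  keep <- profile$release <= 60
  dissolution_profile(
    formulation_id = profile$formulation_id,
    times = profile$times[keep],
    release = profile$release[keep],
    ph = if (is.null(profile$ph)) NULL else profile$ph[keep],
    replicate_id = profile$replicate_id
  )
}

# Internal: build a kinetic_fit from a linear fit on a transformed scale.
# x, y are the transformed regression variables; predict_raw maps the
# fitted line back to the raw % release scale at the used times.
new_kinetic_fit <- function(model, profile, t_used, q_used, x, y,
                            predict_raw, truncated_at_60) {
  if (length(unique(x)) < 2 || var(y) == 0) {
    dk_skip(sprintf("%s fit is degenerate (zero variance in %s)", model,
                    if (length(unique(x)) < 2) "predictor" else "response"),
            reason = "degenerate data")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- stats::cor(x, y)^2
  pred <- predict_raw(slope, intercept, t_used)
  mpe <- as.vector(compute_mpe(q_used, pred))
  r2_raw <- if (var(pred) == 0) NA_real_ else stats::cor(q_used, pred)^2
  structure(
    list(
      model = model,
      formulation_id = profile$formulation_id,
      rate_constant = NA_real_,   # filled by the caller
      exponent_n = NA_real_,
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      r_squared_raw = r2_raw,
      mpe = mpe,
      n_points_used = length(t_used),
      truncated_at_60 = truncated_at_60,
      times = t_used,
      observed = q_used,
      predicted = pred
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s on %s: k = %.4g%s, R² = %.4f, MPE = %.2f%% (%d points%s)\n",
              x$model, x$formulation_id, x$rate_constant,
              if (!is.na(x$exponent_n)) sprintf(", n = %.3f", x$exponent_n) else "",
              x$r_squared, x$mpe, x$n_points_used,
              if (x$truncated_at_60) ", truncated at 60%" else ""))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.kinetic_fit <- function(x, ...) {
  tibble(
    formulation_id = x$formulation_id, model = x$model,
    rate_constant = x$rate_constant, exponent_n = x$exponent_n,
    intercept = x$intercept, r_squared = x$r_squared,
    r_squared_raw = x$r_squared_raw, mpe = x$mpe,
    n_points_used = x$n_points_used, truncated_at_60 = x$truncated_at_60
  )
}

#' Fit release kinetics models to a dissolution profile
#'
#' Each fitter linearizes its model, runs ordinary least squares on the
#' transformed scale, and reports the squared Pearson correlation on that
#' scale as R-squared together with the mean percentage error
#' ([compute_mpe()]) of the back-transformed predictions on the raw %
#' scale:
#'
#' * `fit_zero_order`: release at a constant rate, `Q = k0 * t + c`; the
#'   rate constant `k0` is in %/min.
#' * `fit_first_order`: release proportional to drug remaining,
#'   `log10(100 - Q) = c - (k1 / 2.303) * t`; points with Q >= 100 are
#'   dropped (the log of remaining drug is undefined there). `k1` is
#'   reported in natural-log units (1/min, transformed-scale slope times
#'   ln 10); the base-10 slope is kept in `$slope`.
#' * `fit_higuchi`: diffusion from an insoluble matrix,
#'   `Q = kH * sqrt(t) + c`; applied after [truncate_to_60()], `kH` in
#'   %/sqrt(min).
#' * `fit_korsmeyer_peppas`: power law `Q = k * t^n`, fitted as
#'   `log10(Q) = log10(k) + n * log10(t)` after [truncate_to_60()]; points
#'   with t = 0 or Q = 0 are excluded (log singularity). The diffusional
#'   exponent `n` diagnoses the transport mechanism
#'   ([classify_mechanism()]).
#'
#' All fitters need at least 3 usable points. Zero- and first-order fits
#' raise an insufficient-data error below that; the truncating fitters
#' (Higuchi, Korsmeyer-Peppas) signal a skip condition instead, which
#' [analyze_profile()] records in `skipped_models` — mirroring release
#' tables where these parameters "cannot be calculated" for fast-releasing
#' formulations.
#'
#' @param profile A [dissolution_profile()].
#' @return An object of class `kinetic_fit` with fields `model`,
#'   `rate_constant`, `exponent_n` (Korsmeyer-Peppas only), `intercept`,
#'   `r_squared` (transformed scale), `r_squared_raw` (diagnostic, raw
#'   scale), `mpe`, `n_points_used`, `truncated_at_60`.
#' @seealso [analyze_profile()], [select_best_model()]
#' @export
fit_zero_order <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  t <- profile$times; q <- profile$release
  if (length(t) < 3) {
    dk_skip("zero-order fit needs at least 3 points",
            reason = "insufficient data")
  }
  out <- new_kinetic_fit("zero_order", profile, t, q, x = t, y = q,
                         predict_raw = function(s, c0, tt) s * tt + c0,
                         truncated_at_60 = FALSE)
  out$rate_constant <- out$slope
  out
}

#' @rdname fit_zero_order
#' @export
fit_first_order <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  keep <- profile$release < 100
  t <- profile$times[keep]; q <- profile$release[keep]
  if (length(t) < 3) {
    dk_skip("first-order fit needs at least 3 points with release < 100%",
            reason = "insufficient data")
  }
  out <- new_kinetic_fit("first_order", profile, t, q,
                         x = t, y = log10(100 - q),
                         predict_raw = function(s, c0, tt) 100 - 10^(c0 + s * tt),
                         truncated_at_60 = FALSE)
  out$rate_constant <- -out$slope * log(10)   # 1/min, natural-log convention
  out
}

#' @rdname fit_zero_order
#' @export
fit_higuchi <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  trunc <- truncate_to_60(profile)
  t <- trunc$times; q <- trunc$release
  if (length(t) < 3) {
    dk_skip("too few points at <= 60% release for the Higuchi model",
            reason = "fast drug release")
  }
  out <- new_kinetic_fit("higuchi", profile, t, q, x = sqrt(t), y = q,
                         predict_raw = function(s, c0, tt) s * sqrt(tt) + c0,
                         truncated_at_60 = TRUE)
  out$rate_constant <- out$slope
  out
}

#' @rdname fit_zero_order
#' @export
fit_korsmeyer_peppas <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  trunc <- truncate_to_60(profile)
  keep <- trunc$times > 0 & trunc$release > 0
  t <- trunc$times[keep]; q <- trunc$release[keep]
  if (length(t) < 3) {
    dk_skip("too few usable points at <= 60% release for the Korsmeyer-Peppas model",
            reason = "fast drug release")
  }
  out <- new_kinetic_fit("korsmeyer_peppas", profile, t, q,
                         x = log10(t), y = log10(q),
                         predict_raw = function(s, c0, tt) 10^c0 * tt^s,
                         truncated_at_60 = TRUE)
  out$exponent_n <- out$slope
  out$rate_constant <- 10^out$intercept
  out
}

#' Mean percentage error of model predictions
#'
#' The average absolute relative deviation of predicted from observed
#' cumulative release, in percent:
#' `MPE = 100 / N * sum(|Q_obs - Q_pred| / Q_obs)`,
#' with predictions on the raw % release scale (back-transformed from the
#' model's linearized scale). Points with observed release <= 0 are
#' excluded (the relative error is undefined there); the count of excluded
#' points is attached as attribute `n_excluded`.
#'
#' @param observed Numeric vector of observed % release.
#' @param predicted Numeric vector of predicted % release, same length.
#' @return MPE in percent (>= 0), with attribute `n_excluded`.
#' @export
#' @examples
#' compute_mpe(c(25, 50), c(30, 45))  # 15
compute_mpe <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    dk_stop_argument("`observed` and `predicted` must have the same length")
  }
  use <- observed > 0
  if (!any(use)) {
    dk_stop("no points with observed release > 0; MPE is undefined",
            "dissolkin_computation_error")
  }
  out <- 100 * mean(abs(observed[use] - predicted[use]) / observed[use])
  attr(out, "n_excluded") <- sum(!use)
  out
}

#' Select the best-fitting kinetics model
#'
#' The primary criterion is the highest R-squared; fits whose R-squared
#' agree within 1e-6 are then ranked by lowest mean percentage error, and
#' any remaining exact tie is broken by model parsimony (zero-order over
#' first-order over Higuchi over Korsmeyer-Peppas), so noise-free data
#' that two nested models reproduce exactly is attributed to the simpler
#' one.
#'
#' @param fits Either a list of `kinetic_fit` objects or a data frame with
#'   columns `model`, `r_squared` and (optionally) `mpe` — the latter form
#'   lets the rule be applied to published goodness-of-fit tables.
#' @return The name of the selected model (character scalar).
#' @export
select_best_model <- function(fits) {
  if (is.data.frame(fits)) {
    df <- fits
    if (!"mpe" %in% names(df)) df$mpe <- NA_real_
  } else {
    if (length(fits) == 0) {
      dk_stop("no fits supplied to select from", "dissolkin_selection_error")
    }
    stopifnot(all(vapply(fits, inherits, logical(1), "kinetic_fit")))
    df <- data.frame(
      model = vapply(fits, `[[`, character(1), "model"),
      r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
      mpe = vapply(fits, `[[`, numeric(1), "mpe")
    )
  }
  if (nrow(df) == 0) {
    dk_stop("no fits supplied to select from", "dissolkin_selection_error")
  }
  best_r2 <- max(df$r_squared)
  cand <- df[df$r_squared >= best_r2 - 1e-6, , drop = FALSE]
  if (nrow(cand) > 1 && !all(is.na(cand$mpe))) {
    best_mpe <- min(cand$mpe, na.rm = TRUE)
    cand <- cand[is.na(cand$mpe) | cand$mpe <= best_mpe + 1e-9, , drop = FALSE]
  }
  cand$model[order(MODEL_PARSIMONY[cand$model])][1]
}

#' Classify the drug transport mechanism from the diffusional exponent
#'
#' Interprets the Korsmeyer-Peppas exponent n with the thresholds used for
#' cylindrical matrices:
#' n < 0.45 Fickian diffusion; 0.45 <= n < 0.89 anomalous (non-Fickian)
#' transport; 0.89 <= n <= 1.0 case II (swelling/relaxation controlled,
#' zero-order-like) transport; n > 1.0 super case II.
#'
#' @param exponent_n Diffusional exponent(s); finite numeric.
#' @return Character vector with values `"fickian"`, `"anomalous"`,
#'   `"case_II"` or `"super_case_II"`.
#' @export
#' @examples
#' classify_mechanism(c(0.30, 0.941, 1.030))
classify_mechanism <- function(exponent_n) {
  if (any(!is.finite(exponent_n))) {
    dk_stop_argument("`exponent_n` must be finite")
  }
  vapply(exponent_n, function(n) {
    if (n < 0.45) "fickian"
    else if (n < 0.89) "anomalous"
    else if (n <= 1.0) "case_II"
    else "super_case_II"
  }, character(1))
}

#' Fit, score and rank all release models for one profile
#'
#' Runs the requested model fits on one dissolution profile, records
#' models that cannot be fitted (with the reason), selects the best model
#' ([select_best_model()]) and classifies the release mechanism from the
#' Korsmeyer-Peppas exponent when that fit exists.
#'
#' Fast-release guard: when fewer than `min_points_60` points lie at
#' <= 60% release, the Higuchi and Korsmeyer-Peppas models are not
#' attempted (reason `"fast drug release"`) — their short-time
#' approximation has no support on such profiles, so only the zero- and
#' first-order models are applied.
#'
#' @param profile A [dissolution_profile()].
#' @param models Character vector of models to fit, a subset of
#'   `c("zero_order", "first_order", "higuchi", "korsmeyer_peppas")`.
#' @param min_points_60 Minimum number of points at <= 60% release needed
#'   to attempt the truncating models; default 4.
#' @return An object of class `model_selection_report` with fields
#'   `formulation_id`, `fits` (named list of `kinetic_fit`), `best_model`,
#'   `mechanism` (`"not_applicable"` without a Korsmeyer-Peppas fit) and
#'   `skipped_models` (tibble of model/reason).
#' @export
analyze_profile <- function(profile, models = KINETIC_MODELS,
                            min_points_60 = 4) {
  stopifnot(inherits(profile, "dissolution_profile"))
  models <- match.arg(models, KINETIC_MODELS, several.ok = TRUE)
  n_below_60 <- sum(profile$release <= 60)

  fitters <- list(
    zero_order = fit_zero_order,
    first_order = fit_first_order,
    higuchi = fit_higuchi,
    korsmeyer_peppas = fit_korsmeyer_peppas
  )
  fits <- list()
  skipped <- tibble(model = character(), reason = character())
  for (m in models) {
    if (m %in% c("higuchi", "korsmeyer_peppas") && n_below_60 < min_points_60) {
      skipped <- rbind(skipped, tibble(model = m, reason = "fast drug release"))
      next
    }
    res <- tryCatch(fitters[[m]](profile), dissolkin_model_skip = function(e) e)
    if (inherits(res, "dissolkin_model_skip")) {
      skipped <- rbind(skipped, tibble(model = m, reason = res$reason))
    } else {
      fits[[m]] <- res
    }
  }
  if (length(fits) == 0) {
    dk_stop(sprintf("no model could be fitted to profile '%s' (%s)",
                    profile$formulation_id,
                    paste(skipped$reason, collapse = "; ")),
            "dissolkin_analysis_error")
  }
  best <- select_best_model(fits)
  mech <- if ("korsmeyer_peppas" %in% names(fits)) {
    classify_mechanism(fits$korsmeyer_peppas$exponent_n)
  } else {
    "not_applicable"
  }
  structure(
    list(
      formulation_id = profile$formulation_id,
      fits = fits,
      best_model = best,
      mechanism = mech,
      skipped_models = skipped
    ),
    class = "model_selection_report"
  )
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("<model_selection_report> %s\n", x$formulation_id))
  for (f in x$fits) {
    cat("  "); print(f)
  }
  if (nrow(x$skipped_models) > 0) {
    cat(sprintf("  skipped: %s\n",
                paste(sprintf("%s (%s)", x$skipped_models$model,
                              x$skipped_models$reason), collapse = ", ")))
  }
  cat(sprintf("  best model: %s; mechanism: %s\n", x$best_model, x$mechanism))
  invisible(x)
}

#' Tabulate kinetic analyses of several profiles
#'
#' Runs [analyze_profile()] on each profile and assembles a wide
#' release-parameters table (one row per profile: R-squared and MPE per
#' model, Korsmeyer-Peppas exponent, best-fit model, mechanism) of the
#' shape conventional in dissolution studies. Models that could not be
#' fitted appear as NA.
#'
#' @param profiles List of [dissolution_profile()] objects.
#' @inheritParams analyze_profile
#' @return A tibble with one row per profile.
#' @export
kinetic_report <- function(profiles, models = KINETIC_MODELS,
                           min_points_60 = 4) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    rep <- analyze_profile(p, models = models, min_points_60 = min_points_60)
    g <- function(m, field) {
      if (m %in% names(rep$fits)) rep$fits[[m]][[field]] else NA_real_
    }
    tibble(
      formulation_id = rep$formulation_id,
      zero_order_r2 = g("zero_order", "r_squared"),
      zero_order_mpe = g("zero_order", "mpe"),
      zero_order_k = g("zero_order", "rate_constant"),
      first_order_r2 = g("first_order", "r_squared"),
      first_order_mpe = g("first_order", "mpe"),
      first_order_k = g("first_order", "rate_constant"),
      higuchi_r2 = g("higuchi", "r_squared"),
      higuchi_mpe = g("higuchi", "mpe"),
      higuchi_k = g("higuchi", "rate_constant"),
      kp_r2 = g("korsmeyer_peppas", "r_squared"),
      kp_mpe = g("korsmeyer_peppas", "mpe"),
      kp_n = g("korsmeyer_peppas", "exponent_n"),
      kp_k = g("korsmeyer_peppas", "rate_constant"),
      best_model = rep$best_model,
      mechanism = rep$mechanism
    )
  })
  do.call(rbind, rows)
}
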