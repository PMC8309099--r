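#' Align two dissolution profiles on common time points
#'
#' Builds the paired (reference, test) release table that the
#' model-independent factors f1 and f2 consume. Alignment requires exact
#' time matches (within 1e-9 min); profiles compared this way are assumed
#' to have been sampled on one shared schedule, so no interpolation is
#' attempted.
#'
#' Point-selection rules:
#' * `"all"` keeps every common time point;
#' * `"fda85"` (the regulatory convention for rapidly dissolving products)
#'   keeps common points up to and including the first at which the
#'   *reference* exceeds 85% release, discarding later points where both
#'   curves sit on their plateau and would inflate apparent similarity.
#'
#' @param reference,test [dissolution_profile()] objects.
#' @param rule Point-selection rule, `"fda85"` (default) or `"all"`.
#' @return An object of class `comparison_set` with fields `times`,
#'   `reference`, `test`, `n_points`.
#' @export
select_points <- function(reference, test, rule = c("fda85", "all")) {
  rule <- match.arg(rule)
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  idx <- outer(reference$times, test$times,
               function(a, b) abs(a - b) < 1e-9)
  ref_i <- which(rowSums(idx) > 0)
  test_i <- apply(idx[ref_i, , drop = FALSE], 1, which.max)
  if (length(ref_i) < 2) {
    dk_stop(sprintf(
      "profiles '%s' and '%s' share fewer than 2 common time points",
      reference$formulation_id, test$formulation_id),
      "dissolkin_comparison_error")
  }
  times <- reference$times[ref_i]
  r <- reference$release[ref_i]
  t_ <- test$release[test_i]
  if (rule == "fda85") {
    over <- which(r > 85)
    if (length(over) > 0) {
      keep <- seq_len(over[1])
      times <- times[keep]; r <- r[keep]; t_ <- t_[keep]
    }
    if (length(times) < 2) {
      dk_stop("fewer than 2 points remain after the 85% truncation rule",
              "dissolkin_comparison_error")
    }
  }
  structure(
    list(times = times, reference = r, test = t_, n_points = length(times)),
    class = "comparison_set"
  )
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> %d aligned points, t = %g..%g min\n",
              x$n_points, min(x$times), max(x$times)))
  invisible(x)
}

#' Difference factor f1
#'
#' The normalized cumulative absolute difference between a reference and a
#' test dissolution profile:
#' `f1 = 100 * sum(|R_t - T_t|) / sum(R_t)`.
#'
#' f1 is 0 for identical profiles, grows with divergence, is asymmetric in
#' (reference, test) because of the reference-sum denominator, and has no
#' upper bound (values well above 100 occur for strongly divergent
#' profiles).
#'
#' @param set A `comparison_set` from [select_points()].
#' @return The f1 value (dimensionless, >= 0).
#' @export
difference_factor <- function(set) {
  stopifnot(inherits(set, "comparison_set"))
  denom <- sum(set$reference)
  if (denom <= 0) {
    dk_stop(paste("f1 is undefined for an all-zero reference profile",
                  "(sum of reference release is 0)"),
            "dissolkin_computation_error")
  }
  100 * sum(abs(set$reference - set$test)) / denom
}

#' Similarity factor f2
#'
#' The logarithmic reciprocal-square-root transform of the mean squared
#' difference between two profiles:
#' `f2 = 50 * log10(100 * (1 + mean((R_t - T_t)^2))^(-1/2))`,
#' equivalently `f2 = 100 - 25 * log10(1 + mean squared difference)`.
#'
#' f2 equals 100 for identical profiles, 50 at a root-mean-square
#' difference of about 10%, and may be negative for extremely divergent
#' profiles (no lower clamp is applied). f2 is symmetric under swapping
#' reference and test.
#'
#' @inheritParams difference_factor
#' @return The f2 value (dimensionless, <= 100).
#' @export
similarity_factor <- function(set) {
  stopifnot(inherits(set, "comparison_set"))
  if (set$n_points < 2) {
    dk_stop("f2 needs at least 2 aligned points", "dissolkin_comparison_error")
  }
  msd <- mean((set$reference - set$test)^2)
  50 * log10(100 * (1 + msd)^(-0.5))
}

#' Profile equivalence verdict from f1 and f2
#'
#' Two dissolution profiles are declared equivalent when the difference
#' factor lies in \[0, 15\] and the similarity factor in \[50, 100\] — the
#' acceptance bands used in regulatory profile comparison.
#'
#' @param f1 Difference factor value.
#' @param f2 Similarity factor value.
#' @return `TRUE` if both factors fall in their acceptance bands.
#' @export
#' @examples
#' equivalence_verdict(3.50, 79.65)  # TRUE
#' equivalence_verdict(49, 34)       # FALSE
equivalence_verdict <- function(f1, f2) {
  if (!is.finite(f1) || !is.finite(f2)) {
    dk_stop_argument("`f1` and `f2` must be finite")
  }
  f1 >= 0 && f1 <= 15 && f2 >= 50 && f2 <= 100
}

#' Compare two dissolution profiles
#'
#' Convenience wrapper: aligns the profiles ([select_points()]), computes
#' f1 and f2, and applies the equivalence rule. When a list of replicate
#' profiles is supplied for either side, the pointwise mean profile over
#' replicates is compared (replicates must share one sampling schedule).
#'
#' @param reference,test A [dissolution_profile()] or a list of replicate
#'   profiles of one formulation.
#' @inheritParams select_points
#' @return An object of class `comparison_result` with fields `f1`, `f2`,
#'   `n_points_used`, `equivalent`, `reference_id`, `test_id`, `rule`.
#' @export
compare_profiles <- function(reference, test, rule = c("fda85", "all")) {
  rule <- match.arg(rule)
  reference <- mean_profile(reference)
  test <- mean_profile(test)
  set <- select_points(reference, test, rule)
  f1 <- difference_factor(set)
  f2 <- similarity_factor(set)
  structure(
    list(
      reference_id = reference$formulation_id,
      test_id = test$formulation_id,
      rule = rule,
      f1 = f1,
      f2 = f2,
      n_points_used = set$n_points,
      equivalent = equivalence_verdict(f1, f2)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s (rule %s)\n",
              x$reference_id, x$test_id, x$rule))
  cat(sprintf("  f1 = %.2f, f2 = %.2f over %d points: %s\n",
              x$f1, x$f2, x$n_points_used,
              if (x$equivalent) "equivalent" else "NOT equivalent"))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.comparison_result <- function(x, ...) {
  tibble(
    reference_id = x$reference_id, test_id = x$test_id, rule = x$rule,
    f1 = x$f1, f2 = x$f2, n_points_used = x$n_points_used,
    equivalent = x$equivalent
  )
}

#' Pointwise mean profile over replicates
#'
#' Averages cumulative release over replicate profiles of one formulation,
#' point by point. All replicates must share the same sampling times.
#'
#' @param profiles A list of [dissolution_profile()] objects (a single
#'   profile is returned unchanged).
#' @return A [dissolution_profile()] with `replicate_id = "mean"` (when
#'   averaging happened).
#' @export
mean_profile <- function(profiles) {
  if (inherits(profiles, "dissolution_profile")) return(profiles)
  stopifnot(is.list(profiles), length(profiles) > 0)
  if (length(profiles) == 1) return(profiles[[1]])
  times <- profiles[[1]]$times
  for (p in profiles[-1]) {
    if (length(p$times) != length(times) || any(abs(p$times - times) > 1e-9)) {
      dk_stop_validation("replicate profiles must share one sampling schedule")
    }
  }
  rel <- rowMeans(vapply(profiles, function(p) p$release, numeric(length(times))))
  dissolution_profile(
    formulation_id = profiles[[1]]$formulation_id,
    times = times, release = rel, ph = profiles[[1]]$ph,
    replicate_id = "mean"
  )
}
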