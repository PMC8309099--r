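#' Run a full dissolution study from one configuration
#'
#' Orchestrates the whole pipeline from a single config (an R list, or a
#' path to a YAML/JSON file): read and/or simulate dissolution profiles,
#' compute profile comparisons (f1/f2/verdict per pair), the kinetic
#' release-parameters table, the derived formulation-composition table and
#' the powder QC table, and write everything to `output_dir` as CSV plus a
#' JSON summary and a manifest (package version, root seed, input file
#' digests). The same config and seed reproduce all reports exactly.
#'
#' Config fields (all optional unless a stage needs them):
#' \describe{
#'   \item{seed}{Root seed; per-simulation streams are derived from it so
#'     stages can be re-run in isolation.}
#'   \item{profiles_csv}{Path to a profile CSV ([read_profiles()]).}
#'   \item{simulations}{List of specs, each with `id`, `model`, `k`,
#'     optional `n`, `noise_sd`, `replicates`, `cap`, `monotone`.}
#'   \item{comparisons}{List of `reference` / `test` / optional `rule`
#'     entries referring to formulation ids.}
#'   \item{models, min_points_60}{Passed to [kinetic_report()].}
#'   \item{formulations}{`"propranolol"` for the built-in composition
#'     table, or a list of rows with the [formulation()] fields.}
#'   \item{qc_csv}{Path to a replicate powder-measurement CSV
#'     ([qc_report()]).}
#' }
#'
#' Numeric report columns are rounded at serialization only: 2 decimals
#' for percentages, f1/f2 and MPE, 3 for R-squared and the diffusional
#' exponent.
#'
#' @param config An R list, or path to a YAML or JSON config file.
#' @param output_dir Directory for the report files; overrides the config
#'   field. `NULL` skips writing and just returns the bundle.
#' @return Invisibly, a list with tibbles `comparisons`, `kinetics`,
#'   `formulations`, `qc`, the profile list, and the `manifest` list.
#' @export
run_study <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- read_study_config(config_path)
  } else {
    config_path <- NA_character_
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  output_dir <- output_dir %||% config$output_dir

  profiles <- list()
  input_digests <- character()
  if (!is.null(config$profiles_csv)) {
    profiles <- read_profiles(config$profiles_csv)
    input_digests[config$profiles_csv] <- unname(tools::md5sum(config$profiles_csv))
  }
  if (!is.null(config$simulations)) {
    sim_seeds <- derive_seeds(seed, length(config$simulations))
    for (i in seq_along(config$simulations)) {
      s <- config$simulations[[i]]
      if (is.null(s$model) || is.null(s$k)) {
        dk_stop_argument(sprintf("simulation %d needs `model` and `k`", i))
      }
      sim <- simulate_profile(
        model = s$model, params = list(k = s$k, n = s$n),
        schedule = s$schedule %||% two_stage_schedule(),
        noise_sd = s$noise_sd %||% 0, cap = s$cap %||% 100,
        monotone = isTRUE(s$monotone), n_replicates = s$replicates %||% 1,
        seed = sim_seeds[i], formulation_id = s$id %||% sprintf("SIM-%d", i)
      )
      profiles <- c(profiles, sim)
    }
  }

  by_id <- split(profiles,
                 vapply(profiles, `[[`, character(1), "formulation_id"))

  comparisons <- NULL
  if (!is.null(config$comparisons)) {
    rows <- lapply(config$comparisons, function(cp) {
      for (side in c("reference", "test")) {
        if (!cp[[side]] %in% names(by_id)) {
          dk_stop_argument(sprintf(
            "comparison stage: formulation id '%s' not found", cp[[side]]))
        }
      }
      res <- compare_profiles(by_id[[cp$reference]], by_id[[cp$test]],
                              rule = cp$rule %||% "fda85")
      as_tibble(res)
    })
    comparisons <- do.call(rbind, rows)
  }

  kinetics <- NULL
  if (length(profiles) > 0) {
    means <- lapply(by_id, mean_profile)
    kinetics <- kinetic_report(
      means,
      models = config$models %||% KINETIC_MODELS,
      min_points_60 = config$min_points_60 %||% 4
    )
  }

  formulations <- NULL
  if (!is.null(config$formulations)) {
    formulations <- if (identical(config$formulations, "propranolol")) {
      formulation_report(propranolol_formulations())
    } else {
      rows <- lapply(config$formulations, function(r) {
        tibble(formulation_id = r$formulation_id,
               vehicle_name = r$vehicle_name %||% "",
               api_mass = r$api_mass,
               vehicle_mass = r$vehicle_mass %||% 0,
               avicel_mass = r$avicel_mass,
               eudragit_mass = r$eudragit_mass %||% 0,
               aerosil_mass = r$aerosil_mass)
      })
      formulation_report(do.call(rbind, rows))
    }
  }

  qc <- NULL
  if (!is.null(config$qc_csv)) {
    qc <- qc_report(read.csv(config$qc_csv, stringsAsFactors = FALSE))
    input_digests[config$qc_csv] <- unname(tools::md5sum(config$qc_csv))
  }

  manifest <- list(
    package = "dissolkin",
    version = as.character(utils::packageVersion("dissolkin")),
    seed = seed,
    config_path = config_path,
    input_digests = as.list(input_digests),
    n_profiles = length(profiles)
  )
  bundle <- list(profiles = profiles, comparisons = comparisons,
                 kinetics = kinetics, formulations = formulations, qc = qc,
                 manifest = manifest)
  if (!is.null(output_dir)) write_study_reports(bundle, output_dir)
  invisible(bundle)
}

read_study_config <- function(path) {
  if (!file.exists(path)) {
    dk_stop_argument(sprintf("config file '%s' does not exist", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_study_reports <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(output_dir, name)
  if (!is.null(bundle$comparisons)) {
    df <- bundle$comparisons
    df$f1 <- round(df$f1, 2); df$f2 <- round(df$f2, 2)
    write.csv(df, out("comparisons.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$kinetics)) {
    df <- bundle$kinetics
    for (col in grep("_r2$", names(df), value = TRUE)) df[[col]] <- round(df[[col]], 3)
    for (col in grep("_mpe$", names(df), value = TRUE)) df[[col]] <- round(df[[col]], 2)
    df$kp_n <- round(df$kp_n, 3)
    write.csv(df, out("kinetics.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$formulations)) {
    write.csv(bundle$formulations, out("formulations.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$qc)) {
    df <- bundle$qc
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 2)
    write.csv(df, out("qc.csv"), row.names = FALSE)
  }
  if (length(bundle$profiles) > 0) {
    write_profiles(bundle$profiles, out("profiles.csv"))
  }
  jsonlite::write_json(
    list(manifest = bundle$manifest,
         summary = list(
           n_profiles = length(bundle$profiles),
           n_comparisons = if (is.null(bundle$comparisons)) 0 else nrow(bundle$comparisons),
           n_formulations = if (is.null(bundle$formulations)) 0 else nrow(bundle$formulations)
         )),
    out("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method tibble::as_tibble
as_tibble.formulation <- function(x, ...) {
  tibble(
    formulation_id = x$formulation_id, vehicle_name = x$vehicle_name,
    api_mass = x$api_mass, vehicle_mass = x$vehicle_mass,
    avicel_mass = x$avicel_mass, eudragit_mass = x$eudragit_mass,
    aerosil_mass = x$aerosil_mass
  )
}
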