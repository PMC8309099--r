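#' Liquisolid / Liqui-Mass formulation composition
#'
#' Holds the component masses of one dosage form: the active ingredient
#' (API), the non-volatile liquid vehicle in which it is solubilized
#' (zero for physical mixtures), the carrier excipients (microcrystalline
#' cellulose, i.e. Avicel, plus the matrix retardant Eudragit RS PO, which
#' is counted as part of the carrier), and the fine coating material
#' (colloidal silica, Aerosil). Granulating water and compression force
#' are process records only — the water evaporates during drying and never
#' contributes to dosage-form mass.
#'
#' @param formulation_id Character label.
#' @param api_mass API mass in mg; > 0.
#' @param vehicle_mass Liquid vehicle mass in mg; >= 0 (0 for physical
#'   mixtures).
#' @param avicel_mass Avicel (MCC carrier) mass in mg.
#' @param eudragit_mass Eudragit RS PO mass in mg; >= 0.
#' @param aerosil_mass Aerosil (coating) mass in mg.
#' @param vehicle_name Name of the liquid vehicle; `""` for physical
#'   mixtures.
#' @param water_volume_per_20g Granulating water (mL per 20 g admixture);
#'   process record only.
#' @param compression_force Compression force in PSI; record only.
#' @return An object of class `formulation`.
#' @export
#' @examples
#' f1 <- formulation("F-1", api_mass = 80, vehicle_mass = 40,
#'                   avicel_mass = 180, aerosil_mass = 9,
#'                   vehicle_name = "Tween 80")
#' total_mass(f1)          # 309
#' liquid_load_factor(f1)  # 0.667
formulation <- function(formulation_id, api_mass, vehicle_mass = 0,
                        avicel_mass, eudragit_mass = 0, aerosil_mass,
                        vehicle_name = "", water_volume_per_20g = NA_real_,
                        compression_force = NA_real_) {
  masses <- c(api_mass, vehicle_mass, avicel_mass, eudragit_mass, aerosil_mass)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    dk_stop_validation("all component masses must be finite and >= 0")
  }
  if (api_mass <= 0) dk_stop_validation("`api_mass` must be > 0")
  if (avicel_mass + eudragit_mass <= 0) {
    dk_stop_validation("carrier mass (avicel + eudragit) must be > 0")
  }
  structure(
    list(
      formulation_id = as.character(formulation_id),
      api_mass = api_mass, vehicle_mass = vehicle_mass,
      avicel_mass = avicel_mass, eudragit_mass = eudragit_mass,
      aerosil_mass = aerosil_mass, vehicle_name = as.character(vehicle_name),
      water_volume_per_20g = water_volume_per_20g,
      compression_force = compression_force
    ),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> %s: API %g mg", x$formulation_id, x$api_mass))
  if (x$vehicle_mass > 0) {
    cat(sprintf(" in %g mg %s", x$vehicle_mass,
                if (nzchar(x$vehicle_name)) x$vehicle_name else "vehicle"))
  }
  cat(sprintf("; Avicel %g, Eudragit %g, Aerosil %g mg; total %g mg\n",
              x$avicel_mass, x$eudragit_mass, x$aerosil_mass, total_mass(x)))
  invisible(x)
}

#' Total dosage-form mass
#'
#' Sum of API, liquid vehicle, carrier (Avicel + Eudragit) and coating
#' (Aerosil) masses. Granulating water is excluded: it is removed by
#' evaporation during drying.
#'
#' @param f A [formulation()].
#' @return Total mass in mg.
#' @export
total_mass <- function(f) {
  stopifnot(inherits(f, "formulation"))
  f$api_mass + f$vehicle_mass + f$avicel_mass + f$eudragit_mass + f$aerosil_mass
}

#' Liquid load factor
#'
#' The classical liquisolid ratio of liquid medication to carrier:
#' `Lf = (api_mass + vehicle_mass) / (avicel_mass + eudragit_mass)`.
#' The liquid medication is the API together with its non-volatile
#' vehicle; the matrix retardant (Eudragit RS PO) is counted as part of
#' the carrier, since it is blended into the carrier bed exactly as the
#' MCC is.
#'
#' @inheritParams total_mass
#' @return The liquid load factor (dimensionless).
#' @export
liquid_load_factor <- function(f) {
  stopifnot(inherits(f, "formulation"))
  carrier <- f$avicel_mass + f$eudragit_mass
  if (carrier <= 0) {
    dk_stop("liquid load factor is undefined with zero carrier mass",
            "dissolkin_computation_error")
  }
  (f$api_mass + f$vehicle_mass) / carrier
}

#' Liquid vehicle content in percent by weight
#'
#' `100 * vehicle_mass / total_mass`.
#'
#' @inheritParams total_mass
#' @return Vehicle content in % w/w.
#' @export
vehicle_percent <- function(f) {
  component_percent(f, "vehicle")
}

#' Component content in percent by weight
#'
#' `100 * component mass / total dosage-form mass` for any single
#' component.
#'
#' @inheritParams total_mass
#' @param component One of `"api"`, `"vehicle"`, `"avicel"`, `"eudragit"`,
#'   `"aerosil"`.
#' @return Component content in % w/w.
#' @export
#' @examples
#' f8 <- formulation("F-8", api_mass = 80, vehicle_mass = 60,
#'                   avicel_mass = 45, eudragit_mass = 135, aerosil_mass = 9)
#' component_percent(f8, "eudragit")  # 41.03
component_percent <- function(f, component) {
  stopifnot(inherits(f, "formulation"))
  component <- match.arg(component,
                         c("api", "vehicle", "avicel", "eudragit", "aerosil"))
  mass <- f[[paste0(component, "_mass")]]
  100 * mass / total_mass(f)
}

#' Carrier-to-coating mass ratio
#'
#' `(avicel_mass + eudragit_mass) / aerosil_mass`; liquisolid designs
#' conventionally hold this ratio fixed (20:1 here) across formulations.
#'
#' @inheritParams total_mass
#' @return The ratio (dimensionless).
#' @export
carrier_coating_ratio <- function(f) {
  stopifnot(inherits(f, "formulation"))
  if (f$aerosil_mass <= 0) {
    dk_stop("carrier:coating ratio is undefined with zero coating mass",
            "dissolkin_computation_error")
  }
  (f$avicel_mass + f$eudragit_mass) / f$aerosil_mass
}

#' Infer the liquid vehicle mass from the total tablet mass
#'
#' Inverse bookkeeping for composition tables that print the total mass
#' but not the vehicle mass:
#' `vehicle = total - (api + avicel + eudragit + aerosil)`.
#'
#' @param total Total dosage-form mass in mg.
#' @param api,avicel,eudragit,aerosil Component masses in mg.
#' @param formulation_id Optional label used in the error message.
#' @return Vehicle mass in mg (0 for a physical mixture).
#' @export
infer_vehicle_mass <- function(total, api, avicel, eudragit = 0, aerosil = 0,
                               formulation_id = NULL) {
  vehicle <- total - (api + avicel + eudragit + aerosil)
  if (any(vehicle < 0)) {
    lab <- if (is.null(formulation_id)) "" else sprintf(" in row '%s'", formulation_id)
    dk_stop_validation(sprintf(
      "total mass below the sum of named solids%s: inconsistent composition", lab))
  }
  vehicle
}

#' Composition of ten sustained-release propranolol tablet formulations
#'
#' The component masses of a published development series of 80 mg
#' propranolol hydrochloride matrix tablets made by Liqui-Mass
#' (extrusion-spheronized pellet) technology: two physical-mixture tablets
#' (PMT-1 without and PMT-2 with the Eudragit RS PO retardant) and eight
#' Liqui-Tablets (F-1..F-8) varying the liquid vehicle (Tween 80,
#' Tween 20, Kolliphor EL), vehicle level and retardant level. Vehicle
#' mass is not printed in such composition tables; it is recovered with
#' [infer_vehicle_mass()]. The carrier-to-coating ratio is 20:1
#' throughout.
#'
#' @return A tibble with columns `formulation_id`, `vehicle_name`,
#'   `api_mass`, `avicel_mass`, `aerosil_mass`, `eudragit_mass`,
#'   `water_volume_per_20g`, `compression_force`, `total_mass_mg` (all
#'   masses in mg).
#' @export
propranolol_formulations <- function() {
  tibble(
    formulation_id = c("PMT-1", "PMT-2", paste0("F-", 1:8)),
    vehicle_name = c("", "", "Tween 80", "Tween 20", "Kolliphor EL",
                     "Tween 20", "Tween 20", "Tween 20", "Tween 20", "Tween 20"),
    api_mass = rep(80, 10),
    avicel_mass = c(180, 135, 180, 180, 180, 180, 180, 135, 90, 45),
    aerosil_mass = rep(9, 10),
    eudragit_mass = c(0, 45, 0, 0, 0, 0, 0, 45, 90, 135),
    water_volume_per_20g = c(22.3, 14.9, 12.9, 12.9, 12.9, 12.2, 11.5, 9.7, 4.86, 3.0),
    compression_force = c(1000, rep(1400, 9)),
    total_mass_mg = c(269, 269, 309, 309, 309, 329, 349, 329, 329, 329)
  )
}

#' Derived composition table for a set of formulations
#'
#' Computes the derived columns of a liquisolid composition table — total
#' mass, liquid load factor, vehicle and retardant % w/w,
#' carrier-to-coating ratio — for a list of [formulation()] objects or a
#' composition tibble like [propranolol_formulations()] (vehicle mass
#' inferred from the printed total when a `total_mass_mg` column is
#' present). Percentages and ratios are rounded to 2 decimals at this
#' reporting layer only; the underlying functions return full precision.
#'
#' @param formulations A list of [formulation()] objects, or a data frame
#'   with the component-mass columns of [propranolol_formulations()].
#' @return A tibble with one row per formulation.
#' @export
formulation_report <- function(formulations = propranolol_formulations()) {
  if (is.data.frame(formulations)) {
    formulations <- lapply(seq_len(nrow(formulations)), function(i) {
      row <- formulations[i, ]
      vehicle <- if ("vehicle_mass" %in% names(row)) {
        row$vehicle_mass
      } else {
        infer_vehicle_mass(row$total_mass_mg, row$api_mass, row$avicel_mass,
                           row$eudragit_mass, row$aerosil_mass,
                           formulation_id = row$formulation_id)
      }
      formulation(row$formulation_id, api_mass = row$api_mass,
                  vehicle_mass = vehicle, avicel_mass = row$avicel_mass,
                  eudragit_mass = row$eudragit_mass,
                  aerosil_mass = row$aerosil_mass,
                  vehicle_name = if ("vehicle_name" %in% names(row)) row$vehicle_name else "")
    })
  }
  rows <- lapply(formulations, function(f) {
    tibble(
      formulation_id = f$formulation_id,
      vehicle_name = f$vehicle_name,
      vehicle_mass_mg = f$vehicle_mass,
      total_mass_mg = total_mass(f),
      liquid_load_factor = round(liquid_load_factor(f), 2),
      vehicle_pct_ww = round(vehicle_percent(f), 2),
      eudragit_pct_ww = round(component_percent(f, "eudragit"), 2),
      carrier_coating_ratio = round(carrier_coating_ratio(f), 2)
    )
  })
  do.call(rbind, rows)
}
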