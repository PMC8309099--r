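# Small builders shared across test files.

# A plain single-stage profile on an arbitrary grid.
make_profile <- function(times, release, id = "TEST", ...) {
  dissolution_profile(id, times = times, release = release, ...)
}

# Noise-free profile from a named model on the standard two-stage schedule,
# with parameters chosen to stay below the 100% cap over the whole run.
oracle_profile <- function(model, params, schedule = two_stage_schedule(),
                           id = model) {
  simulate_profile(model, params, schedule = schedule, noise_sd = 0,
                   formulation_id = id)[[1]]
}

# Replicate powder-measurement table for qc_report tests.
powder_fixture <- function(id = "P-1", bulk = 0.42, tapped = 0.50,
                           height = 2.0, radius = 4.4,
                           flow_mass = 20.58, flow_time = 3) {
  data.frame(
    formulation_id = id, bulk_density = bulk, tapped_density = tapped,
    cone_height = height, cone_radius = radius,
    flow_mass_g = flow_mass, flow_time_s = flow_time
  )
}
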