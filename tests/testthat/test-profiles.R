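test_that("constructor enforces profile invariants", {
  expect_error(make_profile(c(0, 15, 15), c(0, 5, 10)),
               class = "dissolkin_validation_error")
  expect_error(make_profile(c(-5, 15), c(0, 5)),
               class = "dissolkin_validation_error")
  expect_error(make_profile(c(0, 15), c(0, 115)),
               class = "dissolkin_validation_error")
  expect_error(make_profile(c(0, 15), c(0, -1)),
               class = "dissolkin_validation_error")
  # slight analytical overshoot above 100% is legitimate
  expect_s3_class(make_profile(c(0, 15), c(0, 104)), "dissolution_profile")
})

test_that("stage table and per-point pH are consistent both ways", {
  stages <- data.frame(start_time = c(0, 120), pH = c(1.2, 7.4))
  p <- make_profile(c(15, 60, 120, 240, 480), c(2, 8, 15, 25, 40),
                    stages = stages)
  # the sample at the changeover time still comes from the outgoing medium
  expect_equal(p$ph, c(1.2, 1.2, 1.2, 7.4, 7.4))
  expect_equal(as.data.frame(profile_stages(p)), stages)
  expect_error(
    make_profile(c(15, 30), c(1, 2),
                 stages = data.frame(start_time = c(10, 120), pH = c(1.2, 7.4))),
    class = "dissolkin_validation_error")
})

test_that("read_profiles parses, groups and validates CSV input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("formulation_id,time_min,release_pct",
               "A,0,0", "A,15,10", "A,30,20"), path)
  profs <- read_profiles(path)
  expect_length(profs, 1)
  expect_equal(profs[[1]]$times, c(0, 15, 30))
  expect_equal(profs[[1]]$release, c(0, 10, 20))

  # two replicates of one formulation give two profiles sharing the id
  writeLines(c("formulation_id,replicate,time_min,release_pct",
               "A,r1,15,10", "A,r1,30,20", "A,r2,15,11", "A,r2,30,19"), path)
  profs <- read_profiles(path)
  expect_length(profs, 2)
  expect_equal(vapply(profs, `[[`, character(1), "formulation_id"),
               c("A", "A"))
  expect_equal(vapply(profs, `[[`, character(1), "replicate_id"),
               c("r1", "r2"))

  # unsorted rows are sorted by time; duplicated times are an error
  writeLines(c("formulation_id,time_min,release_pct",
               "A,30,20", "A,15,10"), path)
  expect_equal(read_profiles(path)[[1]]$times, c(15, 30))
  writeLines(c("formulation_id,time_min,release_pct",
               "A,15,10", "A,15,12"), path)
  expect_error(read_profiles(path), "duplicated sampling times",
               class = "dissolkin_validation_error")

  writeLines(c("formulation_id,minutes,release_pct", "A,15,10"), path)
  expect_error(read_profiles(path), "time_min",
               class = "dissolkin_format_error")
  # ...unless a dialect maps the odd column name
  writeLines(c("formulation_id,minutes,release_pct",
               "A,15,10", "A,30,20"), path)
  profs <- read_profiles(path, dialect = c(time_min = "minutes"))
  expect_equal(profs[[1]]$times, c(15, 30))
})

test_that("write then read round-trips values exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_profile("higuchi", list(k = 6.5), noise_sd = 1,
                          n_replicates = 2, seed = 11, formulation_id = "F-8")
  write_profiles(sim, path)
  back <- read_profiles(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$times, sim[[i]]$times, tolerance = 1e-12)
    expect_equal(back[[i]]$release, sim[[i]]$release, tolerance = 1e-12)
    expect_equal(back[[i]]$ph, sim[[i]]$ph)
    expect_equal(back[[i]]$formulation_id, sim[[i]]$formulation_id)
  }

  # empty collection -> header-only file
  write_profiles(list(), path)
  expect_equal(readLines(path),
               "formulation_id,replicate,time_min,release_pct,pH")

  # 5 profiles x 14 points -> 70 data rows
  many <- lapply(1:5, function(i) {
    make_profile(seq(15, 15 * 14, by = 15), seq(2, 28, by = 2),
                 id = sprintf("P%d", i))
  })
  write_profiles(many, path)
  expect_length(readLines(path), 71)
})

test_that("absorbance_to_release applies the calibration arithmetic", {
  cal <- calibration_line(slope = 0.08)
  expect_equal(
    absorbance_to_release(1.0, cal, dilution_factor = 1,
                          vessel_volume = 900, dose = 80),
    90)
  expect_equal(
    absorbance_to_release(0, cal, vessel_volume = 900, dose = 80), 0)
  a <- c(0.2, 0.5, 0.9)
  base <- absorbance_to_release(a, cal, vessel_volume = 900, dose = 80)
  # affine in absorbance, linear in the dilution factor
  expect_equal(
    absorbance_to_release(a, cal, dilution_factor = 2,
                          vessel_volume = 900, dose = 80),
    2 * base)
  cal2 <- calibration_line(slope = 0.08, intercept = 0.01)
  shift <- absorbance_to_release(a, cal2, vessel_volume = 900, dose = 80)
  expect_equal(shift - base, rep(0.01 * 900 / 80 * 100, 3))

  # withdrawal correction adds back the aliquot mass removed earlier
  corr <- absorbance_to_release(a, cal, vessel_volume = 900, dose = 80,
                                sample_volume = 9)
  expect_equal(corr[1], base[1])
  expect_equal(corr[2], base[2] + 9 / 900 * base[1])
  expect_equal(corr[3], base[3] + 9 / 900 * (base[1] + base[2]))

  expect_error(absorbance_to_release(a, cal, vessel_volume = 900, dose = 0),
               class = "dissolkin_argument_error")
  expect_error(absorbance_to_release(a, cal, vessel_volume = 0, dose = 80),
               class = "dissolkin_argument_error")
  expect_error(calibration_line(slope = -1),
               class = "dissolkin_argument_error")
})
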