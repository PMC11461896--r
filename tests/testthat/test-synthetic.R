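test_that("generator and estimators are an identity at zero noise", {
  sc <- synthetic_scenario(noise_sd = 0, seed = 5)
  hs <- generate_headspace_dataset(sc)
  recovered <- vapply(seq_len(nrow(hs)), function(i)
    dissolved_concentration(headspace_vial(
      hs$water_volume_ml[i], hs$headspace_volume_ml[i], hs$equil_temp_c[i],
      hs$pressure_atm[i], hs$ch4_ppm[i])), numeric(1))
  expect_equal(recovered, hs$true_ch4_um, tolerance = 1e-12)

  inc <- generate_incubation_dataset(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(inc, path, row.names = FALSE)
  assays <- read_incubation_csv(path)
  expect_equal(net_volumetric_rate(assays$river), -2.97, tolerance = 1e-12)
  expect_equal(net_volumetric_rate(assays$lake), 0.12, tolerance = 1e-12)
  # a zero true rate is recognized as balanced
  flat <- synthetic_scenario(sites = "pond", true_concentration_um = 1,
                             true_rate_um_l_d = 0, incubation_c0_um = NULL,
                             duration_h = 24, noise_sd = 0, seed = 5)
  a <- generate_incubation_dataset(flat)
  expect_identical(
    net_rate(incubation_assay("pond", a$ch4_um[a$phase == "initial"],
                              a$ch4_um[a$phase == "final"], 24))$direction,
    "balanced")
})

test_that("identical seeds give identical datasets and files", {
  sc <- synthetic_scenario(seed = 99)
  expect_identical(generate_headspace_dataset(sc),
                   generate_headspace_dataset(sc))
  expect_identical(generate_incubation_dataset(sc),
                   generate_incubation_dataset(sc))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_dataset(sc, d1)
  p2 <- write_synthetic_dataset(sc, d2)
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  # different seed, different measurements
  expect_false(identical(
    generate_headspace_dataset(synthetic_scenario(seed = 1))$ch4_ppm,
    generate_headspace_dataset(synthetic_scenario(seed = 2))$ch4_ppm))
})

test_that("recovered concentration mean stays within the sampling-error bound", {
  sc <- synthetic_scenario(sites = "river", true_concentration_um = 0.536,
                           true_rate_um_l_d = -2.97, incubation_c0_um = 3.0,
                           duration_h = 21, noise_sd = 0.01,
                           n_replicates = 2, seed = 21)
  hs <- generate_headspace_dataset(sc)
  recovered <- vapply(seq_len(nrow(hs)), function(i)
    dissolved_concentration(headspace_vial(
      hs$water_volume_ml[i], hs$headspace_volume_ml[i], hs$equil_temp_c[i],
      hs$pressure_atm[i], hs$ch4_ppm[i])), numeric(1))
  expect_lt(abs(mean(recovered) - 0.536), 3 * 0.01 / sqrt(2))
})

test_that("rate estimator is unbiased over 200 simulated triplicate assays", {
  estimates <- vapply(1:200, function(s) {
    inc <- generate_incubation_dataset(recovery_scenario(seed = s))
    net_volumetric_rate(incubation_assay(
      "river", inc$ch4_um[inc$phase == "initial"],
      inc$ch4_um[inc$phase == "final"], 21))
  }, numeric(1))
  se <- stats::sd(estimates) / sqrt(length(estimates))
  expect_lt(abs(mean(estimates) - (-2.97)), 2 * se)
})

test_that("negative simulated finals are truncated at zero and flagged", {
  crash <- synthetic_scenario(sites = "river", true_concentration_um = 0.5,
                              true_rate_um_l_d = -5, incubation_c0_um = 0.5,
                              duration_h = 24, noise_sd = 0, seed = 1)
  inc <- generate_incubation_dataset(crash)
  finals <- inc[inc$phase == "final", ]
  expect_true(all(finals$ch4_um == 0))
  expect_true(all(finals$truncated))
  expect_false(any(inc$truncated[inc$phase == "initial"]))
})

test_that("scenario invariants are enforced", {
  expect_error(synthetic_scenario(noise_sd = -1), "noise_sd")
  expect_error(synthetic_scenario(n_replicates = 0), "n_replicates")
  expect_error(synthetic_scenario(true_concentration_um = 1), "length")
})
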