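test_that("the energy shift between maxima follows hc arithmetic", {
  expect_equal(shift_ev(477, 523), hc_ev_nm() * (1 / 477 - 1 / 523))
  expect_lt(abs(shift_ev(477, 523) - 0.2286), 5e-5)
  expect_lt(abs(shift_ev(426, 471) - 0.2781), 5e-5)
  expect_equal(shift_ev(500, 500), 0)
  expect_error(shift_ev(-1, 500), class = "specens_argument_error")
  set.seed(13)
  l1 <- runif(20, 300, 700)
  l2 <- runif(20, 300, 700)
  expect_equal(shift_ev(l1, l2), -shift_ev(l2, l1), tolerance = 1e-12)
})

test_that("solvent shifts are plain wavelength differences", {
  expect_equal(solvent_shift_nm(561, 477), 84)
  expect_equal(solvent_shift_nm(486, 418), 68)
  expect_equal(solvent_shift_nm(500, 500), 0)
})

test_that("a full-circle window reproduces the whole conformational spectrum", {
  scen <- default_scenario("gas")
  scen$schedule$duration_ps <- 400 # 101 frames -> 11 conformers
  dat <- gen_scenario_data(scen, seed = 6)
  full <- normalize_spectrum(reconstruct_spectrum(dat$conf, broadening_params()))
  win <- windowed_spectrum(dat$conf, dat$angles, 0, 180, broadening_params())
  expect_equal(win$intensity, full$intensity, tolerance = 1e-12)
})

test_that("an unpopulated window errors and names nearby angles", {
  scen <- default_scenario("gas")
  scen$schedule$duration_ps <- 400
  dat <- gen_scenario_data(scen, seed = 6)
  expect_error(
    windowed_spectrum(dat$conf, dat$angles, 90, 1, broadening_params()),
    class = "specens_empty_window", regexp = "nearest")
  expect_error(
    windowed_spectrum(dat$conf, dat$angles, 90, 0, broadening_params()),
    class = "specens_argument_error")
})

test_that("a window at the coupling reference blue-shifts relative to the full band", {
  scen <- default_scenario("gas")
  scen$torsion <- torsion_model(c(-113, -76), kappa = 50)
  scen$coupling <- coupling_model(coupling_amplitude_eV = 0.3, noise_sd_eV = 0)
  dat <- gen_scenario_data(scen, seed = 8)
  full <- normalize_spectrum(reconstruct_spectrum(dat$conf, broadening_params()))
  at_min <- windowed_spectrum(dat$conf, dat$angles, -66, 8, broadening_params())
  expect_lt(lambda_max(at_min), lambda_max(full))
})

test_that("shift reports are zero for identical inputs, positive under coupling", {
  rec <- toy_ensemble(c(2.5, 2.9), c(0.8, 0.1))
  rep0 <- build_shift_report(rec, rec)
  expect_equal(rep0$delta_E_eV, 0)
  expect_s3_class(rep0, "shift_report")

  scen <- default_scenario("gas")
  scen$schedule$duration_ps <- 400
  scen$coupling <- coupling_model(coupling_amplitude_eV = 0, noise_sd_eV = 0)
  dat <- gen_scenario_data(scen, seed = 2)
  expect_equal(build_shift_report(dat$conf, dat$opt)$delta_E_eV, 0)

  scen$coupling <- coupling_model(coupling_amplitude_eV = 0.5, noise_sd_eV = 0)
  dat <- gen_scenario_data(scen, seed = 2)
  expect_gt(build_shift_report(dat$conf, dat$opt)$delta_E_eV, 0)
})

test_that("mismatched provenance tags are rejected in reports", {
  conf <- toy_ensemble(2.5, 1, functional = "B3LYP")
  opt <- toy_ensemble(2.5, 1, functional = "BLYP")
  expect_error(build_shift_report(conf, opt), class = "specens_validation_error")
})

test_that("increasing the coupling amplitude never decreases the shift", {
  scen <- default_scenario("gas")
  scen$schedule$duration_ps <- 1000 # 251 frames -> 26 conformers
  scen$torsion <- torsion_model(c(-113, -76), kappa = 50)
  des <- sapply(c(0, 0.025, 0.05, 0.1), function(a) {
    scen$coupling <- coupling_model(coupling_amplitude_eV = a, noise_sd_eV = 0.01)
    dat <- gen_scenario_data(scen, seed = 5)
    build_shift_report(dat$conf, dat$opt)$delta_E_eV
  })
  expect_true(!is.unsorted(des))
})

test_that("solvent shifts derive from stacked phase reports", {
  reports <- dplyr::bind_rows(
    tibble::tibble(functional_tag = "BLYP", phase_tag = "gas",
                   lambda_conf_nm = 523, lambda_opt_nm = 477,
                   delta_E_eV = shift_ev(477, 523), n_conformers = 126L),
    tibble::tibble(functional_tag = "BLYP", phase_tag = "solution",
                   lambda_conf_nm = 590, lambda_opt_nm = 561,
                   delta_E_eV = shift_ev(561, 590), n_conformers = 126L)
  )
  st <- solvent_shift_table(reports)
  expect_equal(st$solvent_shift_opt_nm, 84)
  expect_equal(st$solvent_shift_conf_nm, 67)
  expect_error(solvent_shift_table(reports[1, ]), class = "specens_argument_error")
})
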