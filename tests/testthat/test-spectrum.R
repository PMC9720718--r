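test_that("the lineshape is a unit-area Gaussian with the stated width", {
  sigma <- 0.2 / (2 * sqrt(2 * log(2)))
  expect_equal(gaussian_lineshape(2.5, 2.5, 0.2), 1 / (sigma * sqrt(2 * pi)),
               tolerance = 1e-12)
  # half maximum at center +/- fwhm/2
  expect_equal(gaussian_lineshape(2.5 + 0.1, 2.5, 0.2),
               gaussian_lineshape(2.5, 2.5, 0.2) / 2, tolerance = 1e-12)
  expect_equal(gaussian_lineshape(2.5 - 0.1, 2.5, 0.2),
               gaussian_lineshape(2.5, 2.5, 0.2) / 2, tolerance = 1e-12)
  q <- integrate(gaussian_lineshape, 2.5 - 10 * sigma, 2.5 + 10 * sigma,
                 center_eV = 2.5, fwhm_eV = 0.2)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(gaussian_lineshape(2.5, 2.5, 0), class = "specens_argument_error")
})

test_that("a single transition reconstructs to one band of FWHM 0.2 eV", {
  ens <- toy_ensemble(2.5, 1)
  sp <- reconstruct_spectrum(ens, broadening_params(grid_min_eV = 1.5,
                                                    grid_max_eV = 3.5))
  expect_equal(e_max(sp), 2.5, tolerance = 1e-9)
  expect_equal(measure_fwhm(sp), 0.2, tolerance = 1e-6)
  expect_equal(max(sp$intensity), gaussian_lineshape(2.5, 2.5, 0.2),
               tolerance = 1e-12)
})

test_that("well-separated states average with the 1/N_p prefactor", {
  ens <- toy_ensemble(c(2.0, 3.0), c(1, 1), ids = c("a", "b"))
  sp <- reconstruct_spectrum(ens, broadening_params())
  peak <- gaussian_lineshape(0, 0, 0.2)
  i1 <- sp$intensity[sp$energy_eV == 2.0]
  i2 <- sp$intensity[sp$energy_eV == 3.0]
  expect_equal(i1, peak / 2, tolerance = 1e-6)
  expect_equal(i2, peak / 2, tolerance = 1e-6)
})

test_that("duplicating every conformer leaves the averaged spectrum unchanged", {
  set.seed(21)
  ens <- toy_ensemble(runif(6, 2, 3), runif(6), ids = rep(c("a", "b"), each = 3))
  doubled <- new_ensemble(
    dplyr::bind_rows(
      tibble::as_tibble(ens),
      dplyr::mutate(tibble::as_tibble(ens),
                    conformer_id = paste0(conformer_id, "_dup"))
    )
  )
  p <- broadening_params(grid_min_eV = 1, grid_max_eV = 4, grid_step_eV = 0.005)
  expect_equal(reconstruct_spectrum(doubled, p)$intensity,
               reconstruct_spectrum(ens, p)$intensity, tolerance = 1e-12)
})

test_that("the vectorised reconstruction matches the naive double loop", {
  set.seed(33)
  p <- broadening_params(grid_min_eV = 1, grid_max_eV = 4, grid_step_eV = 0.005)
  for (rep in 1:5) {
    np <- sample(1:20, 1)
    ns <- sample(1:5, 1)
    ens <- toy_ensemble(runif(np * ns, 1.6, 3.4), runif(np * ns),
                        ids = rep(paste0("c", seq_len(np)), each = ns))
    sp <- reconstruct_spectrum(ens, p)
    expect_equal(max(abs(sp$intensity - naive_spectrum(ens, p))), 0,
                 tolerance = 1e-12)
  }
})

test_that("normalisation fixes the maximum at one and keeps the peak", {
  ens <- toy_ensemble(c(2.3, 2.6), c(0.8, 0.3))
  sp <- reconstruct_spectrum(ens, broadening_params())
  ns <- normalize_spectrum(sp)
  expect_equal(max(ns$intensity), 1, tolerance = 1e-12)
  expect_true(attr(ns, "normalized"))
  expect_equal(normalize_spectrum(ns)$intensity, ns$intensity)
  expect_equal(e_max(ns), e_max(sp))
  zero <- toy_ensemble(2.5, 0)
  expect_error(normalize_spectrum(reconstruct_spectrum(zero, broadening_params())),
               class = "specens_argument_error")
})

test_that("lambda_max refines the grid argmax and converts through hc", {
  ens <- toy_ensemble(2.3305, 1)
  sp <- reconstruct_spectrum(ens, broadening_params(grid_min_eV = 1.5,
                                                    grid_max_eV = 3.5))
  expect_equal(lambda_max(sp), hc_ev_nm() / 2.3305, tolerance = 1e-4)
  # merged symmetric doublet peaks midway
  doublet <- toy_ensemble(c(2.4, 2.6), c(1, 1))
  spd <- reconstruct_spectrum(doublet, broadening_params(fwhm_eV = 0.5,
                                                         grid_min_eV = 1.5,
                                                         grid_max_eV = 3.5))
  expect_equal(lambda_max(spd), hc_ev_nm() / 2.5, tolerance = 1e-3)
  # two equal well-separated peaks: tie broken toward lower energy
  sep <- toy_ensemble(c(2.0, 3.0), c(1, 1))
  sps <- reconstruct_spectrum(sep, broadening_params())
  expect_equal(e_max(sps), 2.0, tolerance = 1e-6)
})

test_that("lambda_max agrees with a dense-grid argmax on random ensembles", {
  set.seed(55)
  for (rep in 1:3) {
    ens <- toy_ensemble(runif(9, 2.1, 2.9), runif(9, 0.1, 1),
                        ids = rep(paste0("c", 1:3), each = 3))
    sp <- reconstruct_spectrum(ens, broadening_params())
    dense <- seq(2.0, 3.0, by = 1e-4)
    sigma <- 0.2 / (2 * sqrt(2 * log(2)))
    ad <- rowSums(vapply(seq_len(nrow(ens)), function(i) {
      ens$oscillator_strength[i] * dnorm(dense, ens$energy_eV[i], sigma)
    }, numeric(length(dense))))
    expect_lt(abs(e_max(sp) - dense[which.max(ad)]), 0.001 + 1e-9)
  }
})

test_that("shifting every excitation shifts the maximum covariantly", {
  set.seed(77)
  ens <- toy_ensemble(runif(6, 2.2, 2.8), runif(6, 0.2, 1),
                      ids = rep(c("a", "b"), each = 3))
  sp0 <- reconstruct_spectrum(ens, broadening_params())
  shifted <- new_ensemble(dplyr::mutate(tibble::as_tibble(ens),
                                        energy_eV = energy_eV + 0.15,
                                        wavelength_nm = NULL))
  sp1 <- reconstruct_spectrum(shifted, broadening_params())
  expect_equal(e_max(sp1), e_max(sp0) + 0.15, tolerance = 0.001)
})

test_that("the integrated band strength equals the mean total f", {
  ens <- toy_ensemble(c(2.4, 2.9), c(0.8, 0.1))
  sp <- reconstruct_spectrum(ens, broadening_params())
  expect_equal(integrated_strength(sp), 0.9, tolerance = 1e-4)
  expect_equal(integrated_strength(ens), 0.9)
  zero <- reconstruct_spectrum(toy_ensemble(2.5, 0), broadening_params())
  expect_equal(integrated_strength(zero), 0)
  # area does not depend on the broadening width
  a1 <- integrated_strength(reconstruct_spectrum(ens, broadening_params(fwhm_eV = 0.1)))
  a2 <- integrated_strength(reconstruct_spectrum(ens, broadening_params(fwhm_eV = 0.3)))
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("clipped transitions warn and void the area check", {
  ens <- toy_ensemble(c(2.5, 6.0), c(0.5, 0.5))
  expect_warning(sp <- reconstruct_spectrum(ens, broadening_params()),
                 regexp = "clipped")
  expect_warning(expect_true(is.na(integrated_strength(sp))), regexp = "skipped")
})

test_that("broadening parameter validation enforces grid sanity", {
  expect_error(broadening_params(fwhm_eV = 0), class = "specens_argument_error")
  expect_error(broadening_params(grid_min_eV = 3, grid_max_eV = 2),
               class = "specens_argument_error")
  expect_error(broadening_params(grid_step_eV = 0.05),
               class = "specens_argument_error")
})

test_that("tidy and glance expose the wavelength view and the peak summary", {
  ens <- toy_ensemble(2.5, 1)
  sp <- reconstruct_spectrum(ens, broadening_params(grid_min_eV = 1.5,
                                                    grid_max_eV = 3.5))
  td <- generics::tidy(sp)
  expect_equal(td$wavelength_nm, hc_ev_nm() / td$energy_eV)
  gl <- generics::glance(sp)
  expect_equal(gl$lambda_max_nm, hc_ev_nm() / 2.5, tolerance = 1e-3)
  expect_equal(gl$n_conformers, 1L)
})
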