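gaussian_log_lines <- function() {
  c(
    " Excitation energies and oscillator strengths:",
    " Excited State   1:      Singlet-A      2.6500 eV  467.86 nm  f=0.8012  <S**2>=0.000",
    "      38 -> 39         0.70502",
    " Excited State   2:      Singlet-A      3.0500 eV  406.51 nm  f=0.0210",
    " Excited State   3:      Singlet-A      3.3500 eV  370.10 nm  f=0.0150",
    " Excited State   4:      Singlet-A      3.8000 eV  326.27 nm  f=0.0030",
    " Excited State   5:      Singlet-A      4.1000 eV  302.40 nm  f=0.0001",
    " SavETr:  write IOETrn to disk"
  )
}

test_that("a five-state log excerpt parses with the bright state intact", {
  rec <- parse_gaussian_excited_states(gaussian_log_lines(), conformer_id = "c7",
                                       functional_tag = "B3LYP")
  expect_s3_class(rec, "conformer_ensemble")
  expect_equal(nrow(rec), 5)
  expect_equal(rec$energy_eV[1], 2.65)
  expect_equal(rec$oscillator_strength[1], 0.8012)
  expect_equal(attr(rec, "functional_tag"), "B3LYP")
  b <- bright_state(rec)
  expect_equal(b$state_index, 1L)
})

test_that("re-printed state blocks supersede earlier ones", {
  lines <- c(gaussian_log_lines(),
             " Excited State   1:      Singlet-A      2.7000 eV  459.20 nm  f=0.7500")
  rec <- parse_gaussian_excited_states(lines)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$energy_eV[rec$state_index == 1], 2.70)
})

test_that("parser failures are typed and informative", {
  expect_error(parse_gaussian_excited_states(character(0)),
               class = "specens_no_data")
  expect_error(parse_gaussian_excited_states(" nothing relevant here "),
               class = "specens_no_data")
  expect_error(
    parse_gaussian_excited_states(
      " Excited State   1:      Singlet-A      abc eV  467.86 nm  f=0.80"),
    class = "specens_parse_error")
  expect_error(
    parse_gaussian_excited_states(
      " Excited State   1:      Singlet-A      2.6500 eV  400.00 nm  f=0.80"),
    class = "specens_validation_error")
})

test_that("state tables round-trip exactly and group by conformer", {
  scen <- default_scenario("gas")
  dat <- gen_scenario_data(scen, seed = 4)
  expect_equal(n_conformers(dat$conf), 126)
  expect_true(all(table(dat$conf$conformer_id) == 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_table(dat$conf, path)
  back <- read_state_table(path)
  expect_equal(as.data.frame(back), as.data.frame(dat$conf), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "functional_tag"), attr(dat$conf, "functional_tag"))
  expect_equal(attr(back, "phase_tag"), attr(dat$conf, "phase_tag"))
})

test_that("row order within the table does not change the ensemble", {
  ens <- toy_ensemble(c(2.5, 3.0, 2.2, 2.9), c(0.8, 0.1, 0.7, 0.2),
                      ids = c("a", "a", "b", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_table(ens, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, path2)
  a <- dplyr::arrange(tibble::as_tibble(read_state_table(path)),
                      conformer_id, state_index)
  b <- dplyr::arrange(tibble::as_tibble(read_state_table(path2)),
                      conformer_id, state_index)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("single-row tables and validation errors behave", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("conformer_id,state_index,energy_eV,oscillator_strength",
               "k1,1,2.5,0.9"), path)
  ens <- read_state_table(path)
  expect_equal(n_conformers(ens), 1)
  expect_equal(nrow(ens), 1)

  writeLines(c("conformer_id,state_index,energy_eV,oscillator_strength",
               "k1,1,2.5,0.9", "k1,2,-0.1,0.2"), path)
  expect_error(read_state_table(path), class = "specens_validation_error",
               regexp = "row 2")
  writeLines(c("conformer_id,state_index,energy_eV,oscillator_strength",
               "k1,1,2.5,-0.9"), path)
  expect_error(read_state_table(path), class = "specens_validation_error")
})

test_that("mixed provenance tags are rejected, heterogeneous N_s only warns", {
  mixed <- tibble::tibble(
    conformer_id = c("a", "b"), state_index = 1L,
    energy_eV = c(2.5, 2.6), oscillator_strength = 0.5,
    functional_tag = c("B3LYP", "BLYP")
  )
  expect_error(new_ensemble(mixed), class = "specens_validation_error")
  hetero <- tibble::tibble(
    conformer_id = c("a", "b", "b"), state_index = c(1L, 1L, 2L),
    energy_eV = c(2.5, 2.6, 3.0), oscillator_strength = 0.5
  )
  expect_warning(new_ensemble(hetero), regexp = "heterogeneous")
})

test_that("bright_state picks the maximal strength, ties to the lowest index", {
  rec <- toy_ensemble(c(2.5, 2.8, 3.1), c(0.01, 0.80, 0.02))
  expect_equal(bright_state(rec)$state_index, 2L)
  tie <- toy_ensemble(c(2.5, 2.8, 3.1), c(0.3, 0.3, 0.3))
  expect_equal(bright_state(tie)$state_index, 1L)
  set.seed(9)
  ens <- toy_ensemble(runif(30, 2, 4), runif(30),
                      ids = rep(paste0("c", 1:10), each = 3))
  b <- bright_state(ens)
  ref <- tapply(ens$oscillator_strength, ens$conformer_id, max)
  expect_equal(b$oscillator_strength, as.numeric(ref[b$conformer_id]))
})
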