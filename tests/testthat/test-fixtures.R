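test_that("fixtures are reproducible from the seed alone", {
  a <- generate_sppo_fixture(n_sppos = 15L, noise_rate = 0.1, seed = 77L)
  b <- generate_sppo_fixture(n_sppos = 15L, noise_rate = 0.1, seed = 77L)
  expect_identical(a$sppos, b$sppos)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$ledger$true_class, b$ledger$true_class)
  c <- generate_sppo_fixture(n_sppos = 15L, noise_rate = 0.1, seed = 78L)
  expect_false(identical(a$measurements, c$measurements))
  expect_error(generate_sppo_fixture(n_sppos = 15L), "seed")

  la <- generate_logbb_fixture(n = 40L, seed = 5L)
  lb <- generate_logbb_fixture(n = 40L, seed = 5L)
  expect_identical(la$data, lb$data)
})

test_that("zero-noise percents bin back to the ledger classes exactly", {
  fx <- small_sppo_fixture()
  binned <- as.character(bin_reactivation(fx$measurements$reactivation_percent))
  expect_identical(binned, fx$ledger$true_class$class)
  expect_identical(fx$ledger$true_class$class,
                   fx$ledger$true_class$emitted_class)
})

test_that("the label-flip fraction matches the configured noise rate", {
  fx <- generate_sppo_fixture(n_sppos = 150L, noise_rate = 0.05, seed = 13L)
  led <- fx$ledger$true_class
  n <- nrow(led)
  expect_equal(n, 600L)
  flipped <- mean(led$class != led$emitted_class)
  # a flip draws one of the other two classes, so every flip changes the label
  ci <- 2.58 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(flipped - 0.05), ci + 1e-12)
  # emitted percents bin to the emitted (post-flip) classes
  expect_identical(
    as.character(bin_reactivation(fx$measurements$reactivation_percent)),
    led$emitted_class)
})

test_that("every generated structure passes compound validation", {
  fx <- small_sppo_fixture()
  rec <- compound_records(paste0("v", seq_len(nrow(fx$sppos))),
                          fx$sppos$smiles, role = "SPPO")
  expect_equal(nrow(rec), nrow(fx$sppos))
  expect_true(all(smarts_count(fx$sppos$smiles, "[n+]1ccccc1") == 1L))
  expect_true(all(smarts_count(fx$sppos$smiles,
                               "[CX3]=[NX2][OX2H1]") == 1L))
  fb <- generate_logbb_fixture(n = 50L, seed = 9L)
  expect_equal(nrow(compound_records(fb$data$compound_id, fb$data$smiles)),
               50L)
})

test_that("zero-noise logBB refits recover the planted coefficients", {
  fx <- generate_logbb_fixture(n = 150L, noise_sd = 0, seed = 21L)
  d <- descriptor_matrix(compound_records(fx$data$compound_id,
                                          fx$data$smiles))
  fit <- lm(fx$data$logBB ~ d[, "MolLogP"] + d[, "TPSA"] + d[, "MolWt"] +
              d[, "NumHDonors"])
  expect_equal(unname(coef(fit)), unname(fx$ledger$coefficients),
               tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("infeasible fixture sizes are refused", {
  expect_error(generate_logbb_fixture(n = 1e6, seed = 1L), "diversity")
})

test_that("fixtures serialize to the ingester CSV schemas", {
  dir <- withr::local_tempdir()
  fx <- generate_sppo_fixture(n_sppos = 10L, seed = 3L)
  write_fixture(fx, dir)
  m <- read_reactivation_measurements(file.path(dir, "reactivation.csv"))
  expect_equal(nrow(m), nrow(fx$measurements))
  sppos <- read_compounds(file.path(dir, "sppos.csv"))
  expect_equal(sppos$smiles, fx$sppos$smiles)
  expect_true(file.exists(file.path(dir, "ledger.json")))
  fb <- generate_logbb_fixture(n = 20L, seed = 3L)
  write_fixture(fb, dir)
  expect_true(file.exists(file.path(dir, "logbb.csv")))
})
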