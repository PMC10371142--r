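test_that("CSV reading canonicalizes and reports parse failures by row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("c1ccccc1,benzene", f)
  rec <- read_compounds(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$smiles, canonical_smiles("c1ccccc1"))
  expect_equal(rec$name, "benzene")

  writeLines(c("id,smiles", "ok,CCO", "bad,C1CC"), f)
  expect_error(read_compounds(f), "bad")

  writeLines("id,smiles", f)
  expect_error(read_compounds(f), "no valid molecules")
})

test_that("duplicate ids and unknown roles are rejected", {
  expect_error(compound_records(c("a", "a"), c("C", "CC")), "duplicate")
  expect_error(compound_records("a", "C", role = "LIGAND"), "role")
})

test_that("SDF records are parsed with titles as ids", {
  # minimal hand-written molblock: ethanol
  sdf <- c("ethanol", "  test", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  rec <- read_compounds(f)
  expect_equal(rec$id, "ethanol")
  expect_equal(rec$smiles, "CCO")
})

test_that("the OP challenge panel has five organophosphates", {
  ops <- op_panel()
  expect_setequal(ops$id, c("PIMP", "NEMP", "PXN", "DFP", "GV"))
  expect_true(all(ops$role == "OP"))
  expect_true(all(smarts_count(ops$smiles, "[#15]") == 1L))
  # panel subsetting preserves order and rejects unknown ids
  expect_equal(op_panel(c("DFP", "GV"))$id, c("DFP", "GV"))
  expect_error(op_panel("VX"), "unknown")
})

test_that("canonicalization is idempotent on a diverse set", {
  smiles <- c("OCC", "c1ccccc1", "C/C=N/O", op_panel()$smiles,
              "ON=Cc1cc[n+](CCCOc2ccccc2)cc1")
  canon <- canonical_smiles(smiles)
  expect_identical(canonical_smiles(canon), canon)
  # the two ethanol spellings collapse
  expect_equal(canonical_smiles("OCC"), canonical_smiles("CCO"))
})
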