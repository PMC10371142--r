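test_that("battery values are sane on hand-checkable molecules", {
  d <- compute_descriptors("C")
  expect_equal(unname(d[["MolWt"]]), 16.043, tolerance = 1e-3)
  expect_identical(unname(d[["TPSA"]]), 0)
  expect_identical(unname(d[["NumOximeGroups"]]), 0)
  # an aldoxime fragment carries exactly one oxime group
  expect_gte(compute_descriptors("C/C=N/O")[["NumOximeGroups"]], 1)
  # pyridinium oxime: one aromatic heterocycle, one HBD (the N-OH)
  sppo <- compute_descriptors("ON=Cc1cc[n+](CCCOc2ccccc2)cc1")
  expect_equal(unname(sppo[["NumAromaticHeterocycles"]]), 1)
  expect_equal(unname(sppo[["NumOximeGroups"]]), 1)
  expect_true(sppo[["qed"]] > 0 && sppo[["qed"]] < 1)
})

test_that("descriptors are invariant to SMILES spelling and deterministic", {
  a <- compute_descriptors("CCO")
  b <- compute_descriptors("OCC")
  expect_identical(a, b)
  m1 <- descriptor_matrix(c("CCO", "c1ccccc1", "CC(=O)O"))
  m2 <- descriptor_matrix(c("CCO", "c1ccccc1", "CC(=O)O"))
  expect_identical(m1, m2)
  expect_equal(ncol(m1), length(descriptor_names()))
  expect_true(all(is.finite(m1)))
})

test_that("unparseable input is an error naming the molecule", {
  expect_error(descriptor_matrix(c("CCO", "C1CC")), "molecule 2")
})

test_that("battery agrees with an independent toolkit on shared descriptors", {
  # ChemmineOB (OpenBabel) computes MW, TPSA, HBD and logP independently of
  # the backend; exact equality is not expected for logP (different atom
  # parameter sets), so it is checked loosely, the others tightly
  suppressMessages({
    library(ChemmineR)
    library(ChemmineOB)
  })
  smiles <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C/C=N/O")
  ours <- descriptor_matrix(smiles)
  sdf <- smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  theirs <- propOB(sdf)
  expect_equal(unname(ours[, "MolWt"]), theirs$MW, tolerance = 1e-3)
  expect_equal(unname(ours[, "TPSA"]), theirs$TPSA, tolerance = 1e-6)
  expect_equal(unname(ours[, "NumHDonors"]), theirs$HBD, tolerance = 0)
  expect_equal(unname(ours[, "MolLogP"]), theirs$logP, tolerance = 0.8)
})

test_that("pair features concatenate the two batteries order-sensitively", {
  a <- compute_descriptors("CCO")
  b <- compute_descriptors("c1ccccc1")
  pair <- build_pair_features(a, b)
  expect_length(pair, 2L * length(a))
  expect_identical(unname(pair[seq_along(a)]), unname(a))
  expect_identical(unname(pair[length(a) + seq_along(b)]), unname(b))
  expect_true(startsWith(names(pair)[1], "sppo__"))
  expect_true(startsWith(names(pair)[length(a) + 1L], "op__"))
  # self-pairing: halves equal; swapped arguments: different vector
  self <- build_pair_features(a, a)
  expect_identical(unname(self[seq_along(a)]),
                   unname(self[length(a) + seq_along(a)]))
  expect_false(identical(unname(build_pair_features(b, a)), unname(pair)))
  expect_error(build_pair_features(a, a[-1]), "batteries")
})

test_that("pair matrices resolve ids and double the battery width", {
  s <- descriptor_matrix(compound_records(c("s1", "s2"), c("CCO", "CCN")))
  o <- descriptor_matrix(compound_records(c("o1", "o2"),
                                          c("CC(C)OP(=O)(F)OC(C)C", "COP(=O)(OC)OC")))
  pm <- pair_feature_matrix(s, o, c("s1", "s2", "s1"), c("o1", "o1", "o2"))
  expect_equal(dim(pm), c(3L, 2L * ncol(s)))
  expect_equal(rownames(pm), c("s1:o1", "s2:o1", "s1:o2"))
  expect_error(pair_feature_matrix(s, o, "s9", "o1"), "unresolvable")
})
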