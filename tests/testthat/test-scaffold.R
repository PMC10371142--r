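test_that("reassemble/decompose round-trips across scaffolds and R-groups", {
  cases <- list(
    decomposition("bare", "pyr4", 3),
    decomposition("a", "pyr2", 3, c(R3 = "*OC")),
    decomposition("b", "pyr3", 5, c(R1 = "*c1ccccc1", R3 = "*C(C)C",
                                    R4 = "*Cl")),
    decomposition("c", "pyr4", 4, c(R2 = "*OC", R4 = "*F", R5 = "*C")),
    decomposition("d", "pyr4", 3, c("R2&R3" = "*OCO*", R5 = "*C")),
    decomposition("e", "pyr3", 4, c("R3&R4" = "*OCCO*",
                                    R1 = "*[N+](=O)[O-]"))
  )
  smi <- reassemble(cases)
  redo <- decompose(smi)
  expect_identical(unname(reassemble(redo)), smi)
  expect_equal(vapply(redo, function(d) d$scaffold_id, character(1)),
               stats::setNames(vapply(cases, function(d) d$scaffold_id,
                                      character(1)),
                               names(redo)))
  expect_equal(unname(vapply(redo, function(d) d$n, integer(1))),
               vapply(cases, function(d) d$n, integer(1)))
})

test_that("an unsubstituted decomposition is the bare scaffold", {
  smi <- reassemble(decomposition("bare", "pyr4", 3))
  expect_equal(smi, canonical_smiles("ON=Cc1cc[n+](CCCOc2ccccc2)cc1"))
  d <- decompose(smi)
  expect_true(all(d$rgroups == "H"))
})

test_that("non-SPPO structures and malformed fragments are rejected", {
  expect_error(decompose("c1ccccc1"), "pyridinium")
  expect_error(decompose("ON=Cc1cc[n+](C)cc1"), "linker|aryl ether")
  expect_error(decomposition("x", "pyr4", 3, c(R1 = "*C*")),
               "attachment point")
  expect_error(decomposition("x", "pyr4", 3, c("R2&R3" = "*C")),
               "attachment point")
  expect_error(decomposition("x", "pyr4", 3, c(R3 = "*C", "R2&R3" = "*OCO*")),
               "more than once")
})

test_that("linker lengths outside 3..5 decompose but are flagged", {
  smi <- reassemble(decomposition("long", "pyr4", 7, c(R3 = "*C")))
  d <- decompose(smi)
  expect_equal(d$n, 7L)
  expect_true(isTRUE(attr(d, "out_of_rule")))
})

test_that("fragment pooling records positions and sources", {
  decs <- decompose(reassemble(list(
    decomposition("s1", "pyr4", 3, c(R1 = "*C", R3 = "*OC")),
    decomposition("s2", "pyr4", 4, c(R4 = "*C", R3 = "*Cl"))
  )))
  pool <- fragment_pool(decs)
  methyl <- pool[pool$smiles == "*C", ]
  # R1 on one molecule mirrors to the same pooled slot as R4 on the other
  expect_equal(nrow(methyl), 1L)
  expect_true(all(strsplit(methyl$positions_observed, ",")[[1]] %in%
                    c("R1", "R4", "R5", "R2")))
  expect_setequal(strsplit(methyl$source_ids, ",")[[1]], c("m1", "m2"))
})

test_that("enumeration obeys the linker and whitelist rules", {
  expect_error(enumeration_rules(r3_whitelist = character()), "whitelist")
  expect_error(enumeration_rules(r3_whitelist = "*C", n_values = 6),
               "allow_any_n")
  r <- enumeration_rules(r3_whitelist = "*C", n_values = 6,
                         allow_any_n = TRUE)
  expect_equal(r$n_values, 6L)
})

test_that("an H-only swap pool gives scaffolds x n x R3 candidates", {
  pool19 <- c("*C", "*CC", "*CCC", "*C(C)C", "*CC(C)C", "*C(C)(C)C", "*OC",
              "*OCC", "*OC(C)C", "*CO", "*F", "*Cl", "*Br", "*I", "*C#N",
              "*[N+](=O)[O-]", "*C(F)(F)F", "*c1ccccc1", "*N(C)C")
  rules <- enumeration_rules(r3_whitelist = pool19, n_values = 3:5,
                             scaffolds = "pyr4")
  lib <- enumerate_candidates(rules)
  expect_equal(count_combinations(rules), 3 * 19)
  expect_equal(nrow(lib$records), 57L)
  expect_false(any(duplicated(lib$records$smiles)))
})

test_that("the streaming enumerator matches a brute-force oracle", {
  rules <- enumeration_rules(r3_whitelist = c("*C", "*OC"),
                             swap_pool = c("*F", "*Cl"),
                             n_values = 3:4,
                             scaffolds = "pyr4",
                             specials = list("R2&R3" = "*OCO*"))
  expect_lte(count_combinations(rules), 500)
  lib <- enumerate_candidates(rules)

  # independent oracle: exhaustive nested loops, then canonical dedup
  oracle <- new.env(parent = emptyenv())
  swap <- c("H", "*F", "*Cl")
  decs <- list()
  for (sc in "pyr4") for (n in 3:4) {
    for (r3 in c("*C", "*OC")) {
      for (r1 in swap) for (r2 in swap) for (r4 in swap) for (r5 in swap) {
        rg <- c(R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5)
        decs[[length(decs) + 1L]] <- decomposition("o", sc, n,
                                                   rg[rg != "H"])
      }
    }
    for (sp in "*OCO*") {
      for (r1 in swap) for (r4 in swap) for (r5 in swap) {
        rg <- c("R2&R3" = sp, R1 = r1, R4 = r4, R5 = r5)
        decs[[length(decs) + 1L]] <- decomposition("o", sc, n,
                                                   rg[rg != "H"])
      }
    }
  }
  oracle_set <- unique(reassemble(decs))
  expect_setequal(lib$records$smiles, oracle_set)
})

test_that("every candidate carries one pyridinium ring and an oxime", {
  rules <- enumeration_rules(r3_whitelist = c("*C#N", "*c1ccccc1"),
                             swap_pool = "*OC", n_values = 3,
                             scaffolds = "pyr3")
  lib <- enumerate_candidates(rules)  # validate = TRUE would stop otherwise
  expect_true(all(smarts_count(lib$records$smiles, "[n+]1ccccc1") == 1L))
  expect_true(all(smarts_count(lib$records$smiles,
                               "[CX3]=[NX2][OX2H1]") >= 1L))
})

test_that("input structures are excluded from the emitted library", {
  rules <- enumeration_rules(r3_whitelist = "*C", swap_pool = "*F",
                             n_values = 3, scaffolds = "pyr4")
  all_lib <- enumerate_candidates(rules)
  one <- all_lib$records$smiles[1]
  excl <- enumerate_candidates(rules, exclude = one)
  expect_false(one %in% excl$records$smiles)
  expect_equal(nrow(excl$records), nrow(all_lib$records) - 1L)
  expect_equal(excl$stats$inputs_excluded, 1L)
})

test_that("libraries serialize to .smi.gz plus a JSONL manifest", {
  rules <- enumeration_rules(r3_whitelist = "*C", n_values = 3:4,
                             scaffolds = "pyr4")
  lib <- enumerate_candidates(rules)
  f <- withr::local_tempfile(fileext = ".smi.gz")
  write_library(lib, f)
  lines <- readLines(gzfile(f))
  expect_equal(length(lines), nrow(lib$records))
  man <- lapply(readLines(paste0(f, ".jsonl")), jsonlite::fromJSON)
  expect_equal(vapply(man, function(m) m$smiles, character(1)),
               lib$records$smiles)
  expect_true(all(vapply(man, function(m) m$n %in% 3:4, logical(1))))
})
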