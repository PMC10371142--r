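test_that("reactivation binning follows the documented conventions", {
  expect_equal(as.character(bin_reactivation(0)), "No")
  expect_equal(as.character(bin_reactivation(63)), "High")
  # the 40% boundary belongs to Low ("greater than 40" is strictly greater)
  expect_equal(as.character(bin_reactivation(40)), "Low")
  expect_equal(as.character(bin_reactivation(40.0001)), "High")
  # the approximately-zero band is symmetric with half-width zero_tolerance
  expect_equal(as.character(bin_reactivation(c(-0.5, 0.5, 0.6))),
               c("No", "No", "Low"))
  expect_error(bin_reactivation(-11), "range")
  expect_error(bin_reactivation(110.5), "range")
  expect_error(bin_reactivation(-5), "negative")
  expect_equal(as.character(bin_reactivation(-5, zero_tolerance = 6)), "No")
})

test_that("binning is total, exclusive and monotone", {
  grid <- c(seq(0, 110, by = 0.25), 0.4999, 0.5001, 39.999, 40.001)
  cls <- bin_reactivation(sort(grid))
  expect_false(anyNA(cls))
  # order-preserving: class index never decreases with percent
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("logBB thresholding is total with ties below", {
  expect_equal(as.character(bin_logbb(0.5)), "BBB+")
  expect_equal(as.character(bin_logbb(-1.2)), "BBB-")
  expect_equal(as.character(bin_logbb(0)), "BBB-")     # boundary convention
  expect_equal(as.character(bin_logbb(0, threshold = -0.5)), "BBB+")
  expect_error(bin_logbb(NaN), "finite")
  v <- bin_logbb(rnorm(100))
  expect_false(anyNA(v))
})

test_that("dataset assembly conserves rows and tallies the ledger classes", {
  fx <- small_sppo_fixture()
  ds <- assemble_reactivation_dataset(fx$measurements, fx$sppos, fx$ops)
  expect_equal(nrow(ds$features$matrix), nrow(fx$measurements))
  truth <- fx$ledger$true_class
  expect_equal(as.vector(ds$tally[c("No", "Low", "High")]),
               as.vector(table(factor(truth$class,
                                      c("No", "Low", "High")))))
  # pair features live in [0,1] after scaling
  expect_true(all(ds$features$matrix >= 0 & ds$features$matrix <= 1))
})

test_that("assembly rejects bad inputs loudly", {
  fx <- small_sppo_fixture()
  expect_error(assemble_reactivation_dataset(fx$measurements[0, ], fx$sppos,
                                             fx$ops), "empty")
  bad <- fx$measurements
  bad$sppo_id[1] <- "ghost"
  expect_error(assemble_reactivation_dataset(bad, fx$sppos, fx$ops),
               "ghost")
  # duplicated pairing with a conflicting class
  dup <- rbind(fx$measurements,
               within(fx$measurements[1, ], reactivation_percent <- 90))
  dup$reactivation_percent[1] <- 10
  expect_error(assemble_reactivation_dataset(dup, fx$sppos, fx$ops),
               "conflicting")
  # duplicated pairing with an agreeing class is collapsed, not an error
  agree <- rbind(fx$measurements, fx$measurements[1, ])
  ds <- assemble_reactivation_dataset(agree, fx$sppos, fx$ops)
  expect_equal(nrow(ds$features$matrix), nrow(fx$measurements))
})

test_that("replicate measurement rows are averaged on ingestion", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sppo_id = "s1", op_id = "PXN",
                       reactivation_percent = c(50, 60, 70),
                       replicate = 1:3), f, row.names = FALSE)
  m <- read_reactivation_measurements(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$reactivation_percent, 60)
})

test_that("the BBB dataset maps published column names and tallies classes", {
  fb <- generate_logbb_fixture(n = 60, seed = 3)
  names(fb$data) <- c("NO.", "SMILES", "logBB")
  ds <- assemble_bbb_dataset(fb$data,
                             columns = c(id = "NO.", smiles = "SMILES",
                                         logbb = "logBB"))
  expect_equal(nrow(ds$features$matrix), 60L)
  expect_equal(sum(ds$tally), 60L)
  expect_identical(as.character(ds$labels),
                   as.character(bin_logbb(fb$data$logBB)))
})

test_that("broad-spectrum means High against every panel OP", {
  fx <- small_sppo_fixture()
  bundle <- cached("small_model", function() {
    train_reactivation_model(fx$measurements, fx$sppos, fx$ops,
                             grid = data.frame(nrounds = 80L, max_depth = 4L,
                                               eta = 0.2),
                             rs_sizes = NULL, nfold = 3, seed = 7)
  })
  panel <- op_panel()
  res <- predict_broad_spectrum(bundle$artifact, fx$sppos[1:12, ],
                                ops = panel, scaler = bundle$scaler,
                                chem_columns = bundle$chem_columns)
  # set-logic oracle: the flag equals the row-wise all-High reduction
  manual <- apply(res[, panel$id, drop = FALSE], 1L,
                  function(r) all(r == "High"))
  expect_identical(res$broad_spectrum, unname(manual))
  # the flag is monotone non-increasing as the panel grows
  res4 <- predict_broad_spectrum(bundle$artifact, fx$sppos[1:12, ],
                                 ops = panel[panel$id != "GV", ],
                                 scaler = bundle$scaler,
                                 chem_columns = bundle$chem_columns)
  expect_true(all(res$broad_spectrum <= res4$broad_spectrum))
  expect_error(predict_broad_spectrum(bundle$artifact, fx$sppos[1:2, ],
                                      ops = panel[0, ]), "empty")
})
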