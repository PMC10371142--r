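toy_table <- function(mat) {
  feature_table(mat)
}

test_that("min-max scaling maps fitted columns onto [0, 1]", {
  m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  sc <- minmax_scale(toy_table(m))
  expect_equal(unname(sc$matrix[, "x"]), c(0, 0.5, 1))
  # constant columns map to 0 by convention
  m2 <- cbind(m, k = c(5, 5, 5))
  sc2 <- minmax_scale(toy_table(m2))
  expect_equal(unname(sc2$matrix[, "k"]), c(0, 0, 0))
})

test_that("values transformed outside the fitted range are clipped", {
  m <- matrix(c(2, 4, 5), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  sc <- minmax_scale(toy_table(m), fit_rows = c("a", "b"))
  # (5 - 2) / (4 - 2) = 1.5 -> clipped to 1
  expect_equal(unname(sc$matrix["c", "x"]), 1)
  un <- apply_scaler(matrix(5, 1, 1, dimnames = list("z", "x")), sc$scaler,
                     clip = FALSE)
  expect_equal(unname(un[1, 1]), 1.5)
})

test_that("scaling round-trips through the stored scaler", {
  set.seed(3)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(paste0("r", 1:12), paste0("c", 1:5)))
  sc <- minmax_scale(toy_table(m))
  back <- inverse_scale(sc)
  expect_equal(back, m, tolerance = 1e-9)
  expect_error(minmax_scale(sc), "already scaled")
})

test_that("variance filtering drops low-variance columns and records them", {
  m <- cbind(const = rep(1, 4),
             tiny = c(0, 0.1, 0.2, 0.3) * sqrt(0.01 / var(c(0, .1, .2, .3))),
             big = c(0, 1, 2, 3) * sqrt(0.5 / var(c(0, 1, 2, 3))))
  rownames(m) <- paste0("r", 1:4)
  ft <- toy_table(m)
  expect_equal(apply(m, 2, var), c(const = 0, tiny = 0.01, big = 0.5),
               tolerance = 1e-12)
  out <- variance_filter(ft, threshold = 0.02)
  expect_equal(colnames(out$matrix), "big")
  expect_setequal(out$dropped_columns, c("const", "tiny"))
  # a constant column is dropped at any threshold >= 0
  expect_true("const" %in% variance_filter(ft, 0)$dropped_columns)
  expect_error(variance_filter(ft, -1), "non-negative")
})

test_that("feature tables survive a CSV + manifest round-trip", {
  m <- matrix(runif(20), 4, 5,
              dimnames = list(paste0("r", 1:4), paste0("c", 1:5)))
  ft <- minmax_scale(feature_table(m))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, f, seed = 99L)
  back <- read_feature_table(f)
  expect_equal(back$matrix, ft$matrix)
  expect_equal(back$scaler$min, ft$scaler$min)
  expect_equal(back$scaler$max, ft$scaler$max)
  man <- jsonlite::fromJSON(paste0(f, ".manifest.json"))
  expect_equal(man$seed, 99L)
  expect_equal(man$toolkit$name, "rdkit")
})
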