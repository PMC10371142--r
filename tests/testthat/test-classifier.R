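test_that("stratified splitting tolerates degenerate clusters", {
  x <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), paste0("f", 1:3)))
  y <- rep(c("a", "b"), 5)
  plan <- stratified_split(x, y, k = 2, seed = 1)
  expect_equal(sum(plan$assignment == "test"), 2L)
  expect_setequal(names(plan$assignment), rownames(x))
})

test_that("splits are deterministic and class-balanced", {
  x <- toy_features(300, seed = 5)
  y <- rep(c("No", "Low", "High"), each = 100)
  p1 <- stratified_split(x, y, seed = 42)
  p2 <- stratified_split(x, y, seed = 42)
  expect_identical(p1, p2)
  expect_lte(abs(sum(p1$assignment == "test") - 60L), 1L)
  for (cls in unique(y)) {
    share <- mean(p1$assignment[y == cls] == "test")
    expect_lt(abs(share - 0.2), 0.10)
  }
  # a different seed gives a different split
  expect_false(identical(p1$assignment,
                         stratified_split(x, y, seed = 43)$assignment))
  expect_error(stratified_split(x[1:3, ], y[1:3], k = 10), "exceeds")
})

test_that("reduced-set selection recovers a single planted feature", {
  x <- toy_features(240, p = 8, seed = 9)
  y <- ifelse(x[, "f3"] > 0, "pos", "neg")
  rs <- select_reduced_set(x, y, sizes = c(1L, 4L), nfold = 3, seed = 2)
  expect_true("f3" %in% rs$names)
  size1 <- rs$candidates$macro_f1[rs$candidates$size == 1L]
  expect_gte(size1, 0.95)
  # both sizes separate perfectly here, so the tie falls to the smaller set
  expect_equal(length(rs$names), 1L)
})

test_that("a full-size-only grid returns the full feature set", {
  x <- toy_features(120, p = 5, seed = 4)
  y <- ifelse(x[, 1] + 0.3 * x[, 2] > 0, "a", "b")
  rs <- select_reduced_set(x, y, sizes = 5L, nfold = 3, seed = 1)
  expect_setequal(rs$names, colnames(x))
})

test_that("training is deterministic and fits separable data perfectly", {
  x <- toy_features(100, p = 4, seed = 8)
  y <- ifelse(x[, "f1"] > 0, "hi", "lo")
  grid <- data.frame(nrounds = 50L, max_depth = 3L, eta = 0.3)
  m1 <- train_classifier(x, y, grid = grid, nfold = 3, seed = 5)
  expect_equal(mean(predict(m1, x) == y), 1.0)
  m2 <- train_classifier(x, y, grid = grid, nfold = 3, seed = 5)
  probe <- toy_features(40, p = 4, seed = 99)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_error(train_classifier(x, y, grid = grid[0, ]), "grid")
  expect_error(train_classifier(x, rep("a", 100), grid = grid), "single class")
})

test_that("confusion-matrix metrics match hand-computed values", {
  cm <- matrix(c(10, 1, 0, 0, 8, 1, 0, 1, 9), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # rows = truth: A [10,0,0]; B [1,8,1]; C [0,1,9]
  rep <- confusion_metrics(cm)
  expect_equal(rep$overall_accuracy, 27 / 30)
  expect_equal(rep$per_class$sensitivity[rep$per_class$class == "A"], 1.0)
  expect_equal(rep$per_class$sensitivity[rep$per_class$class == "B"], 0.8)
  expect_equal(rep$per_class$selectivity[rep$per_class$class == "A"],
               19 / 20)
  expect_equal(rowSums(rep$normalized), c(A = 1, B = 1, C = 1))
  # constant predictor on a balanced 2-class set
  cm2 <- matrix(c(5, 5, 0, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  rep2 <- confusion_metrics(cm2)
  expect_equal(rep2$overall_accuracy, 0.5)
  expect_equal(sort(rep2$per_class$sensitivity), c(0, 1))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 5), k, k,
                 dimnames = list(letters[1:k], letters[1:k]))
    rep <- confusion_metrics(cm)
    expect_equal(rep$overall_accuracy, sum(diag(cm)) / sum(cm))
    ok <- !is.na(rep$per_class$precision) & !is.na(rep$per_class$sensitivity)
    lo <- pmin(rep$per_class$precision, rep$per_class$sensitivity)[ok]
    hi <- pmax(rep$per_class$precision, rep$per_class$sensitivity)[ok]
    expect_true(all(rep$per_class$f1[ok] >= lo - 1e-12 &
                      rep$per_class$f1[ok] <= hi + 1e-12))
    expect_true(all(rep$per_class$f1 >= 0 & rep$per_class$f1 <= 1))
  }
})

test_that("evaluation rejects unknown test classes and perfect is perfect", {
  x <- toy_features(80, p = 3, seed = 6)
  y <- ifelse(x[, 1] > 0, "a", "b")
  m <- train_classifier(x, y, grid = data.frame(nrounds = 60L, max_depth = 3L,
                                                eta = 0.3), nfold = 3,
                        seed = 1)
  rep <- evaluate_classifier(m, x, y)  # training data: separable, so perfect
  expect_equal(rep$overall_accuracy, 1.0)
  expect_true(all(rep$per_class$f1 == 1.0))
  expect_error(evaluate_classifier(m, x, rep("c", 80)), "absent")
  expect_error(evaluate_classifier(m, x[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("artifacts reload with identical predictions", {
  x <- toy_features(90, p = 4, seed = 12)
  y <- ifelse(x[, 2] - x[, 3] > 0, "a", "b")
  m <- train_classifier(x, y, grid = data.frame(nrounds = 80L, max_depth = 4L,
                                                eta = 0.2), nfold = 3,
                        seed = 3)
  dir <- withr::local_tempdir()
  save_classifier(m, dir)
  m2 <- load_classifier(dir)
  probe <- toy_features(50, p = 4, seed = 77)
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_identical(m2$feature_names, m$feature_names)
  expect_identical(m2$classes, m$classes)
})
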