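cm_of <- function(tp, fn, tn, fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")

test_that("metrics follow the standard confusion-matrix identities", {
  m <- metrics(cm_of(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(unname(m), c(0.9, 0.8, 0.2, 9 / 11, 2 * 0.9 * (9 / 11) /
                              (0.9 + 9 / 11), 0.85),
               tolerance = 1e-9)

  set.seed(15)
  for (i in 1:20) {
    cm <- cm_of(sample(1:50, 1), sample(1:50, 1),
                sample(1:50, 1), sample(1:50, 1))
    mm <- metrics(cm)
    expect_equal(unname(mm["fpr"] + mm["specificity"]), 1)
    expect_equal(unname(mm["f_score"]),
                 2 * mm[["recall"]] * mm[["precision"]] /
                   (mm[["recall"]] + mm[["precision"]]))
    expect_equal(unname(mm["accuracy"]),
                 (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn))
    expect_true(all(mm >= 0 & mm <= 1))
  }

  none <- metrics(cm_of(tp = 0, fn = 0, tn = 5, fp = 5))
  expect_true(is.na(none["recall"]))
  expect_false(is.na(none["specificity"]))
})

test_that("F-score works on fractions and percentages alike", {
  expect_equal(f_score(0.9, 0.9), 0.9)
  expect_equal(round(f_score(99.1, 98.3), 1), 98.7)
  expect_true(is.na(f_score(0, 0)))
})

test_that("both model kinds separate a separable toy problem deterministically", {
  set.seed(16)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 4), ncol = 2))
  y <- rep(c("NORMAL", "ST_ELEVATION"), each = 30)
  for (kind in c("svm_poly3", "knn")) {
    m <- train_model(x, y, model_spec(kind), seed = 4)
    expect_equal(mean(predict(m, x) == y), 1)
    m2 <- train_model(x, y, model_spec(kind), seed = 4)
    expect_identical(predict(m, x), predict(m2, x))
  }
  expect_error(train_model(x, rep("NORMAL", 60)), "two classes")
  m <- train_model(x, y)
  expect_error(predict(m, x[, 1, drop = FALSE]), "dimension")
})

test_that("standardization uses training statistics only", {
  set.seed(17)
  x <- matrix(rnorm(200), ncol = 2)
  y <- rep(c("NORMAL", "ST_ELEVATION"), each = 50)
  x[y == "ST_ELEVATION", ] <- x[y == "ST_ELEVATION", ] + 2
  m <- train_model(x, y)
  expect_equal(m$center, colMeans(x))
  expect_equal(m$scale, apply(x, 2, sd))
  # the stored transform, applied by hand, reproduces predict()
  xt <- matrix(rnorm(20), ncol = 2)
  xs <- scale(xt, center = m$center, scale = m$scale)
  expect_identical(predict(m, xt),
                   as.character(predict(m$fit, xs)))
})

test_that("cross-validation partitions every sample exactly once, stratified", {
  set.seed(18)
  x <- matrix(rnorm(300), ncol = 3)
  y <- rep(c("NORMAL", "ST_ELEVATION"), each = 50)
  x[y == "ST_ELEVATION", 1] <- x[y == "ST_ELEVATION", 1] + 3
  cv <- cross_validate(x, y, positive = "ST_ELEVATION", k = 5, seed = 2)
  expect_equal(sort(table(cv$fold_assignment)), sort(rep(20L, 5)),
               ignore_attr = TRUE)
  for (f in 1:5)
    expect_equal(as.integer(table(y[cv$fold_assignment == f])), c(10L, 10L))
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(unname(cv$mean["accuracy"]), mean(cv$folds$accuracy))
  expect_equal(unname(cv$sd["recall"]), sd(cv$folds$recall))

  # degenerate boundary: folds of one sample per class
  small_x <- x[c(1:5, 51:55), ]
  small_y <- y[c(1:5, 51:55)]
  cv1 <- cross_validate(small_x, small_y, positive = "ST_ELEVATION",
                        k = 5, seed = 1)
  expect_equal(nrow(cv1$folds), 5L)
  expect_error(cross_validate(small_x, small_y, positive = "ST_ELEVATION",
                              k = 6), "too few")
})

test_that("run_tasks requires all three classes", {
  ds <- list(traces = matrix(rnorm(40), 4, 10),
             label = c("NORMAL", "NORMAL", "ST_ELEVATION", "ST_ELEVATION"),
             fs = 500)
  expect_error(run_tasks(ds), "T_INVERSION")
})
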