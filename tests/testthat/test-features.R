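# Direct Table-style moment evaluation, written independently of
# t_features.
moments_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  c(mean = m, variance = v,
    skewness = sum((x - m)^3) / (n * s^3),
    kurtosis = sum((x - m)^4) / (n * s^4),
    cv = s / m)
}

test_that("time-domain moments are population moments, with sentinels", {
  expect_equal(t_features(c(1, 2, 3, 4)),
               c(mean = 2.5, variance = 1.25, skewness = 0,
                 kurtosis = 1.64, cv = 0.4472136),
               tolerance = 1e-6)
  const <- t_features(rep(2, 10))
  expect_equal(unname(const["variance"]), 0)
  expect_true(all(is.na(const[c("skewness", "kurtosis", "cv")])))

  sym <- c(-3, -1, 0, 1, 3) + 10
  expect_equal(unname(t_features(sym)["skewness"]), 0, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 5))
    expect_equal(t_features(x), moments_oracle(x), tolerance = 1e-12)
  }
})

test_that("spectral features hit their concentration and uniform limits", {
  imp <- c(1, rep(0, 31))
  fi <- f_features(imp)
  expect_equal(unname(fi["spectral_flatness"]), 1, tolerance = 1e-9)
  expect_equal(unname(fi["spectral_entropy"]), 1, tolerance = 1e-9)

  tone <- sin(2 * pi * 8 * (0:63) / 64)
  ft <- f_features(tone)
  expect_lt(ft["spectral_entropy"], 0.05)
  expect_lt(ft["spectral_flatness"], 0.05)
  expect_lt(ft["spectral_flux"], 1e-9)

  am <- tone * (1 + 0.8 * sin(2 * pi * (0:63) / 64))
  expect_gt(f_features(am)["spectral_flux"], 10 * max(ft["spectral_flux"], 1e-12))
  expect_error(f_features(1:4), "short")
})

test_that("joint features scale as their formulas dictate", {
  set.seed(12)
  x <- sin(2 * pi * 0.1 * (0:99)) + 0.3 * rnorm(100)
  j1 <- joint_tf_features(wvd(x, 1))
  j2 <- joint_tf_features(wvd(4 * x, 1))
  expect_equal(j1["tf_spectral_entropy"], j2["tf_spectral_entropy"],
               tolerance = 1e-9)
  expect_equal(j1["tf_spectral_flatness"], j2["tf_spectral_flatness"],
               tolerance = 1e-9)
  expect_equal(unname(j2["tf_mean"] / j1["tf_mean"]), 16, tolerance = 1e-6)
  expect_equal(unname(j2["tf_variance"] / j1["tf_variance"]), 256,
               tolerance = 1e-6)
  expect_equal(j1["tf_skewness"], j2["tf_skewness"], tolerance = 1e-9)

  one <- joint_tf_features(wvd(cos(2 * pi * 0.1 * (0:63)), 1))
  two <- joint_tf_features(
    wvd(cos(2 * pi * 0.1 * (0:63)) + cos(2 * pi * 0.3 * (0:63)), 1))
  expect_gt(two["tf_variance"], one["tf_variance"])

  zero <- wvd(sin(2 * pi * 0.2 * (0:31)), 1)
  zero$values[] <- 0
  expect_error(joint_tf_features(zero), "all-zero")
})

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(feature_auc(c(10, 20), c(1, 2)), 1)
  expect_equal(feature_auc(rep(5, 4), rep(5, 6)), 0.5)
  expect_equal(feature_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)

  set.seed(13)
  for (i in 1:10) {
    p <- round(rnorm(sample(1:50, 1)), 1)  # rounding forces ties
    q <- round(rnorm(sample(1:50, 1)), 1)
    expect_equal(feature_auc(p, q), concordance_auc(p, q), tolerance = 1e-12)
  }
  expect_error(feature_auc(numeric(0), 1), "non-empty")
})

test_that("feature screening applies the inclusive 0.5 threshold to raw AUC", {
  rep_df <- data.frame(feature = c("a", "b", "c"),
                       auc = c(0.50, 0.49, 0.81),
                       auc_folded = c(0.50, 0.51, 0.81),
                       selected = NA)
  expect_setequal(select_features(rep_df), c("a", "c"))
  expect_error(select_features(rep_df[0, ]), "empty")

  set.seed(14)
  fx <- data.frame(good = c(rnorm(30, 2), rnorm(30)),
                   noise = rnorm(60),
                   label = rep(c("ST_ELEVATION", "NORMAL"), each = 30))
  rp <- feature_auc_report(fx, positive = "ST_ELEVATION")
  expect_true(all(rp$auc >= 0 & rp$auc <= 1))
  expect_gt(rp$auc[rp$feature == "good"], 0.95)
  expect_true(all(rp$auc_folded >= 0.5))
})
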