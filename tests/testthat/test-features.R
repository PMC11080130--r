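test_that("time-domain features match closed forms", {
  v <- td_features(rep(2.5, 10))
  expect_equal(unname(v[c("RMS", "MAV", "iEMG", "WL", "ZC", "SSC")]),
               c(2.5, 2.5, 25, 0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(td_features(c(0, 1, 0, 1))[["WL"]]), 3,
               tolerance = 1e-12)
  alt <- td_features(c(1, -1, 1, -1, 1))
  expect_identical(unname(alt[["ZC"]]), 4)
  expect_identical(unname(alt[["SSC"]]), 3)
  expect_error(td_features(numeric(0)), "empty")
})

test_that("iEMG equals N x MAV and amplitude features are 1-homogeneous", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(50)
    v <- td_features(x)
    expect_equal(unname(v[["iEMG"]]), 50 * unname(v[["MAV"]]),
                 tolerance = 1e-12)
    g <- runif(1, 0.5, 4)
    vg <- td_features(g * x)
    for (f in c("RMS", "MAV", "iEMG", "WL")) {
      expect_equal(unname(vg[[f]]), g * unname(v[[f]]), tolerance = 1e-10)
    }
    expect_identical(vg[["ZC"]], v[["ZC"]])  # threshold 0 scales trivially
    expect_identical(vg[["SSC"]], v[["SSC"]])
  }
})

test_that("the dead band suppresses sub-threshold crossings", {
  x <- c(0.1, -0.1, 5, -5, 0.1)
  expect_identical(unname(td_features(x, threshold = 0)[["ZC"]]), 4)
  expect_identical(unname(td_features(x, threshold = 1)[["ZC"]]), 1)
})

test_that("cwt is linear, vanishes on zero input and localizes frequency", {
  expect_true(all(Mod(cwt(rep(0, 128))$coef) == 0))
  set.seed(6)
  x <- rnorm(200)
  C1 <- cwt(x)$coef
  C2 <- cwt(3.25 * x)$coef
  expect_equal(C2, 3.25 * C1, tolerance = 1e-12)
  # a sinusoid at the pseudo-frequency of a chosen scale peaks there
  fs <- 2000; w0 <- 5
  for (a_star in c(10.6, 30.6, 50.6)) {
    f_star <- w0 * fs / (2 * pi * a_star)
    t <- (0:399) / fs
    C <- cwt(sin(2 * pi * f_star * t), fs = fs)
    peak <- C$scales[which.max(scale_power(C))]
    expect_lt(abs(peak - a_star), 1.5)
  }
  expect_error(cwt(rnorm(100), scales = c(-1, 2)), "positive")
  expect_error(cwt(3), "2 samples")
})

test_that("fast cwt agrees with direct summation of the defining integral", {
  set.seed(7)
  for (L in c(64, 128, 256, 400)) {
    x <- rnorm(L)
    Cf <- cwt(x)$coef
    Cb <- brute_cwt(x, default_scales())
    expect_lt(max(Mod(Cf - Cb)) / max(Mod(Cb)), 1e-6)
  }
})

test_that("wavelet power and entropy match hand-computable cases", {
  expect_equal(cwt_power(matrix(c(1, -1, 1, -1), 1)), 1, tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(150)
  expect_equal(cwt_power(cwt(3 * x)), 9 * cwt_power(cwt(x)),
               tolerance = 1e-9)
  expect_equal(wavelet_entropy(c(7, rep(0, 59))), 0, tolerance = 1e-12)
  expect_equal(wavelet_entropy(rep(2.5, 60)), log(60), tolerance = 1e-12)
  expect_equal(wavelet_entropy(c(0.5, 0.5, rep(0, 58))), log(2),
               tolerance = 1e-12)
  expect_error(wavelet_entropy(rep(0, 60)), "all-zero")
  # upper bound with equality iff uniform
  p <- runif(60)
  expect_lt(wavelet_entropy(p), log(60))
})

test_that("the kurtosis kernel matches direct evaluation and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- 6; s <- sd(x)
  direct <- m * (m + 1) / ((m - 1) * (m - 2) * (m - 3)) *
    sum(((x - mean(x)) / s)^4) - 3 * (m - 1)^2 / ((m - 2) * (m - 3))
  expect_equal(sample_excess_kurtosis(x), direct, tolerance = 1e-12)
  expect_equal(direct, -1.2, tolerance = 1e-12)
  expect_error(sample_excess_kurtosis(rep(1, 10)), "degenerate")
  expect_error(cwt_kurtosis(matrix(1 + 0i, 4, 50)), "degenerate")
})

test_that("cwt kurtosis is invariant to positive rescaling", {
  set.seed(9)
  for (i in 1:5) {
    C <- cwt(rnorm(256))$coef
    g <- runif(1, 0.2, 8)
    expect_equal(cwt_kurtosis(g * C), cwt_kurtosis(C), tolerance = 1e-9)
  }
})

test_that("the batched wavelet features agree with the single-window path", {
  set.seed(10)
  W <- matrix(rnorm(5 * 400), 5, 400)
  batch <- window_features(W)
  for (i in 1:5) {
    C <- cwt(W[i, ])
    expect_equal(unname(batch[i, "CWT_power"]), cwt_power(C),
                 tolerance = 1e-4)
    expect_equal(unname(batch[i, "WE"]), wavelet_entropy(C),
                 tolerance = 1e-4)
    expect_equal(unname(batch[i, "CWT_kurtosis"]), cwt_kurtosis(C),
                 tolerance = 1e-3)
  }
})

make_feature_table <- function() {
  data.frame(
    subject = "S1", group = "healthy", sex = "F",
    level = rep(c("MVC", "MVC", "MVC", "0.2"), each = 1),
    channel = "FCR", trial = c(1L, 2L, 3L, 4L), window = 1L,
    feature = "RMS", raw = c(4, 4, 4, 2), stringsAsFactors = FALSE)
}

test_that("MVC normalization divides by the mean MVC reference", {
  tab <- make_feature_table()
  norm <- mvc_normalize(tab)
  expect_equal(norm$normalized, 0.5, tolerance = 1e-12)
  tab$raw[4] <- 4
  expect_equal(mvc_normalize(tab)$normalized, 1, tolerance = 1e-12)
  tab$raw[1:3] <- 0
  expect_error(mvc_normalize(tab), "zero MVC reference")
  tab2 <- make_feature_table()
  tab2$channel[1:3] <- "FDS"                 # no reference for FCR
  expect_error(mvc_normalize(tab2), "FCR")
})

test_that("aggregation reduces to means with the expected symmetries", {
  tab <- data.frame(
    subject = "S1", group = "healthy", level = "0.2",
    channel = c("FCR", "FCR", "FDS", "FDS"), trial = c(1L, 2L, 1L, 2L),
    window = 1L, feature = "RMS", normalized = c(1, 3, 5, 7),
    stringsAsFactors = FALSE)
  a <- aggregate_features(tab, "stats")
  expect_equal(a$value, 4)
  b <- aggregate_features(tab, "classify", channels = c("FCR", "FDS"))
  expect_equal(b$value, (2 + 6) / 2)
  # permuting trial order leaves the aggregate unchanged
  tab2 <- tab[c(2, 1, 4, 3), ]
  expect_equal(aggregate_features(tab2, "stats")$value, a$value)
  # single window, trial, channel: identity
  one <- tab[1, ]
  expect_equal(aggregate_features(one, "stats")$value, 1)
  expect_error(aggregate_features(tab, "classify", channels = character(0)),
               "non-empty")
})
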