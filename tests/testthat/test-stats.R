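test_that("the AWGS rule reproduces reference profiles", {
  expect_identical(awgs_screen("M", grip = 23.8, smi = 6.5, cst = 10.1),
                   "sarcopenic")
  expect_identical(awgs_screen("F", grip = 22.4, smi = 6.4, cst = 9.7),
                   "healthy")
  expect_identical(awgs_screen("M", grip = 20, smi = 7.5, cst = 10),
                   "intermediate")
  expect_error(awgs_screen("X", 20, 6, 10), "unknown sex")
})

test_that("the AWGS rule is monotone in each measurement", {
  severity <- function(cat) c(healthy = 0, intermediate = 1,
                              sarcopenic = 2)[cat]
  set.seed(11)
  n <- 2000
  sex <- sample(c("M", "F"), n, replace = TRUE)
  grip <- runif(n, 5, 45)
  smi <- runif(n, 4, 9)
  cst <- runif(n, 5, 20)
  base <- severity(awgs_screen(sex, grip, smi, cst))
  expect_true(all(severity(awgs_screen(sex, grip + runif(n, 0, 10),
                                       smi, cst)) <= base))
  expect_true(all(severity(awgs_screen(sex, grip, smi + runif(n, 0, 2),
                                       cst)) <= base))
  expect_true(all(severity(awgs_screen(sex, grip, smi,
                                       pmax(0.1, cst - runif(n, 0, 5)))) <=
                    base))
})

test_that("Mann-Whitney matches hand-derived exact cases", {
  t <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(t$statistic, 0)
  expect_equal(t$p, 0.1, tolerance = 1e-12)
  same <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_identical(same$statistic, 16 / 2)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # complementarity under swapping groups
  set.seed(12)
  a <- sample(1:5, 4, replace = TRUE)
  b <- sample(1:5, 6, replace = TRUE)
  t1 <- mann_whitney_u(a, b)
  t2 <- mann_whitney_u(b, a)
  expect_equal(t1$statistic + t2$statistic, length(a) * length(b))
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("the exact Mann-Whitney branch equals full enumeration with ties", {
  set.seed(13)
  for (rep in 1:25) {
    na <- sample(1:5, 1)
    nb <- sample(1:5, 1)
    a <- sample(1:4, na, replace = TRUE)
    b <- sample(1:4, nb, replace = TRUE)
    got <- mann_whitney_u(a, b)
    oracle <- mwu_enum(a, b)
    expect_equal(got$statistic, oracle$u, tolerance = 1e-12)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("the tie-free exact branch agrees with the reference implementation", {
  set.seed(14)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(7)
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal branches agree near the crossover", {
  set.seed(15)
  devs <- replicate(60, {
    a <- rnorm(10)
    b <- rnorm(10)
    abs(mann_whitney_u(a, b, exact_max = 20)$p -
          mann_whitney_u(a, b, exact_max = 0)$p)
  })
  expect_lt(stats::median(devs), 0.01)
  expect_lt(max(devs), 0.05)
})

test_that("Wilcoxon signed-rank matches hand-derived exact cases", {
  t <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_identical(t$statistic, 6)            # positive-rank sum
  expect_equal(t$p, 0.25, tolerance = 1e-12)
  # sign symmetry
  set.seed(16)
  d <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p,
               tolerance = 1e-12)
  tie <- wilcoxon_signed_rank(c(1, -1))
  expect_equal(tie$p, 1, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("the exact signed-rank branch equals sign-flip enumeration", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d)
    oracle <- wsr_enum(d)
    expect_equal(got$statistic, oracle$w, tolerance = 1e-12)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("variance and normality audits behave on degenerate input", {
  set.seed(18)
  a <- rnorm(30)
  res <- variance_and_normality_checks(a, a)
  expect_equal(res$levene$statistic, 0, tolerance = 1e-12)
  big <- rnorm(4000)
  res2 <- variance_and_normality_checks(big, rnorm(30))
  expect_lt(res2$ks_a$statistic, 0.03)       # consistency at large n
  expect_error(variance_and_normality_checks(rep(1, 5), rep(2, 5)),
               "degenerate")
})

test_that("Levene p-values are calibrated under the null", {
  set.seed(19)
  pv <- replicate(400, {
    variance_and_normality_checks(rnorm(15), rnorm(15))$levene$p
  })
  expect_gt(mean(pv), 0.40)
  expect_lt(mean(pv), 0.60)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
})

test_that("the feature comparison report runs both test families", {
  set.seed(20)
  subj <- sprintf("S%02d", 1:12)
  grp <- rep(c("healthy", "sarcopenic"), each = 6)
  tab <- expand.grid(subject = subj, level = c("0.2", "0.5"),
                     feature = c("RMS", "WE"), stringsAsFactors = FALSE)
  tab$group <- grp[match(tab$subject, subj)]
  tab$value <- rnorm(nrow(tab)) +
    ifelse(tab$group == "sarcopenic" & tab$feature == "RMS", 3, 0)
  rep_ <- feature_comparison_report(tab)
  expect_identical(nrow(rep_), 8L)            # 2x2 group + 2x2 level tests
  rms_group <- rep_[rep_$feature == "RMS" & grepl("group", rep_$comparison), ]
  expect_true(all(rms_group$significant))
  # single-subject group errors
  bad <- tab[tab$subject %in% c("S01", "S07"), ]
  expect_error(feature_comparison_report(bad), "fewer than 2")
  # missing level errors
  expect_error(feature_comparison_report(tab[tab$level == "0.2" |
                                               tab$feature == "WE", ]),
               "missing level")
})
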