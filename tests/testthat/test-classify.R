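test_that("fold assignments are balanced, deterministic and guarded", {
  y <- c(rep(0, 45), rep(1, 48))
  f <- make_folds(y, 5, seed = 3)
  sizes <- tabulate(f, 5)
  expect_setequal(sizes, c(19, 19, 19, 18, 18))
  for (k in 1:5) {
    gap <- abs(sum(y[f == k] == 0) - sum(y[f == k] == 1))
    expect_lte(gap, 1)
  }
  expect_identical(f, make_folds(y, 5, seed = 3))
  y2 <- rep(0:1, each = 10)
  f2 <- make_folds(y2, 5, seed = 1)
  for (k in 1:5) {
    expect_identical(sum(y2[f2 == k] == 0), 2L)
    expect_identical(sum(y2[f2 == k] == 1), 2L)
  }
  expect_error(make_folds(c(0, 0, 1, 1), 5), "infeasible")
})

test_that("members fit a separable problem perfectly and reject one class", {
  d <- blob_data(12, shift = 6, seed = 21)
  m <- fit_members(d$x, d$y, fast_spec(), seed = 1)
  p <- predict_members(m, d$x)
  expect_true(all((p[, "svm"] >= 0.5) == d$y))
  expect_true(all((p[, "rf"] >= 0.5) == d$y))
  expect_true(all((p[, "gbm"] >= 0.5) == d$y))
  expect_error(fit_members(d$x[d$y == 1, ], d$y[d$y == 1]),
               "single-class")
})

test_that("label-permuted training yields chance-level held-out accuracy", {
  accs <- sapply(1:12, function(s) {
    d <- blob_data(16, shift = 2, seed = 400 + s)
    set.seed(500 + s)
    y_perm <- sample(d$y)
    tr <- c(1:12, 17:28)
    te <- setdiff(seq_len(32), tr)
    m <- fit_members(d$x[tr, ], y_perm[tr], fast_spec(), seed = s)
    w <- search_weights(m)
    mean(soft_vote(m, w, d$x[te, ])$label == y_perm[te])
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("weight search concentrates on a dominant member and breaks ties", {
  # synthetic members object: member 2 perfect, members 1/3 at chance
  set.seed(22)
  y <- rep(0:1, each = 20)
  oof <- cbind(svm = runif(40, 0.4, 0.6), rf = ifelse(y == 1, 0.9, 0.1),
               gbm = runif(40, 0.4, 0.6))
  members <- structure(list(oof = oof, y = y), class = "semg_members")
  w <- search_weights(members)
  expect_gt(w[2], 0.6)
  # identical members: every weight ties, lexicographically least returned
  oof_same <- cbind(svm = ifelse(y == 1, 0.8, 0.2),
                    rf = ifelse(y == 1, 0.8, 0.2),
                    gbm = ifelse(y == 1, 0.8, 0.2))
  members2 <- structure(list(oof = oof_same, y = y),
                        class = "semg_members")
  w2 <- search_weights(members2)
  expect_equal(unname(w2), c(0, 0, 1))      # lowest nonzero lattice point
  # single-point grid
  w3 <- search_weights(members2, grid = 1)
  expect_equal(unname(w3), c(1, 1, 1) / 3)
})

test_that("the soft vote follows the weighted-probability arithmetic", {
  d <- blob_data(10, shift = 4, seed = 23)
  m <- fit_members(d$x, d$y, fast_spec(), seed = 2)
  p <- predict_members(m, d$x)
  sv <- soft_vote(m, c(1, 1, 1), d$x)
  expect_equal(sv$score, rowMeans(p), tolerance = 1e-12)
  expect_identical(sv$label, as.integer(rowMeans(p) >= 0.5))
  # single nonzero weight reproduces that member exactly
  for (i in 1:3) {
    w <- c(0, 0, 0); w[i] <- 1
    svi <- soft_vote(m, w, d$x)
    expect_equal(svi$score, unname(p[, i]), tolerance = 1e-12)
    expect_identical(svi$label, as.integer(p[, i] >= 0.5))
  }
  expect_error(soft_vote(m, c(0, 0, 0), d$x), "not all zero")
})

test_that("metrics match their defining ratios and flag undefined cases", {
  y <- c(rep(1, 48), rep(0, 45))
  pred <- c(rep(1, 38), rep(0, 10), rep(1, 15), rep(0, 30))
  m <- classification_metrics(y, pred)
  expect_equal(m$sensitivity, 38 / 48, tolerance = 1e-12)
  expect_equal(m$specificity, 30 / 45, tolerance = 1e-12)
  expect_equal(m$accuracy, 68 / 93, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 38 / (2 * 38 + 15 + 10), tolerance = 1e-12)
  perfect <- classification_metrics(y, y)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity",
                                   "specificity", "f1")]) == 1))
  allpos <- classification_metrics(y, rep(1, 93))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  onecls <- classification_metrics(rep(1, 5), rep(1, 5))
  expect_true(is.nan(onecls$specificity))
  expect_match(attr(onecls$specificity, "undefined"), "specificity")
})

test_that("AUC equals the pairwise rank-sum oracle and handles edge cases", {
  set.seed(24)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # force ties
    expect_equal(roc_auc(scores, y)$auc, auc_pairwise(scores, y),
                 tolerance = 1e-12)
  }
  y <- rep(0:1, each = 10)
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), y)$auc, 1)
  expect_warning(r <- roc_auc(rep(0.5, 20), y), "constant")
  expect_equal(r$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  y <- rep(0:1, each = 30)
  scores <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, y)$auc, ref, tolerance = 1e-12)
})

test_that("the operating point maximizes sensitivity above the floor", {
  pts <- data.frame(threshold = c(0.9, 0.6, 0.3),
                    sensitivity = c(0.5, 0.8, 0.95),
                    specificity = c(0.9, 0.7, 0.6))
  oop <- select_oop(pts, 0.65)
  expect_equal(oop$sensitivity, 0.8)
  expect_equal(oop$specificity, 0.7)
  expect_error(select_oop(pts, 0.95), "no operating point")
  single <- pts[1, ]
  expect_equal(select_oop(single, 0.65)$sensitivity, 0.5)
  # sensitivity tie resolves to the higher specificity
  tie <- data.frame(threshold = c(0.5, 0.4),
                    sensitivity = c(0.8, 0.8),
                    specificity = c(0.7, 0.75))
  expect_equal(select_oop(tie, 0.65)$specificity, 0.75)
})

test_that("cross-validation is deterministic and leakage-free", {
  d <- blob_data(15, shift = 2.5, seed = 26)
  cv1 <- cross_validate(d$x, d$y, fast_spec(), k = 5, seed = 4,
                        keep_models = TRUE)
  cv2 <- cross_validate(d$x, d$y, fast_spec(), k = 5, seed = 4,
                        keep_models = TRUE)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  # scrambling the held-out fold's features must not change the model
  # trained for that fold
  x_noise <- d$x
  te1 <- which(cv1$fold == 1)
  set.seed(99)
  x_noise[te1, ] <- matrix(rnorm(length(te1) * ncol(d$x)), length(te1))
  cv3 <- cross_validate(x_noise, d$y, fast_spec(), k = 5, seed = 4,
                        keep_models = TRUE)
  probe <- blob_data(5, shift = 2.5, seed = 27)$x
  p_before <- predict_members(cv1$models[[1]]$members, probe)
  p_after <- predict_members(cv3$models[[1]]$members, probe)
  expect_identical(p_before, p_after)
  expect_identical(cv1$models[[1]]$w, cv3$models[[1]]$w)
})
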