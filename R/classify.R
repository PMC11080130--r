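#' Voting-ensemble specification
#'
#' Member models and search grids for the weighted soft-voting classifier:
#' a linear-kernel support vector machine (probabilities via Platt scaling
#' fitted on inner-fold decision values), a random forest, and a gradient
#' boosting machine.  Hyperparameters are chosen by grid search on inner
#' cross-validation folds of the training data only; voting weights are
#' searched on a `{0, 0.1, ..., 1}^3` grid to maximize inner-fold
#' sensitivity.
#'
#' @param svm_cost margin-penalty grid for the linear SVM.
#' @param rf_trees number of trees in the forest.
#' @param rf_depth depth grid for the forest (0 = unlimited).
#' @param gbm_eta learning-rate grid for boosting.
#' @param gbm_rounds boosting rounds.
#' @param gbm_depth boosting tree depth.
#' @param inner_k inner cross-validation folds.
#' @param weight_grid marginal grid for each voting weight.
#' @return object of class `semg_ensemble_spec`.
#' @export
ensemble_spec <- function(svm_cost = c(0.1, 1, 10),
                          rf_trees = 200, rf_depth = c(3, 5, 0),
                          gbm_eta = c(0.05, 0.1), gbm_rounds = 200,
                          gbm_depth = 3, inner_k = 3,
                          weight_grid = seq(0, 1, by = 0.1)) {
  out <- list(svm_cost = svm_cost, rf_trees = rf_trees, rf_depth = rf_depth,
              gbm_eta = gbm_eta, gbm_rounds = gbm_rounds,
              gbm_depth = gbm_depth, inner_k = inner_k,
              weight_grid = weight_grid)
  class(out) <- "semg_ensemble_spec"
  out
}

#' Balanced subject-level folds
#'
#' Partitions subjects into `k` folds such that, within every fold, the
#' two class counts differ by at most one and fold sizes differ by at
#' most one.  Deterministic given the seed.
#'
#' @param y 0/1 class labels (one per subject).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment (1..k) per subject.
#' @export
make_folds <- function(y, k = 5, seed = 1L) {
  y <- as.integer(y)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < k || n1 < k) {
    stop("infeasible balance: need at least k subjects per class")
  }
  set.seed(seed)
  chunk_sizes <- function(n) {
    s <- rep(n %/% k, k)
    if (n %% k) s[seq_len(n %% k)] <- s[seq_len(n %% k)] + 1L
    s
  }
  # pair the larger chunks of one class with the smaller of the other
  s0 <- sort(chunk_sizes(n0), decreasing = TRUE)
  s1 <- sort(chunk_sizes(n1), decreasing = FALSE)
  i0 <- sample(which(y == 0))
  i1 <- sample(which(y == 1))
  fold <- integer(length(y))
  fold[i0] <- rep(seq_len(k), times = s0)
  fold[i1] <- rep(seq_len(k), times = s1)
  fold
}

fit_one_svm <- function(x, y, cost) {
  e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
             cost = cost, scale = TRUE)
}

svm_decision <- function(model, x) {
  p <- predict(model, x, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  # orient so that larger values favour class 1
  if (colnames(attr(p, "decision.values"))[1] == "0/1") dv <- -dv
  dv
}

fit_one_rf <- function(x, y, depth, trees, seed) {
  ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                 num.trees = trees, max.depth = depth,
                 probability = TRUE, num.threads = 1, seed = seed)
}

fit_one_gbm <- function(x, y, eta, rounds, depth, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eta = eta, max_depth = depth,
                                   nthread = 1, seed = seed),
                     data = dtrain, nrounds = rounds, verbose = 0)
}

#' Fit the three ensemble members
#'
#' Selects each member's hyperparameters by grid search over balanced
#' inner cross-validation folds of the training data (highest mean inner
#' accuracy; first grid point on ties), refits on the full training set,
#' and fits the SVM's Platt probability calibration on inner-fold
#' out-of-fold decision values.  The members' inner-fold out-of-fold
#' class-1 probabilities are retained for the voting-weight search.
#'
#' @param x training feature matrix (subjects x features).
#' @param y 0/1 labels, sarcopenic = 1.
#' @param spec an [ensemble_spec()].
#' @param seed integer seed.
#' @return object of class `semg_members` with fitted models,
#'   calibration, chosen hyperparameters and inner-fold out-of-fold
#'   probabilities.
#' @export
fit_members <- function(x, y, spec = ensemble_spec(), seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("single-class training set")
  k <- min(spec$inner_k, sum(y == 0), sum(y == 1))
  if (k < 2) stop("too few subjects per class for inner folds")
  fold <- make_folds(y, k, seed = seed)
  acc <- function(pred) mean(pred == y)

  inner_hard <- function(fit_fun, predict_hard) {
    pred <- integer(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_fun(x[tr, , drop = FALSE], y[tr], f)
      pred[!tr] <- predict_hard(m, x[!tr, , drop = FALSE])
    }
    acc(pred)
  }

  # ---- SVM: choose cost -------------------------------------------------
  svm_acc <- vapply(spec$svm_cost, function(cost) {
    inner_hard(function(xx, yy, f) fit_one_svm(xx, yy, cost),
               function(m, xx) as.integer(as.character(predict(m, xx))))
  }, 0)
  best_cost <- spec$svm_cost[which.max(svm_acc)]
  # ---- RF: choose depth -------------------------------------------------
  rf_acc <- vapply(spec$rf_depth, function(depth) {
    inner_hard(function(xx, yy, f) fit_one_rf(xx, yy, depth, spec$rf_trees,
                                              seed + f),
               function(m, xx) {
                 as.integer(predict(m, xx, num.threads = 1)$predictions[, "1"] >= 0.5)
               })
  }, 0)
  best_depth <- spec$rf_depth[which.max(rf_acc)]
  # ---- GBM: choose eta --------------------------------------------------
  gbm_acc <- vapply(spec$gbm_eta, function(eta) {
    inner_hard(function(xx, yy, f) fit_one_gbm(xx, yy, eta, spec$gbm_rounds,
                                               spec$gbm_depth, seed + f),
               function(m, xx) as.integer(predict(m, as.matrix(xx)) >= 0.5))
  }, 0)
  best_eta <- spec$gbm_eta[which.max(gbm_acc)]

  # ---- out-of-fold class-1 probabilities at the chosen hyperparameters --
  oof <- matrix(NA_real_, length(y), 3,
                dimnames = list(NULL, c("svm", "rf", "gbm")))
  oof_dv <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- which(!tr)
    m_svm <- fit_one_svm(x[tr, , drop = FALSE], y[tr], best_cost)
    oof_dv[te] <- svm_decision(m_svm, x[te, , drop = FALSE])
    m_rf <- fit_one_rf(x[tr, , drop = FALSE], y[tr], best_depth,
                       spec$rf_trees, seed + f)
    oof[te, "rf"] <- predict(m_rf, x[te, , drop = FALSE],
                             num.threads = 1)$predictions[, "1"]
    m_gbm <- fit_one_gbm(x[tr, , drop = FALSE], y[tr], best_eta,
                         spec$gbm_rounds, spec$gbm_depth, seed + f)
    oof[te, "gbm"] <- predict(m_gbm, x[te, , drop = FALSE])
  }
  # Platt scaling of the SVM on the out-of-fold decision values
  platt <- suppressWarnings(glm(y ~ dv, family = binomial(),
                                data = data.frame(y = y, dv = oof_dv)))
  oof[, "svm"] <- as.numeric(predict(platt, data.frame(dv = oof_dv),
                                     type = "response"))

  # final member fits on the full training set
  svm_final <- fit_one_svm(x, y, best_cost)
  rf_final <- fit_one_rf(x, y, best_depth, spec$rf_trees, seed)
  gbm_final <- fit_one_gbm(x, y, best_eta, spec$gbm_rounds,
                           spec$gbm_depth, seed)
  out <- list(svm = svm_final, rf = rf_final, gbm = gbm_final,
              platt = platt,
              hyper = list(cost = best_cost, depth = best_depth,
                           eta = best_eta),
              oof = oof, y = y, inner_fold = fold)
  class(out) <- "semg_members"
  out
}

#' Member class-1 probabilities
#'
#' @param members a [fit_members()] result.
#' @param x feature matrix.
#' @return n x 3 matrix of calibrated class-1 probabilities.
#' @export
predict_members <- function(members, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  dv <- svm_decision(members$svm, x)
  p_svm <- as.numeric(predict(members$platt, data.frame(dv = dv),
                              type = "response"))
  p_rf <- predict(members$rf, x, num.threads = 1)$predictions[, "1"]
  p_gbm <- as.numeric(predict(members$gbm, x))
  cbind(svm = p_svm, rf = p_rf, gbm = p_gbm)
}

weight_lattice <- function(grid) {
  W <- as.matrix(expand.grid(w3 = grid, w2 = grid,
                             w1 = grid))[, 3:1, drop = FALSE]
  W[rowSums(W) > 0, , drop = FALSE]
}

#' Grid search of the voting weights
#'
#' Exhaustive search over the weight lattice, scoring each weight vector
#' by the sensitivity of the soft vote on the members' inner-fold
#' out-of-fold probabilities.  Ties are broken by higher specificity,
#' then by the lexicographically smallest weight vector.  Weights are
#' returned normalized to sum to one.
#'
#' @param members a [fit_members()] result.
#' @param grid marginal weight grid.
#' @return numeric weight vector of length 3 (svm, rf, gbm).
#' @export
search_weights <- function(members, grid = seq(0, 1, by = 0.1)) {
  W <- weight_lattice(grid)
  P <- members$oof
  y <- members$y
  scores <- (P %*% t(W)) / rep(rowSums(W), each = nrow(P))
  pred <- scores >= 0.5                      # tie votes positive
  sens <- colMeans(pred[y == 1, , drop = FALSE])
  spec_ <- colMeans(!pred[y == 0, , drop = FALSE])
  ord <- order(-sens, -spec_, W[, 1], W[, 2], W[, 3])
  w <- W[ord[1], ]
  w / sum(w)
}

#' Weighted soft vote
#'
#' Combines member class probabilities as `sum_i w_i P_i,j`; the label is
#' the class with the larger weighted sum, with exact ties voting
#' sarcopenic (screening favours sensitivity).  The reported score is the
#' normalized class-1 weighted sum.
#'
#' @param members a [fit_members()] result.
#' @param w length-3 weight vector, not all zero.
#' @param x feature matrix.
#' @return list with `score` (class-1 weighted probability) and `label`
#'   (0/1).
#' @export
soft_vote <- function(members, w, x) {
  if (length(w) != 3 || any(w < 0) || sum(w) == 0) {
    stop("weights must be 3 non-negative values, not all zero")
  }
  P <- predict_members(members, x)
  score <- as.numeric(P %*% w) / sum(w)
  list(score = score, label = as.integer(score >= 0.5))
}

#' Screening metrics
#'
#' Accuracy, sensitivity (recall of the sarcopenic class), specificity
#' and F1 score.  Undefined ratios are returned as `NaN` with the reason
#' in attribute `"undefined"`.
#'
#' @param y true 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @return named list of the four metrics plus the confusion counts.
#' @export
classification_metrics <- function(y, pred) {
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
  tn <- sum(y == 0 & pred == 0); fp <- sum(y == 0 & pred == 1)
  div <- function(num, den, what) {
    if (den == 0) {
      out <- NaN
      attr(out, "undefined") <- paste0(what, ": zero denominator")
      out
    } else num / den
  }
  list(accuracy = div(tp + tn, length(y), "accuracy"),
       sensitivity = div(tp, tp + fn, "sensitivity"),
       specificity = div(tn, tn + fp, "specificity"),
       f1 = div(2 * tp, 2 * tp + fp + fn, "f1"),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' ROC curve and AUC
#'
#' Operating points at every distinct score (prediction positive when the
#' score is at or above the threshold) plus sentinels; AUC by the
#' trapezoid rule, which equals the tie-averaged rank-sum statistic
#' normalized by `n0 * n1`.
#'
#' @param scores continuous class-1 scores.
#' @param y true 0/1 labels.
#' @return list with `points` (threshold, fpr, tpr, sensitivity,
#'   specificity) and `auc`.
#' @export
roc_auc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC is 0.5 by convention")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr,
                           sensitivity = tpr, specificity = 1 - fpr),
       auc = auc)
}

#' Optimal operating point under a specificity floor
#'
#' Among ROC points whose specificity exceeds the floor, returns the one
#' with maximal sensitivity; ties resolve to the higher specificity.
#'
#' @param roc a [roc_auc()] result (or its `points` data.frame).
#' @param spec_floor minimum acceptable specificity.
#' @return one row of the ROC points.
#' @export
select_oop <- function(roc, spec_floor = 0.65) {
  pts <- if (is.data.frame(roc)) roc else roc$points
  ok <- pts$specificity > spec_floor
  if (!any(ok)) {
    stop(sprintf("no operating point with specificity > %.2f (best achievable at nonzero sensitivity: %.3f)",
                 spec_floor, max(pts$specificity[pts$sensitivity > 0], 0)))
  }
  cand <- pts[ok, , drop = FALSE]
  cand[order(-cand$sensitivity, -cand$specificity), ][1, ]
}

#' Subject-level k-fold cross-validation of the voting classifier
#'
#' For each fold: members and voting weights are trained on the remaining
#' folds only (hyperparameters and weights from inner folds of that
#' training set), then evaluated on the held-out fold.  Reports per-fold
#' metrics, their mean and SD, the pooled ROC/AUC and the optimal
#' operating point.
#'
#' @param x subject feature matrix.
#' @param y 0/1 labels, sarcopenic = 1.
#' @param spec an [ensemble_spec()].
#' @param k number of outer folds.
#' @param seed integer seed.
#' @param spec_floor specificity floor for the operating point.
#' @param keep_models keep each fold's fitted members in the report.
#' @return object of class `semg_cv_report`.
#' @export
cross_validate <- function(x, y, spec = ensemble_spec(), k = 5, seed = 1L,
                           spec_floor = 0.65, keep_models = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fold <- make_folds(y, k, seed = seed)
  per_fold <- vector("list", k)
  scores <- numeric(length(y))
  preds <- integer(length(y))
  weights <- matrix(NA_real_, k, 3,
                    dimnames = list(NULL, c("svm", "rf", "gbm")))
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- which(!tr)
    if (length(unique(y[te])) < 2) stop("fold with one class only")
    members <- fit_members(x[tr, , drop = FALSE], y[tr], spec,
                           seed = seed + f)
    w <- search_weights(members, spec$weight_grid)
    weights[f, ] <- w
    sv <- soft_vote(members, w, x[te, , drop = FALSE])
    scores[te] <- sv$score
    preds[te] <- sv$label
    per_fold[[f]] <- classification_metrics(y[te], sv$label)
    if (keep_models) models[[f]] <- list(members = members, w = w)
  }
  mnames <- c("accuracy", "sensitivity", "specificity", "f1")
  fold_tab <- t(vapply(per_fold,
                       function(m) unlist(m[mnames]), numeric(4)))
  roc <- roc_auc(scores, y)
  oop <- tryCatch(select_oop(roc, spec_floor), error = function(e) NULL)
  out <- list(fold_metrics = as.data.frame(fold_tab),
              mean = colMeans(fold_tab), sd = apply(fold_tab, 2, sd),
              weights = weights, scores = scores, predictions = preds,
              labels = y, fold = fold, roc = roc, auc = roc$auc,
              oop = oop, models = models)
  class(out) <- "semg_cv_report"
  out
}

#' @export
print.semg_cv_report <- function(x, ...) {
  cat("Subject-level", nrow(x$fold_metrics), "fold cross-validation\n")
  m <- x$mean; s <- x$sd
  for (n in names(m)) {
    cat(sprintf("  %-11s %.3f (+/- %.3f)\n", n, m[n], s[n]))
  }
  cat(sprintf("  AUC         %.3f\n", x$auc))
  if (!is.null(x$oop)) {
    cat(sprintf("  OOP         sensitivity %.3f at specificity %.3f\n",
                x$oop$sensitivity, x$oop$specificity))
  }
  invisible(x)
}
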