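#' Permutation-sampling Shapley feature impacts
#'
#' Model-agnostic Monte-Carlo estimator of Shapley values on a continuous
#' model score.  For each sampled feature ordering, features are switched
#' one at a time from a background row to the explained subject's values
#' and the marginal score changes are accredited to the switched feature;
#' averaging over orderings gives the Shapley estimate.  Background rows
#' are cycled deterministically (a variance-reduction choice): within one
#' permutation the marginal contributions telescope, so whenever the
#' permutation count is a multiple of the background size each subject's
#' impacts sum exactly to its score minus the expected background score
#' (exact local accuracy).
#'
#' @param score_fun function mapping a feature matrix to a numeric score
#'   per row (for the voting classifier: the weighted class-1
#'   probability).
#' @param x feature matrix of the subjects to explain.
#' @param background feature matrix of background subjects (the reference
#'   distribution; typically up to 50 training subjects).
#' @param n_permutations Monte-Carlo sample size.
#' @param seed integer seed.
#' @return object of class `semg_shap`: per-subject-per-feature `values`,
#'   their Monte-Carlo standard errors `se`, the expected background
#'   score `base`, per-subject standard error of the impact sum
#'   `sum_se`, the model `score` of each subject, and `feature_order`
#'   (descending mean absolute impact).
#' @export
shapley_impacts <- function(score_fun, x, background,
                            n_permutations = 200, seed = 1L) {
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must be non-empty")
  if (n_permutations < 1) stop("need at least one permutation")
  set.seed(seed)
  n <- nrow(x); f <- ncol(x)
  nbg <- nrow(background)
  vals <- matrix(0, n, f, dimnames = dimnames(x))
  sq <- matrix(0, n, f, dimnames = dimnames(x))
  z0_sum <- numeric(n)
  z0_sq <- numeric(n)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(f)
    z <- background[((p - 1L) %% nbg) + 1L, ]
    cur <- matrix(z, n, f, byrow = TRUE, dimnames = dimnames(x))
    prev <- score_fun(cur)
    z0_sum <- z0_sum + prev
    z0_sq <- z0_sq + prev^2
    for (j in ord) {
      cur[, j] <- x[, j]
      s <- score_fun(cur)
      contrib <- s - prev
      vals[, j] <- vals[, j] + contrib
      sq[, j] <- sq[, j] + contrib^2
      prev <- s
    }
  }
  P <- n_permutations
  values <- vals / P
  se <- if (P > 1) sqrt(pmax(sq / P - values^2, 0) / (P - 1)) else 0 * vals
  base_draws_mean <- z0_sum / P
  base_var <- pmax(0, z0_sq / P - base_draws_mean^2)
  sum_se <- if (P > 1) sqrt(base_var / (P - 1)) else rep(0, n)
  score <- score_fun(x)
  imp <- colMeans(abs(values))
  out <- list(values = values, se = se,
              base = mean(score_fun(background)),
              base_mc = base_draws_mean, sum_se = sum_se,
              score = score,
              feature_order = colnames(x)[order(-imp)],
              mean_abs_impact = sort(imp, decreasing = TRUE))
  class(out) <- "semg_shap"
  out
}

#' Drop the least impactful features
#'
#' Removes the `n_drop` features with the smallest mean absolute Shapley
#' impact.  Ties at the cut are resolved by dropping the
#' lexicographically later feature names.
#'
#' @param summary a [shapley_impacts()] result.
#' @param n_drop number of features to remove.
#' @return character vector of retained feature names, in descending
#'   impact order.
#' @export
rank_and_drop <- function(summary, n_drop = 3) {
  imp <- colMeans(abs(summary$values))
  nm <- names(imp)
  if (length(nm) < n_drop + 1) stop("too few features to drop from")
  if (n_drop == 0) return(nm[order(-imp, nm)])
  # drop smallest impacts; among ties prefer dropping later names
  drop_order <- nm[order(imp, -rank(nm))]
  dropped <- drop_order[seq_len(n_drop)]
  kept <- setdiff(nm, dropped)
  kept[order(-imp[kept], kept)]
}

#' Long-form table for a Shapley summary (beeswarm) plot
#'
#' One row per subject and feature: the Shapley value and the feature
#' value, with features ordered by descending mean absolute impact.
#'
#' @param summary a [shapley_impacts()] result.
#' @param x the feature matrix that was explained.
#' @return data.frame with feature (ordered factor), subject, shapley,
#'   feature_value.
#' @export
summary_plot_data <- function(summary, x) {
  x <- as.matrix(x)
  ord <- summary$feature_order
  subj <- rownames(x)
  if (is.null(subj)) subj <- as.character(seq_len(nrow(x)))
  out <- data.frame(
    feature = factor(rep(colnames(x), each = nrow(x)), levels = ord),
    subject = rep(subj, times = ncol(x)),
    shapley = as.numeric(summary$values),
    feature_value = as.numeric(x),
    stringsAsFactors = FALSE)
  out[order(out$feature, out$subject), ]
}
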