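#' AWGS 2019 sarcopenia screening rule
#'
#' Cutoffs: low muscle mass when the skeletal muscle index is below
#' 7.0 kg/m2 (men) or 5.7 kg/m2 (women); low strength when grip strength
#' is below 28 kg (men) or 18 kg (women); low physical performance when
#' the five-times chair-stand time is 12 s or more.  A subject is
#' sarcopenic with low mass plus at least one of the other two deficits,
#' healthy with no deficit at all, and intermediate otherwise.
#' Vectorized over records.
#'
#' @param sex `"M"` or `"F"`.
#' @param grip grip strength in kg.
#' @param smi skeletal muscle index in kg/m2.
#' @param cst five-times chair sit-to-stand time in seconds.
#' @return character vector: `"healthy"`, `"sarcopenic"` or
#'   `"intermediate"`.
#' @export
awgs_screen <- function(sex, grip, smi, cst) {
  if (!all(sex %in% c("M", "F"))) {
    stop("unknown sex code: ", paste(setdiff(sex, c("M", "F")), collapse = ", "))
  }
  stopifnot(all(grip > 0), all(smi > 0), all(cst > 0))
  low_mass <- smi < ifelse(sex == "M", 7.0, 5.7)
  low_strength <- grip < ifelse(sex == "M", 28, 18)
  low_perf <- cst >= 12
  out <- rep("intermediate", length(low_mass))
  out[low_mass & (low_strength | low_perf)] <- "sarcopenic"
  out[!low_mass & !low_strength & !low_perf] <- "healthy"
  out
}

# Exact null distribution of the rank sum of group a: probability vector
# over doubled rank sums (index s+1 = doubled sum s) when n_a of the
# doubled midranks r2 are assigned to group a.
rank_sum_distribution <- function(r2, n_a) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n_a)])
  f <- matrix(0, n_a + 1, smax + 1)
  f[1, 1] <- 1
  for (r in r2) {
    kmax <- n_a
    for (k in kmax:1) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + r
        ok <- tgt <= smax + 1
        f[k + 1, tgt[ok]] <- f[k + 1, tgt[ok]] + f[k, nz[ok]]
      }
    }
  }
  p <- f[n_a + 1, ]
  p / sum(p)
}

two_sided_p <- function(cdf_le, cdf_ge) min(1, 2 * min(cdf_le, cdf_ge))

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling (number of pairs in which `a`
#' exceeds `b`, ties counting one half).  The null distribution is exact
#' (full permutation distribution of the rank sum, valid under ties) when
#' the combined sample size is at most `exact_max`; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.  Two-sided.
#'
#' @param a,b numeric samples.
#' @param exact_max combined-size crossover between the exact and the
#'   approximate branch.
#' @return object of class `semg_test`: test name, statistic, p-value,
#'   group sizes, branch used.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  u <- ra - na * (na + 1) / 2
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    dist <- rank_sum_distribution(r2, na)
    ra2 <- as.integer(round(2 * ra))
    cdf <- cumsum(dist)
    p_le <- cdf[ra2 + 1]
    p_ge <- 1 - if (ra2 >= 1) cdf[ra2] else 0
    p <- two_sided_p(p_le, p_ge)
    branch <- "exact"
  } else {
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- if (u == mu) 0 else 0.5
    z <- (u - mu - sign(u - mu) * cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    branch <- "normal"
  }
  out <- list(test = "Mann-Whitney U", statistic = u, p = p,
              n = c(na, nb), branch = branch)
  class(out) <- "semg_test"
  out
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped, midranks are taken on the absolute
#' differences, and the statistic is the positive-rank sum.  The exact
#' sign-flip distribution is used for up to `exact_max` nonzero pairs,
#' a tie-corrected normal approximation with continuity correction
#' beyond.  Two-sided.
#'
#' @param d paired differences.
#' @param exact_max crossover between the exact and the normal branch.
#' @return object of class `semg_test`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    # distribution of the doubled positive-rank sum over sign flips
    f <- numeric(sum(r2) + 1)
    f[1] <- 1
    for (rr in r2) {
      g <- numeric(length(f))
      g[(rr + 1):length(f)] <- f[seq_len(length(f) - rr)]
      f <- (f + g) / 2
    }
    w2 <- as.integer(round(2 * w))
    cdf <- cumsum(f)
    p_le <- cdf[w2 + 1]
    p_ge <- 1 - if (w2 >= 1) cdf[w2] else 0
    p <- two_sided_p(p_le, p_ge)
    branch <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- if (w == mu) 0 else 0.5
    z <- (w - mu - sign(w - mu) * cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    branch <- "normal"
  }
  out <- list(test = "Wilcoxon signed rank", statistic = w, p = p,
              n = n, branch = branch)
  class(out) <- "semg_test"
  out
}

#' @export
print.semg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s branch, n = %s)\n",
              x$test, x$statistic, x$p, x$branch,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Variance-homogeneity and normality audit
#'
#' Classic Levene test (one-way F on absolute deviations from the group
#' means) and one-sample Kolmogorov-Smirnov tests of each group against a
#' Gaussian with its own sample mean and SD.  Reported for audit only;
#' the pipeline's group comparisons are always nonparametric.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list with elements `levene`, `ks_a`, `ks_b` (each
#'   `semg_test`).
#' @export
variance_and_normality_checks <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) stop("degenerate (zero-variance) input")
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  z <- c(abs(a - mean(a)), abs(b - mean(b)))
  fit <- anova(aov(z ~ g))
  lev <- list(test = "Levene (centre = mean)",
              statistic = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
              n = c(length(a), length(b)), branch = "F")
  class(lev) <- "semg_test"
  ks1 <- function(x, lab) {
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    out <- list(test = paste("Kolmogorov-Smirnov vs fitted Gaussian,", lab),
                statistic = unname(kt$statistic), p = kt$p.value,
                n = length(x), branch = "asymptotic")
    class(out) <- "semg_test"
    out
  }
  list(levene = lev, ks_a = ks1(a, "group a"), ks_b = ks1(b, "group b"))
}

#' Group and level comparisons of all features
#'
#' For a subject-level aggregated table ("stats" mode): Mann-Whitney U
#' between groups for every (feature, level), and Wilcoxon signed-rank
#' between the two force levels within each (feature, group).  No
#' multiplicity correction by default, mirroring common reporting
#' practice; Holm adjustment is available.
#'
#' @param agg output of [aggregate_features()] in `"stats"` mode.
#' @param alpha significance level.
#' @param adjust `"none"` or `"holm"`.
#' @return data.frame with feature, comparison, test, statistic, p and a
#'   significance flag.
#' @export
feature_comparison_report <- function(agg, alpha = 0.05,
                                      adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  levels_ <- sort(unique(agg$level))
  groups <- sort(unique(agg$group))
  if (length(groups) < 2) stop("both groups must be present")
  for (g in groups) {
    if (length(unique(agg$subject[agg$group == g])) < 2) {
      stop("group ", g, " has fewer than 2 subjects")
    }
  }
  rows <- list()
  for (f in unique(agg$feature)) {
    for (lv in levels_) {
      sub <- agg[agg$feature == f & agg$level == lv, ]
      if (nrow(sub) == 0) stop("missing level ", lv, " for feature ", f)
      t <- mann_whitney_u(sub$value[sub$group == groups[1]],
                          sub$value[sub$group == groups[2]])
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, comparison = paste0("group@", lv), test = t$test,
        statistic = t$statistic, p = t$p, stringsAsFactors = FALSE)
    }
    if (length(levels_) == 2) {
      for (g in groups) {
        sub <- agg[agg$feature == f & agg$group == g, ]
        wide <- merge(sub[sub$level == levels_[1], c("subject", "value")],
                      sub[sub$level == levels_[2], c("subject", "value")],
                      by = "subject")
        t <- wilcoxon_signed_rank(wide$value.y - wide$value.x)
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, comparison = paste0("level@", g), test = t$test,
          statistic = t$statistic, p = t$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$significant <- out$p < alpha
  out
}
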