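# Independent oracles used across the suite.  Each one recomputes a
# quantity by the most transparent route available (direct summation,
# exhaustive enumeration, pairwise counting) without touching the code
# paths it checks.

# Morlet CWT by direct evaluation of the defining sum,
# C[a, b] = (1/sqrt(a)) * sum_t x[t] * psi*((t - b)/a),
# using the full (untruncated) kernel over the window support.
brute_cwt <- function(x, scales, w0 = 5) {
  L <- length(x)
  C <- matrix(0 + 0i, length(scales), L)
  u <- -(L - 1):(L - 1)
  for (s in seq_along(scales)) {
    a <- scales[s]
    kv <- Conj(exp(1i * w0 * (u / a)) * exp(-(u / a)^2 / 2)) / sqrt(a)
    # M[b, t] = k(t - b); t - b ranges over u, offset by L
    M <- matrix(kv[outer(1:L, 1:L, function(b, t) t - b + L)], L, L)
    C[s, ] <- as.vector(M %*% x)
  }
  C
}

# Two-sided Mann-Whitney p by full enumeration of group assignments.
mwu_enum <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(pooled)
  cmb <- utils::combn(n, na)
  u_all <- apply(cmb, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Two-sided Wilcoxon signed-rank p by enumeration of all sign flips.
wsr_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(w = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# AUC as the tie-averaged pairwise comparison count.
auc_pairwise <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small, fast simulation configuration for structural tests; any
# argument of simulation_config() may be overridden.
tiny_config <- function(...) {
  args <- list(n_healthy = 2, n_sarcopenic = 2, n_channels = 2,
               trial_duration = 3, mvc_duration = 3, mu_count_mean = 40)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

# Gaussian blob data for classifier tests.
blob_data <- function(n_per_class, f = 4, shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * f), n, f,
              dimnames = list(NULL, paste0("F", seq_len(f))))
  y <- rep(0:1, each = n_per_class)
  x[y == 1, 1] <- x[y == 1, 1] + shift
  x[y == 1, 2] <- x[y == 1, 2] - shift / 2
  list(x = x, y = y)
}

fast_spec <- function() {
  ensemble_spec(svm_cost = 1, rf_depth = c(3, 0), gbm_eta = 0.1,
                gbm_rounds = 50)
}
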