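#' Default wavelet scale set
#'
#' Sixty scales, 3.6 to 62.6 in steps of 1.  With the Morlet centre
#' frequency `w0 = 5` the pseudo-frequency of scale `a` is
#' `f = w0 * fs / (2 * pi * a)`, so at 2000 Hz the set spans roughly
#' 25-440 Hz, covering the energetic part of the surface-EMG band.
#'
#' @return numeric vector of scales.
#' @export
default_scales <- function() seq(3.6, 62.6, by = 1)

# Morlet mother wavelet, psi(t) = exp(i w0 t) exp(-t^2 / 2).
morlet <- function(t, w0 = 5) exp(1i * w0 * t) * exp(-t^2 / 2)

# Cache of kernel spectra keyed by (scales, L, w0).  Each entry holds the
# FFTs of the reversed, circularly wrapped kernels g(u) = psi*(u/a)/sqrt(a)
# truncated at |u| <= 6*max(scale), plus the FFT length.
.kern_cache <- new.env(parent = emptyenv())

morlet_kernels <- function(scales, L, w0 = 5, h_factor = 6) {
  key <- paste0(L, "|", w0, "|", h_factor, "|",
                paste(scales, collapse = ","))
  hit <- .kern_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- ceiling(h_factor * max(scales))
  nfft <- 2^ceiling(log2(L + 2 * h + 1))
  K <- matrix(0 + 0i, nfft, length(scales))
  v <- -h:h
  pos <- (v %% nfft) + 1L
  for (s in seq_along(scales)) {
    a <- scales[s]
    g <- Conj(morlet(-v / a, w0)) / sqrt(a)   # g(-v) placed at position v
    vec <- complex(nfft)
    vec[pos] <- g
    K[, s] <- fft(vec)
  }
  out <- list(kernfft = K, nfft = nfft, h = h, scales = scales, w0 = w0)
  .kern_cache[[key]] <- out
  out
}

#' Continuous wavelet transform of one analysis window
#'
#' Morlet CWT evaluated by discrete convolution:
#' `C[a, b] = (1 / sqrt(a)) * sum_t x[t] * psi*((t - b) / a)` with the
#' signal taken as zero outside the window.  Scales are expressed in
#' samples; `fs` is carried along for the scale-to-frequency mapping.
#'
#' @param x numeric window (length >= 2).
#' @param scales strictly increasing positive scales.
#' @param w0 Morlet centre frequency.
#' @param fs sampling rate in Hz.
#' @return object of class `semg_cwt`: complex coefficient matrix
#'   (scales x samples), the scale set, `w0`, `fs` and the pseudo-
#'   frequencies of the scales.
#' @export
cwt <- function(x, scales = default_scales(), w0 = 5, fs = 2000) {
  if (length(x) < 2) stop("window must contain at least 2 samples")
  if (any(scales <= 0)) stop("scales must be positive")
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing")
  }
  kern <- morlet_kernels(scales, length(x), w0)
  C <- cpp_cwt_window(as.numeric(x), kern$kernfft)
  out <- list(coef = C, scales = scales, w0 = w0, fs = fs,
              freqs = w0 * fs / (2 * pi * scales))
  class(out) <- "semg_cwt"
  out
}

coef_matrix <- function(C) {
  if (inherits(C, "semg_cwt")) C$coef else as.matrix(C)
}

#' Per-scale wavelet power
#'
#' `power[a] = mean_b |C[a, b]|^2` (mean over the sampling points).
#'
#' @param C a [cwt()] result or a coefficient matrix (scales x samples).
#' @return numeric vector, one value per scale.
#' @export
scale_power <- function(C) {
  M <- coef_matrix(C)
  rowMeans(Mod(M)^2)
}

#' Mean wavelet power
#'
#' Per-scale power averaged over the scale set.
#'
#' @inheritParams scale_power
#' @return scalar.
#' @export
cwt_power <- function(C) mean(scale_power(C))

#' Wavelet entropy
#'
#' Shannon entropy (natural log) of the per-scale power distribution
#' `h[a] = power[a] / sum(power)`; scales with zero power contribute
#' nothing.  Bounded by `log(n_scales)`, attained for uniform power.
#'
#' @param C a [cwt()] result, a coefficient matrix, or a numeric vector of
#'   per-scale powers.
#' @return scalar entropy in nats.
#' @export
wavelet_entropy <- function(C) {
  p <- if (is.numeric(C) && is.null(dim(C))) C else scale_power(C)
  if (any(p < 0)) stop("negative power")
  tot <- sum(p)
  if (tot <= 0) stop("all-zero wavelet power: entropy undefined")
  h <- p / tot
  h <- h[h > 0]
  -sum(h * log(h))
}

#' Bias-corrected sample excess kurtosis
#'
#' The G2 estimator:
#' `m(m+1)/((m-1)(m-2)(m-3)) * sum(((x - mean)/s)^4) - 3(m-1)^2/((m-2)(m-3))`
#' with `s` the sample standard deviation.
#'
#' @param x numeric vector, length >= 4.
#' @return scalar excess kurtosis.
#' @export
sample_excess_kurtosis <- function(x) {
  m <- length(x)
  if (m < 4) stop("need at least 4 values")
  s <- sd(x)
  if (s == 0) stop("degenerate input: zero spread (S = 0)")
  m * (m + 1) / ((m - 1) * (m - 2) * (m - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (m - 1)^2 / ((m - 2) * (m - 3))
}

# Gaussian-kernel density on an m-point equispaced grid spanning the data
# range; linear binning, Scott's-rule bandwidth.  Mirrors the compiled
# batch path.
kde_grid_pdf <- function(v, m = 100) {
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("degenerate input: zero spread (S = 0)")
  n <- length(v)
  delta <- (hi - lo) / (m - 1)
  bw <- sd(v) * n^(-1 / 5)
  pos <- (v - lo) / delta
  j <- pmin(floor(pos), m - 1)
  w <- pos - j
  cnt <- numeric(m)
  add <- tapply(c(1 - w, w[j < m - 1]),
                c(j + 1, (j + 2)[j < m - 1]), sum)
  cnt[as.integer(names(add))] <- add
  phi <- dnorm((0:(m - 1)) * delta, 0, bw)
  P <- phi[abs(outer(seq_len(m), seq_len(m), `-`)) + 1]
  dim(P) <- c(m, m)
  as.numeric(P %*% cnt) / n
}

#' Kurtosis of the wavelet-coefficient density
#'
#' Pools the coefficient moduli over all scales and times, estimates their
#' probability density with a Gaussian kernel on `m` equally spaced grid
#' points spanning the pooled range (Scott's-rule bandwidth), and returns
#' the bias-corrected excess kurtosis of the `m` density ordinates.
#'
#' @inheritParams scale_power
#' @param m number of density evaluation points.
#' @return scalar excess kurtosis of the density ordinates.
#' @export
cwt_kurtosis <- function(C, m = 100) {
  v <- as.numeric(Mod(coef_matrix(C)))
  sample_excess_kurtosis(kde_grid_pdf(v, m))
}
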