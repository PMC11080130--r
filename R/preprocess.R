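#' Filter specification
#'
#' Mains-interference notch filters at integer multiples of the base
#' frequency plus a Butterworth band-pass.  Only harmonics strictly below
#' the upper band edge are notched.
#'
#' @param notch_base mains base frequency in Hz.
#' @param notch_q quality factor of each second-order notch; the default
#'   (30) is narrow enough to spare the surrounding EMG band.
#' @param band band-pass corner frequencies in Hz.
#' @param order Butterworth band-pass order.
#' @return an object of class `semg_filter_spec`.
#' @export
filter_spec <- function(notch_base = 50, notch_q = 30,
                        band = c(10, 500), order = 3) {
  stopifnot(band[1] > 0, band[1] < band[2], order >= 1, notch_q > 0)
  out <- list(notch_base = notch_base, notch_q = notch_q,
              band = band, order = order)
  class(out) <- "semg_filter_spec"
  out
}

# Second-order IIR notch (biquad) at f0 with quality factor Q.
iir_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering: odd-reflection padding of three filter lengths,
# forward pass, time reversal, second pass, trim.
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- cpp_iir_filter(b, a, ext)
  y <- rev(cpp_iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Apply notch and band-pass filters to a recording
#'
#' Removes the DC component, notches every mains harmonic strictly below
#' the upper band-pass corner and applies the Butterworth band-pass.  All
#' stages run forward-backward (zero phase), so waveform-shape features
#' downstream are not biased by phase distortion.
#'
#' @param rec a `semg_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered recording (same shape).
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  sig <- rec$samples
  bad <- !apply(is.finite(sig), 1, all)
  if (any(bad)) {
    stop("non-finite samples in channel(s): ",
         paste(rec$channels[bad], collapse = ", "))
  }
  fs <- rec$fs
  stopifnot(spec$band[2] < fs / 2)
  harmonics <- seq(spec$notch_base, spec$band[2] - 1e-9, by = spec$notch_base)
  harmonics <- harmonics[harmonics < spec$band[2]]
  notches <- lapply(harmonics, iir_notch, fs = fs, Q = spec$notch_q)
  bp <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
  for (c in seq_len(nrow(sig))) {
    x <- sig[c, ] - mean(sig[c, ])
    for (nf in notches) x <- filtfilt_reflect(nf$b, nf$a, x)
    x <- filtfilt_reflect(bp$b, bp$a, x)
    sig[c, ] <- x
  }
  rec$samples <- sig
  rec$filtered <- TRUE
  rec
}

#' Select the stationary analysis segment
#'
#' Deterministic surrogate for visual stationarity inspection: among all
#' contiguous slices of the requested duration, returns the one minimizing
#' the variance of the 250-ms moving-RMS envelope, summed over channels.
#' Exact ties resolve to the earliest start.
#'
#' @param rec a `semg_recording`.
#' @param duration segment length in seconds.
#' @return the sliced recording; the chosen sample range is stored in
#'   attribute `"segment"`.
#' @export
select_segment <- function(rec, duration = 3) {
  fs <- rec$fs
  ls <- as.integer(round(duration * fs))
  n <- ncol(rec$samples)
  if (n < ls) stop("trial shorter than the requested segment")
  if (n == ls) {
    attr(rec, "segment") <- c(1L, n)
    return(rec)
  }
  w <- max(1L, round(0.25 * fs))
  n_start <- n - ls + 1L
  crit <- numeric(n_start)
  for (c in seq_len(nrow(rec$samples))) {
    x2 <- rec$samples[c, ]^2
    cs <- c(0, cumsum(x2))
    # trailing moving-mean power, envelope = sqrt
    idx <- w:n
    env <- sqrt((cs[idx + 1L] - cs[idx - w + 1L]) / w)
    # variance of env over each candidate slice of the envelope
    m <- length(env)
    lw <- ls - w + 1L                       # envelope samples per slice
    e1 <- c(0, cumsum(env))
    e2 <- c(0, cumsum(env^2))
    st <- seq_len(m - lw + 1L)
    s1 <- e1[st + lw] - e1[st]
    s2 <- e2[st + lw] - e2[st]
    v <- (s2 - s1^2 / lw) / (lw - 1)
    crit <- crit + v[seq_len(min(length(v), n_start))]
  }
  best <- which.min(crit)
  rec$samples <- rec$samples[, best:(best + ls - 1L), drop = FALSE]
  attr(rec, "segment") <- c(best, best + ls - 1L)
  rec
}

#' Cut a segment into overlapping analysis windows
#'
#' 200-ms windows advanced by 50 ms (150 ms overlap); the window count is
#' `floor((segment_len - window_len) / step) + 1` and no sample beyond the
#' segment end is used.
#'
#' @param segment a `semg_recording` (typically from [select_segment()]).
#' @param window_s,step_s window length and increment in seconds.
#' @return a list with one element per channel, each of class
#'   `semg_windows`: the trial/channel identifiers, window length, step,
#'   and a windows-by-samples matrix.
#' @export
make_windows <- function(segment, window_s = 0.2, step_s = 0.05) {
  fs <- segment$fs
  wl <- round(window_s * fs)
  st <- round(step_s * fs)
  n <- ncol(segment$samples)
  if (n < wl) stop("segment shorter than one analysis window")
  nw <- floor((n - wl) / st) + 1L
  starts <- (seq_len(nw) - 1L) * st
  idx <- outer(starts, seq_len(wl), `+`)
  out <- lapply(seq_len(nrow(segment$samples)), function(c) {
    W <- matrix(segment$samples[c, ][idx], nrow = nw, ncol = wl)
    wm <- list(trial = segment$trial, channel = segment$channels[c],
               window_len = wl, step = st, starts = starts, windows = W)
    class(wm) <- "semg_windows"
    wm
  })
  names(out) <- segment$channels
  out
}
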