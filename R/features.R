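feature_names <- c("RMS", "MAV", "iEMG", "WL", "ZC", "SSC",
                   "CWT_power", "WE", "CWT_kurtosis")

#' Hudgins time-domain features of one window
#'
#' Root mean square, mean absolute value, integrated EMG, waveform length,
#' zero crossings and slope sign changes.  A zero crossing is counted when
#' consecutive samples change sign and both flanking amplitudes exceed the
#' dead-band threshold; a slope sign change when
#' `(x[k] - x[k-1]) * (x[k] - x[k+1]) > 0` with both slopes exceeding the
#' threshold.
#'
#' @param x numeric window.
#' @param threshold dead-band amplitude for ZC/SSC (default 0; for noisy
#'   signals a small fraction of the window RMS is typical).
#' @return named numeric vector: RMS, MAV, iEMG, WL, ZC, SSC.
#' @export
td_features <- function(x, threshold = 0) {
  if (length(x) == 0) stop("empty window")
  td_features_matrix(matrix(x, nrow = 1), threshold)[1, ]
}

# Vectorized over windows (rows of W); threshold recycled per window.
td_features_matrix <- function(W, threshold = 0) {
  L <- ncol(W)
  rms <- sqrt(rowMeans(W^2))
  mav <- rowMeans(abs(W))
  iemg <- rowSums(abs(W))
  A <- W[, -L, drop = FALSE]
  B <- W[, -1, drop = FALSE]
  D <- B - A
  wl <- rowSums(abs(D))
  thr <- rep_len(threshold, nrow(W))
  zc <- rowSums(A * B < 0 & abs(A) > thr & abs(B) > thr)
  if (L >= 3) {
    D1 <- D[, -(L - 1), drop = FALSE]
    D2 <- D[, -1, drop = FALSE]
    ssc <- rowSums(D1 * D2 < 0 & abs(D1) > thr & abs(D2) > thr)
  } else {
    ssc <- numeric(nrow(W))
  }
  cbind(RMS = rms, MAV = mav, iEMG = iemg, WL = wl, ZC = zc, SSC = ssc)
}

#' All nine features for a window matrix
#'
#' Computes the Hudgins time-domain set plus the three wavelet-domain
#' features (mean wavelet power, wavelet entropy, coefficient-density
#' kurtosis) for every window of a [make_windows()] channel.
#'
#' @param wm an `semg_windows` object or a windows-by-samples matrix.
#' @param scales wavelet scales (samples).
#' @param w0 Morlet centre frequency.
#' @param m density grid size for the kurtosis feature.
#' @param zc_ssc_frac ZC/SSC dead band as a fraction of each window's RMS.
#' @return matrix windows x 9 named features.
#' @export
window_features <- function(wm, scales = default_scales(), w0 = 5,
                            m = 100, zc_ssc_frac = 0.01) {
  W <- if (inherits(wm, "semg_windows")) wm$windows else as.matrix(wm)
  td <- td_features_matrix(W, threshold = zc_ssc_frac * sqrt(rowMeans(W^2)))
  # kernel truncation at 4.5 scale units (amplitude error < 5e-5
  # relative) keeps the FFT length at the next power of two above the
  # window length for the default scale set
  kern <- morlet_kernels(scales, ncol(W), w0, h_factor = 4.5)
  cw <- cpp_cwt_features(t(W), kern$kernfft, as.integer(m))
  cbind(td,
        CWT_power = colMeans(cw$power),
        WE = as.numeric(cw$we),
        CWT_kurtosis = as.numeric(cw$kurtosis))
}

# Window-level features for one subject: filter, segment, window, extract.
# Returns a long data.frame (subject, group, sex, level, channel, trial,
# window, feature, raw).
subject_features <- function(subject, fspec = filter_spec(),
                             scales = default_scales(), w0 = 5, m = 100,
                             zc_ssc_frac = 0.01, segment_s = 3) {
  pieces <- vector("list", length(subject$trials) * 8L)
  k <- 0L
  for (rec in subject$trials) {
    seg <- select_segment(apply_filters(rec, fspec), segment_s)
    wnd <- make_windows(seg)
    for (ch in names(wnd)) {
      F <- window_features(wnd[[ch]], scales, w0, m, zc_ssc_frac)
      nw <- nrow(F)
      k <- k + 1L
      pieces[[k]] <- data.frame(
        subject = subject$id, group = subject$group, sex = subject$sex,
        level = rec$level, channel = ch, trial = rec$trial,
        window = rep(seq_len(nw), times = ncol(F)),
        feature = rep(colnames(F), each = nw),
        raw = as.numeric(F), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pieces[seq_len(k)])
}

#' Window-level feature table for a study
#'
#' Runs preprocessing (zero-phase filtering, stationary 3-s segment
#' selection, 200-ms/50-ms windowing) and nine-feature extraction on every
#' trial and channel of every subject.
#'
#' @param study a [simulate_study()] result (or any list with a
#'   `subjects` element of the same shape).
#' @param fspec a [filter_spec()].
#' @inheritParams window_features
#' @param segment_s analysis segment length in seconds.
#' @return long data.frame with columns subject, group, sex, level,
#'   channel, trial, window, feature, raw.
#' @export
extract_features <- function(study, fspec = filter_spec(),
                             scales = default_scales(), w0 = 5, m = 100,
                             zc_ssc_frac = 0.01, segment_s = 3) {
  tabs <- lapply(study$subjects, subject_features, fspec = fspec,
                 scales = scales, w0 = w0, m = m,
                 zc_ssc_frac = zc_ssc_frac, segment_s = segment_s)
  data.table::setDF(data.table::rbindlist(tabs))
}

#' MVC-normalize a feature table
#'
#' Divides every raw feature value by the subject's MVC reference for the
#' same channel and feature: the mean over the MVC trials of each trial's
#' mean feature value.
#'
#' @param table window-level feature table (sub-maximal rows, or a mixed
#'   table whose `level == "MVC"` rows supply the references when
#'   `mvc_table` is `NULL`).
#' @param mvc_table optional separate table of MVC rows.
#' @return the sub-maximal rows of `table` with a `normalized` column.
#' @export
mvc_normalize <- function(table, mvc_table = NULL) {
  if (is.null(mvc_table)) {
    mvc_table <- table[table$level == "MVC", , drop = FALSE]
    table <- table[table$level != "MVC", , drop = FALSE]
  }
  if (nrow(mvc_table) == 0) stop("no MVC rows to normalize against")
  mt <- data.table::as.data.table(mvc_table)
  trial_means <- mt[, list(v = mean(raw)),
                    by = c("subject", "channel", "feature", "trial")]
  ref <- trial_means[, list(mvc_ref = mean(v)),
                     by = c("subject", "channel", "feature")]
  dt <- data.table::as.data.table(table)
  dt <- merge(dt, ref, by = c("subject", "channel", "feature"),
              all.x = TRUE, sort = FALSE)
  bad <- is.na(dt$mvc_ref) | dt$mvc_ref == 0
  if (any(bad)) {
    b <- dt[which(bad)[1], ]
    stop(sprintf("missing or zero MVC reference for subject %s, channel %s, feature %s",
                 b$subject, b$channel, b$feature))
  }
  dt[, "normalized" := dt$raw / dt$mvc_ref]
  dt[, "mvc_ref" := NULL]
  data.table::setDF(dt)
}

#' Aggregate window-level features to the subject level
#'
#' Two aggregation modes: `"stats"` averages the normalized values over
#' all channels, trials and windows (one record per subject, level and
#' feature, matching how the group statistics are run); `"classify"`
#' first averages over windows and trials within each requested channel,
#' then averages over the channel set.
#'
#' @param table normalized feature table from [mvc_normalize()].
#' @param mode `"stats"` or `"classify"`.
#' @param channels channel labels (or indices into [semg_channels]) used
#'   in `"classify"` mode.
#' @param value which column to aggregate.
#' @return data.frame with subject, group, level, feature, value.
#' @export
aggregate_features <- function(table, mode = c("stats", "classify"),
                               channels = NULL, value = "normalized") {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(table)
  dt[, "v" := dt[[value]]]
  if (mode == "classify") {
    if (is.null(channels) || length(channels) == 0) {
      stop("classify mode needs a non-empty channel set")
    }
    if (is.numeric(channels)) channels <- semg_channels[channels]
    dt <- dt[dt$channel %in% channels, ]
    if (nrow(dt) == 0) stop("no rows for the requested channels")
    per_ch <- dt[, list(v = mean(v)),
                 by = c("subject", "group", "level", "feature", "channel")]
    out <- per_ch[, list(value = mean(v)),
                  by = c("subject", "group", "level", "feature")]
  } else {
    out <- dt[, list(value = mean(v)),
              by = c("subject", "group", "level", "feature")]
  }
  data.table::setDF(out[order(out$subject, out$level, out$feature), ])
}

#' Subject-by-feature matrix for classification
#'
#' Pivots an aggregated (`"classify"` mode) table into one row per subject
#' with `feature@level` columns in a fixed order, optionally dropping a
#' feature list, plus the 0/1 class labels (sarcopenic = 1).
#'
#' @param agg output of [aggregate_features()] in classify mode.
#' @param drop character vector of `feature@level` names to remove.
#' @return list with `x` (numeric matrix), `y` (0/1 integer vector) and
#'   `subjects`.
#' @export
subject_feature_matrix <- function(agg, drop = character(0)) {
  agg$key <- paste0(agg$feature, "@", agg$level)
  levs <- sort(unique(agg$level))
  keys <- as.vector(outer(feature_names, levs, paste, sep = "@"))
  keys <- keys[keys %in% unique(agg$key)]
  keys <- setdiff(keys, drop)
  subjects <- unique(agg$subject)
  x <- matrix(NA_real_, length(subjects), length(keys),
              dimnames = list(subjects, keys))
  for (k in keys) {
    sub <- agg[agg$key == k, ]
    x[sub$subject, k] <- sub$value
  }
  if (anyNA(x)) stop("missing feature entries after pivot")
  grp <- agg$group[match(subjects, agg$subject)]
  list(x = x, y = as.integer(grp == "sarcopenic"), subjects = subjects)
}
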