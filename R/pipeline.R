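#' Run the full screening pipeline on a simulated study
#'
#' Streams subject by subject to keep memory flat: simulate the subject's
#' recordings, filter, select the stationary segment, cut windows,
#' extract the nine features, MVC-normalize, and aggregate.  Afterwards
#' runs the nonparametric group comparisons and the voting classifier
#' under balanced subject-level cross-validation.
#'
#' The default classifier input mirrors the screening protocol: the mean
#' of channels 2-3 (FCR, FDS), nine features at the two force levels,
#' minus the three least informative entries (wavelet power and wavelet
#' entropy at 20% MVC, slope sign changes at 50% MVC), leaving 15
#' entries per subject.
#'
#' @param config a [simulation_config()].
#' @param channels channel indices (or labels) aggregated for the
#'   classifier.
#' @param drop `feature@level` entries removed from the classifier input.
#' @param spec an [ensemble_spec()].
#' @param k outer cross-validation folds.
#' @param cv_seed seed for fold making and member fitting.
#' @param fspec a [filter_spec()].
#' @param verbose print a progress line per subject.
#' @return list with `stats_table` (subject-level, all channels),
#'   `classify_table`, `vectors` (`x`, `y`, `subjects`), `comparisons`
#'   (the statistical report) and `cv` (the cross-validation report).
#' @export
run_screening_pipeline <- function(config,
                                   channels = c(2, 3),
                                   drop = c("CWT_power@0.2", "WE@0.2",
                                            "SSC@0.5"),
                                   spec = ensemble_spec(), k = 5,
                                   cv_seed = config$seed,
                                   fspec = filter_spec(),
                                   verbose = FALSE) {
  seeds <- subject_seeds(config)
  groups <- c(rep("healthy", config$n_healthy),
              rep("sarcopenic", config$n_sarcopenic))
  ids <- sprintf("S%03d", seq_along(groups))
  stats_rows <- vector("list", length(ids))
  cls_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    subj <- generate_subject(config, groups[i], ids[i], seeds[i])
    tab <- subject_features(subj, fspec = fspec)
    norm <- mvc_normalize(tab)
    stats_rows[[i]] <- aggregate_features(norm, "stats")
    cls_rows[[i]] <- aggregate_features(norm, "classify",
                                        channels = channels)
    if (verbose) message("processed ", ids[i], " (", groups[i], ")")
  }
  stats_table <- data.table::setDF(data.table::rbindlist(stats_rows))
  classify_table <- data.table::setDF(data.table::rbindlist(cls_rows))
  vectors <- subject_feature_matrix(classify_table, drop = drop)
  comparisons <- feature_comparison_report(stats_table)
  cv <- cross_validate(vectors$x, vectors$y, spec = spec, k = k,
                       seed = cv_seed)
  list(stats_table = stats_table, classify_table = classify_table,
       vectors = vectors, comparisons = comparisons, cv = cv)
}
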