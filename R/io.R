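#' Write a simulated study to disk
#'
#' One delimited text file per trial (header row of channel labels, one
#' row per sample) plus a `manifest.dcf` with per-subject metadata (sex,
#' group, AWGS measurements) and per-trial paths, level tags and sampling
#' rate.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- list()
  for (s in study$subjects) {
    paths <- character(length(s$trials))
    levels_ <- character(length(s$trials))
    for (i in seq_along(s$trials)) {
      rec <- s$trials[[i]]
      fn <- sprintf("%s_trial%02d.csv", s$id, rec$trial)
      df <- as.data.frame(t(rec$samples))
      names(df) <- rec$channels
      utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
      paths[i] <- fn
      levels_[i] <- rec$level
    }
    records[[length(records) + 1]] <- c(
      subject = s$id, group = s$group, sex = s$sex,
      grip = format(s$awgs$grip), smi = format(s$awgs$smi),
      cst = format(s$awgs$cst),
      fs = format(study$config$fs),
      trials = paste(paths, collapse = " "),
      levels = paste(levels_, collapse = " "))
  }
  manifest <- file.path(dir, "manifest.dcf")
  write.dcf(do.call(rbind, records), manifest)
  invisible(manifest)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing `manifest.dcf` and the trial files.
#' @return an object of class `semg_study` (without a simulation
#'   configuration).
#' @export
read_study <- function(dir) {
  man <- read.dcf(file.path(dir, "manifest.dcf"))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    fs <- as.numeric(row[["fs"]])
    paths <- strsplit(row[["trials"]], " ")[[1]]
    levels_ <- strsplit(row[["levels"]], " ")[[1]]
    trials <- lapply(seq_along(paths), function(j) {
      df <- utils::read.csv(file.path(dir, paths[j]), check.names = FALSE)
      sig <- t(as.matrix(df))
      rec <- list(subject = row[["subject"]], trial = j,
                  level = levels_[j], channels = names(df), fs = fs,
                  samples = sig)
      class(rec) <- "semg_recording"
      rec
    })
    list(id = row[["subject"]], group = row[["group"]], sex = row[["sex"]],
         awgs = list(sex = row[["sex"]], grip = as.numeric(row[["grip"]]),
                     smi = as.numeric(row[["smi"]]),
                     cst = as.numeric(row[["cst"]])),
         trials = trials)
  })
  study <- list(subjects = subjects, config = NULL)
  class(study) <- "semg_study"
  study
}

#' Write / read a feature table
#'
#' Tab-separated long-form table with one row per (subject, level,
#' channel, trial, window, feature).
#'
#' @param table a feature table data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(level = "character"))
}
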