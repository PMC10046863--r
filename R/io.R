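# Plain-text readers and writers for the pipeline's external formats: ROI
# time series and event tables as TSV, selection reports as JSON, tensors
# and model bundles as RDS (documented array containers at run time).

#' Write / read an ROI time-series matrix as TSV
#'
#' First column `time` (volume index, 1-based), remaining columns one per
#' ROI with the ROI labels as header.
#'
#' @param Y A [roi_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(Y, path) {
  stopifnot(inherits(Y, "roi_matrix"))
  df <- data.frame(time = seq_len(nrow(Y$data)), Y$data, check.names = FALSE)
  names(df) <- c("time", Y$roi_labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @param TR Repetition time to attach on reading.
#' @export
read_roi_tsv <- function(path, TR = NA_real_) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("expected first column 'time'")
  roi_matrix(as.matrix(df[, -1, drop = FALSE]),
             roi_labels = names(df)[-1], TR = TR)
}

#' Write / read a stimulus event table as TSV
#'
#' Columns `onset` (s), `duration` (s), `condition` (win/lose), one row per
#' feedback event.
#'
#' @param stim A [generate_stimulus_timecourse()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_timecourse"))
  trial_len <- sum(stim$schedule)
  fb_off <- cumsum(c(0, stim$schedule))[match("feedback", names(stim$schedule))]
  df <- data.frame(
    onset = (seq_len(stim$n_trials) - 1) * trial_len + fb_off,
    duration = stim$schedule[["feedback"]],
    condition = ifelse(stim$wins, "win", "lose")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(df))) stop("events TSV must have onset, duration, condition")
  df
}

#' Reconstruct a binary stimulus vector from an event table
#'
#' Marks every volume whose acquisition window `[t, t + TR)` overlaps an
#' event of the matching condition.
#'
#' @param events data.frame from [read_events_tsv()].
#' @param n_volumes Number of volumes; @param TR Repetition time (s).
#' @param condition `"win"`, `"lose"` or `"both"`.
#' @return Binary integer vector of length `n_volumes`.
#' @export
events_to_timecourse <- function(events, n_volumes, TR,
                                 condition = c("both", "win", "lose")) {
  condition <- match.arg(condition)
  keep <- if (condition == "both") rep(TRUE, nrow(events)) else events$condition == condition
  values <- integer(n_volumes)
  for (i in which(keep)) {
    a <- events$onset[i]; b <- a + events$duration[i]
    v <- which(seq_len(n_volumes) * TR > a & (seq_len(n_volumes) - 1) * TR < b)
    values[v] <- 1L
  }
  values
}

#' Export the signature tables of a fitted model
#'
#' One TSV per component per mode (temporal, spectral, channel, ROI), each
#' with columns `index` and `value` — `4 * R` files in total.
#'
#' @param model A [cmtf_model()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Character vector of the `4 * R` paths, invisibly.
#' @export
write_signature_tsvs <- function(model, dir, prefix = "component") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    temporal = model$S, spectral = model$F,
    channel = model$C, roi = model$V
  )
  paths <- character(0)
  for (r in seq_len(model$R)) {
    for (nm in names(tabs)) {
      M <- tabs[[nm]]
      p <- file.path(dir, sprintf("%s%02d_%s.tsv", prefix, r, nm))
      utils::write.table(
        data.frame(index = seq_len(nrow(M)), value = M[, r]), p,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
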