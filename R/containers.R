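#' EEG spectral-power tensor container
#'
#' Third-order nonnegative array of multitaper band power, time segments x
#' frequency bins x channels, synchronized with the fMRI volume clock.
#'
#' @param data 3-d array (segments x frequency bins x channels).
#' @param freq_bin_edges Increasing vector of bin edges in Hz; bins are
#'   half-open `[left, right)`. Length must be `dim(data)[2] + 1`.
#' @param channel_labels Character vector of channel identifiers.
#' @param fs EEG sampling rate in Hz.
#' @param TR fMRI repetition time (= segment length) in seconds.
#' @return Object of class `eeg_tensor`.
#' @export
eeg_tensor <- function(data, freq_bin_edges, channel_labels = NULL,
                       fs = NA_real_, TR = NA_real_) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be a 3-d array")
  if (length(freq_bin_edges) != d[2] + 1L) {
    stop("freq_bin_edges must have one more entry than frequency bins")
  }
  if (any(diff(freq_bin_edges) <= 0)) stop("freq_bin_edges must be strictly increasing")
  if (is.null(channel_labels)) channel_labels <- sprintf("E%02d", seq_len(d[3]))
  if (length(channel_labels) != d[3]) stop("one label per channel required")
  structure(
    list(data = data, freq_bin_edges = as.numeric(freq_bin_edges),
         channel_labels = channel_labels, fs = fs, TR = TR),
    class = "eeg_tensor"
  )
}

#' @export
print.eeg_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_tensor> %d segments x %d bins [%g, %g) Hz x %d channels (fs = %g Hz, TR = %g s)\n",
    d[1], d[2], min(x$freq_bin_edges), max(x$freq_bin_edges), d[3], x$fs, x$TR
  ))
  invisible(x)
}

#' Default frequency-bin edges: 0.5 Hz bins covering [1, 30) Hz
#'
#' @param fmin,fmax Range in Hz.
#' @param width Bin width in Hz.
#' @return Numeric vector of bin edges (58 bins for the defaults).
#' @export
default_freq_edges <- function(fmin = 1, fmax = 30, width = 0.5) {
  seq(fmin, fmax, by = width)
}

#' fMRI ROI time-series matrix container
#'
#' BOLD time series averaged per region of interest, time points x ROIs.
#'
#' @param data Numeric matrix (time points x ROIs); finite entries.
#' @param roi_labels Character vector of ROI names (AAL-style).
#' @param TR Repetition time in seconds.
#' @return Object of class `roi_matrix`.
#' @export
roi_matrix <- function(data, roi_labels = NULL, TR = NA_real_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("ROI matrix entries must be finite")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(data)))
  if (length(roi_labels) != ncol(data)) stop("one label per ROI required")
  structure(
    list(data = data, roi_labels = roi_labels, TR = TR),
    class = "roi_matrix"
  )
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %d time points x %d ROIs (TR = %g s)\n",
              nrow(x$data), ncol(x$data), x$TR))
  invisible(x)
}

# Coerce tensor-or-array input to the bare array.
tensor_data <- function(X) {
  if (inherits(X, "eeg_tensor")) X$data else X
}

matrix_data <- function(Y) {
  if (inherits(Y, "roi_matrix")) Y$data else Y
}
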