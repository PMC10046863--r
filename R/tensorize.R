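# EEG tensorization: segment the recording per fMRI volume, estimate each
# segment's power spectrum with Thomson's multitaper method, and average the
# squared Fourier amplitudes into half-open frequency bins, yielding the
# third-order tensor (segments x frequency bins x channels).

#' Segment a multichannel EEG recording per fMRI volume
#'
#' Cuts `n_volumes` consecutive, non-overlapping segments of `fs * TR`
#' samples each, starting at sample 1 (the first volume marker).
#'
#' @param raw Numeric matrix (samples x channels) or vector (one channel).
#' @param fs Sampling rate in Hz; `fs * TR` must be an integer.
#' @param TR Segment length in seconds.
#' @param n_volumes Number of segments to cut.
#' @return List of `n_volumes` matrices (`fs * TR` samples x channels).
#' @export
segment_eeg <- function(raw, fs, TR, n_volumes) {
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1)
  nseg <- fs * TR
  if (abs(nseg - round(nseg)) > 1e-9) stop("fs * TR must be an integer number of samples")
  nseg <- as.integer(round(nseg))
  need <- n_volumes * nseg
  if (nrow(raw) < need) {
    stop(sprintf("length error: %d samples available, %d required", nrow(raw), need))
  }
  lapply(seq_len(n_volumes), function(i) {
    raw[((i - 1L) * nseg + 1L):(i * nseg), , drop = FALSE]
  })
}

#' Discrete prolate spheroidal sequences (DPSS / Slepian tapers)
#'
#' Computes the first `n_tapers` DPSS of length `n` and time-bandwidth
#' product `NW` via the symmetric tridiagonal eigenproblem, each normalized
#' to unit energy. Sign convention: the mean of even-order tapers and the
#' first lag-weighted moment of odd-order tapers are positive.
#'
#' @param n Sequence length in samples.
#' @param NW Time-bandwidth product.
#' @param n_tapers Number of tapers (`<= 2 * NW - 1`).
#' @return `n x n_tapers` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, NW, n_tapers) {
  if (n_tapers > 2 * NW - 1) {
    stop("validation error: n_tapers must not exceed 2 * NW - 1")
  }
  if (n < 8) stop("segment too short for spectral estimation")
  W <- NW / n
  i <- seq_len(n)
  diag_main <- ((n - 1 - 2 * (i - 1)) / 2)^2 * cos(2 * pi * W)
  diag_off <- (i * (n - i) / 2)[seq_len(n - 1)]
  A <- matrix(0, n, n)
  A[cbind(i, i)] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- diag_off
  A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(n_tapers), drop = FALSE]
  for (j in seq_len(n_tapers)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v * v))
    if (j %% 2L == 1L) {             # even-order taper (0-based): positive mean
      if (sum(v) < 0) v <- -v
    } else {                          # odd-order: positive initial slope
      if (sum(v * (i - (n + 1) / 2)) < 0) v <- -v
    }
    tapers[, j] <- v
  }
  tapers
}

#' Multitaper power spectral estimate of one segment
#'
#' Thomson's estimator: the segment (mean-removed) is multiplied by each
#' DPSS taper, and the squared Fourier amplitudes are averaged across
#' tapers. The estimate is returned on the one-sided fine grid
#' `0, fs/n, ..., fs/2`.
#'
#' @param segment Numeric vector, one channel's samples.
#' @param fs Sampling rate in Hz.
#' @param NW Time-bandwidth product (default 2).
#' @param n_tapers Number of tapers (default 3, i.e. `2 * NW - 1`).
#' @param tapers Optional precomputed [dpss_tapers()] matrix (cached by
#'   callers that process many segments).
#' @param demean Remove the segment mean before tapering (default `TRUE`,
#'   prevents DC leakage into the lowest bins).
#' @return List with `freq` (Hz) and `power` (nonnegative, same length).
#' @export
multitaper_band_power <- function(segment, fs, NW = 2, n_tapers = 2 * NW - 1,
                                  tapers = NULL, demean = TRUE) {
  n <- length(segment)
  if (is.null(tapers)) tapers <- dpss_tapers(n, NW, n_tapers)
  if (nrow(tapers) != n) stop("taper length does not match segment")
  x <- if (demean) segment - mean(segment) else segment
  n_half <- floor(n / 2) + 1L
  acc <- numeric(n_half)
  for (j in seq_len(ncol(tapers))) {
    sp <- Mod(stats::fft(tapers[, j] * x))^2
    acc <- acc + sp[seq_len(n_half)]
  }
  list(freq = (seq_len(n_half) - 1) * fs / n, power = acc / ncol(tapers))
}

#' Average a fine-grid spectral estimate into frequency bins
#'
#' Bin `j` is the mean of the estimate at grid frequencies in the half-open
#' interval `[edges[j], edges[j + 1])`. Empty bins are set to 0 with a
#' warning.
#'
#' @param power Fine-grid power values.
#' @param freq Grid frequencies in Hz (same length as `power`).
#' @param edges Strictly increasing bin edges in Hz.
#' @return Numeric vector of `length(edges) - 1` binned values.
#' @export
bin_spectrum <- function(power, freq, edges) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  nb <- length(edges) - 1L
  idx <- findInterval(freq, edges, left.open = FALSE, rightmost.closed = FALSE)
  # findInterval gives j for freq in [edges[j], edges[j+1]); drop out-of-range
  keep <- idx >= 1L & idx <= nb & freq < edges[nb + 1L]
  out <- numeric(nb)
  cnt <- tabulate(idx[keep], nbins = nb)
  sums <- numeric(nb)
  if (any(keep)) {
    agg <- rowsum(power[keep], group = idx[keep])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  empty <- cnt == 0L
  out[!empty] <- sums[!empty] / cnt[!empty]
  if (any(empty)) warning(sprintf("%d empty frequency bin(s) set to 0", sum(empty)))
  out
}

#' Build the EEG spectral tensor from a raw recording
#'
#' Composes [segment_eeg()], [multitaper_band_power()] per channel and
#' [bin_spectrum()] into the tensor (volumes x bins x channels).
#'
#' @param raw Numeric matrix (samples x channels).
#' @param fs Sampling rate in Hz.
#' @param TR Segment length in seconds.
#' @param n_volumes Number of fMRI volumes (segments).
#' @param edges Frequency-bin edges in Hz (default 0.5 Hz bins on [1, 30)).
#' @param NW,n_tapers Multitaper parameters.
#' @param channel_labels Optional channel names.
#' @return An [eeg_tensor()] of shape `(n_volumes, length(edges) - 1, channels)`.
#' @export
build_eeg_tensor <- function(raw, fs, TR, n_volumes,
                             edges = default_freq_edges(),
                             NW = 2, n_tapers = 2 * NW - 1,
                             channel_labels = NULL) {
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1)
  segs <- segment_eeg(raw, fs, TR, n_volumes)
  nseg <- nrow(segs[[1]])
  nch <- ncol(raw)
  tapers <- dpss_tapers(nseg, NW, n_tapers)
  nb <- length(edges) - 1L
  X <- array(0, dim = c(n_volumes, nb, nch))
  first <- TRUE
  for (t in seq_len(n_volumes)) {
    for (ch in seq_len(nch)) {
      est <- multitaper_band_power(segs[[t]][, ch], fs, NW, n_tapers,
                                   tapers = tapers)
      X[t, , ch] <- if (first) {
        # warn (about empty bins) at most once per tensor build
        b <- bin_spectrum(est$power, est$freq, edges); first <- FALSE; b
      } else {
        suppressWarnings(bin_spectrum(est$power, est$freq, edges))
      }
    }
  }
  eeg_tensor(X, edges, channel_labels = channel_labels, fs = fs, TR = TR)
}
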