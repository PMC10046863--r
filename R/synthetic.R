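# Synthetic ground truth and forward models. The generator mirrors the
# decomposition it is meant to exercise: shared temporal signatures expressed
# in EEG as band-limited oscillatory power (trilinear tensor structure) and
# in fMRI as HRF-convolved ROI activation plus an uncoupled low-rank term.

ar1 <- function(n, phi, sd_innov = 1) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sd_innov), phi,
                           method = "recursive"))
}

#' Generate ground-truth sources for a coupled EEG-fMRI simulation
#'
#' Draws the full latent structure the coupled factorization assumes: shared
#' temporal signatures `S`, nonnegative unimodal spectral signatures `F`,
#' smooth channel topographies `C`, sparse ROI signatures `V`, near-canonical
#' HRF basis coefficients `B`, and an uncoupled fMRI term `N`, `P`. One
#' temporal signature (`stim_component_index`) tracks the stimulus
#' timecourse: the binary paradigm vector smoothed by a short three-point
#' moving average plus low-amplitude AR(1) noise. The remaining temporal
#' signatures are smooth AR(1) processes.
#'
#' @param R Number of shared sources (>= 1).
#' @param K Number of HRF basis functions (>= 1).
#' @param Q Rank of the uncoupled fMRI term (>= 0).
#' @param dims Integer vector `(Is, If, Ic, Iv)`: time segments, frequency
#'   bins, channels, ROIs.
#' @param stimulus A [generate_stimulus_timecourse()] object of length `Is`.
#' @param seed Integer seed; all draws flow from one seeded generator.
#' @param stim_component_index Which source is stimulus-driven (1-based).
#' @param roi_sparsity Fraction of ROIs with nonzero loading per source
#'   (<= 0.2).
#' @param hrf_perturb Standard deviation of the perturbation of the
#'   coefficient rows around `(1, 0, ...)`.
#' @param freq_range Range in Hz spanned by the `If` spectral bins.
#' @return Object of class `cmtf_ground_truth` with fields `S`, `F`, `C`,
#'   `V`, `B`, `N`, `P`, `stim_component_index`, `stimulus`,
#'   `freq_bin_edges`, `seed`.
#' @export
generate_ground_truth <- function(R, K, Q, dims, stimulus, seed = 1L,
                                  stim_component_index = 1L,
                                  roi_sparsity = 0.15,
                                  hrf_perturb = 0.1,
                                  freq_range = c(1, 30)) {
  if (length(dims) != 4L || any(dims <= 0) || any(dims != round(dims))) {
    stop("dims must be four positive integers (Is, If, Ic, Iv)")
  }
  Is <- dims[1]; If <- dims[2]; Ic <- dims[3]; Iv <- dims[4]
  if (R < 1 || K < 1 || Q < 0) stop("need R >= 1, K >= 1, Q >= 0")
  if (Q > 0 && Iv < Q) stop("dimension error: Iv < Q")
  if (roi_sparsity <= 0 || roi_sparsity > 0.2) {
    stop("roi_sparsity must be in (0, 0.2]")
  }
  check_stimulus(stimulus, n = Is)
  if (stim_component_index < 1 || stim_component_index > R) {
    stop("stim_component_index must lie in [1, R]")
  }

  edges <- seq(freq_range[1], freq_range[2], length.out = If + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  out <- with_seed(seed, {
    ## temporal signatures
    S <- matrix(0, Is, R)
    for (r in seq_len(R)) {
      if (r == stim_component_index) {
        x <- as.numeric(stimulus$values)
        # short weighted moving average: spike mostly preserved so the
        # signature stays close to the paradigm vector
        k <- c(0.25, 1, 0.25); k <- k / sum(k)
        pad <- c(0, x, 0)
        sm <- k[1] * pad[1:Is] + k[2] * pad[2:(Is + 1)] + k[3] * pad[3:(Is + 2)]
        s <- sm + 0.05 * ar1(Is, 0.5)
        # unit variance like every other signature: sources have comparable
        # energy, and correlation with the stimulus is scale-invariant
        S[, r] <- s / stats::sd(s)
      } else {
        s <- ar1(Is, 0.9)
        S[, r] <- s / stats::sd(s)
      }
    }

    ## spectral signatures: unimodal nonnegative bumps in distinct bands
    span <- diff(range(centers))
    ctr <- seq(freq_range[1] + 0.15 * span, freq_range[2] - 0.15 * span,
               length.out = max(R, 2))[seq_len(R)]
    ctr <- ctr + stats::runif(R, -0.02, 0.02) * span
    width <- span / (3 * max(R, 2))
    F_ <- sapply(seq_len(R), function(r) exp(-(centers - ctr[r])^2 / (2 * width^2)))
    F_ <- matrix(F_, If, R)

    ## channel topographies: smooth bumps over the channel index
    C_ <- matrix(0, Ic, R)
    idx <- seq_len(Ic)
    for (r in seq_len(R)) {
      mu <- stats::runif(1, 1, Ic)
      sig <- Ic / 4
      noise <- as.numeric(stats::filter(stats::rnorm(Ic), rep(1 / 3, 3), sides = 2))
      noise[is.na(noise)] <- 0
      C_[, r] <- exp(-(idx - mu)^2 / (2 * sig^2)) + 0.1 * noise
    }

    ## ROI signatures: sparse activation patterns
    V <- matrix(0, Iv, R)
    n_act <- max(1L, round(roi_sparsity * Iv))
    for (r in seq_len(R)) {
      idx <- sample.int(Iv, n_act)
      V[idx, r] <- 1 + 0.3 * stats::rnorm(n_act)
    }

    ## HRF coefficients near (1, 0, ..., 0): every ROI near-canonical
    B <- matrix(stats::rnorm(Iv * K, sd = hrf_perturb), Iv, K)
    B[, 1] <- B[, 1] + 1

    ## uncoupled fMRI structure
    if (Q > 0) {
      N <- sapply(seq_len(Q), function(q) { z <- ar1(Is, 0.8); z / stats::sd(z) })
      N <- matrix(N, Is, Q)
      P <- matrix(stats::rnorm(Iv * Q), Iv, Q)
    } else {
      N <- matrix(0, Is, 0)
      P <- matrix(0, Iv, 0)
    }
    list(S = S, F = F_, C = C_, V = V, B = B, N = N, P = P)
  })

  structure(
    c(out, list(stim_component_index = as.integer(stim_component_index),
                stimulus = stimulus, freq_bin_edges = edges, seed = seed)),
    class = "cmtf_ground_truth"
  )
}

#' @export
print.cmtf_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<cmtf_ground_truth> R = %d sources, K = %d HRF bases, Q = %d uncoupled; dims (Is, If, Ic, Iv) = (%d, %d, %d, %d); stimulus component %d\n",
    ncol(x$S), ncol(x$B), ncol(x$N), nrow(x$S), nrow(x$F), nrow(x$C),
    nrow(x$V), x$stim_component_index
  ))
  invisible(x)
}

# Scale white Gaussian noise to an exact SNR in dB relative to `signal`.
scaled_noise <- function(signal, snr_db) {
  if (is.infinite(snr_db)) return(array(0, dim = dim(signal) %||% length(signal)))
  z <- array(stats::rnorm(length(signal)), dim = dim(signal) %||% length(signal))
  target <- fnorm(signal) / (10^(snr_db / 20))
  z * (target / fnorm(z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize raw multichannel EEG from ground-truth sources
#'
#' For each source, emits a sum of cosines at the spectral-bin centers with
#' amplitudes following the square root of the spectral signature, scaled per
#' fMRI-volume segment by the square root of the (clipped-nonnegative)
#' temporal signature, and mixed across channels by the channel signature.
#' White noise is added at the requested SNR.
#'
#' @param gt A [generate_ground_truth()] object.
#' @param fs Sampling rate in Hz; `fs * TR` must be an integer.
#' @param TR Segment length in seconds.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param seed Integer seed.
#' @return Numeric matrix (`Is * fs * TR` samples x `Ic` channels) with
#'   attributes `fs` and `TR`.
#' @export
synthesize_raw_eeg <- function(gt, fs, TR, snr_db = Inf, seed = 1L) {
  stopifnot(inherits(gt, "cmtf_ground_truth"))
  nseg <- fs * TR
  if (abs(nseg - round(nseg)) > 1e-9) stop("fs * TR must be an integer number of samples")
  nseg <- as.integer(round(nseg))
  Is <- nrow(gt$S); Ic <- nrow(gt$C); R <- ncol(gt$S)
  n <- Is * nseg
  edges <- gt$freq_bin_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  tt <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    out <- matrix(0, n, Ic)
    for (r in seq_len(R)) {
      amp <- sqrt(pmax(gt$F[, r], 0))
      keep <- which(amp > 1e-6 * max(amp, 1e-300))
      phases <- stats::runif(length(centers), 0, 2 * pi)
      osc <- numeric(n)
      for (j in keep) {
        osc <- osc + amp[j] * cos(2 * pi * centers[j] * tt + phases[j])
      }
      env <- rep(sqrt(pmax(gt$S[, r], 0)), each = nseg)
      src <- osc * env
      out <- out + tcrossprod(src, gt$C[, r])
    }
    out <- out + scaled_noise(out, snr_db)
    attr(out, "fs") <- fs
    attr(out, "TR") <- TR
    out
  })
}

#' Assemble the noiseless-or-noisy EEG spectral tensor from ground truth
#'
#' Builds the trilinear tensor `X[t, f, c] = sum_r S[t, r] F[f, r] C[c, r]`
#' plus white noise scaled to `snr_db`.
#'
#' @param gt A [generate_ground_truth()] object.
#' @param snr_db SNR in dB (`Inf` = noiseless).
#' @param seed Integer seed for the noise draw.
#' @param nonneg If `TRUE`, clip negative entries to zero after adding noise.
#' @param fs,TR Stored as metadata on the returned tensor.
#' @return An [eeg_tensor()].
#' @export
assemble_eeg_tensor <- function(gt, snr_db = Inf, seed = 1L, nonneg = FALSE,
                                fs = NA_real_, TR = NA_real_) {
  stopifnot(inherits(gt, "cmtf_ground_truth"))
  d <- c(nrow(gt$S), nrow(gt$F), nrow(gt$C))
  Xhat <- fold(gt$S %*% t(khatri_rao(gt$C, gt$F)), 1L, d)
  X <- with_seed(seed, Xhat + scaled_noise(Xhat, snr_db))
  if (nonneg) X[X < 0] <- 0
  if (is.na(TR) && !is.null(gt$stimulus)) TR <- gt$stimulus$TR
  eeg_tensor(X, gt$freq_bin_edges, fs = fs, TR = TR)
}

#' Assemble the coupled fMRI ROI matrix from ground truth
#'
#' Forward model
#' `Y[t, v] = sum_r sum_k (H_k S[, r])[t] * B[v, k] * V[v, r] + (N P')[t, v]`
#' plus white noise scaled to `snr_db`. The convolution operators `H_k` come
#' from the HRF basis.
#'
#' @param gt A [generate_ground_truth()] object.
#' @param basis An [build_hrf_basis()] object with `K` matching `gt`.
#' @param snr_db SNR in dB (`Inf` = noiseless).
#' @param seed Integer seed for the noise draw.
#' @return A [roi_matrix()].
#' @export
assemble_fmri_matrix <- function(gt, basis, snr_db = Inf, seed = 1L) {
  stopifnot(inherits(gt, "cmtf_ground_truth"))
  if (ncol(gt$B) != hrf_K(basis)) stop("dimension error: basis K does not match ground truth")
  Is <- nrow(gt$S)
  Yhat <- fmri_forward_factors(gt$S, gt$V, gt$B, gt$N, gt$P, basis, Is)
  Y <- with_seed(seed, Yhat + scaled_noise(Yhat, snr_db))
  roi_matrix(Y, TR = basis$TR)
}
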