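# Hemodynamic response basis and causal convolution operators. The coupling
# between the shared temporal signatures and the BOLD signal is linear:
# each ROI's HRF is a K-term combination of a canonical double-gamma response
# and its temporal and dispersion derivatives, applied as a causal Toeplitz
# convolution at TR resolution.

# Continuous canonical double-gamma response. Parametrized so the positive
# lobe's mode sits exactly at `peak` seconds and the undershoot's at `under`:
# gamma densities with shape = delay/dispersion + 1.
double_gamma <- function(t, theta) {
  pk <- theta[["peak"]]; un <- theta[["under"]]
  dp <- theta[["disp"]]; du <- theta[["u_disp"]]; ratio <- theta[["ratio"]]
  h <- stats::dgamma(t, shape = pk / dp + 1, rate = 1 / dp) -
    ratio * stats::dgamma(t, shape = un / du + 1, rate = 1 / du)
  h[t < 0] <- 0
  h
}

default_hrf_theta <- function() {
  c(peak = 6, under = 16, disp = 1, u_disp = 1, ratio = 1 / 6)
}

#' Build an HRF basis (canonical double-gamma plus derivatives)
#'
#' Basis function 1 is the canonical double-gamma response (positive lobe
#' peaking at `theta["peak"]` seconds, default 6 s; undershoot at 16 s with
#' amplitude ratio 1/6), normalized to peak value 1. Basis 2 is its temporal
#' derivative and basis 3 its dispersion derivative, both scaled by the same
#' normalization so linear combinations remain commensurate. All functions
#' are causal (zero at negative lags) and sampled at the fMRI TR.
#'
#' @param K Number of basis functions, 1 to 3.
#' @param TR Sampling interval in seconds.
#' @param duration Support of the basis in seconds (>= 16 s recommended).
#' @param theta Named shape parameters `peak`, `under`, `disp`, `u_disp`,
#'   `ratio`; defaults give the canonical shape.
#' @param kind Basis family; only `"canonical+derivatives"` is provided.
#' @return Object of class `hrf_basis`: list with `lags` (seconds), `basis`
#'   (length(lags) x K matrix), `theta`, `TR`.
#' @export
build_hrf_basis <- function(K = 3, TR = 2, duration = 32,
                            theta = default_hrf_theta(),
                            kind = "canonical+derivatives") {
  if (kind != "canonical+derivatives") stop("unsupported basis kind")
  if (!(K %in% 1:3)) stop("unsupported: K must be 1, 2 or 3 for this basis kind")
  th <- default_hrf_theta()
  th[names(theta)] <- theta
  lags <- seq(0, duration, by = TR)
  h1 <- double_gamma(lags, th)
  peak_val <- max(h1)
  if (peak_val <= 0) stop("degenerate HRF: nonpositive peak")
  H <- matrix(0, length(lags), K)
  H[, 1] <- h1 / peak_val
  if (K >= 2) {
    # temporal derivative by central differences of the continuous response
    d <- 1e-3
    H[, 2] <- (double_gamma(lags + d, th) - double_gamma(lags - d, th)) /
      (2 * d) / peak_val
  }
  if (K >= 3) {
    # dispersion derivative: finite difference in the dispersion parameter
    dd <- 0.01
    th2 <- th; th2[["disp"]] <- th[["disp"]] + dd
    H[, 3] <- (double_gamma(lags, th) - double_gamma(lags, th2)) / dd / peak_val
  }
  structure(list(lags = lags, basis = H, theta = th, TR = TR),
            class = "hrf_basis")
}

hrf_K <- function(basis) ncol(basis$basis)

#' @export
print.hrf_basis <- function(x, ...) {
  cat(sprintf("<hrf_basis> K = %d, %d lags at TR = %g s (0 to %g s), peak delay %g s\n",
              hrf_K(x), length(x$lags), x$TR, max(x$lags), x$theta[["peak"]]))
  invisible(x)
}

#' Causal convolution operator for one HRF basis function
#'
#' Returns the linear operator `H_k` acting on length-`Is` signals:
#' `(H_k s)[t] = sum_{tau >= 0} h_k[tau] s[t - tau]` with zero initial
#' conditions and output truncated to `Is` samples.
#'
#' @param basis An [build_hrf_basis()] object.
#' @param k Basis index (1-based), `k <= K`.
#' @param Is Signal length in samples (volumes).
#' @return Object of class `conv_operator` with `apply(s)` (FFT-based
#'   convolution) and `matrix` (the explicit `Is x Is` lower-triangular
#'   Toeplitz matrix).
#' @export
make_convolution_operator <- function(basis, k, Is) {
  if (k < 1 || k > hrf_K(basis)) stop("index error: k out of range")
  h <- basis$basis[, k]
  apply_fun <- function(s) {
    stopifnot(length(s) == Is)
    stats::convolve(c(s, numeric(length(h))), rev(h), type = "open")[seq_len(Is)]
  }
  m <- min(length(h), Is)
  Tm <- matrix(0, Is, Is)
  for (j in seq_len(m)) {
    idx <- seq_len(Is - j + 1L)
    Tm[cbind(idx + j - 1L, idx)] <- h[j]
  }
  structure(list(apply = apply_fun, matrix = Tm, k = k, Is = Is),
            class = "conv_operator")
}

# Materialized Toeplitz matrices for all K basis functions.
conv_matrices <- function(basis, Is) {
  lapply(seq_len(hrf_K(basis)), function(k) make_convolution_operator(basis, k, Is)$matrix)
}

#' ROI-specific HRF curve
#'
#' The HRF of ROI `v` is the coefficient-weighted combination
#' `sum_k B[v, k] h_k` on the basis lag grid.
#'
#' @param B Coefficient matrix (`Iv x K`).
#' @param basis An [build_hrf_basis()] object.
#' @param v ROI index (1-based).
#' @return Numeric vector on `basis$lags`.
#' @export
roi_hrf <- function(B, basis, v) {
  if (ncol(B) != hrf_K(basis)) stop("coefficient/basis K mismatch")
  if (v < 1 || v > nrow(B)) stop("index error: v out of range")
  as.numeric(basis$basis %*% B[v, ])
}

#' HRF basis as a data frame (lag, h_1 ... h_K) for export
#'
#' @param basis An [build_hrf_basis()] object.
#' @return data.frame with columns `lag` and `h_1` ... `h_K`.
#' @export
hrf_basis_table <- function(basis) {
  df <- data.frame(lag = basis$lags)
  for (k in seq_len(hrf_K(basis))) df[[paste0("h_", k)]] <- basis$basis[, k]
  df
}
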