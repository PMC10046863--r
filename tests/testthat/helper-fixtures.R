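# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# A short task: 10 trials of 14 s at TR = 2 s -> 70 volumes.
tiny_stimulus <- function(n_trials = 10, TR = 2, seed = 1L, ...) {
  generate_stimulus_timecourse(n_trials, TR = TR, seed = seed, ...)
}

tiny_ground_truth <- function(R = 2, K = 2, Q = 1,
                              dims = c(70, 12, 8, 15),
                              seed = 1L, ...) {
  stim <- tiny_stimulus(n_trials = dims[1] %/% 7, seed = seed)
  generate_ground_truth(R, K, Q, dims = dims, stimulus = stim,
                        seed = seed, ...)
}

# HRF basis whose first function is a unit impulse at lag 0 (identity
# convolution); useful to collapse the coupled model onto Y = S V'.
impulse_basis <- function(K = 1, TR = 2, n_lags = 5) {
  B <- matrix(0, n_lags, K)
  B[1, 1] <- 1
  structure(list(lags = seq(0, by = TR, length.out = n_lags), basis = B,
                 theta = c(peak = 0), TR = TR),
            class = "hrf_basis")
}

relerr_arr <- function(est, ref) {
  sqrt(sum((est - ref)^2)) / sqrt(sum(ref^2))
}

# Brute-force CP reconstruction by explicit triple loop (independent oracle).
loop_cp_reconstruct <- function(S, F_, C_) {
  Is <- nrow(S); If <- nrow(F_); Ic <- nrow(C_); R <- ncol(S)
  X <- array(0, dim = c(Is, If, Ic))
  for (t in seq_len(Is)) for (f in seq_len(If)) for (ch in seq_len(Ic)) {
    acc <- 0
    for (r in seq_len(R)) acc <- acc + S[t, r] * F_[f, r] * C_[ch, r]
    X[t, f, ch] <- acc
  }
  X
}

# Brute-force coupled fMRI forward model (loops over t, v, r, k, q).
loop_fmri_forward <- function(S, V, B, N, P, basis, Is) {
  h <- basis$basis
  Iv <- nrow(V); R <- ncol(S); K <- ncol(B); Q <- ncol(N)
  nl <- nrow(h)
  Y <- matrix(0, Is, Iv)
  for (t in seq_len(Is)) for (v in seq_len(Iv)) {
    acc <- 0
    for (r in seq_len(R)) for (k in seq_len(K)) {
      conv <- 0
      for (tau in 0:(min(nl, t) - 1)) {
        conv <- conv + h[tau + 1, k] * S[t - tau, r]
      }
      acc <- acc + conv * B[v, k] * V[v, r]
    }
    if (Q > 0) for (q in seq_len(Q)) acc <- acc + N[t, q] * P[v, q]
    Y[t, v] <- acc
  }
  Y
}

# Align columns of estimated factors to the truth by |cos| of the shared
# temporal mode; returns per-column |cos| for the requested mode.
aligned_abs_cos <- function(truth_S, est_S, truth_M, est_M) {
  ncol_ <- function(M) dim(M)[2]
  sim <- abs(crossprod(apply(truth_S, 2, function(x) x / sqrt(sum(x^2))),
                       apply(est_S, 2, function(x) x / sqrt(sum(x^2)))))
  perm <- apply(sim, 1, which.max)
  vapply(seq_len(ncol_(truth_M)), function(r) {
    a <- truth_M[, r]; b <- est_M[, perm[r]]
    abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
}
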