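# A small, fully coupled synthetic problem reused across the CMTF tests.
cmtf_problem <- function(seed = 1, snr_db = 20, dims = c(70, 12, 8, 15),
                         R = 2, K = 2, Q = 1) {
  gt <- tiny_ground_truth(R = R, K = K, Q = Q, dims = dims, seed = seed)
  basis <- build_hrf_basis(K = K, TR = 2, duration = 24)
  list(
    gt = gt, basis = basis,
    X = assemble_eeg_tensor(gt, snr_db = snr_db, seed = seed + 50),
    Y = assemble_fmri_matrix(gt, basis, snr_db = snr_db, seed = seed + 60)
  )
}

gt_model <- function(p, weights) {
  cmtf_model(p$gt$S, p$gt$F, p$gt$C, p$gt$V, p$gt$B, p$gt$N, p$gt$P,
             weights, p$basis)
}

test_that("the fMRI forward model matches its special cases and the loop oracle", {
  p <- cmtf_problem(seed = 2, Q = 0, K = 1, dims = c(35, 6, 5, 10))
  w <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  # impulse HRF, unit coefficients -> Yhat = S V'
  m <- cmtf_model(p$gt$S, p$gt$F, p$gt$C, p$gt$V, matrix(1, 10, 1),
                  p$gt$N, p$gt$P, w, impulse_basis(K = 1))
  expect_lt(max(abs(fmri_forward(m) - tcrossprod(p$gt$S, p$gt$V))), 1e-12)

  p2 <- cmtf_problem(seed = 3, dims = c(28, 5, 4, 9))
  m2 <- gt_model(p2, w)
  m2$S <- matrix(0, 28, 2)
  expect_equal(fmri_forward(m2), tcrossprod(p2$gt$N, p2$gt$P), tolerance = 1e-12)

  m3 <- gt_model(p2, w)
  oracle <- loop_fmri_forward(p2$gt$S, p2$gt$V, p2$gt$B, p2$gt$N, p2$gt$P,
                              p2$basis, 28)
  expect_lt(max(abs(fmri_forward(m3) - oracle)) / max(abs(oracle)), 1e-10)
})

test_that("per-component amplitudes follow the norm-product formulas", {
  p <- cmtf_problem(seed = 4, dims = c(21, 6, 5, 8))
  w <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  m <- gt_model(p, w)
  lam <- amplitudes(m)
  # direct-formula oracle
  for (r in 1:2) {
    lx <- sqrt(sum(m$S[, r]^2)) * sqrt(sum(m$F[, r]^2)) * sqrt(sum(m$C[, r]^2))
    ly <- sum(vapply(1:2, function(k) sqrt(sum((m$B[, k] * m$V[, r])^2)),
                     numeric(1)))
    expect_equal(lam$lambda_x[r], lx, tolerance = 1e-12)
    expect_equal(lam$lambda_y[r], ly, tolerance = 1e-12)
  }
  # unit-norm EEG columns -> lambda_x = 1
  mu <- m
  for (r in 1:2) {
    mu$S[, r] <- mu$S[, r] / sqrt(sum(mu$S[, r]^2))
    mu$F[, r] <- mu$F[, r] / sqrt(sum(mu$F[, r]^2))
    mu$C[, r] <- mu$C[, r] / sqrt(sum(mu$C[, r]^2))
  }
  expect_equal(amplitudes(mu)$lambda_x, c(1, 1), tolerance = 1e-12)
  mb <- m
  mb$B <- matrix(0, 8, 2)
  expect_equal(amplitudes(mb)$lambda_y, c(0, 0))
})

test_that("the objective equals its definition term by term", {
  p <- cmtf_problem(seed = 5, snr_db = Inf, dims = c(28, 5, 4, 9))
  w0 <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  expect_lt(cmtf_objective(gt_model(p, w0), p$X, p$Y), 1e-18)

  w <- list(beta_x = 0.7, beta_y = 1.3, gamma_x = 0.2, gamma_y = 0.4)
  m <- gt_model(p, w)
  # elementwise oracle
  Xhat <- loop_cp_reconstruct(m$S, m$F, m$C)
  Yhat <- loop_fmri_forward(m$S, m$V, m$B, m$N, m$P, p$basis, 28)
  lam <- amplitudes(m)
  J_oracle <- 0.7 * sum((p$X$data - Xhat)^2) + 1.3 * sum((p$Y$data - Yhat)^2) +
    0.2 * sum(lam$lambda_x) + 0.4 * sum(lam$lambda_y)
  expect_lt(abs(cmtf_objective(m, p$X, p$Y) - J_oracle) / abs(J_oracle), 1e-10)

  # all-zero model: J = bx ||X||^2 + by ||Y||^2
  z <- cmtf_model(matrix(0, 28, 2), matrix(0, 5, 2), matrix(0, 4, 2),
                  matrix(0, 9, 2), matrix(0, 9, 2), matrix(0, 28, 1),
                  matrix(0, 9, 1), w, p$basis)
  expect_equal(cmtf_objective(z, p$X, p$Y),
               0.7 * sum(p$X$data^2) + 1.3 * sum(p$Y$data^2),
               tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  p <- cmtf_problem(seed = 6, snr_db = 10, dims = c(28, 6, 5, 9))
  w <- default_cmtf_weights(p$X, p$Y, gamma_x = 0.05, gamma_y = 0.05)
  d <- list(Is = 28, If = 6, Ic = 5, Iv = 9, R = 2, K = 2, Q = 1)
  ev <- cmtfusion:::make_cmtf_evaluator(p$X, p$Y$data, p$basis, d, w)
  npar <- 28 * 2 + 6 * 2 + 5 * 2 + 9 * 2 + 9 * 2 + 28 + 9
  set.seed(99)
  par <- rnorm(npar)
  g <- ev$gr(par)
  h <- 1e-6
  idx <- sort(sample.int(npar, 80))
  fd <- vapply(idx, function(i) {
    e <- numeric(npar); e[i] <- h
    (ev$fn(par + e) - ev$fn(par - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(abs(fd), 1e-6)), 1e-5)
})

test_that("the ground truth is a stationary point of the idealized objective", {
  # gamma = 0, Q = 0, K = 1, impulse HRF, noiseless data: coupled CP problem
  p <- cmtf_problem(seed = 7, snr_db = Inf, Q = 0, K = 1, dims = c(35, 6, 5, 10))
  ib <- impulse_basis(K = 1)
  gt <- p$gt
  gt$B <- matrix(1, 10, 1)
  Y <- assemble_fmri_matrix(gt, ib, snr_db = Inf)
  w <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  d <- list(Is = 35, If = 6, Ic = 5, Iv = 10, R = 2, K = 1, Q = 0)
  ev <- cmtfusion:::make_cmtf_evaluator(p$X, Y$data, ib, d, w)
  m <- cmtf_model(gt$S, gt$F, gt$C, gt$V, gt$B, gt$N, gt$P, w, ib)
  g <- ev$gr(cmtfusion:::pack_params(m))
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("zero-iteration CMTF returns the deterministic initialization", {
  p <- cmtf_problem(seed = 8, dims = c(28, 5, 4, 9))
  init <- random_init(c(28, 5, 4), 2, seed = 1)
  fit <- cmtf_fit(p$X, p$Y, p$basis, R = 2, Q = 1, init = init, max_iter = 0)
  expect_false(fit$diagnostics$converged)
  expect_identical(fit$model$S, init$S)
  expect_equal(fit$model$B[, 1], rep(1, 9))   # canonical start
  fit2 <- cmtf_fit(p$X, p$Y, p$basis, R = 2, Q = 1, init = init, max_iter = 0)
  expect_identical(fit$model$V, fit2$model$V)
  bad <- p$X$data; bad[1] <- Inf
  expect_error(cmtf_fit(bad, p$Y, p$basis, R = 2, Q = 1, init = init),
               "finite")
})

test_that("the CMTF cost trace is monotone and the fit beats its start", {
  p <- cmtf_problem(seed = 9)
  cp <- cpd_fit(p$X, 2, init = random_init(c(70, 12, 8), 2, seed = 2),
                max_iter = 100)
  fit <- cmtf_fit(p$X, p$Y, p$basis, R = 2, Q = 1, init = cp$factors,
                  max_iter = 300)
  tr <- fit$diagnostics$trace
  expect_true(all(diff(tr) <= 1e-10))
  expect_lt(tr[length(tr)], tr[1])
})

test_that("perturbing the shared temporal factor moves both reconstructions", {
  p <- cmtf_problem(seed = 10, dims = c(28, 5, 4, 9))
  w <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  m <- gt_model(p, w)
  X0 <- cpd_reconstruct(cpd_factors(m$S, m$F, m$C))
  Y0 <- fmri_forward(m)
  m$S[5, 1] <- m$S[5, 1] + 0.1
  X1 <- cpd_reconstruct(cpd_factors(m$S, m$F, m$C))
  Y1 <- fmri_forward(m)
  expect_gt(max(abs(X1 - X0)), 1e-4)
  expect_gt(max(abs(Y1 - Y0)), 1e-4)
})

test_that("normalization canonicalizes without changing the reconstructions", {
  p <- cmtf_problem(seed = 11, dims = c(28, 5, 4, 9))
  w <- default_cmtf_weights(p$X, p$Y)
  m <- gt_model(p, w)
  n1 <- normalize_model(m)
  expect_equal(sqrt(colSums(n1$F^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(sqrt(colSums(n1$C^2)), c(1, 1), tolerance = 1e-12)
  # reconstructions preserved
  expect_lt(max(abs(cpd_reconstruct(cpd_factors(n1$S, n1$F, n1$C)) -
                    cpd_reconstruct(cpd_factors(m$S, m$F, m$C)))), 1e-10)
  expect_lt(max(abs(fmri_forward(n1) - fmri_forward(m))), 1e-10)
  # idempotent, and invariant to compensated rescaling
  expect_equal(normalize_model(n1)$F, n1$F, tolerance = 1e-12)
  # compensated rescaling of the EEG gauge maps to the same canonical S, F, C
  m2 <- m
  m2$F[, 1] <- 3 * m2$F[, 1]
  m2$S[, 1] <- m2$S[, 1] / 3
  n2 <- normalize_model(m2)
  expect_equal(n2$F, n1$F, tolerance = 1e-12)
  expect_equal(n2$S, n1$S, tolerance = 1e-12)
  expect_equal(n2$C, n1$C, tolerance = 1e-12)
  # and still preserves that model's own fMRI reconstruction
  expect_lt(max(abs(fmri_forward(n2) - fmri_forward(m2))), 1e-10)
})

test_that("stronger amplitude penalties do not increase the fitted amplitudes", {
  p <- cmtf_problem(seed = 12, dims = c(42, 8, 6, 10))
  cp <- cpd_fit(p$X, 2, init = random_init(c(42, 8, 6), 2, seed = 5),
                max_iter = 200)
  l1 <- vapply(c(0, 0.1, 0.5), function(g) {
    w <- default_cmtf_weights(p$X, p$Y, gamma_x = g, gamma_y = g)
    fit <- cmtf_fit(p$X, p$Y, p$basis, R = 2, Q = 1, init = cp$factors,
                    weights = w, max_iter = 600)
    sum(amplitudes(fit$model)$lambda_x)
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("small ensembles are reproducible with distinct initializations", {
  p <- cmtf_problem(seed = 13, dims = c(28, 6, 5, 9))
  e1 <- run_ensemble(p$X, p$Y, p$basis, R = 2, Q = 1, n_runs = 2, seed = 3,
                     cpd_max_iter = 50, cmtf_max_iter = 50)
  e2 <- run_ensemble(p$X, p$Y, p$basis, R = 2, Q = 1, n_runs = 2, seed = 3,
                     cpd_max_iter = 50, cmtf_max_iter = 50)
  expect_length(e1, 2)
  expect_identical(e1[[1]]$model$S, e2[[1]]$model$S)
  expect_identical(e1[[2]]$model$S, e2[[2]]$model$S)
  expect_false(identical(e1[[1]]$model$S, e1[[2]]$model$S))
  expect_equal(vapply(e1, function(f) f$seed, numeric(1)), c(4, 5))
  e3 <- run_ensemble(p$X, p$Y, p$basis, R = 1, Q = 0, n_runs = 1, seed = 1,
                     cpd_max_iter = 20, cmtf_max_iter = 20)
  expect_length(e3, 1)
})
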