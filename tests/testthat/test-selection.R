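test_that("CORCONDIA is 100 for exact factors and invariant to gauge changes", {
  truth <- random_init(c(15, 10, 8), 3, seed = 2)
  X <- cpd_reconstruct(truth)
  expect_equal(corcondia(X, truth), 100, tolerance = 1e-6)
  # permutation + compensated rescaling leave it unchanged
  g <- truth
  perm <- c(2, 3, 1)
  g$S <- truth$S[, perm] * 2
  g$F <- truth$F[, perm] * -1
  g$C <- truth$C[, perm] * -0.5
  expect_equal(corcondia(X, g), 100, tolerance = 1e-6)
})

test_that("any best rank-1 fit scores a perfect core consistency", {
  gt <- tiny_ground_truth(R = 3, dims = c(21, 8, 6, 5), seed = 4)
  X <- assemble_eeg_tensor(gt, snr_db = 5, seed = 4)
  fit <- cpd_fit(X, 1, init = random_init(dim(X$data), 1, seed = 1),
                 max_iter = 100)
  expect_equal(corcondia(X, fit$factors), 100, tolerance = 1e-6)
})

test_that("CORCONDIA with overfactoring matches a dense least-squares core oracle", {
  gt <- tiny_ground_truth(R = 2, dims = c(14, 8, 6, 5), seed = 6)
  X <- assemble_eeg_tensor(gt, snr_db = 15, seed = 6)
  fit <- cpd_fit(X, 4, init = random_init(dim(X$data), 4, seed = 3),
                 max_iter = 200)
  ours <- corcondia(X, fit$factors)
  # oracle: solve the R^3 core entries by explicit least squares over the
  # Kronecker design matrix
  S <- fit$factors$S; F_ <- fit$factors$F; C_ <- fit$factors$C
  D <- kronecker(C_, kronecker(F_, S))
  g <- qr.solve(D, as.numeric(X$data))
  G <- array(g, c(4, 4, 4))
  I4 <- array(0, c(4, 4, 4)); I4[cbind(1:4, 1:4, 1:4)] <- 1
  oracle <- 100 * (1 - sum((G - I4)^2) / 4)
  expect_equal(ours, oracle, tolerance = 1e-6)
  expect_lte(ours, 100)
})

test_that("component similarity is a sign-invariant product of cosines", {
  a <- list(s = c(1, 2, 3), f = c(2, 0, 1), c = c(1, 1), v = c(0, 3, 1))
  expect_equal(component_similarity(a, a), 1.0)
  neg <- lapply(a, function(x) -x)
  expect_equal(component_similarity(a, neg), 1.0)
  orth <- list(s = c(-2, 1, 0), f = a$f, c = a$c, v = a$v)
  expect_equal(component_similarity(a, orth), 0.0, tolerance = 1e-12)
  expect_equal(component_similarity(a, list(s = c(0, 0, 0), f = a$f,
                                            c = a$c, v = a$v)), 0.0)
  expect_error(component_similarity(a, list(s = c(1, 2))), "length mismatch")
})

# Build a minimal normalized model whose signatures are given explicitly.
stub_model <- function(S, F_, C_, V, basis = impulse_basis(K = 1)) {
  w <- list(beta_x = 1, beta_y = 1, gamma_x = 0, gamma_y = 0)
  cmtf_model(S, F_, C_, V, matrix(1, nrow(V), 1),
             matrix(0, nrow(S), 0), matrix(0, nrow(V), 0), w, basis)
}

test_that("graph clustering groups identical components and splits orthogonal ones", {
  set.seed(8)
  m <- stub_model(matrix(rnorm(40), 20, 2), matrix(rnorm(16), 8, 2),
                  matrix(rnorm(12), 6, 2), matrix(rnorm(10), 5, 2))
  ens <- lapply(1:50, function(i) list(model = m))
  cl <- graph_cluster(ens, threshold = 0.9)
  expect_length(cl, 2)
  expect_equal(vapply(cl, function(x) x$cardinality, numeric(1)), c(50, 50))
  expect_equal(nrow(cl[[1]]$members), 50)

  # two runs with mutually orthogonal signatures -> 2R singleton clusters
  m1 <- stub_model(diag(20)[, 1:2], diag(8)[, 1:2], diag(6)[, 1:2], diag(5)[, 1:2])
  m2 <- stub_model(diag(20)[, 3:4], diag(8)[, 3:4], diag(6)[, 3:4], diag(5)[, 3:4])
  cl2 <- graph_cluster(list(list(model = m1), list(model = m2)), threshold = 0.9)
  expect_length(cl2, 4)
  expect_true(all(vapply(cl2, function(x) x$cardinality, numeric(1)) == 1))

  # threshold 0 -> one cluster holding every node; threshold > 1 -> singletons
  cl0 <- graph_cluster(list(list(model = m1), list(model = m2)), threshold = 0)
  expect_length(cl0, 1)
  expect_equal(nrow(cl0[[1]]$members), 4)
  cl3 <- graph_cluster(ens[1:3], threshold = 1.000001)
  expect_length(cl3, 6)
})

test_that("cluster centroids belong to their cluster", {
  set.seed(9)
  m <- stub_model(matrix(rnorm(40), 20, 2), matrix(rnorm(16), 8, 2),
                  matrix(rnorm(12), 6, 2), matrix(rnorm(10), 5, 2))
  cl <- graph_cluster(lapply(1:5, function(i) list(model = m)), threshold = 0.5)
  for (x in cl) expect_true(x$centroid %in% seq_len(nrow(x$members)))
})

stub_cluster <- function(card) {
  structure(list(members = data.frame(run = seq_len(card), comp = 1),
                 centroid = 1L, cardinality = card),
            class = "component_cluster")
}

test_that("the reproducibility filter retains cardinality strictly above the bound", {
  cl <- lapply(c(15, 12, 10, 3), stub_cluster)
  kept <- reproducibility_filter(cl, 10)
  expect_equal(vapply(kept, function(x) x$cardinality, numeric(1)), c(15, 12))
  expect_identical(reproducibility_filter(kept, 10), kept)   # idempotent
  all50 <- lapply(rep(50, 4), stub_cluster)
  expect_length(reproducibility_filter(all50, 10), 4)
  expect_length(reproducibility_filter(list(), 10), 0)
})

test_that("stimulus similarity is absolute Pearson correlation", {
  stim <- tiny_stimulus(n_trials = 80, seed = 1)
  expect_equal(stimulus_similarity(as.numeric(stim$values), stim), 1.0)
  expect_equal(stimulus_similarity(-as.numeric(stim$values), stim), 1.0)
  set.seed(3)
  s <- rnorm(560)
  # textbook formula oracle
  v <- stim$values
  oracle <- abs(sum((s - mean(s)) * (v - mean(v))) /
                sqrt(sum((s - mean(s))^2) * sum((v - mean(v))^2)))
  expect_equal(stimulus_similarity(s, stim), oracle, tolerance = 1e-12)
  expect_error(stimulus_similarity(rep(1, 560), stim), "constant")
  expect_error(stimulus_similarity(s[1:10], stim), "length")
  # optional HRF convolution: a BOLD-like signature correlates better with
  # the convolved paradigm than with the raw binary vector
  basis <- build_hrf_basis(K = 1, TR = 2)
  bold <- make_convolution_operator(basis, 1, 560)$apply(as.numeric(v))
  expect_gt(stimulus_similarity(bold, stim, convolve = TRUE, basis = basis),
            stimulus_similarity(bold, stim))
  expect_equal(stimulus_similarity(bold, stim, convolve = TRUE, basis = basis),
               1.0, tolerance = 1e-12)
})

test_that("the permutation map flags planted ROIs and respects alpha = 1", {
  set.seed(14)
  Is <- 100; Iv <- 20
  basis <- build_hrf_basis(K = 1, TR = 2)
  s <- as.numeric(arima.sim(list(ar = 0.6), Is))
  z <- make_convolution_operator(basis, 1, Is)$matrix %*% s
  V <- matrix(0, Iv, 1)
  planted <- c(2, 5, 9, 13, 17)
  V[planted, 1] <- 1
  Y <- tcrossprod(as.numeric(z), V[, 1]) + 0.1 * matrix(rnorm(Is * Iv), Is, Iv)
  m <- stub_model(matrix(s, ncol = 1), matrix(1, 4, 1), matrix(1, 3, 1), V,
                  basis = basis)
  res <- snpm_significance(m, Y, r = 1, alpha = 0.05, n_perm = 199, seed = 5)
  expect_setequal(res$significant, planted)
  expect_equal(sort(order(res$stat, decreasing = TRUE)[1:5]), planted)
  res1 <- snpm_significance(m, Y, r = 1, alpha = 1.0, n_perm = 99, seed = 5)
  expect_equal(res1$significant, 1:Iv)
  mconst <- m
  mconst$S[, 1] <- 1
  expect_error(snpm_significance(mconst, Y, r = 1, n_perm = 99), "degenerate")
  expect_error(snpm_significance(m, Y, r = 1, n_perm = 50), "99")
  expect_error(snpm_significance(m, Y, r = 3, n_perm = 99), "out of range")
})

stub_report <- function(R, corcondia, similarity, cardinality, retained) {
  structure(
    list(R = R, corcondia = corcondia, clusters = list(), retained = list(),
         centroid_similarities = similarity,
         best = list(run = 1L, comp = 1L, similarity = similarity,
                     cardinality = cardinality, retained = retained),
         snpm = NULL, model = NULL),
    class = "cmtf_candidate_report"
  )
}

test_that("model selection gates on core consistency and reproducibility", {
  # single eligible candidate
  sel <- select_best_model(list(stub_report(2, 95, 0.8, 20, TRUE)))
  expect_equal(sel$chosen_R, 2)
  expect_false(sel$no_eligible_model)

  # only R = 2 passes the CORCONDIA gate
  sel2 <- select_best_model(list(stub_report(2, 92, 0.6, 20, TRUE),
                                 stub_report(5, 40, 0.9, 20, TRUE)))
  expect_equal(sel2$chosen_R, 2)

  # among eligible candidates the higher similarity wins; ties -> smaller R
  sel3 <- select_best_model(list(stub_report(2, 90, 0.5, 20, TRUE),
                                 stub_report(3, 90, 0.7, 20, TRUE)))
  expect_equal(sel3$chosen_R, 3)
  sel4 <- select_best_model(list(stub_report(3, 90, 0.6, 20, TRUE),
                                 stub_report(2, 90, 0.6, 20, TRUE)))
  expect_equal(sel4$chosen_R, 2)

  # reproducibility gate: best component must survive the filter
  sel5 <- select_best_model(list(stub_report(2, 95, 0.9, 5, FALSE),
                                 stub_report(3, 85, 0.4, 20, TRUE)))
  expect_equal(sel5$chosen_R, 3)

  # nothing eligible -> least-bad candidate, flagged
  sel6 <- select_best_model(list(stub_report(2, 40, 0.9, 5, FALSE),
                                 stub_report(3, 30, 0.5, 5, FALSE)))
  expect_equal(sel6$chosen_R, 2)
  expect_true(sel6$no_eligible_model)
  expect_error(select_best_model(list()), "no candidate")

  # deterministic: same reports, same choice
  reps <- list(stub_report(2, 90, 0.5, 20, TRUE), stub_report(3, 90, 0.7, 20, TRUE))
  expect_identical(select_best_model(reps)$chosen_R,
                   select_best_model(reps)$chosen_R)
})
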