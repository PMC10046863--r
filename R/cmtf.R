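# Coupled matrix-tensor factorization. The EEG tensor X and the fMRI ROI
# matrix Y are decomposed jointly: X as a rank-R CP model [[S, F, C]] and Y
# as the HRF-convolved expansion of the *same* temporal signatures S,
#   Yhat[t, v] = sum_r sum_k (H_k S[, r])[t] B[v, k] V[v, r] + (N P')[t, v],
# plus an uncoupled rank-Q term. The objective
#   J = bx ||X - Xhat||_F^2 + by ||Y - Yhat||_F^2 + gx ||lam_x||_1 + gy ||lam_y||_1
# penalizes source amplitudes through the L1 norms of the per-component
# amplitude vectors. Optimization is limited-memory quasi-Newton on the
# concatenated parameter vector with analytic gradients.

#' Construct a CMTF model object
#'
#' @param S,F,C EEG factor matrices (shared temporal, spectral, channel).
#' @param V fMRI spatial signatures (`Iv x R`).
#' @param B HRF basis coefficients per ROI (`Iv x K`).
#' @param N,P Uncoupled temporal/spatial factors (`Is x Q`, `Iv x Q`).
#' @param weights List with nonnegative scalars `beta_x`, `beta_y`,
#'   `gamma_x`, `gamma_y`.
#' @param basis The [build_hrf_basis()] object the model is coupled through.
#' @return Object of class `cmtf_model`.
#' @export
cmtf_model <- function(S, F, C, V, B, N, P, weights, basis) {
  R <- ncol(S)
  if (ncol(F) != R || ncol(C) != R || ncol(V) != R) {
    stop("S, F, C, V must share R columns")
  }
  if (ncol(N) != ncol(P)) stop("N and P must share Q columns")
  if (nrow(B) != nrow(V) || nrow(P) != nrow(V)) stop("V, B, P must share Iv rows")
  if (ncol(B) != hrf_K(basis)) stop("B columns must match basis K")
  w <- weights
  stopifnot(all(unlist(w[c("beta_x", "beta_y", "gamma_x", "gamma_y")]) >= 0))
  structure(
    list(S = S, F = F, C = C, V = V, B = B, N = N, P = P,
         R = R, Q = ncol(N), K = ncol(B), weights = w, basis = basis),
    class = "cmtf_model"
  )
}

#' @export
print.cmtf_model <- function(x, ...) {
  cat(sprintf(
    "<cmtf_model> R = %d shared sources, K = %d HRF bases, Q = %d uncoupled; dims (Is, If, Ic, Iv) = (%d, %d, %d, %d)\n",
    x$R, x$K, x$Q, nrow(x$S), nrow(x$F), nrow(x$C), nrow(x$V)
  ))
  invisible(x)
}

#' Default objective weights
#'
#' Data-fit weights equalize modality scales (`beta = 1 / ||data||_F^2`),
#' so each fit term is the squared relative error. The amplitude penalties
#' are made dimensionless the same way: the stated `gamma` (default 0.01)
#' is divided by the data Frobenius norm, so it penalizes amplitudes
#' measured relative to the data scale.
#'
#' @param X EEG tensor (or array); @param Y ROI matrix (or matrix).
#' @param gamma_x,gamma_y L1 amplitude-penalty weights (relative scale).
#' @return Weight list for [cmtf_model()].
#' @export
default_cmtf_weights <- function(X, Y, gamma_x = 0.01, gamma_y = 0.01) {
  nx <- fnorm(tensor_data(X)); ny <- fnorm(matrix_data(Y))
  list(beta_x = 1 / nx^2, beta_y = 1 / ny^2,
       gamma_x = gamma_x / nx, gamma_y = gamma_y / ny)
}

# Shared forward model on bare factor matrices (used by the synthetic
# generator and by fitted models alike).
fmri_forward_factors <- function(S, V, B, N, P, basis, Is,
                                 Hmats = conv_matrices(basis, Is)) {
  Iv <- nrow(V)
  Yhat <- matrix(0, Is, Iv)
  for (k in seq_len(ncol(B))) {
    Zk <- Hmats[[k]] %*% S
    Wk <- V * B[, k]
    Yhat <- Yhat + tcrossprod(Zk, Wk)
  }
  if (ncol(N) > 0) Yhat <- Yhat + tcrossprod(N, P)
  Yhat
}

#' Predicted fMRI matrix of a CMTF model
#'
#' @param model A [cmtf_model()].
#' @param basis HRF basis (defaults to the one stored in the model).
#' @return `Is x Iv` matrix.
#' @export
fmri_forward <- function(model, basis = model$basis) {
  if (ncol(model$B) != hrf_K(basis)) stop("dimension mismatch: basis K")
  fmri_forward_factors(model$S, model$V, model$B, model$N, model$P,
                       basis, nrow(model$S))
}

#' Per-component amplitudes of a CMTF model
#'
#' `lambda_x[r] = ||s_r|| * ||f_r|| * ||c_r||` and
#' `lambda_y[r] = sum_k ||b_k * v_r||` (elementwise product over ROIs).
#'
#' @param model A [cmtf_model()].
#' @return List with numeric vectors `lambda_x`, `lambda_y` of length R.
#' @export
amplitudes <- function(model) {
  ns <- sqrt(colSums(model$S^2))
  nf <- sqrt(colSums(model$F^2))
  nc <- sqrt(colSums(model$C^2))
  lam_y <- numeric(model$R)
  for (k in seq_len(model$K)) {
    lam_y <- lam_y + sqrt(colSums((model$B[, k] * model$V)^2))
  }
  list(lambda_x = ns * nf * nc, lambda_y = lam_y)
}

#' CMTF objective value
#'
#' `J = bx ||X - Xhat||_F^2 + by ||Y - Yhat||_F^2 + gx ||lambda_x||_1 +
#' gy ||lambda_y||_1` with `Xhat` the CP reconstruction and `Yhat` the
#' HRF-coupled forward model.
#'
#' @param model A [cmtf_model()].
#' @param X EEG tensor; @param Y ROI matrix.
#' @param basis HRF basis (defaults to the model's).
#' @return Scalar objective value.
#' @export
cmtf_objective <- function(model, X, Y, basis = model$basis) {
  A <- tensor_data(X); Ym <- matrix_data(Y)
  w <- model$weights
  Xhat <- cpd_reconstruct(cpd_factors(model$S, model$F, model$C))
  Yhat <- fmri_forward(model, basis)
  lam <- amplitudes(model)
  w$beta_x * ssq(A - Xhat) + w$beta_y * ssq(Ym - Yhat) +
    w$gamma_x * sum(lam$lambda_x) + w$gamma_y * sum(lam$lambda_y)
}

## ---- parameter packing ----------------------------------------------------

cmtf_dims <- function(model) {
  list(Is = nrow(model$S), If = nrow(model$F), Ic = nrow(model$C),
       Iv = nrow(model$V), R = model$R, K = model$K, Q = model$Q)
}

pack_params <- function(m) {
  c(m$S, m$F, m$C, m$V, m$B, m$N, m$P)
}

unpack_params <- function(par, d) {
  sizes <- c(d$Is * d$R, d$If * d$R, d$Ic * d$R, d$Iv * d$R,
             d$Iv * d$K, d$Is * d$Q, d$Iv * d$Q)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  take <- function(i, nr, nc) matrix(par[starts[i]:ends[i]], nr, nc)
  list(
    S = take(1, d$Is, d$R), F = take(2, d$If, d$R), C = take(3, d$Ic, d$R),
    V = take(4, d$Iv, d$R), B = take(5, d$Iv, d$K),
    N = if (d$Q > 0) take(6, d$Is, d$Q) else matrix(0, d$Is, 0),
    P = if (d$Q > 0) take(7, d$Iv, d$Q) else matrix(0, d$Iv, 0)
  )
}

## ---- objective + analytic gradient ---------------------------------------

# Builds a closure computing the smoothed objective and its gradient at a
# packed parameter vector. The L1-of-norms terms are smoothed as
# sqrt(. ^ 2 + eps) for quasi-Newton compatibility. The last evaluation is
# cached so optim's paired fn/gr calls cost one computation.
make_cmtf_evaluator <- function(X, Y, basis, d, weights, eps = 1e-9) {
  A <- tensor_data(X); Ym <- matrix_data(Y)
  X1 <- unfold(A, 1L); X2 <- unfold(A, 2L); X3 <- unfold(A, 3L)
  nX2 <- ssq(A); nY2 <- ssq(Ym)
  Hmats <- conv_matrices(basis, d$Is)
  HmatsT <- lapply(Hmats, t)
  bx <- weights$beta_x; by <- weights$beta_y
  gx <- weights$gamma_x; gy <- weights$gamma_y

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    m <- unpack_params(par, d)
    S <- m$S; F_ <- m$F; C_ <- m$C; V <- m$V; B <- m$B; N <- m$N; P <- m$P

    ## EEG fit term via Gram identities (no dense Xhat)
    Gcf <- crossprod(C_) * crossprod(F_)
    M1 <- X1 %*% khatri_rao(C_, F_)
    StS <- crossprod(S)
    fitX <- nX2 - 2 * sum(S * M1) + sum(StS * Gcf)

    ## fMRI forward
    Zk <- lapply(Hmats, function(H) H %*% S)
    Wk <- lapply(seq_len(d$K), function(k) V * B[, k])
    Yhat <- matrix(0, d$Is, d$Iv)
    for (k in seq_len(d$K)) Yhat <- Yhat + tcrossprod(Zk[[k]], Wk[[k]])
    if (d$Q > 0) Yhat <- Yhat + tcrossprod(N, P)
    Ey <- Yhat - Ym
    fitY <- ssq(Ey)

    ## smoothed amplitude penalties
    ns <- sqrt(colSums(S^2) + eps)
    nf <- sqrt(colSums(F_^2) + eps)
    nc_ <- sqrt(colSums(C_^2) + eps)
    lamx <- ns * nf * nc_
    Mkr <- matrix(0, d$K, d$R)        # m[k, r] = sqrt(sum_v B[v,k]^2 V[v,r]^2 + eps)
    for (k in seq_len(d$K)) {
      Mkr[k, ] <- sqrt(colSums((B[, k] * V)^2) + eps)
    }
    J <- bx * fitX + by * fitY + gx * sum(lamx) + gy * sum(Mkr)

    ## gradients
    gS <- 2 * bx * (S %*% Gcf - M1)
    Gcs <- crossprod(C_) * StS
    gF <- 2 * bx * (F_ %*% Gcs - X2 %*% khatri_rao(C_, S))
    Gfs <- crossprod(F_) * StS
    gC <- 2 * bx * (C_ %*% Gfs - X3 %*% khatri_rao(F_, S))

    gV <- matrix(0, d$Iv, d$R)
    gB <- matrix(0, d$Iv, d$K)
    for (k in seq_len(d$K)) {
      Mk <- crossprod(Ey, Zk[[k]])    # Iv x R
      gV <- gV + 2 * by * (B[, k] * Mk)
      gB[, k] <- 2 * by * rowSums(V * Mk)
      gS <- gS + 2 * by * (HmatsT[[k]] %*% (Ey %*% Wk[[k]]))
    }
    gN <- if (d$Q > 0) 2 * by * (Ey %*% P) else matrix(0, d$Is, 0)
    gP <- if (d$Q > 0) 2 * by * crossprod(Ey, N) else matrix(0, d$Iv, 0)

    if (gx > 0) {
      gS <- gS + gx * sweep(S, 2, nf * nc_ / ns, "*")
      gF <- gF + gx * sweep(F_, 2, ns * nc_ / nf, "*")
      gC <- gC + gx * sweep(C_, 2, ns * nf / nc_, "*")
    }
    if (gy > 0) {
      for (k in seq_len(d$K)) {
        gV <- gV + gy * sweep(B[, k]^2 * V, 2, Mkr[k, ], "/")
        gB[, k] <- gB[, k] + gy * (B[, k] * ((V^2) %*% (1 / Mkr[k, ])))
      }
    }

    val <- list(J = J, grad = c(gS, gF, gC, gV, gB, gN, gP),
                fitX = fitX, fitY = fitY)
    cache$par <- par
    cache$val <- val
    val
  }

  list(
    fn = function(par) evaluate(par)$J,
    gr = function(par) evaluate(par)$grad,
    detail = evaluate
  )
}

## ---- initialization -------------------------------------------------------

# Deterministic completion of a CP initialization into a full CMTF model:
# B rows start canonical (1, 0, ...); V by ridge least squares of Y on
# H_1 S; N, P by truncated SVD of the remaining residual.
cmtf_init_model <- function(init, X, Y, basis, Q, weights, ridge = 1e-8) {
  Ym <- matrix_data(Y)
  Is <- nrow(init$S); Iv <- ncol(Ym); K <- hrf_K(basis)
  H1 <- make_convolution_operator(basis, 1, Is)$matrix
  Z1 <- H1 %*% init$S
  G <- crossprod(Z1)
  diag(G) <- diag(G) + ridge * max(diag(G), 1)
  V <- t(solve(G, crossprod(Z1, Ym)))
  B <- matrix(0, Iv, K); B[, 1] <- 1
  Ry <- Ym - tcrossprod(Z1, V)
  if (Q > 0) {
    sv <- svd(Ry, nu = Q, nv = Q)
    scl <- sqrt(sv$d[seq_len(Q)])
    N <- sv$u %*% diag(scl, Q, Q)
    P <- sv$v %*% diag(scl, Q, Q)
  } else {
    N <- matrix(0, Is, 0); P <- matrix(0, Iv, 0)
  }
  cmtf_model(init$S, init$F, init$C, V, B, N, P, weights, basis)
}

## ---- fitting --------------------------------------------------------------

#' Fit the coupled matrix-tensor factorization
#'
#' Starting from a CP initialization of the EEG factors (with `V`, `B`
#' completed by ridge least squares and `N`, `P` by truncated SVD of the
#' residual), minimizes the CMTF objective by limited-memory quasi-Newton
#' (L-BFGS) over all factors jointly, with analytic gradients. The L1
#' amplitude penalties are smoothed as `sqrt(x^2 + eps)`. Optimization runs
#' in segments; the cost after each segment forms a monotone trace, and
#' iteration stops at `max_iter` total iterations or when the relative cost
#' update between segments falls below `tol`.
#'
#' @param X An [eeg_tensor()] or 3-d array.
#' @param Y A [roi_matrix()] or matrix sharing the time dimension with `X`.
#' @param basis An [build_hrf_basis()] object.
#' @param R Number of shared components (taken from `init`).
#' @param Q Rank of the uncoupled fMRI term.
#' @param init A [cpd_factors()] initialization, e.g. a fitted CP model.
#' @param weights Objective weights (default [default_cmtf_weights()]).
#' @param max_iter Maximum total quasi-Newton iterations (default 1000).
#' @param tol Relative cost-update tolerance (default 1e-8).
#' @param eps Smoothing constant for the L1 terms.
#' @param segment Iterations per trace segment.
#' @return List `(model, diagnostics)`: diagnostics hold the monotone cost
#'   `trace`, `iterations`, `converged`, final `gradient_norm` and relative
#'   fit errors per modality.
#' @export
cmtf_fit <- function(X, Y, basis, R = init$R, Q = 1, init,
                     weights = default_cmtf_weights(X, Y),
                     max_iter = 1000, tol = 1e-8, eps = 1e-9,
                     segment = 100) {
  A <- tensor_data(X); Ym <- matrix_data(Y)
  if (!all(is.finite(A)) || !all(is.finite(Ym))) {
    stop("validation error: inputs must be finite")
  }
  if (nrow(Ym) != dim(A)[1]) stop("X and Y must share the time dimension")
  stopifnot(inherits(init, "cpd_factors"), init$R == R)

  model0 <- cmtf_init_model(init, X, Ym, basis, Q, weights)
  d <- cmtf_dims(model0)
  ev <- make_cmtf_evaluator(X, Ym, basis, d, weights, eps = eps)
  par <- pack_params(model0)
  J0 <- ev$fn(par)
  trace <- J0

  if (max_iter > 0) {
    iters <- 0L
    converged <- FALSE
    factr <- max(tol / .Machine$double.eps, 10)
    while (iters < max_iter) {
      step <- min(segment, max_iter - iters)
      opt <- stats::optim(par, ev$fn, ev$gr, method = "L-BFGS-B",
                          control = list(maxit = step, factr = factr))
      par <- opt$par
      iters <- iters + step
      J <- opt$value
      prev <- trace[length(trace)]
      trace <- c(trace, J)
      if (J > 10 * J0 + 1e-12) stop("optimization error: cost diverged")
      if (prev > 0 && abs(prev - J) / prev < tol) {
        converged <- TRUE
        break
      }
    }
  } else {
    iters <- 0L
    converged <- FALSE
  }

  det <- ev$detail(par)
  m <- unpack_params(par, d)
  model <- cmtf_model(m$S, m$F, m$C, m$V, m$B, m$N, m$P, weights, basis)
  list(
    model = model,
    diagnostics = list(
      trace = trace,
      iterations = iters,
      converged = converged,
      gradient_norm = fnorm(det$grad),
      rel_error_x = sqrt(max(det$fitX, 0) / ssq(A)),
      rel_error_y = sqrt(max(det$fitY, 0) / ssq(Ym))
    )
  )
}

#' Canonicalize a fitted CMTF model
#'
#' Scales each `F` and `C` column to unit 2-norm, absorbing the scale
#' `alpha_r = ||f_r|| * ||c_r||` into the shared temporal signature `S`,
#' and dividing the ROI signature `v_r` by the same `alpha_r` so the fMRI
#' reconstruction (which also contains `S`) is preserved. The sign is fixed
#' so the largest-magnitude entry of each `F` column is positive
#' (compensated in `C`). Both reconstructions are unchanged. `V` itself is
#' not forced to unit norm — its scale is tied to `S` through the coupling,
#' and clustering uses cosine similarity, which is scale-free.
#'
#' @param model A [cmtf_model()].
#' @return Equivalent canonical `cmtf_model`; zero columns are left
#'   unchanged and flagged in `attr(, "zero_columns")`.
#' @export
normalize_model <- function(model) {
  S <- model$S; F_ <- model$F; C_ <- model$C; V <- model$V
  zero <- integer(0)
  for (r in seq_len(model$R)) {
    nf <- sqrt(ssq(F_[, r])); nc_ <- sqrt(ssq(C_[, r]))
    if (nf == 0 || nc_ == 0) {
      zero <- c(zero, r)
      next
    }
    F_[, r] <- F_[, r] / nf
    C_[, r] <- C_[, r] / nc_
    S[, r] <- S[, r] * nf * nc_
    V[, r] <- V[, r] / (nf * nc_)    # compensates S so Yhat is unchanged
    # sign convention: dominant entry of the spectral signature positive
    if (F_[which.max(abs(F_[, r])), r] < 0) {
      F_[, r] <- -F_[, r]
      C_[, r] <- -C_[, r]
    }
  }
  out <- cmtf_model(S, F_, C_, V, model$B, model$N, model$P,
                    model$weights, model$basis)
  attr(out, "zero_columns") <- zero
  out
}

#' Run an ensemble of CMTF fits from random initializations
#'
#' For each run: a fresh seeded random CP initialization, a CP fit of the
#' EEG tensor, then a CMTF fit of both modalities; the fitted model is
#' canonicalized with [normalize_model()]. Individual run failures are
#' skipped and logged.
#'
#' @inheritParams cmtf_fit
#' @param n_runs Number of runs (the study protocol uses 50).
#' @param seed Base seed; run `i` initializes with `seed + i`.
#' @param cpd_max_iter,cpd_tol CP-stage controls.
#' @param cmtf_max_iter,cmtf_tol CMTF-stage controls.
#' @return List of per-run lists `(model, diagnostics, seed)`; failed runs
#'   are dropped, with the count in `attr(, "n_failed")`.
#' @export
run_ensemble <- function(X, Y, basis, R, Q = 1, n_runs = 50,
                         weights = default_cmtf_weights(X, Y), seed = 1L,
                         cpd_max_iter = 500, cpd_tol = 1e-8,
                         cmtf_max_iter = 1000, cmtf_tol = 1e-8) {
  stopifnot(n_runs >= 1)
  d <- dim(tensor_data(X))
  out <- list()
  n_failed <- 0L
  for (i in seq_len(n_runs)) {
    run_seed <- seed + i
    res <- tryCatch({
      init <- random_init(d, R, seed = run_seed)
      cp <- cpd_fit(X, R, init = init, max_iter = cpd_max_iter, tol = cpd_tol)
      fit <- cmtf_fit(X, Y, basis, R = R, Q = Q, init = cp$factors,
                      weights = weights, max_iter = cmtf_max_iter,
                      tol = cmtf_tol)
      fit$model <- normalize_model(fit$model)
      fit$seed <- run_seed
      fit
    }, error = function(e) {
      message(sprintf("ensemble run %d (seed %d) failed: %s",
                      i, run_seed, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else out[[length(out) + 1L]] <- res
  }
  attr(out, "n_failed") <- n_failed
  out
}
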