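# Canonical polyadic decomposition of the EEG tensor. The CPD is both the
# initializer of the coupled factorization and the basis of the core
# consistency diagnostic. Fitting is alternating least squares on the
# Frobenius objective with ridge-stabilised normal equations; the full cost
# trace is exposed so convergence can be audited.

#' Random CP factor initialization
#'
#' Standard-normal factor matrices drawn from one seeded generator.
#'
#' @param dims Integer vector `(Is, If, Ic)`.
#' @param R Number of components.
#' @param seed Integer seed.
#' @return Object of class `cpd_factors` with `S`, `F`, `C`.
#' @export
random_init <- function(dims, R, seed = 1L) {
  stopifnot(length(dims) == 3L, R >= 1)
  with_seed(seed, {
    cpd_factors(
      S = matrix(stats::rnorm(dims[1] * R), dims[1], R),
      F = matrix(stats::rnorm(dims[2] * R), dims[2], R),
      C = matrix(stats::rnorm(dims[3] * R), dims[3], R)
    )
  })
}

#' Construct a `cpd_factors` object
#'
#' @param S,F,C Factor matrices (time x R, frequency x R, channel x R) with
#'   a common number of columns; amplitude is absorbed into `S`.
#' @return Object of class `cpd_factors`.
#' @export
cpd_factors <- function(S, F, C) {
  R <- ncol(S)
  if (ncol(F) != R || ncol(C) != R) stop("factor matrices must share R columns")
  structure(list(S = S, F = F, C = C, R = R), class = "cpd_factors")
}

#' @export
print.cpd_factors <- function(x, ...) {
  cat(sprintf("<cpd_factors> R = %d, dims (%d, %d, %d)\n",
              x$R, nrow(x$S), nrow(x$F), nrow(x$C)))
  invisible(x)
}

#' Reconstruct a tensor from CP factors
#'
#' `Xhat[t, f, c] = sum_r S[t, r] F[f, r] C[c, r]`.
#'
#' @param factors A [cpd_factors()] object.
#' @return 3-d array.
#' @export
cpd_reconstruct <- function(factors) {
  d <- c(nrow(factors$S), nrow(factors$F), nrow(factors$C))
  fold(factors$S %*% t(khatri_rao(factors$C, factors$F)), 1L, d)
}

#' Fit a CP decomposition by alternating least squares
#'
#' Minimizes `||X - [[S, F, C]]||_F^2`. Each mode update solves the
#' ridge-stabilised normal equations of the matricized problem. Iteration
#' stops at `max_iter` or when the relative cost update drops below `tol`.
#'
#' @param X An [eeg_tensor()] or 3-d array.
#' @param R Number of components.
#' @param init A [cpd_factors()] initialization (e.g. [random_init()]).
#' @param max_iter Maximum ALS sweeps (default 2000).
#' @param tol Relative cost-update tolerance (default 1e-8).
#' @param ridge Ridge added to the normal equations for degenerate modes.
#' @return List `(factors, diagnostics)`; diagnostics hold `trace` (cost per
#'   accepted iterate), `iterations`, `converged`, `rel_error`
#'   (`||X - Xhat||_F / ||X||_F`).
#' @export
cpd_fit <- function(X, R, init = NULL, max_iter = 2000, tol = 1e-8,
                    ridge = 1e-12) {
  A <- tensor_data(X)
  if (!all(is.finite(A))) stop("validation error: tensor entries must be finite")
  d <- dim(A)
  if (is.null(init)) init <- random_init(d, R, seed = 1L)
  stopifnot(inherits(init, "cpd_factors"), init$R == R)
  S <- init$S; F_ <- init$F; C_ <- init$C
  X1 <- unfold(A, 1L); X2 <- unfold(A, 2L); X3 <- unfold(A, 3L)
  nX2 <- ssq(A)

  solve_mode <- function(M, G) {
    # M = Xn %*% khatri_rao pair, G = Gram product of the other two modes
    diag(G) <- diag(G) + ridge * max(diag(G), 1)
    t(solve(G, t(M)))
  }
  # ||X - Xhat||^2 via the Gram identity (no dense reconstruction)
  cost_from <- function(A, M, G) nX2 - 2 * sum(A * M) + sum(crossprod(A) * G)

  trace <- cost_from(S, X1 %*% khatri_rao(C_, F_),
                     crossprod(C_) * crossprod(F_))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S  <- solve_mode(X1 %*% khatri_rao(C_, F_), crossprod(C_) * crossprod(F_))
    F_ <- solve_mode(X2 %*% khatri_rao(C_, S), crossprod(C_) * crossprod(S))
    M3 <- X3 %*% khatri_rao(F_, S)
    G3 <- crossprod(F_) * crossprod(S)
    C_ <- solve_mode(M3, G3)
    J <- max(cost_from(C_, M3, G3), 0)
    trace <- c(trace, J)
    prev <- trace[length(trace) - 1L]
    if (J <= 1e-14 * nX2 || (prev > 0 && abs(prev - J) / prev < tol)) {
      converged <- TRUE
      break
    }
  }
  factors <- cpd_factors(S, F_, C_)
  list(
    factors = factors,
    diagnostics = list(
      trace = trace,
      iterations = it,
      converged = converged,
      rel_error = sqrt(trace[length(trace)] / nX2)
    )
  )
}

#' Best-of-n CP fit from random initializations
#'
#' Runs [cpd_fit()] from `n_starts` seeded random initializations and keeps
#' the lowest-cost solution.
#'
#' @inheritParams cpd_fit
#' @param n_starts Number of random starts.
#' @param seed Base seed; start `i` uses `seed + i`.
#' @return As [cpd_fit()], plus `diagnostics$start_costs`.
#' @export
cpd_fit_multi <- function(X, R, n_starts = 10, seed = 1L, max_iter = 2000,
                          tol = 1e-8) {
  best <- NULL
  costs <- numeric(n_starts)
  d <- dim(tensor_data(X))
  for (i in seq_len(n_starts)) {
    fit <- cpd_fit(X, R, init = random_init(d, R, seed = seed + i),
                   max_iter = max_iter, tol = tol)
    costs[i] <- utils::tail(fit$diagnostics$trace, 1)
    if (is.null(best) || costs[i] < utils::tail(best$diagnostics$trace, 1)) {
      best <- fit
    }
  }
  best$diagnostics$start_costs <- costs
  best
}

#' Factor match score between two CP factor sets
#'
#' Permutation-, sign- and scale-invariant similarity: the maximum over
#' component permutations of the mean over components of the product across
#' modes of the absolute cosine similarity of paired columns.
#'
#' @param a,b [cpd_factors()] objects with equal dims and R.
#' @return Score in `[0, 1]` (1 = identical up to permutation/sign/scale).
#' @export
factor_match_score <- function(a, b) {
  if (a$R != b$R) stop("factor sets must share R")
  R <- a$R
  # pairwise per-component similarity matrix: product of |cos| across modes
  sim <- matrix(1, R, R)
  for (m in c("S", "F", "C")) {
    A <- unit_cols(a[[m]]); B <- unit_cols(b[[m]])
    sim <- sim * abs(crossprod(A, B))
  }
  best <- 0
  for (p in all_perms(R)) {
    sc <- mean(sim[cbind(seq_len(R), p)])
    if (sc > best) best <- sc
  }
  best
}
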