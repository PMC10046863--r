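# Internal helpers: tensor algebra primitives and RNG discipline shared by
# every module. All tensors are plain base-R 3-d arrays in column-major order.

#' @keywords internal
"_PACKAGE"

## ---- RNG ------------------------------------------------------------------

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
# Every public generator routes its randomness through this so that a fixed
# seed gives bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## ---- small numerics -------------------------------------------------------

ssq <- function(x) sum(x * x)

fnorm <- function(x) sqrt(ssq(x))

relerr <- function(est, ref) fnorm(est - ref) / fnorm(ref)

# |cosine| between two vectors; 0 if either is the zero vector.
abs_cosine <- function(a, b) {
  na <- sqrt(ssq(a)); nb <- sqrt(ssq(b))
  if (na == 0 || nb == 0) return(0)
  abs(sum(a * b)) / (na * nb)
}

## ---- tensor algebra -------------------------------------------------------

# Khatri-Rao (column-wise Kronecker) product. Row index of the result runs
# with B's row fastest: kr(A, B)[(i-1)*J + j, r] = A[i, r] * B[j, r].
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  I <- nrow(A); J <- nrow(B)
  A[rep(seq_len(I), each = J), , drop = FALSE] *
    B[rep(seq_len(J), times = I), , drop = FALSE]
}

# Mode-n unfolding of a 3-d array, Kolda-Bader convention: the remaining
# modes index columns with the lower-numbered mode varying fastest.
unfold <- function(X, mode) {
  d <- dim(X)
  stopifnot(length(d) == 3L, mode %in% 1:3)
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  Xp <- aperm(X, perm)
  dim(Xp) <- c(d[mode], prod(d[-mode]))
  Xp
}

# Inverse of unfold(): rebuild the 3-d array of dimensions `d` from its
# mode-n unfolding.
fold <- function(M, mode, d) {
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(2L, 3L, 1L))
  dims <- switch(mode, `1` = d, `2` = d[c(2L, 1L, 3L)], `3` = d[c(3L, 1L, 2L)])
  dim(M) <- dims
  aperm(M, perm)
}

# Ridge-stabilised pseudo-inverse via SVD. Singular values below
# `tol * max(sv)` are damped rather than dropped so near-rank-deficient
# factor sets still yield a usable least-squares core.
pinv_ridge <- function(A, ridge = 1e-12) {
  sv <- svd(A)
  d <- sv$d
  if (length(d) == 0L) return(t(A))
  dmax <- max(d)
  small <- d < dmax * 1e-10
  if (any(small)) {
    warning("rank-deficient matrix in pseudo-inverse; ridge applied")
  }
  dinv <- d / (d * d + ridge * dmax * dmax)
  sv$v %*% (dinv * t(sv$u))
}

# All permutations of 1..n (n small; used for component matching).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Normalise matrix columns to unit 2-norm; zero columns pass through.
unit_cols <- function(M) {
  nrm <- sqrt(colSums(M * M))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}
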