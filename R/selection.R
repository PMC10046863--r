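# Model selection. For each candidate number of components R, an ensemble of
# randomly initialized fits is summarized by four indicators: core
# consistency of the EEG factors (CORCONDIA), reproducibility of components
# under graph-structured clustering, similarity of the temporal signature to
# the stimulus timecourse, and permutation-based significance of the spatial
# signature with familywise error control.

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computes the least-squares Tucker core `G` of the tensor given the three
#' factor matrices (via ridge-stabilised pseudo-inverses) and measures its
#' distance from the superdiagonal identity core `I`:
#' `100 * (1 - sum((G - I)^2) / R)`. 100 indicates ideal CP structure; the
#' value can be negative. Invariant to component permutation and to column
#' rescaling with compensating weights.
#'
#' @param X An [eeg_tensor()] or 3-d array.
#' @param factors A [cpd_factors()] object (or any list with `S`, `F`, `C`).
#' @param ridge Ridge for near-rank-deficient factor sets.
#' @return Percentage (scalar), at most 100.
#' @export
corcondia <- function(X, factors, ridge = 1e-12) {
  A <- tensor_data(X)
  S <- factors$S; F_ <- factors$F; C_ <- factors$C
  R <- ncol(S)
  stopifnot(dim(A)[1] == nrow(S), dim(A)[2] == nrow(F_), dim(A)[3] == nrow(C_))
  G1 <- pinv_ridge(S, ridge) %*% unfold(A, 1L)
  T1 <- fold(G1, 1L, c(R, dim(A)[2], dim(A)[3]))
  G2 <- pinv_ridge(F_, ridge) %*% unfold(T1, 2L)
  T2 <- fold(G2, 2L, c(R, R, dim(A)[3]))
  G3 <- pinv_ridge(C_, ridge) %*% unfold(T2, 3L)
  G <- fold(G3, 3L, c(R, R, R))
  I_core <- array(0, dim = c(R, R, R))
  I_core[cbind(seq_len(R), seq_len(R), seq_len(R))] <- 1
  100 * (1 - ssq(G - I_core) / R)
}

#' Similarity between two components' signature sets
#'
#' Product over available modes of the absolute cosine similarity of the
#' paired signatures; sign- and scale-invariant. A zero vector contributes
#' 0.
#'
#' @param a,b Lists with any of `s`, `f`, `c`, `v` (numeric vectors); only
#'   modes present in both contribute.
#' @return Score in `[0, 1]`.
#' @export
component_similarity <- function(a, b) {
  modes <- intersect(intersect(names(a), names(b)), c("s", "f", "c", "v"))
  if (length(modes) == 0) stop("no common signature modes")
  out <- 1
  for (m in modes) {
    if (length(a[[m]]) != length(b[[m]])) stop("signature length mismatch")
    out <- out * abs_cosine(a[[m]], b[[m]])
  }
  out
}

# Extract the signature list of component r of a normalized model.
component_signatures <- function(model, r) {
  list(s = model$S[, r], f = model$F[, r], c = model$C[, r], v = model$V[, r])
}

#' Graph-structured clustering of ensemble components
#'
#' Every component of every run is a graph node; edges connect pairs whose
#' [component_similarity()] is at least `threshold`; clusters are the
#' connected components. Each cluster's centroid is the member with maximal
#' summed similarity to the cluster; cardinality counts the distinct runs
#' represented. Clusters are sorted by cardinality, decreasing.
#'
#' @param ensemble A [run_ensemble()] result (list of fits with `$model`).
#' @param threshold Similarity cutoff in `[0, 1]` (default 0.9).
#' @return List of `component_cluster` objects: `members` (data.frame with
#'   `run`, `comp`), `centroid` (row index into `members`), `cardinality`.
#' @export
graph_cluster <- function(ensemble, threshold = 0.9) {
  stopifnot(length(ensemble) >= 1)
  runs <- integer(0); comps <- integer(0)
  mats <- list(s = NULL, f = NULL, c = NULL, v = NULL)
  for (i in seq_along(ensemble)) {
    m <- ensemble[[i]]$model
    for (r in seq_len(m$R)) {
      runs <- c(runs, i); comps <- c(comps, r)
    }
    mats$s <- cbind(mats$s, m$S); mats$f <- cbind(mats$f, m$F)
    mats$c <- cbind(mats$c, m$C); mats$v <- cbind(mats$v, m$V)
  }
  n <- length(runs)
  sim <- matrix(1, n, n)
  for (m in names(mats)) {
    sim <- sim * abs(crossprod(unit_cols(mats[[m]])))
  }
  adj <- sim >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  clusters <- lapply(sort(unique(memb)), function(cl) {
    idx <- which(memb == cl)
    within <- sim[idx, idx, drop = FALSE]
    centroid <- which.max(rowSums(within))
    structure(
      list(members = data.frame(run = runs[idx], comp = comps[idx]),
           centroid = centroid,
           cardinality = length(unique(runs[idx]))),
      class = "component_cluster"
    )
  })
  clusters[order(vapply(clusters, function(cl) cl$cardinality, numeric(1)),
                 decreasing = TRUE)]
}

#' @export
print.component_cluster <- function(x, ...) {
  cat(sprintf("<component_cluster> %d members from %d runs; centroid run %d comp %d\n",
              nrow(x$members), x$cardinality,
              x$members$run[x$centroid], x$members$comp[x$centroid]))
  invisible(x)
}

#' Retain reproducible clusters
#'
#' Keeps clusters whose cardinality (distinct runs) is strictly greater
#' than `min_cardinality` (study retention rule: greater than 10 of 50
#' runs). Idempotent.
#'
#' @param clusters A [graph_cluster()] result.
#' @param min_cardinality Strict lower bound (default 10).
#' @return Filtered list of clusters.
#' @export
reproducibility_filter <- function(clusters, min_cardinality = 10) {
  stopifnot(min_cardinality >= 1)
  Filter(function(cl) cl$cardinality > min_cardinality, clusters)
}

#' Similarity of a temporal signature to the stimulus timecourse
#'
#' Absolute Pearson correlation between the signature and the binary
#' paradigm vector (absolute value because factor signs are indeterminate).
#' The raw binary vector is the default comparison; optionally it can be
#' convolved with the canonical HRF first (useful when the signature being
#' scored lives on the BOLD rather than the neural time scale).
#'
#' @param s Numeric temporal signature.
#' @param stim A [generate_stimulus_timecourse()] object or binary vector
#'   of the same length.
#' @param convolve If `TRUE`, convolve the stimulus with `h_1` of `basis`
#'   before correlating (default `FALSE`).
#' @param basis HRF basis used when `convolve = TRUE`.
#' @return Value in `[0, 1]`.
#' @export
stimulus_similarity <- function(s, stim, convolve = FALSE, basis = NULL) {
  v <- if (inherits(stim, "stimulus_timecourse")) stim$values else stim
  if (length(s) != length(v)) stop("signature and stimulus length differ")
  if (convolve) {
    if (is.null(basis)) basis <- build_hrf_basis(K = 1, TR = 2)
    v <- make_convolution_operator(basis, 1, length(v))$apply(as.numeric(v))
  }
  if (stats::sd(s) == 0 || stats::sd(v) == 0) {
    stop("undefined correlation for a constant input")
  }
  abs(stats::cor(s, v))
}

#' Permutation-based significance of a spatial signature (SnPM)
#'
#' For component `r`, each ROI's regressor is the model-implied coupled
#' time course `sum_k B[v, k] (H_k s_r)[t]`; the observed statistic is the
#' absolute t statistic of the simple regression of `Y[, v]` on that
#' regressor. The null distribution of the maximum statistic over ROIs is
#' built by circularly shifting the regressors by a random offset per
#' permutation; the familywise-error threshold is the `(1 - alpha)`
#' quantile of the null maxima (observed maximum included), and ROIs
#' strictly exceeding it are significant.
#'
#' @param model A [cmtf_model()].
#' @param Y A [roi_matrix()] or matrix.
#' @param r Component index.
#' @param alpha FWE level (default 0.05); `alpha = 1` marks every ROI.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutation offsets.
#' @param basis HRF basis (defaults to the model's).
#' @return List with `stat` (per-ROI), `threshold`, `significant` (ROI
#'   indices), `max_stat`, `null_max`, `alpha`, `n_perm`.
#' @export
snpm_significance <- function(model, Y, r, alpha = 0.05, n_perm = 999,
                              seed = 1L, basis = model$basis) {
  Ym <- matrix_data(Y)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (r < 1 || r > model$R) stop("component index out of range")
  s <- model$S[, r]
  if (stats::sd(s) == 0) stop("degenerate (constant) temporal signature")
  Is <- length(s); Iv <- ncol(Ym)
  Hmats <- conv_matrices(basis, Is)
  Zs <- vapply(Hmats, function(H) as.numeric(H %*% s), numeric(Is))  # Is x K
  Xreg <- Zs %*% t(model$B)                                           # Is x Iv

  tstat <- function(Xr) {
    xc <- sweep(Xr, 2, colMeans(Xr))
    yc <- sweep(Ym, 2, colMeans(Ym))
    Sxx <- colSums(xc^2); Sxy <- colSums(xc * yc); Syy <- colSums(yc^2)
    denom <- Sxx * Syy - Sxy^2
    out <- abs(Sxy) * sqrt(pmax(Is - 2, 1)) / sqrt(pmax(denom, 0))
    out[Sxx <= 0 | denom <= 0] <- 0
    out
  }

  stat <- tstat(Xreg)
  null_max <- with_seed(seed, {
    offs <- sample.int(Is - 1L, n_perm, replace = TRUE)
    vapply(offs, function(o) {
      max(tstat(Xreg[c((o + 1L):Is, 1L:o), , drop = FALSE]))
    }, numeric(1))
  })
  maxdist <- c(max(stat), null_max)
  k <- ceiling((1 - alpha) * length(maxdist))
  threshold <- if (k < 1) -Inf else sort(maxdist)[k]
  list(stat = stat, threshold = threshold,
       significant = which(stat > threshold),
       max_stat = max(stat), null_max = null_max,
       alpha = alpha, n_perm = n_perm)
}

#' Score one candidate number of components from its ensemble
#'
#' Clusters the ensemble, applies the reproducibility filter, scores every
#' cluster centroid's similarity to the stimulus, and evaluates CORCONDIA
#' and the SnPM on the model containing the best-similarity centroid.
#'
#' @param X EEG tensor; @param Y ROI matrix.
#' @param ensemble A [run_ensemble()] result for this `R`.
#' @param stim Stimulus timecourse.
#' @param threshold Clustering similarity cutoff.
#' @param min_cardinality Reproducibility retention bound (strict).
#' @param alpha,n_perm,seed SnPM controls (`n_perm = 0` skips the SnPM).
#' @return `cmtf_candidate_report`: list with `R`, `corcondia`, `clusters`,
#'   `retained`, `best` (run, comp, similarity, cardinality, retained),
#'   `snpm`, `model` (the representative fitted model).
#' @export
evaluate_candidate <- function(X, Y, ensemble, stim, threshold = 0.9,
                               min_cardinality = 10, alpha = 0.05,
                               n_perm = 499, seed = 1L) {
  stopifnot(length(ensemble) >= 1)
  R <- ensemble[[1]]$model$R
  clusters <- graph_cluster(ensemble, threshold)
  retained <- reproducibility_filter(clusters, min_cardinality)

  cent_sim <- vapply(clusters, function(cl) {
    i <- cl$members$run[cl$centroid]; r <- cl$members$comp[cl$centroid]
    stimulus_similarity(ensemble[[i]]$model$S[, r], stim)
  }, numeric(1))
  best_idx <- which.max(cent_sim)
  bc <- clusters[[best_idx]]
  best <- list(
    run = bc$members$run[bc$centroid],
    comp = bc$members$comp[bc$centroid],
    similarity = cent_sim[best_idx],
    cardinality = bc$cardinality,
    retained = bc$cardinality > min_cardinality
  )
  model <- ensemble[[best$run]]$model
  cc <- corcondia(X, cpd_factors(model$S, model$F, model$C))
  snpm <- if (n_perm > 0) {
    snpm_significance(model, Y, best$comp, alpha = alpha, n_perm = n_perm,
                      seed = seed)
  } else NULL
  structure(
    list(R = R, corcondia = cc, clusters = clusters, retained = retained,
         centroid_similarities = cent_sim, best = best, snpm = snpm,
         model = model),
    class = "cmtf_candidate_report"
  )
}

#' @export
print.cmtf_candidate_report <- function(x, ...) {
  cat(sprintf(
    "<cmtf_candidate_report> R = %d: CORCONDIA %.1f%%, %d clusters (%d retained), best similarity %.3f (cardinality %d)\n",
    x$R, x$corcondia, length(x$clusters), length(x$retained),
    x$best$similarity, x$best$cardinality
  ))
  invisible(x)
}

#' Select the number of components and the stimulus-related component
#'
#' Deterministic gate-then-maximize rule: a candidate R is eligible when
#' its CORCONDIA is at least `corcondia_min` (study guideline: below 80%
#' indicates an inappropriate model) and its best-similarity component
#' survives the reproducibility filter. Among eligible candidates the one
#' with the highest stimulus similarity wins; ties go to the smaller R. If
#' none is eligible, the candidate with the highest similarity is returned
#' flagged `no_eligible_model`.
#'
#' @param reports List of [evaluate_candidate()] results (one per R).
#' @param corcondia_min Eligibility threshold in percent (default 80).
#' @return `model_selection_report`: `chosen_R`, `chosen_component` (run,
#'   comp within the representative model), `no_eligible_model` flag, and a
#'   per-R scoring `trace` data.frame.
#' @export
select_best_model <- function(reports, corcondia_min = 80) {
  if (length(reports) == 0) stop("no candidate reports")
  trace <- do.call(rbind, lapply(reports, function(rep) {
    data.frame(
      R = rep$R,
      corcondia = rep$corcondia,
      best_similarity = rep$best$similarity,
      best_cardinality = rep$best$cardinality,
      retained = rep$best$retained,
      eligible = rep$corcondia >= corcondia_min && rep$best$retained
    )
  }))
  pool <- if (any(trace$eligible)) which(trace$eligible) else seq_len(nrow(trace))
  sims <- trace$best_similarity[pool]
  # maximize similarity; ties broken toward smaller R (trace is in input
  # order, so order by similarity then -R)
  ord <- pool[order(-sims, trace$R[pool])]
  pick <- ord[1]
  chosen <- reports[[pick]]
  structure(
    list(chosen_R = chosen$R,
         chosen_component = list(run = chosen$best$run, comp = chosen$best$comp),
         chosen_report = chosen,
         no_eligible_model = !any(trace$eligible),
         trace = trace),
    class = "model_selection_report"
  )
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("<model_selection_report> chosen R = %d (component %d of run %d)%s\n",
              x$chosen_R, x$chosen_component$comp, x$chosen_component$run,
              if (x$no_eligible_model) " [no eligible model]" else ""))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
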