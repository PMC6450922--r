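#' Fisher z-transformation with clipping at |r| = 1
#'
#' z = atanh(r), with r clipped into [-1 + eps, 1 - eps] (eps = 1e-7) so
#' perfectly correlated pairs map to a large finite value (about 8.4) rather
#' than infinity; downstream cosine similarities then stay finite.
#'
#' @param r Correlation value(s) in [-1, 1].
#' @param eps Clip margin (default 1e-7).
#' @return z value(s), finite.
#' @export
#' @examples
#' fisher_z(c(0, 0.5, 1))
fisher_z <- function(r, eps = 1e-7) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("correlations must be finite with |r| <= 1", call. = FALSE)
  }
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Static Pearson functional connectivity
#'
#' Pairwise Pearson correlation over the full run, Fisher z-transformed
#' element-wise, zero diagonal.
#'
#' @param ts An `fp_timeseries` with T >= 3 and no constant column.
#' @return An `fp_fc` with `method_tag = "pearson_sfc"`.
#' @export
pearson_sfc <- function(ts) {
  stopifnot(inherits(ts, "fp_timeseries"))
  x <- unclass(ts)
  if (nrow(x) < 3L) stop("Pearson sFC needs T >= 3", call. = FALSE)
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance node(s): ",
         paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  z <- fisher_z(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # kill numeric asymmetry from atanh rounding
  fp_fc(z, method_tag = "pearson_sfc", node_ids = colnames(x))
}

#' Static partial-correlation functional connectivity
#'
#' Partial correlations from the inverse of the (unbiased) sample
#' covariance: with precision P = Sigma^-1, the edge (i, j) is
#' -P_ij / sqrt(P_ii P_jj), Fisher z-transformed. Estimates the direct
#' connection between two nodes conditioning on all others, which is what
#' makes it robust to the indirect correlations that inflate Pearson FC.
#'
#' @param ts An `fp_timeseries`; requires T > n and a well-conditioned
#'   covariance (condition number below `max_condition`).
#' @param ridge Optional ridge term added to the covariance diagonal
#'   (fraction of the mean diagonal; default 0 = plain inversion).
#' @param max_condition Condition-number ceiling (default 1e12).
#' @return An `fp_fc` with `method_tag = "partial_sfc"`.
#' @export
partial_sfc <- function(ts, ridge = 0, max_condition = 1e12) {
  stopifnot(inherits(ts, "fp_timeseries"))
  x <- unclass(ts)
  T_ <- nrow(x); n <- ncol(x)
  if (T_ <= n) {
    stop("partial correlation needs more time points than nodes (T > n); ",
         "got T = ", T_, ", n = ", n,
         " - use a longer series or fewer nodes", call. = FALSE)
  }
  S <- stats::cov(x)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), n)
  kap <- kappa(S, exact = FALSE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("sample covariance is (near-)singular (condition ~ ",
         format(kap, digits = 3),
         "); use a longer series, fewer nodes, or ridge > 0", call. = FALSE)
  }
  P <- solve(S)
  d <- 1 / sqrt(diag(P))
  r <- -P * outer(d, d)
  diag(r) <- 0
  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -1), 1)
  z <- fisher_z(r)
  diag(z) <- 0
  fp_fc(z, method_tag = "partial_sfc", node_ids = colnames(x))
}

#' Sliding-window configuration for dynamic FC
#'
#' Defaults match the 3T analysis: window 85 samples (61.2 s at TR = 0.72 s,
#' i.e. 1/f_min of the band-pass), step 5 samples (3.6 s), K = 4 states.
#'
#' @param window_tr Window length in samples (positive integer).
#' @param step_tr Step between window starts in samples (default 5).
#' @param n_states Number of K-means states K (default 4).
#' @param seed Integer seed for the clustering.
#' @param n_restarts K-means restarts; best fit by total within-cluster sum
#'   of squares is kept (default 10).
#' @param max_iter,tol Lloyd iteration cap and relative tolerance.
#' @return A `dfc_config` list.
#' @export
dfc_config <- function(window_tr = 85L, step_tr = 5L, n_states = 4L,
                       seed = 1L, n_restarts = 10L, max_iter = 300L,
                       tol = 1e-6) {
  if (window_tr < 2L) stop("window_tr must be >= 2 samples", call. = FALSE)
  if (step_tr < 1L) stop("step_tr must be >= 1", call. = FALSE)
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  structure(list(window_tr = as.integer(window_tr),
                 step_tr = as.integer(step_tr),
                 n_states = as.integer(n_states), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "dfc_config")
}

#' Windowed Pearson FC vectors
#'
#' Z-scores each node's series over the run, slides a window of
#' `cfg$window_tr` samples in steps of `cfg$step_tr` (a window is used iff
#' it fits entirely, so the count is floor((T - w)/step) + 1), computes
#' Pearson correlation within each window, Fisher z-transforms, and
#' vectorizes the upper triangle.
#'
#' @param ts An `fp_timeseries`.
#' @param cfg A [dfc_config()]; `window_tr` must not exceed T.
#' @return A numeric matrix, windows x edges, with attributes `starts`
#'   (first sample of each window), `n_nodes`, `node_ids`.
#' @export
#' @examples
#' n_windows(1200, 85, 5) # 224
sliding_windows <- function(ts, cfg = dfc_config()) {
  stopifnot(inherits(ts, "fp_timeseries"), inherits(cfg, "dfc_config"))
  x <- unclass(ts)
  T_ <- nrow(x)
  w <- cfg$window_tr
  if (w > T_) {
    stop("window (", w, " samples) exceeds run length T = ", T_,
         call. = FALSE)
  }
  x <- scale(x)  # per-run z-score; Pearson within windows is unaffected
  starts <- seq.int(1L, T_ - w + 1L, by = cfg$step_tr)
  vecs <- vapply(starts, function(s) {
    r <- stats::cor(x[s:(s + w - 1L), , drop = FALSE])
    z <- fisher_z(r)
    diag(z) <- 0
    z <- (z + t(z)) / 2
    as.numeric(vectorize_upper(fp_fc(z, "dfc_state", colnames(x))))
  }, numeric(n_edges(ncol(x))))
  out <- t(vecs)
  structure(out, starts = starts, n_nodes = ncol(x),
            node_ids = colnames(x))
}

#' Window count for a sliding-window analysis
#'
#' @param T_ Run length in samples.
#' @param window_tr,step_tr Window and step in samples.
#' @return floor((T - window)/step) + 1.
#' @export
n_windows <- function(T_, window_tr, step_tr) {
  if (window_tr > T_) stop("window exceeds run length", call. = FALSE)
  as.integer((T_ - window_tr) %/% step_tr + 1L)
}

#' K-means state extraction from windowed FC vectors
#'
#' Clusters window vectors with K-means (squared Euclidean, seeded, best of
#' `n_restarts` by within-cluster sum of squares), then orders the K states
#' by occupancy, descending; occupancy ties are broken by the first window
#' index assigned to the state. Should a restart produce an empty cluster,
#' that centroid is re-seeded at the point farthest from its nearest
#' centroid and the restart is repeated.
#'
#' @param windows A windows x edges matrix from [sliding_windows()] (rows
#'   from several runs may be stacked before calling).
#' @param cfg A [dfc_config()]; `n_states` must not exceed the window count.
#' @return A `dynamic_states` object: list with `states` (list of K
#'   `fp_fc` centroids, Fisher-z units), `counts` (occupancies, descending),
#'   `assignments` (per-window state index after reordering), `tot_withinss`.
#' @export
cluster_states <- function(windows, cfg = dfc_config()) {
  stopifnot(inherits(cfg, "dfc_config"))
  W <- as.matrix(windows)
  K <- cfg$n_states
  if (K > nrow(W)) {
    stop("K = ", K, " states but only ", nrow(W), " windows", call. = FALSE)
  }
  node_ids <- attr(windows, "node_ids")
  fit <- withr::with_seed(cfg$seed, kmeans_best(W, K, cfg))
  ord <- order(-fit$size, fit$first_window)
  counts <- fit$size[ord]
  relabel <- match(seq_len(K), ord)
  assignments <- relabel[fit$cluster]
  states <- lapply(ord, function(k)
    devectorize(fit$centers[k, ], method_tag = "dfc_state",
                node_ids = node_ids))
  structure(list(states = states, counts = as.integer(counts),
                 assignments = as.integer(assignments),
                 tot_withinss = fit$tot_withinss),
            class = "dynamic_states")
}

# best-of-n_restarts Lloyd k-means; empty clusters re-seeded at the point
# farthest from its nearest centroid (then that restart is rerun)
kmeans_best <- function(W, K, cfg) {
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    centers <- W[sample.int(nrow(W), K), , drop = FALSE]
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(W, centers = centers,
                                       iter.max = cfg$max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && !any(fit$size == 0L)) break
      # re-seed: greedy farthest-point init replaces the failed draw
      centers <- farthest_point_init(W, K)
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot_withinss) {
      best <- list(cluster = fit$cluster, centers = fit$centers,
                   size = fit$size, tot_withinss = fit$tot.withinss,
                   first_window = vapply(seq_len(K), function(k)
                     which(fit$cluster == k)[1L], integer(1)))
    }
  }
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  best
}

farthest_point_init <- function(W, K) {
  idx <- sample.int(nrow(W), 1L)
  d2 <- rowSums(sweep(W, 2L, W[idx, ])^2)
  while (length(idx) < K) {
    nxt <- which.max(d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(W, 2L, W[nxt, ])^2))
  }
  W[idx, , drop = FALSE]
}

#' Dynamic FC for one or more runs of a session
#'
#' Composition of [sliding_windows()] and [cluster_states()]. When several
#' runs of the same session are supplied, their window vectors are pooled
#' before a single clustering (averaging K centroid sets across runs is
#' ill-defined; pooling is the session-level analogue of run averaging).
#'
#' @param ts An `fp_timeseries` or a list of them (same nodes).
#' @param cfg A [dfc_config()].
#' @return A `dynamic_states`.
#' @export
dfc_for_run <- function(ts, cfg = dfc_config()) {
  runs <- if (inherits(ts, "fp_timeseries")) list(ts) else ts
  mats <- lapply(runs, sliding_windows, cfg = cfg)
  pooled <- do.call(rbind, mats)
  attr(pooled, "node_ids") <- attr(mats[[1L]], "node_ids")
  attr(pooled, "n_nodes") <- attr(mats[[1L]], "n_nodes")
  cluster_states(pooled, cfg)
}

#' @export
print.dynamic_states <- function(x, ...) {
  cat(sprintf("<dynamic_states> K=%d states over %d windows; counts: %s\n",
              length(x$states), sum(x$counts),
              paste(x$counts, collapse = ", ")))
  invisible(x)
}
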