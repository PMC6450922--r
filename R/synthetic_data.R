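#' Configuration for synthetic multi-subject cohorts
#'
#' Describes a cohort of N subjects scanned in `sessions` sessions of
#' `runs_per_session` runs each. Each run is a multivariate Gaussian time
#' series whose precision (inverse covariance) matrix is the sum of a
#' shared base network, a stable subject-specific fingerprint, a sex-group
#' component, and per-session jitter - so partial correlation sees the
#' direct connections while Pearson correlation also picks up the indirect
#' paths the base network induces. Defaults mirror a two-session,
#' two-run-per-session resting-state cohort on a 90-node, 14-network
#' parcellation at TR = 0.72 s.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes,n_networks Parcellation size (defaults 90 and 14).
#' @param t_per_run Time points per run (default 1200).
#' @param tr_seconds Sampling interval (default 0.72).
#' @param runs_per_session,sessions Cohort structure (defaults 2 and 2).
#' @param subject_effect Magnitude of the subject-specific precision
#'   perturbation (the fingerprint; default 0.8).
#' @param sex_effect Magnitude of the sex-group precision component
#'   (default 0).
#' @param session_noise SD of the dense per-session precision jitter
#'   (default 0.08).
#' @param fraction_subject_edges Fraction of node pairs carrying each
#'   subject's fingerprint (default 0.12).
#' @param fraction_sex_edges Fraction of node pairs carrying the sex
#'   component; disjoint from all subject edge sets (default 0.10).
#' @param between_density Probability that a between-network node pair gets
#'   a base-precision entry (default 0.05).
#' @param n_states Number of connectivity states (1 = static cohort; >= 2
#'   enables the Markov state-switching variant).
#' @param state_dwell Mean dwell time per state in samples (default 50).
#' @param ar_coef Optional AR(1) coefficient for temporally smooth
#'   innovations (default 0 = white).
#' @param fd_meanlog,fd_sdlog Log-normal parameters for per-subject mean
#'   framewise displacement in mm (defaults log(0.15) and 0.25).
#' @param fd_outliers,fd_outlier_scale Number of injected high-motion
#'   subjects and their multiplicative FD inflation (defaults 0 and 10).
#' @param seed Integer master seed; everything is deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects, n_nodes = 90L, n_networks = 14L,
                             t_per_run = 1200L, tr_seconds = 0.72,
                             runs_per_session = 2L, sessions = 2L,
                             subject_effect = 0.8, sex_effect = 0,
                             session_noise = 0.08,
                             fraction_subject_edges = 0.12,
                             fraction_sex_edges = 0.10,
                             between_density = 0.05,
                             n_states = 1L, state_dwell = 50L,
                             ar_coef = 0,
                             fd_meanlog = log(0.15), fd_sdlog = 0.25,
                             fd_outliers = 0L, fd_outlier_scale = 10,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_nodes >= 2, n_networks <= n_nodes,
            t_per_run >= 2, tr_seconds > 0, sessions >= 1,
            runs_per_session >= 1, subject_effect >= 0, sex_effect >= 0,
            session_noise >= 0, n_states >= 1, state_dwell >= 1,
            abs(ar_coef) < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Synthetic atlas of contiguous near-equal networks
#'
#' Nodes are split into `n_networks` contiguous blocks whose sizes differ
#' by at most 1 (90 nodes / 14 networks gives blocks of 6 and 7).
#'
#' @param n_nodes,n_networks Parcellation size.
#' @param seed Accepted for interface symmetry; the construction is
#'   deterministic.
#' @return An `fp_atlas`.
#' @export
#' @examples
#' table(make_atlas(90, 14)$network)
make_atlas <- function(n_nodes = 90L, n_networks = 14L, seed = 1L) {
  if (n_networks > n_nodes) {
    stop("more networks than nodes", call. = FALSE)
  }
  base <- n_nodes %/% n_networks
  extra <- n_nodes %% n_networks
  sizes <- rep(base, n_networks) + c(rep(1L, extra),
                                     rep(0L, n_networks - extra))
  nets <- sprintf("RSN%02d", seq_len(n_networks))
  fp_atlas(sprintf("roi_%03d", seq_len(n_nodes)), rep(nets, times = sizes))
}

# sub-seed derivation, kept inside 32-bit range
derive_seed <- function(seed, ...) {
  off <- sum(c(...) * (10007L^(seq_along(c(...)) - 1L))) %% 1000003L
  as.integer((as.numeric(seed) * 2017L + off) %% 2147483647L)
}

# fixed (seed-determined) cohort-level components, all on the edge scale:
# base off-diagonal vector, sex edge set + per-sex values, per-subject edge
# sets + values, and (state-switching variant) per-state base vectors
cohort_components <- function(config) {
  E <- n_edges(config$n_nodes)
  atlas <- make_atlas(config$n_nodes, config$n_networks)
  emap <- edge_index_map(atlas)
  withr::with_seed(derive_seed(config$seed, 1L), {
    base_off <- lapply(seq_len(max(1L, config$n_states)), function(st)
      draw_base_off(emap, config))
    n_sex <- max(1L, round(config$fraction_sex_edges * E))
    sex_edges <- sort(sample.int(E, n_sex))
    sex_values <- list(
      M = stats::runif(n_sex, 0.5, 1) * sample(c(-1, 1), n_sex, TRUE),
      F = stats::runif(n_sex, 0.5, 1) * sample(c(-1, 1), n_sex, TRUE))
    pool <- setdiff(seq_len(E), sex_edges)
    n_subj_edges <- max(1L, round(config$fraction_subject_edges * E))
    subject_edges <- vector("list", config$n_subjects)
    subject_values <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      subject_edges[[s]] <- sort(sample(pool, n_subj_edges))
      subject_values[[s]] <- stats::runif(n_subj_edges, 0.5, 1) *
        sample(c(-1, 1), n_subj_edges, TRUE)
    }
  })
  list(atlas = atlas, emap = emap, base_off = base_off,
       sex_edges = sex_edges, sex_values = sex_values,
       subject_edges = subject_edges, subject_values = subject_values)
}

# base precision off-diagonals: within-network pairs get mixed-sign
# magnitudes U(0.15, 0.3) (random sign per edge, so independent draws -
# e.g. distinct state templates - differ structurally, not just in
# magnitude); between-network pairs are sparse U(0.05, 0.15)
draw_base_off <- function(emap, config) {
  E <- nrow(emap)
  off <- numeric(E)
  w <- emap$within
  off[w] <- stats::runif(sum(w), 0.15, 0.3) *
    sample(c(-1, 1), sum(w), replace = TRUE)
  b <- !w & stats::runif(E) < config$between_density
  off[b] <- stats::runif(sum(b), 0.05, 0.15) * sample(c(-1, 1), sum(b), TRUE)
  off
}

# assemble an SPD precision matrix from an off-diagonal edge vector:
# diagonal dominance guarantees positive definiteness
precision_from_off <- function(off, n) {
  Om <- as.matrix(devectorize(off, method_tag = "pearson_sfc"))
  diag(Om) <- 0.2 + 1.05 * rowSums(abs(Om))
  unname(Om)
}

#' Ground-truth precision matrix for one subject/session
#'
#' Sum of the seeded base network, the subject's fingerprint perturbation
#' (scaled by `subject_effect`), the sex component (scaled by
#' `sex_effect`), and dense per-session jitter (scaled by
#' `session_noise`); the diagonal is inflated to diagonal dominance, so the
#' result is symmetric positive definite by construction. With
#' `session_noise = 0` a subject's sessions share one precision exactly.
#'
#' @param config A [synthetic_config()].
#' @param subject Subject index (1-based).
#' @param sex `"M"` or `"F"`.
#' @param session Session index (1-based).
#' @param state State index (only > 1 for the state-switching variant).
#' @param components Optional precomputed [cohort_components()] (internal
#'   reuse).
#' @return An n x n SPD precision matrix.
#' @export
build_precision <- function(config, subject, sex = "M", session = 1L,
                            state = 1L, components = NULL) {
  comp <- components %||% cohort_components(config)
  off <- comp$base_off[[state]]
  se <- comp$subject_edges[[subject]]
  off[se] <- off[se] + config$subject_effect * comp$subject_values[[subject]]
  if (config$sex_effect > 0) {
    off[comp$sex_edges] <- off[comp$sex_edges] +
      config$sex_effect * comp$sex_values[[sex]]
  }
  if (config$session_noise > 0) {
    jitter <- withr::with_seed(
      derive_seed(config$seed, 2L, subject, session),
      stats::rnorm(length(off)))
    off <- off + config$session_noise * jitter
  }
  precision_from_off(off, config$n_nodes)
}

#' Sample one Gaussian run from a precision matrix
#'
#' Draws T rows from the zero-mean multivariate Gaussian with covariance
#' equal to the inverse of `precision` (factorized once). With
#' `ar_coef > 0` the innovations follow a unit-variance AR(1), giving
#' temporally smooth series with the same cross-sectional covariance.
#'
#' @param precision SPD matrix.
#' @param T_ Number of time points.
#' @param tr_seconds Sampling interval recorded on the result.
#' @param seed Integer seed.
#' @param node_ids Optional node labels.
#' @param ar_coef AR(1) innovation coefficient in (-1, 1).
#' @param ... Labels passed to [fp_timeseries()].
#' @return An `fp_timeseries` (T x n).
#' @export
simulate_run <- function(precision, T_, tr_seconds = 0.72, seed = 1L,
                         node_ids = NULL, ar_coef = 0, ...) {
  n <- nrow(precision)
  ev <- min(eigen(precision, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("precision matrix is not positive definite",
                    call. = FALSE)
  Sigma <- chol2inv(chol(precision))
  L <- chol(Sigma)
  Z <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(T_ * n), T_, n))
  if (ar_coef != 0) Z <- ar1_smooth(Z, ar_coef)
  fp_timeseries(Z %*% L, tr_seconds = tr_seconds, node_ids = node_ids, ...)
}

ar1_smooth <- function(Z, rho) {
  out <- Z
  scale <- sqrt(1 - rho^2)
  for (t in 2:nrow(Z)) out[t, ] <- rho * out[t - 1L, ] + scale * Z[t, ]
  out
}

#' Simulate a complete synthetic cohort
#'
#' Composes [make_atlas()], [build_precision()] and [simulate_run()] over
#' subjects x sessions x runs, assigns alternating sex labels, and draws
#' per-subject mean framewise displacement (log-normal, with optional
#' injected high-motion outliers). Everything is deterministic given the
#' config.
#'
#' @param config A [synthetic_config()]. `n_states` must be 1 (see
#'   [simulate_dynamic_cohort()] for state switching).
#' @return A `synthetic_cohort`: list with `config`, `atlas`, `subjects`
#'   (tibble: `subject_id`, `sex`, `mean_fd`), `ts`
#'   (`ts[[subject_id]][[session]][[run]]`, `fp_timeseries`), and
#'   `ground_truth` (base off-diagonals, subject/sex edge sets and values,
#'   per-subject-session precisions; plus state sequences for the dynamic
#'   variant).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_states != 1L) {
    return(simulate_dynamic_cohort(config))
  }
  simulate_cohort_impl(config, dynamic = FALSE)
}

#' Simulate a state-switching (dynamic) synthetic cohort
#'
#' As [simulate_cohort()], but each run follows a first-order Markov chain
#' over `n_states` shared connectivity-state templates (each its own base
#' network, with the subject fingerprint and sex component present in every
#' state) with mean dwell `state_dwell` samples; each sample is drawn from
#' the active state's Gaussian. The true state sequence of every run is
#' recorded in `ground_truth$state_sequences`.
#'
#' @param config A [synthetic_config()] with `n_states >= 2`.
#' @return A `synthetic_cohort`.
#' @export
simulate_dynamic_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_states < 2L) {
    stop("dynamic cohort needs n_states >= 2", call. = FALSE)
  }
  simulate_cohort_impl(config, dynamic = TRUE)
}

simulate_cohort_impl <- function(config, dynamic) {
  comp <- cohort_components(config)
  N <- config$n_subjects
  sexes <- rep(c("M", "F"), length.out = N)
  ids <- sprintf("sub_%03d", seq_len(N))
  mean_fd <- withr::with_seed(derive_seed(config$seed, 3L), {
    fd <- stats::rlnorm(N, config$fd_meanlog, config$fd_sdlog)
    if (config$fd_outliers > 0L) {
      out_idx <- sample.int(N, config$fd_outliers)
      fd[out_idx] <- fd[out_idx] * config$fd_outlier_scale
    }
    fd
  })
  n_states <- max(1L, config$n_states)
  ts <- vector("list", N); names(ts) <- ids
  precisions <- vector("list", N); names(precisions) <- ids
  state_seqs <- if (dynamic) vector("list", N) else NULL
  if (dynamic) names(state_seqs) <- ids
  for (s in seq_len(N)) {
    ts[[s]] <- vector("list", config$sessions)
    names(ts[[s]]) <- paste0("S", seq_len(config$sessions))
    precisions[[s]] <- vector("list", config$sessions)
    names(precisions[[s]]) <- names(ts[[s]])
    if (dynamic) {
      state_seqs[[s]] <- ts[[s]]
    }
    for (ses in seq_len(config$sessions)) {
      Oms <- lapply(seq_len(n_states), function(st)
        build_precision(config, s, sexes[s], ses, state = st,
                        components = comp))
      precisions[[s]][[ses]] <- if (n_states == 1L) Oms[[1L]] else Oms
      runs <- vector("list", config$runs_per_session)
      names(runs) <- paste0("R", seq_len(config$runs_per_session))
      seqs <- runs
      for (r in seq_len(config$runs_per_session)) {
        run_seed <- derive_seed(config$seed, 4L, s, ses, r)
        if (!dynamic) {
          runs[[r]] <- simulate_run(
            Oms[[1L]], config$t_per_run, config$tr_seconds, run_seed,
            node_ids = comp$atlas$node_id, ar_coef = config$ar_coef,
            subject_id = ids[s], session_id = paste0("S", ses),
            run_id = paste0("R", r))
        } else {
          sim <- simulate_markov_run(Oms, config, run_seed,
                                     comp$atlas$node_id)
          runs[[r]] <- fp_timeseries(
            sim$values, tr_seconds = config$tr_seconds,
            node_ids = comp$atlas$node_id, subject_id = ids[s],
            session_id = paste0("S", ses), run_id = paste0("R", r))
          seqs[[r]] <- sim$states
        }
      }
      ts[[s]][[ses]] <- runs
      if (dynamic) state_seqs[[s]][[ses]] <- seqs
    }
  }
  structure(list(
    config = config, atlas = comp$atlas,
    subjects = tibble::tibble(subject_id = ids, sex = sexes,
                              mean_fd = mean_fd),
    ts = ts,
    ground_truth = list(base_off = comp$base_off,
                        subject_edges = comp$subject_edges,
                        subject_values = comp$subject_values,
                        sex_edges = comp$sex_edges,
                        sex_values = comp$sex_values,
                        precisions = precisions,
                        state_sequences = state_seqs)),
    class = "synthetic_cohort")
}

# Markov chain over states with stay probability 1 - 1/dwell; each sample
# drawn from the active state's Gaussian
simulate_markov_run <- function(precisions, config, seed, node_ids) {
  K <- length(precisions)
  Ls <- lapply(precisions, function(Om) chol(chol2inv(chol(Om))))
  T_ <- config$t_per_run
  stay <- 1 - 1 / config$state_dwell
  withr::with_seed(as.integer(seed), {
    states <- integer(T_)
    states[1L] <- sample.int(K, 1L)
    u <- stats::runif(T_)
    jumps <- sample.int(K - 1L, T_, replace = TRUE)
    for (t in 2:T_) {
      states[t] <- if (u[t] < stay) states[t - 1L] else
        ((states[t - 1L] - 1L + jumps[t]) %% K) + 1L
    }
    Z <- matrix(stats::rnorm(T_ * nrow(Ls[[1L]])), T_)
    if (config$ar_coef != 0) Z <- ar1_smooth(Z, config$ar_coef)
  })
  vals <- matrix(0, T_, nrow(Ls[[1L]]))
  for (k in seq_len(K)) {
    idx <- states == k
    if (any(idx)) vals[idx, ] <- Z[idx, , drop = FALSE] %*% Ls[[k]]
  }
  list(values = vals, states = states)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<synthetic_cohort> %d subjects x %d sessions x %d ",
                     "runs; n=%d nodes, T=%d, %s\n"),
              cfg$n_subjects, cfg$sessions, cfg$runs_per_session,
              cfg$n_nodes, cfg$t_per_run,
              if (cfg$n_states > 1L)
                sprintf("%d Markov states (dwell %d)", cfg$n_states,
                        cfg$state_dwell)
              else "static"))
  invisible(x)
}

#' Estimate FC for every subject and session of a synthetic cohort
#'
#' Runs the chosen estimator on each run and combines runs within a session
#' (element-wise average of Fisher-z matrices for the static estimators;
#' window pooling before a single clustering for dynamic FC).
#'
#' @param cohort A `synthetic_cohort`.
#' @param method `"pearson"`, `"partial"`, or `"dfc"`.
#' @param dfc_cfg A [dfc_config()] for `method = "dfc"`; its seed is
#'   combined with subject/session indices so each clustering is seeded but
#'   distinct.
#' @param preprocess Optional [preprocess_config()] applied to every run
#'   (detrend/demean + band-pass) before estimation; NULL (default) skips
#'   conditioning, which is exact for the generator's white Gaussian runs.
#' @param ridge Passed to [partial_sfc()].
#' @return An `fc_cohort` with sessions `"S1"`, `"S2"`, ....
#' @export
cohort_fc <- function(cohort, method = c("pearson", "partial", "dfc"),
                      dfc_cfg = dfc_config(), preprocess = NULL,
                      ridge = 0) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- cohort$subjects$subject_id
  repr <- vector("list", length(ids)); names(repr) <- ids
  for (s in seq_along(ids)) {
    sess <- cohort$ts[[s]]
    repr[[s]] <- lapply(seq_along(sess), function(ses) {
      runs <- sess[[ses]]
      if (!is.null(preprocess)) {
        runs <- lapply(runs, preprocess_run, cfg = preprocess)
      }
      if (method == "dfc") {
        cfg <- dfc_cfg
        cfg$seed <- derive_seed(dfc_cfg$seed, 5L, s, ses)
        dfc_for_run(runs, cfg)
      } else {
        fcs <- lapply(runs, function(r)
          if (method == "pearson") pearson_sfc(r) else
            partial_sfc(r, ridge = ridge))
        Reduce(average_runs, fcs)
      }
    })
    names(repr[[s]]) <- names(sess)
  }
  method_tag <- switch(method, pearson = "pearson_sfc",
                       partial = "partial_sfc", dfc = "dfc_state")
  fc_cohort(repr, sex = stats::setNames(cohort$subjects$sex, ids),
            method = method_tag)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes per-run time-series TSVs, the atlas, the per-subject FD table,
#' and a manifest TSV (subject_id, sex, session_id, run_id, path).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  readr::write_tsv(cohort$subjects[, c("subject_id", "mean_fd")],
                   file.path(dir, "fd.tsv"))
  rows <- list()
  for (sid in names(cohort$ts)) {
    for (ses in names(cohort$ts[[sid]])) {
      for (run in names(cohort$ts[[sid]][[ses]])) {
        fn <- sprintf("%s_%s_%s.tsv", sid, ses, run)
        write_timeseries(cohort$ts[[sid]][[ses]][[run]],
                         file.path(dir, fn))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sid,
          sex = cohort$subjects$sex[cohort$subjects$subject_id == sid],
          session_id = ses, run_id = run, path = fn)
      }
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(dplyr::bind_rows(rows), manifest)
  invisible(manifest)
}
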