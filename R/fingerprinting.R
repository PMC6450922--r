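#' Cosine similarity between two FC vectors
#'
#' The inner product of the two edge-strength vectors divided by the product
#' of their norms; ranges from -1 (maximal dissimilarity) to 1 (maximal
#' similarity).
#'
#' @param x,y Numeric vectors of equal length (e.g. from
#'   [vectorize_upper()]), both with nonzero norm.
#' @return A single number in [-1, 1].
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
cosine_similarity <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  }
  s <- sum(x * y) / (nx * ny)
  min(max(s, -1), 1)
}

# any FC representation -> numeric matrix, rows = states (occupancy order,
# 1 row for static FC), cols = edges in the frozen upper-triangle order
as_repr <- function(x) {
  if (is.matrix(x) && !inherits(x, "fp_fc")) return(x)
  if (is.numeric(x) && is.null(dim(x)) && !inherits(x, "fp_fcvec")) {
    return(matrix(as.numeric(x), nrow = 1L))
  }
  if (inherits(x, "fp_fc")) {
    return(matrix(as.numeric(vectorize_upper(x)), nrow = 1L))
  }
  if (inherits(x, "fp_fcvec")) return(matrix(as.numeric(x), nrow = 1L))
  if (inherits(x, "dynamic_states")) {
    return(do.call(rbind, lapply(x$states, function(s)
      as.numeric(vectorize_upper(s)))))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an FC representation", call. = FALSE)
}

#' Similarity between two FC representations
#'
#' For static FC this is plain [cosine_similarity()] of the edge vectors.
#' For dynamic states two conventions are offered (the state-set-to-scalar
#' reduction is a package convention, not canonical): `"rank"` (default)
#' averages the cosine similarity of occupancy-rank-matched states;
#' `"best_match"` maximizes the mean cosine over all one-to-one state
#' assignments (exhaustive, K <= 8).
#'
#' @param a,b FC representations (`fp_fc`, `fp_fcvec`, or
#'   `dynamic_states` with equal K).
#' @param mode `"rank"` or `"best_match"`.
#' @return A single similarity in [-1, 1].
#' @export
fc_similarity <- function(a, b, mode = c("rank", "best_match")) {
  mode <- match.arg(mode)
  A <- as_repr(a); B <- as_repr(b)
  if (ncol(A) != ncol(B)) stop("edge counts differ", call. = FALSE)
  if (nrow(A) != nrow(B)) {
    stop("state counts differ (K = ", nrow(A), " vs ", nrow(B), ")",
         call. = FALSE)
  }
  K <- nrow(A)
  if (K == 1L) return(cosine_similarity(A[1L, ], B[1L, ]))
  cs <- outer(seq_len(K), seq_len(K),
              Vectorize(function(i, j) cosine_similarity(A[i, ], B[j, ])))
  if (mode == "rank") return(mean(diag(cs)))
  if (K > 8L) stop("best_match mode supports K <= 8", call. = FALSE)
  perms <- all_permutations(K)
  max(vapply(perms, function(p) mean(cs[cbind(seq_len(K), p)]), numeric(1)))
}

#' @rdname fc_similarity
#' @export
dfc_similarity <- fc_similarity

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(p, k, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}

#' Match target FC representations to a baseline database
#'
#' Each target is assigned the baseline with the highest similarity; ties
#' are broken deterministically by the lowest baseline index.
#'
#' @param baselines,targets Lists of FC representations sharing method, K,
#'   and node count. `baselines` must be nonempty.
#' @param mode Passed to [fc_similarity()].
#' @return A tibble with one row per target: `target`, `assigned` (baseline
#'   index), `similarity`.
#' @export
identify_targets <- function(baselines, targets,
                             mode = c("rank", "best_match")) {
  mode <- match.arg(mode)
  if (length(baselines) == 0L) stop("empty baseline set", call. = FALSE)
  sims <- vapply(targets, function(tg)
    vapply(baselines, function(bl) fc_similarity(tg, bl, mode), numeric(1)),
    numeric(length(baselines)))
  sims <- matrix(sims, nrow = length(baselines))
  assigned <- apply(sims, 2L, which.max)  # which.max takes first on ties
  tibble::tibble(target = seq_along(targets), assigned = as.integer(assigned),
                 similarity = sims[cbind(assigned, seq_along(targets))])
}

#' Bundle per-subject, per-session FC representations into a cohort
#'
#' @param repr Nested named list: `repr[[subject_id]][[session_id]]` is an
#'   FC representation (all the same method/K/node count).
#' @param sex Named character vector (`"M"`/`"F"`) keyed by subject id, or
#'   NULL when sex is not used.
#' @param method Method tag carried for bookkeeping.
#' @return An `fc_cohort`.
#' @export
fc_cohort <- function(repr, sex = NULL, method = "pearson_sfc") {
  subjects <- names(repr)
  if (is.null(subjects) || anyDuplicated(subjects)) {
    stop("`repr` must be a named list keyed by unique subject ids",
         call. = FALSE)
  }
  sessions <- lapply(repr, names)
  mats <- lapply(repr, function(s) lapply(s, as_repr))
  dims <- unique(unlist(lapply(mats, function(s) lapply(s, dim)),
                        recursive = FALSE))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1) {
    stop("all representations must share K and edge count", call. = FALSE)
  }
  if (!is.null(sex)) {
    sex <- sex[subjects]
    if (anyNA(sex) || !all(sex %in% c("M", "F"))) {
      stop("`sex` must cover every subject with 'M'/'F'", call. = FALSE)
    }
  }
  structure(list(subjects = subjects, sessions = sessions, repr = mats,
                 sex = sex, method = method,
                 n_states = nrow(mats[[1L]][[1L]]),
                 n_edges = ncol(mats[[1L]][[1L]])),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf(
    "<fc_cohort> %d subjects, %s sessions each, method=%s, K=%d, %d edges\n",
    length(x$subjects),
    paste(sort(unique(lengths(x$sessions))), collapse = "/"),
    x$method, x$n_states, x$n_edges))
  invisible(x)
}

# stack chosen-session representations: returns list of K matrices N x E,
# rows L2-normalized (per state)
stack_norm <- function(cohort, chosen) {
  K <- cohort$n_states
  lapply(seq_len(K), function(k) {
    m <- do.call(rbind, lapply(seq_along(cohort$subjects), function(s)
      cohort$repr[[s]][[chosen[s]]][k, ]))
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) {
      stop("zero-norm FC representation encountered", call. = FALSE)
    }
    m / nrm
  })
}

#' Randomized baseline/target subject-identification experiment
#'
#' Per run, one of each subject's two sessions is selected at random as the
#' known baseline; the remaining sessions are the unknown targets. Each
#' target is matched to the baseline with the highest cosine similarity
#' (rank-matched mean over states for dynamic FC); a subject scores 1 when
#' matched to itself. Reported are the per-run accuracy (% correct), the
#' mean accuracy over runs, and the maximum misidentification count.
#'
#' @param cohort An `fc_cohort`; every subject needs exactly 2 sessions.
#' @param runs Number of randomized repetitions (the reference analysis
#'   uses 1000; any value is accepted for desk-scale work).
#' @param seed Integer seed; results are fully reproducible.
#' @param mode State-matching mode for dynamic FC, see [fc_similarity()].
#' @return An `identification_result`: list with `runs` (tibble: `run`,
#'   `accuracy`, `n_misidentified`, `misidentified` list-column of subject
#'   ids), `mean_accuracy`, `max_misidentifications`, `n_targets`, `mode`.
#' @export
run_identification_experiment <- function(cohort, runs = 1000L, seed = 1L,
                                          mode = c("rank", "best_match")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "fc_cohort"))
  if (!all(lengths(cohort$sessions) == 2L)) {
    stop("every subject needs exactly 2 sessions", call. = FALSE)
  }
  N <- length(cohort$subjects)
  withr::with_seed(as.integer(seed), {
    res <- purrr::map(seq_len(runs), function(r) {
      base_ses <- sample.int(2L, N, replace = TRUE)
      score_run(cohort, base_ses, 3L - base_ses, mode)
    })
  })
  finalize_id_result(res, cohort, runs, seed, mode)
}

# one identification pass: baselines = session base_ses[s] of subject s,
# targets = session tgt_ses[s]; returns correctness + misidentified ids
score_run <- function(cohort, base_ses, tgt_ses, mode,
                      target_cohort = NULL) {
  tcoh <- target_cohort %||% cohort
  B <- stack_norm(cohort, base_ses)
  Tg <- stack_norm(tcoh, tgt_ses)
  sim <- similarity_grid(Tg, B, mode)
  assigned <- max.col(sim, ties.method = "first")
  correct <- assigned == seq_len(nrow(sim))
  list(correct = correct, misidentified = tcoh$subjects[!correct])
}

# mean-over-states similarity grid: rows = targets, cols = baselines
similarity_grid <- function(Tg, B, mode) {
  K <- length(Tg)
  if (mode == "rank" || K == 1L) {
    sim <- Tg[[1L]] %*% t(B[[1L]])
    if (K > 1L) for (k in 2L:K) sim <- sim + Tg[[k]] %*% t(B[[k]])
    return(sim / K)
  }
  nT <- nrow(Tg[[1L]]); nB <- nrow(B[[1L]])
  perms <- all_permutations(K)
  sim <- matrix(-Inf, nT, nB)
  per_k <- lapply(seq_len(K), function(i)
    lapply(seq_len(K), function(j) Tg[[i]] %*% t(B[[j]])))
  for (p in perms) {
    s <- per_k[[1L]][[p[1L]]]
    for (k in 2L:K) s <- s + per_k[[k]][[p[k]]]
    sim <- pmax(sim, s / K)
  }
  sim
}

finalize_id_result <- function(res, cohort, runs, seed, mode) {
  n_targets <- length(res[[1L]]$correct)
  runs_tbl <- tibble::tibble(
    run = seq_len(runs),
    accuracy = vapply(res, function(r) 100 * mean(r$correct), numeric(1)),
    n_misidentified = vapply(res, function(r) sum(!r$correct), integer(1)),
    misidentified = lapply(res, function(r) r$misidentified))
  structure(list(runs = runs_tbl,
                 mean_accuracy = mean(runs_tbl$accuracy),
                 max_misidentifications = max(runs_tbl$n_misidentified),
                 n_targets = n_targets, n_runs = runs, seed = seed,
                 mode = mode, method = cohort$method),
            class = "identification_result")
}

#' Cross-condition identification (different sessions/scanners/tasks)
#'
#' Baselines are drawn (one random session per subject per run) from
#' `baseline_cohort`; every session of `target_cohort` is a target. Both
#' cohorts must cover the same subjects. This is the driver for
#' medium-term-change and task-vs-rest comparisons.
#'
#' @param baseline_cohort,target_cohort `fc_cohort`s over identical subject
#'   ids (same method/K/edge count).
#' @inheritParams run_identification_experiment
#' @return An `identification_result` (targets = all target-cohort
#'   sessions).
#' @export
cross_condition_experiment <- function(baseline_cohort, target_cohort,
                                       runs = 1000L, seed = 1L,
                                       mode = c("rank", "best_match")) {
  mode <- match.arg(mode)
  if (!identical(baseline_cohort$subjects, target_cohort$subjects)) {
    stop("baseline and target cohorts must cover the same subjects ",
         "in the same order", call. = FALSE)
  }
  n_ses_b <- unique(lengths(baseline_cohort$sessions))
  if (length(n_ses_b) != 1L) {
    stop("baseline cohort sessions must be balanced", call. = FALSE)
  }
  N <- length(baseline_cohort$subjects)
  tgt_sessions <- unique(unlist(lapply(target_cohort$sessions, seq_along)))
  withr::with_seed(as.integer(seed), {
    res <- purrr::map(seq_len(runs), function(r) {
      base_ses <- sample.int(n_ses_b, N, replace = TRUE)
      per_ses <- lapply(tgt_sessions, function(ts)
        score_run(baseline_cohort, base_ses, rep(ts, N), mode,
                  target_cohort = target_cohort))
      list(correct = unlist(lapply(per_ses, `[[`, "correct")),
           misidentified = unlist(lapply(per_ses, `[[`, "misidentified")))
    })
  })
  finalize_id_result(res, baseline_cohort, runs, seed, mode)
}

#' Group-average FC representation
#'
#' Element-wise mean of the member representations; for dynamic states the
#' occupancy-rank-matched state matrices are averaged (a package
#' convention).
#'
#' @param reprs Nonempty list of FC representations of identical shape.
#' @return A plain representation matrix (states x edges); 1 row for static
#'   FC.
#' @export
group_average_fc <- function(reprs) {
  if (length(reprs) == 0L) stop("empty subset", call. = FALSE)
  mats <- lapply(reprs, as_repr)
  Reduce(`+`, mats) / length(mats)
}

#' Leave-one-out sex classification from group-average FC
#'
#' Per run, one session per subject is chosen at random; each subject's
#' chosen FC is compared (cosine similarity) to the male and female
#' group-average FC computed over the chosen sessions of all *other*
#' subjects. The predicted sex is the closer group; exact ties are counted
#' as errors (undecided).
#'
#' @param cohort An `fc_cohort` with sex labels; at least 2 subjects per
#'   sex.
#' @inheritParams run_identification_experiment
#' @return A `sex_classification_result`: list with `runs` (tibble: `run`,
#'   `accuracy`, `n_misidentified`, `misidentified`), `mean_accuracy`,
#'   `max_misidentifications`.
#' @export
classify_sex <- function(cohort, runs = 1000L, seed = 1L,
                         mode = c("rank", "best_match")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "fc_cohort"))
  if (is.null(cohort$sex)) stop("cohort has no sex labels", call. = FALSE)
  is_m <- cohort$sex == "M"
  if (sum(is_m) < 2L || sum(!is_m) < 2L) {
    stop("need at least 2 subjects of each sex", call. = FALSE)
  }
  N <- length(cohort$subjects)
  n_ses <- unique(lengths(cohort$sessions))
  if (length(n_ses) != 1L) stop("unbalanced sessions", call. = FALSE)
  K <- cohort$n_states
  withr::with_seed(as.integer(seed), {
    res <- purrr::map(seq_len(runs), function(r) {
      ses <- sample.int(n_ses, N, replace = TRUE)
      # raw (unnormalized) chosen representations per state
      raw <- lapply(seq_len(K), function(k)
        do.call(rbind, lapply(seq_len(N), function(s)
          cohort$repr[[s]][[ses[s]]][k, ])))
      sim_m <- loo_group_sim(raw, is_m)
      sim_f <- loo_group_sim(raw, !is_m)
      pred <- ifelse(sim_m > sim_f, "M", ifelse(sim_f > sim_m, "F", "tie"))
      correct <- pred == cohort$sex
      list(correct = correct, misidentified = cohort$subjects[!correct])
    })
  })
  out <- finalize_id_result(res, cohort, runs, seed, mode)
  class(out) <- c("sex_classification_result", class(out))
  out
}

# mean-over-states cosine of each subject vs the leave-one-out average of
# group `grp`; raw = list of K (N x E) matrices of chosen-session vectors
loo_group_sim <- function(raw, grp) {
  N <- nrow(raw[[1L]])
  sims <- matrix(0, N, length(raw))
  for (k in seq_along(raw)) {
    X <- raw[[k]]
    gsum <- colSums(X[grp, , drop = FALSE])
    ng <- sum(grp)
    for (s in seq_len(N)) {
      avg <- if (grp[s]) (gsum - X[s, ]) / (ng - 1L) else gsum / ng
      sims[s, k] <- cosine_similarity(X[s, ], avg)
    }
  }
  rowMeans(sims)
}
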