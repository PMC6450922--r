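test_that("synthetic atlas splits nodes into near-equal contiguous blocks", {
  at <- make_atlas(90, 14)
  sizes <- as.integer(table(factor(at$network,
                                   levels = atlas_networks(at))))
  expect_equal(sum(sizes), 90L)
  expect_true(all(sizes %in% c(6L, 7L)))
  expect_equal(sort(unique(diff(match(at$network,
                                      atlas_networks(at))))), c(0L, 1L))

  expect_equal(as.integer(table(make_atlas(4, 2)$network)), c(2L, 2L))
  expect_error(make_atlas(3, 4), "more networks")
})

test_that("generated precisions are SPD and share structure as configured", {
  cfg0 <- synthetic_config(n_subjects = 4, n_nodes = 15, n_networks = 3,
                           t_per_run = 100, subject_effect = 0,
                           sex_effect = 0, session_noise = 0, seed = 50)
  om_a <- build_precision(cfg0, 1, "M", 1)
  om_b <- build_precision(cfg0, 3, "F", 2)
  expect_equal(om_a, om_b)  # zero effects: everything shares the base

  cfg <- synthetic_config(n_subjects = 4, n_nodes = 15, n_networks = 3,
                          t_per_run = 100, subject_effect = 0.6,
                          sex_effect = 0.4, session_noise = 0.1, seed = 50)
  for (s in 1:4) for (ses in 1:2) {
    om <- build_precision(cfg, s, c("M", "F")[1 + s %% 2], ses)
    expect_true(isSymmetric(om))
    expect_gt(min(eigen(om, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }

  # with session noise off, a subject's sessions share one precision
  cfg_nosess <- synthetic_config(n_subjects = 4, n_nodes = 15,
                                 n_networks = 3, t_per_run = 100,
                                 subject_effect = 0.6, session_noise = 0,
                                 seed = 50)
  expect_equal(build_precision(cfg_nosess, 2, "F", 1),
               build_precision(cfg_nosess, 2, "F", 2))
  # and with it on, only the jitter differs (base + fingerprint fixed)
  d1 <- build_precision(cfg, 2, "F", 1) - build_precision(cfg_nosess, 2, "F", 1)
  expect_lt(max(abs(d1[upper.tri(d1)])), 6 * cfg$session_noise)
})

test_that("simulate_run draws the requested Gaussian", {
  Om <- diag(4)
  Om[1, 2] <- Om[2, 1] <- -0.4
  Sigma <- solve(Om)
  ts <- simulate_run(Om, 100000, seed = 51)
  emp <- cov(unclass(ts))
  expect_lt(max(abs(emp - Sigma)), 0.05)

  expect_identical(unclass(simulate_run(Om, 50, seed = 7))[, ],
                   unclass(simulate_run(Om, 50, seed = 7))[, ])

  iid <- simulate_run(diag(5), 10000, seed = 52)
  r <- cor(unclass(iid))
  expect_lt(max(abs(r[upper.tri(r)])), 0.03)

  bad <- diag(3); bad[1, 1] <- -1
  expect_error(simulate_run(bad, 10), "positive definite")
})

test_that("cohort simulation is fully deterministic given its config", {
  cfg <- synthetic_config(n_subjects = 3, n_nodes = 10, n_networks = 2,
                          t_per_run = 80, seed = 53)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(
    unclass(a$ts$sub_001$S1$R1)[, ], unclass(b$ts$sub_001$S1$R1)[, ])
  expect_identical(a$ground_truth$subject_edges,
                   b$ground_truth$subject_edges)
  # zero-effect config: all subjects share the ground-truth precision
  cfg0 <- synthetic_config(n_subjects = 3, n_nodes = 10, n_networks = 2,
                           t_per_run = 80, subject_effect = 0,
                           session_noise = 0, seed = 53)
  c0 <- simulate_cohort(cfg0)
  expect_equal(c0$ground_truth$precisions$sub_001$S1,
               c0$ground_truth$precisions$sub_003$S2)
})

test_that("sex- and subject-effect edge sets are disjoint", {
  cfg <- synthetic_config(n_subjects = 6, n_nodes = 20, n_networks = 4,
                          t_per_run = 100, sex_effect = 0.5, seed = 54)
  coh <- simulate_cohort(cfg)
  gt <- coh$ground_truth
  for (s in seq_len(6)) {
    expect_length(intersect(gt$subject_edges[[s]], gt$sex_edges), 0)
  }
})

test_that("the base network plants indirect Pearson correlations", {
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 20, n_networks = 4,
                          t_per_run = 100, subject_effect = 0,
                          session_noise = 0, seed = 55)
  coh <- simulate_cohort(cfg)
  Om <- coh$ground_truth$precisions$sub_001$S1
  R <- cov2cor(solve(Om))
  off <- which(upper.tri(Om), arr.ind = TRUE)
  zero_precision <- abs(Om[off]) < 1e-12
  # some truly-absent direct connections still show marginal correlation
  # (sign-alternating blocks attenuate indirect paths, so the effect is
  # modest but clearly distinct from the exact zeros partials recover)
  expect_gt(max(abs(R[off][zero_precision])), 0.015)
})

test_that("subject fingerprints are stable across sessions", {
  cfg <- synthetic_config(n_subjects = 20, n_nodes = 20, n_networks = 4,
                          t_per_run = 5000, runs_per_session = 1,
                          subject_effect = 0.6, session_noise = 0,
                          seed = 56)
  coh <- simulate_cohort(cfg)
  # true partial-correlation structure identical across sessions
  expect_equal(coh$ground_truth$precisions$sub_004$S1,
               coh$ground_truth$precisions$sub_004$S2)
  fc <- cohort_fc(coh, "partial")
  V1 <- do.call(rbind, lapply(fc$repr, function(s) s$S1[1, ]))
  V2 <- do.call(rbind, lapply(fc$repr, function(s) s$S2[1, ]))
  V1 <- V1 / sqrt(rowSums(V1^2)); V2 <- V2 / sqrt(rowSums(V2^2))
  S <- V1 %*% t(V2)
  within <- diag(S)
  between <- S[upper.tri(S) | lower.tri(S)]
  expect_gt(min(within), max(between))
})

test_that("motion outlier injection is caught by the 4-SD rule", {
  cfg <- synthetic_config(n_subjects = 30, n_nodes = 10, n_networks = 2,
                          t_per_run = 80, fd_outliers = 2,
                          fd_outlier_scale = 40, seed = 57)
  coh <- simulate_cohort(cfg)
  res <- motion_exclude(coh$subjects[, c("subject_id", "mean_fd")])
  injected <- order(coh$subjects$mean_fd, decreasing = TRUE)[1:2]
  expect_gte(sum(!res$keep[injected]), 1L)
  expect_true(all(res$keep[-injected]))
})

test_that("dynamic cohorts record their state sequences", {
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 12, n_networks = 3,
                          t_per_run = 400, n_states = 2, state_dwell = 60,
                          sessions = 1, runs_per_session = 1, seed = 58)
  coh <- simulate_dynamic_cohort(cfg)
  seqs <- coh$ground_truth$state_sequences$sub_001$S1$R1
  expect_length(seqs, 400L)
  expect_setequal(unique(seqs), 1:2)
  # mean dwell in the right ballpark (geometric with mean 60)
  runs <- rle(seqs)
  expect_gt(mean(runs$lengths), 20)

  expect_error(simulate_dynamic_cohort(
    synthetic_config(n_subjects = 1, n_nodes = 6, n_networks = 2,
                     t_per_run = 50, n_states = 1, seed = 1)),
    "n_states >= 2")
})

test_that("k-means on a two-state run recovers occupancy fractions", {
  # dwell >> window so that most windows are state-pure
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 20, n_networks = 4,
                          t_per_run = 2400, n_states = 2, state_dwell = 400,
                          subject_effect = 0.3, session_noise = 0.05,
                          sessions = 1, runs_per_session = 1, seed = 59)
  coh <- simulate_dynamic_cohort(cfg)
  dcfg <- dfc_config(window_tr = 85, step_tr = 5, n_states = 2, seed = 59)
  for (s in 1:2) {
    dyn <- dfc_for_run(coh$ts[[s]]$S1$R1, dcfg)
    seqs <- coh$ground_truth$state_sequences[[s]]$S1$R1
    emp <- sort(as.numeric(table(factor(seqs, 1:2))) / length(seqs),
                decreasing = TRUE)
    occ <- dyn$counts / sum(dyn$counts)
    expect_lt(max(abs(occ - emp)), 0.10)
  }
})

test_that("cohorts write to plain text and read back", {
  coh <- tiny_static_cohort(n_subjects = 2, seed = 60)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  expect_equal(nrow(man), 2 * 2 * 2)  # subjects x sessions x runs
  ts <- read_timeseries(file.path(dir, man$path[1]), 0.72)
  orig <- coh$ts[[man$subject_id[1]]][[man$session_id[1]]][[man$run_id[1]]]
  expect_equal(unclass(ts)[, ], unclass(orig)[, ], tolerance = 1e-12)
  at <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(at$node_id, coh$atlas$node_id)
})

test_that("cohort FC estimation produces aligned representations", {
  coh <- tiny_static_cohort(n_subjects = 4, seed = 61)
  for (m in c("pearson", "partial")) {
    fc <- cohort_fc(coh, m)
    expect_s3_class(fc, "fc_cohort")
    expect_equal(length(fc$subjects), 4L)
    expect_equal(fc$n_edges, n_edges(12))
    expect_equal(fc$n_states, 1L)
  }
  dcfg <- dfc_config(window_tr = 50, step_tr = 10, n_states = 2, seed = 2)
  fd <- cohort_fc(coh, "dfc", dfc_cfg = dcfg)
  expect_equal(fd$n_states, 2L)
  expect_identical(fd$method, "dfc_state")
})
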