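test_that("cosine similarity matches closed forms and is bounded", {
  x <- c(3, -1, 2)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(x, -x), -1)
  expect_error(cosine_similarity(x, c(0, 0, 0)), "zero-norm")
  expect_error(cosine_similarity(x, c(1, 2)), "equal length")
})

test_that("cosine similarity is symmetric and scale-invariant", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      x <- rnorm(15); y <- rnorm(15)
      a <- runif(1, 0.1, 5); b <- -runif(1, 0.1, 5)
      cs <- cosine_similarity(x, y)
      expect_equal(cosine_similarity(y, x), cs)
      expect_equal(cosine_similarity(a * x, b * y), sign(a * b) * cs,
                   tolerance = 1e-12)
      expect_true(abs(cs) <= 1)
    }
  })
})

test_that("state-set similarity handles rank and best-match modes", {
  mk_states <- function(vecs, counts) {
    structure(list(states = lapply(vecs, devectorize),
                   counts = as.integer(counts),
                   assignments = rep(seq_along(vecs), counts)),
              class = "dynamic_states")
  }
  E <- n_edges(4)
  v1 <- c(1, rep(0, E - 1)); v2 <- c(0, 1, rep(0, E - 2))
  a <- mk_states(list(v1, v2), c(6, 4))
  expect_equal(fc_similarity(a, a, "rank"), 1)
  expect_equal(fc_similarity(a, a, "best_match"), 1)

  # orthogonal states with swapped occupancy ranks
  b <- mk_states(list(v2, v1), c(6, 4))
  expect_equal(fc_similarity(a, b, "rank"), 0)
  expect_equal(fc_similarity(a, b, "best_match"), 1)

  k1a <- mk_states(list(v1), 5)
  k1b <- mk_states(list(v1 + v2), 5)
  expect_equal(fc_similarity(k1a, k1b), cosine_similarity(v1, v1 + v2))

  expect_error(fc_similarity(a, k1a), "state counts differ")
})

test_that("identify_targets picks the most similar baseline deterministically", {
  E <- 10
  base <- lapply(1:5, function(i) {
    v <- numeric(E); v[i] <- 1
    matrix(v, 1)
  })
  # targets = baselines -> identity
  res <- identify_targets(base, base)
  expect_equal(res$assigned, 1:5)
  expect_equal(res$similarity, rep(1, 5))

  # single baseline absorbs everything
  res1 <- identify_targets(base[1], base)
  expect_true(all(res1$assigned == 1L))

  # noisy targets still resolve: ||noise|| = 0.1 ||x||
  noisy <- withr::with_seed(32, lapply(base, function(b) {
    d <- rnorm(E); d <- d / sqrt(sum(d^2)) * 0.1
    b + matrix(d, 1)
  }))
  expect_equal(identify_targets(base, noisy)$assigned, 1:5)

  expect_error(identify_targets(list(), base), "empty baseline")
})

test_that("duplicate sessions identify perfectly; results are reproducible", {
  V <- withr::with_seed(33, matrix(rnorm(8 * 20), 8, 20))
  coh <- toy_vec_cohort(V, V)
  res <- run_identification_experiment(coh, runs = 25, seed = 9)
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$max_misidentifications, 0L)

  res2 <- run_identification_experiment(coh, runs = 25, seed = 9)
  expect_identical(tidy(res)$accuracy, tidy(res2)$accuracy)
  expect_identical(glance(res)$mean_accuracy, glance(res2)$mean_accuracy)
})

test_that("identification accuracy is invariant to subject ordering", {
  withr::with_seed(34, {
    V1 <- matrix(rnorm(10 * 30), 10, 30)
    V2 <- V1 + matrix(rnorm(10 * 30, sd = 0.4), 10, 30)
  })
  a <- run_identification_experiment(toy_vec_cohort(V1, V2),
                                     runs = 40, seed = 3)
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 4, 6)
  b <- run_identification_experiment(
    toy_vec_cohort(V1[perm, ], V2[perm, ]), runs = 40, seed = 3)
  expect_equal(a$mean_accuracy, b$mean_accuracy)
})

test_that("unstructured fingerprints identify at chance level", {
  # i.i.d. standard-normal session vectors: no session structure at all
  withr::with_seed(35, {
    V1 <- matrix(rnorm(50 * 200), 50, 200)
    V2 <- matrix(rnorm(50 * 200), 50, 200)
  })
  res <- run_identification_experiment(toy_vec_cohort(V1, V2),
                                       runs = 100, seed = 4)
  expect_lt(abs(res$mean_accuracy - 2), 3)  # chance = 100/50
})

test_that("cross-condition identification handles shifts and mismatches", {
  withr::with_seed(36, {
    V1 <- matrix(rnorm(12 * 40), 12, 40)
    V2 <- V1 + matrix(rnorm(12 * 40, sd = 0.2), 12, 40)
  })
  coh <- toy_vec_cohort(V1, V2)
  same <- cross_condition_experiment(coh, coh, runs = 20, seed = 5)
  expect_equal(same$n_targets, 24L)  # every target-cohort session

  # rank-preserving condition shift (positive rescale) keeps 100%
  shifted <- toy_vec_cohort(3 * V1, 3 * V2)
  res <- cross_condition_experiment(coh, shifted, runs = 20, seed = 5)
  expect_equal(res$mean_accuracy, 100)

  # fresh random targets fall to chance
  withr::with_seed(37, {
    R1 <- matrix(rnorm(12 * 40), 12, 40)
    R2 <- matrix(rnorm(12 * 40), 12, 40)
  })
  chance <- cross_condition_experiment(coh, toy_vec_cohort(R1, R2),
                                       runs = 50, seed = 6)
  expect_lt(chance$mean_accuracy, 30)  # chance = 100/12 ~ 8.3

  bad <- toy_vec_cohort(V1[1:11, ], V2[1:11, ])
  expect_error(cross_condition_experiment(coh, bad, runs = 2, seed = 1),
               "same subjects")
})

test_that("group averages are element-wise means", {
  fc1 <- fp_fc(random_fc_values(5, 1))
  expect_equal(group_average_fc(list(fc1)),
               matrix(as.numeric(vectorize_upper(fc1)), 1))
  v <- matrix(rnorm(10), 1)
  expect_equal(max(abs(group_average_fc(list(v, -v)))), 0)
  ms <- withr::with_seed(38, lapply(1:4, function(i) matrix(rnorm(10), 1)))
  expect_equal(group_average_fc(ms), Reduce(`+`, ms) / 4)
  expect_error(group_average_fc(list()), "empty")
})

test_that("sex classification is perfect for disjoint orthogonal groups", {
  E <- 20
  male_pat <- c(rep(1, 10), rep(0, 10))
  female_pat <- c(rep(0, 10), rep(1, 10))
  V <- rbind(matrix(rep(male_pat, 4), 4, E, byrow = TRUE),
             matrix(rep(female_pat, 4), 4, E, byrow = TRUE))
  coh <- toy_vec_cohort(V, V, sex = rep(c("M", "F"), each = 4))
  res <- classify_sex(coh, runs = 10, seed = 7)
  expect_equal(res$mean_accuracy, 100)
  expect_error(classify_sex(toy_vec_cohort(V, V), runs = 2, seed = 1),
               "no sex labels")
  expect_error(
    classify_sex(toy_vec_cohort(V[1:3, ], V[1:3, ],
                                sex = c("M", "F", "F")), 2, 1),
    "at least 2")
})

test_that("sex classification is near chance on a label-free cohort", {
  withr::with_seed(39, {
    V1 <- matrix(rnorm(60 * 100), 60, 100)
    V2 <- V1 + matrix(rnorm(60 * 100, sd = 0.5), 60, 100)
    sex <- sample(rep(c("M", "F"), 30))
  })
  res <- classify_sex(toy_vec_cohort(V1, V2, sex = sex),
                      runs = 50, seed = 8)
  expect_lt(abs(res$mean_accuracy - 50), 15)
})

test_that("identification accuracy degrades monotonically with session noise", {
  noise_grid <- c(0.05, 0.3, 0.8, 1.5)
  accs <- vapply(seq_along(noise_grid), function(k) {
    coh <- simulate_cohort(synthetic_config(
      n_subjects = 12, n_nodes = 20, n_networks = 4, t_per_run = 300,
      subject_effect = 0.5, session_noise = noise_grid[k], seed = 40))
    run_identification_experiment(cohort_fc(coh, "partial"),
                                  runs = 50, seed = 40 + k)$mean_accuracy
  }, numeric(1))
  # non-increasing, allowing 1-point Monte-Carlo violations
  expect_true(all(diff(accs) <= 1))
  expect_gt(accs[1], accs[length(accs)])
})
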