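# shared fixtures and independent oracles

# random symmetric zero-diagonal matrix
random_fc_values <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}

# independent brute-force oracle for the differential-power statistic:
# plain triple loop over (i, j, e) with explicit strict comparisons
dp_oracle <- function(s1, s2) {
  N <- nrow(s1); E <- ncol(s1)
  n1 <- sqrt(rowSums(s1^2)); n2 <- sqrt(rowSums(s2^2))
  phi <- function(i, j, e) s1[i, e] * s2[j, e] / (n1[i] * n2[j])
  dp <- numeric(E)
  for (e in seq_len(E)) {
    total <- 0
    for (i in seq_len(N)) {
      cnt <- 0L
      for (j in seq_len(N)) {
        if (j == i) next
        if (phi(i, i, e) > phi(i, j, e)) cnt <- cnt + 1L
        if (phi(i, i, e) > phi(j, i, e)) cnt <- cnt + 1L
      }
      total <- total + cnt / (2 * (N - 1))
    }
    dp[e] <- total / N
  }
  dp
}

# cohort of plain vector representations (one row per session)
toy_vec_cohort <- function(vectors_s1, vectors_s2, sex = NULL) {
  N <- nrow(vectors_s1)
  ids <- sprintf("sub%02d", seq_len(N))
  repr <- lapply(seq_len(N), function(i)
    list(S1 = matrix(vectors_s1[i, ], 1), S2 = matrix(vectors_s2[i, ], 1)))
  names(repr) <- ids
  if (!is.null(sex)) sex <- stats::setNames(sex, ids)
  fc_cohort(repr, sex = sex)
}

# small synthetic cohorts reused across tests
tiny_static_cohort <- function(n_subjects = 6, seed = 3, ...) {
  simulate_cohort(synthetic_config(
    n_subjects = n_subjects, n_nodes = 12, n_networks = 3,
    t_per_run = 200, seed = seed, ...))
}
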