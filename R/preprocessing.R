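#' Band-pass configuration for run conditioning
#'
#' Defaults follow standard resting-state practice for TR = 0.72 s data:
#' pass band 0.01634--0.15 Hz, second-order Butterworth applied
#' forward-backward (zero phase, effective order 4).
#'
#' @param f_min,f_max Pass-band edges in Hz. Must satisfy
#'   0 < f_min < f_max < Nyquist = 1/(2 TR).
#' @param filter_order Butterworth order of each pass (default 2).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(f_min = 0.01634, f_max = 0.15,
                              filter_order = 2L) {
  if (!(f_min > 0 && f_max > f_min)) {
    stop("need 0 < f_min < f_max", call. = FALSE)
  }
  if (filter_order < 1L) stop("filter_order must be >= 1", call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Remove per-node linear trend and mean
#'
#' For each column, subtracts the least-squares line over time indices.
#' Output columns have mean 0 and zero linear trend; the operation is
#' idempotent.
#'
#' @param ts An `fp_timeseries`.
#' @return An `fp_timeseries` of the same shape.
#' @export
detrend_demean <- function(ts) {
  stopifnot(inherits(ts, "fp_timeseries"))
  x <- unclass(ts)
  t_idx <- seq_len(nrow(x))
  tc <- t_idx - mean(t_idx)
  ss <- sum(tc^2)
  slope <- colSums(x * tc) / ss
  resid <- x - rep(colMeans(x), each = nrow(x)) - outer(tc, slope)
  restamp_timeseries(ts, resid)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (no phase shift),
#' per node. The series is reflect-padded at both ends before filtering to
#' suppress edge transients, then cropped back.
#'
#' @param ts An `fp_timeseries`.
#' @param cfg A [preprocess_config()]. `f_max` must lie below the Nyquist
#'   frequency 1/(2 TR).
#' @return An `fp_timeseries` of the same shape.
#' @export
bandpass <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "fp_timeseries"),
            inherits(cfg, "preprocess_config"))
  tr <- tr_seconds(ts)
  nyq <- 1 / (2 * tr)
  if (cfg$f_max >= nyq) {
    stop(sprintf("f_max = %g Hz is at/above Nyquist (%g Hz) for TR = %g s",
                 cfg$f_max, nyq, tr), call. = FALSE)
  }
  bf <- signal::butter(cfg$filter_order, c(cfg$f_min, cfg$f_max) / nyq,
                       type = "pass")
  x <- unclass(ts)
  T_ <- nrow(x)
  n_pad <- min(T_ - 1L, 6L * ceiling(1 / (cfg$f_min * tr)))
  filt1 <- function(col) {
    padded <- c(2 * col[1L] - rev(col[2L:(n_pad + 1L)]),
                col,
                2 * col[T_] - rev(col[(T_ - n_pad):(T_ - 1L)]))
    out <- signal::filtfilt(bf, padded)
    out[(n_pad + 1L):(n_pad + T_)]
  }
  restamp_timeseries(ts, apply(x, 2L, filt1))
}

#' Run the full conditioning chain on one run
#'
#' Detrend/demean, then zero-phase band-pass: the order used throughout the
#' package before any connectivity estimation.
#'
#' @inheritParams bandpass
#' @return An `fp_timeseries`.
#' @export
preprocess_run <- function(ts, cfg = preprocess_config()) {
  bandpass(detrend_demean(ts), cfg)
}

#' Motion-based subject exclusion at 4 standard deviations
#'
#' Flags subjects whose mean framewise displacement (FD) exceeds the cohort
#' mean by more than four cohort standard deviations (unbiased SD, strict
#' inequality). With zero spread nobody is excluded.
#'
#' @param records A data frame with columns `subject_id` and `mean_fd`
#'   (mm, per-subject run-average framewise displacement), or a bare
#'   numeric vector of mean FD values.
#' @param n_sd Number of standard deviations (default 4).
#' @return A tibble: input columns plus `keep` (logical) and `threshold`
#'   (the cutoff in mm, identical in every row). At least 2 records are
#'   required.
#' @export
#' @examples
#' fd <- tibble::tibble(subject_id = c("a", "b", "c"),
#'                      mean_fd = c(.1, .12, 3))
#' motion_exclude(fd)
motion_exclude <- function(records, n_sd = 4) {
  if (is.numeric(records)) {
    records <- tibble::tibble(subject_id = paste0("s", seq_along(records)),
                              mean_fd = as.numeric(records))
  }
  records <- tibble::as_tibble(records)
  if (!all(c("subject_id", "mean_fd") %in% names(records))) {
    stop("`records` needs columns subject_id and mean_fd", call. = FALSE)
  }
  if (nrow(records) < 2L) {
    stop("motion exclusion needs at least 2 records (SD undefined)",
         call. = FALSE)
  }
  if (any(records$mean_fd < 0)) stop("mean_fd must be >= 0", call. = FALSE)
  thr <- mean(records$mean_fd) + n_sd * stats::sd(records$mean_fd)
  dplyr::mutate(records, keep = .data$mean_fd <= thr, threshold = thr)
}

#' Average two runs' FC matrices element-wise
#'
#' Per-session FC for the static estimators is the element-wise mean of the
#' two runs' Fisher-z matrices.
#'
#' @param fc_a,fc_b `fp_fc` objects with identical node ids and method tags.
#' @return An `fp_fc`.
#' @export
average_runs <- function(fc_a, fc_b) {
  stopifnot(inherits(fc_a, "fp_fc"), inherits(fc_b, "fp_fc"))
  if (nrow(fc_a) != nrow(fc_b) ||
      !identical(rownames(fc_a), rownames(fc_b))) {
    stop("runs have different nodes; cannot average", call. = FALSE)
  }
  if (!identical(method_tag(fc_a), method_tag(fc_b))) {
    stop("runs have different method tags; cannot average", call. = FALSE)
  }
  fp_fc((unclass(fc_a) + unclass(fc_b)) / 2, method_tag = method_tag(fc_a),
        node_ids = rownames(fc_a))
}
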