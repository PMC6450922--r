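#' Per-edge standard deviation across subjects
#'
#' Unbiased (N-1 denominator) standard deviation of each edge's strength
#' over subjects; the basis for edge consistency (low-SD tail) and edge
#' variability (high-SD tail).
#'
#' @param vectors A subjects x edges numeric matrix (one FC vector per
#'   subject; session choice is the caller's), or a list of FC
#'   representations coerced with the package's vectorization convention.
#' @return Numeric vector of per-edge SDs.
#' @export
edge_std <- function(vectors) {
  X <- stack_vectors(vectors)
  if (nrow(X) < 2L) stop("need at least 2 subjects", call. = FALSE)
  apply(X, 2L, stats::sd)
}

stack_vectors <- function(vectors) {
  if (is.matrix(vectors) && !inherits(vectors, "fp_fc")) return(vectors)
  if (is.list(vectors)) {
    mats <- lapply(vectors, as_repr)
    if (any(vapply(mats, nrow, integer(1)) != 1L)) {
      stop("edge statistics expect one vector per subject (static FC)",
           call. = FALSE)
    }
    return(do.call(rbind, mats))
  }
  stop("cannot interpret input as a subjects x edges matrix", call. = FALSE)
}

#' Percentile-threshold edge selection
#'
#' Consistency selects edges whose SD is at or below the q-th percentile;
#' variability selects edges at or above it (typically q = 5 and q = 95).
#' Percentiles use linear interpolation between order statistics;
#' comparisons at the threshold are inclusive.
#'
#' @param stds Numeric vector of per-edge SDs (from [edge_std()]).
#' @param percentile Percentile in (0, 100).
#' @param mode `"consistency"` (low tail) or `"variability"` (high tail).
#' @return Logical mask over edges, with the threshold as attribute
#'   `threshold`.
#' @export
#' @examples
#' sum(threshold_edges(1:100, 5, "consistency")) # 5
threshold_edges <- function(stds, percentile,
                            mode = c("consistency", "variability")) {
  mode <- match.arg(mode)
  if (length(stds) == 0L) stop("empty std vector", call. = FALSE)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  thr <- unname(stats::quantile(stds, percentile / 100, type = 7))
  mask <- if (mode == "consistency") stds <= thr else stds >= thr
  structure(mask, threshold = thr)
}

#' Modified differential power of each edge
#'
#' For subjects i, j with session-1 and session-2 FC vectors X_i^S1, X_j^S2
#' (norms over all edges), the normalized per-edge product is
#' phi_ij(e) = X_i^S1(e) X_j^S2(e) / (||X_i^S1|| ||X_j^S2||).
#' P_i(e) is the fraction of strict inequalities phi_ii(e) > phi_ij(e) and
#' phi_ii(e) > phi_ji(e) over the 2(N-1) comparisons with other subjects,
#' and DP(e) is the mean of P_i(e) over subjects. The mean (rather than a
#' log of an empirical probability) keeps DP defined when a count is zero.
#' Edges with high DP are those whose within-subject cross-session products
#' consistently beat between-subject products - the edges that carry the
#' fingerprint.
#'
#' @param s1,s2 Subjects x edges matrices (or lists of static FC
#'   representations), aligned by subject; N >= 2, no zero-norm rows.
#' @return Numeric vector DP(e) in [0, 1] per edge.
#' @export
differential_power <- function(s1, s2) {
  A <- stack_vectors(s1); B <- stack_vectors(s2)
  if (!identical(dim(A), dim(B))) {
    stop("S1 and S2 must be subjects x edges matrices of equal shape",
         call. = FALSE)
  }
  N <- nrow(A)
  if (N < 2L) stop("differential power needs N >= 2 subjects", call. = FALSE)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("zero-norm FC vector", call. = FALSE)
  }
  An <- A / na; Bn <- B / nb
  E <- ncol(A)
  P <- matrix(0, N, E)
  for (i in seq_len(N)) {
    phi_ii <- An[i, ] * Bn[i, ]                       # within-subject
    phi_ij <- An[rep(i, N), , drop = FALSE] * Bn       # i's S1 vs others' S2
    phi_ji <- An * Bn[rep(i, N), , drop = FALSE]       # others' S1 vs i's S2
    gt_ij <- sweep(phi_ij, 2L, phi_ii, function(x, t) t > x)
    gt_ji <- sweep(phi_ji, 2L, phi_ii, function(x, t) t > x)
    gt_ij[i, ] <- FALSE; gt_ji[i, ] <- FALSE
    P[i, ] <- (colSums(gt_ij) + colSums(gt_ji)) / (2 * (N - 1))
  }
  colMeans(P)
}

#' Group-level differential power (males vs females)
#'
#' Applies the differential-power comparisons with the two sex groups as
#' the two units (N = 2): inputs are the male and female group-average FC
#' vectors for each session. The per-edge P values are reported separately
#' per group and take values in {0, 0.5, 1}.
#'
#' @param male_s1,male_s2,female_s1,female_s2 Group-average FC vectors
#'   (numeric, or static FC representations), all nonzero norm.
#' @return A tibble with columns `edge`, `p_male`, `p_female`.
#' @export
group_differential_power <- function(male_s1, male_s2,
                                     female_s1, female_s2) {
  A <- rbind(as.numeric(as_repr(male_s1)), as.numeric(as_repr(female_s1)))
  B <- rbind(as.numeric(as_repr(male_s2)), as.numeric(as_repr(female_s2)))
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm vector", call. = FALSE)
  An <- A / na; Bn <- B / nb
  p_grp <- function(i, j) {
    phi_ii <- An[i, ] * Bn[i, ]
    ((phi_ii > An[i, ] * Bn[j, ]) + (phi_ii > An[j, ] * Bn[i, ])) / 2
  }
  tibble::tibble(edge = seq_len(ncol(A)),
                 p_male = p_grp(1L, 2L), p_female = p_grp(2L, 1L))
}

#' Per-network contribution of a set of selected edges
#'
#' A within-network edge credits 1 to its network; a between-network edge
#' credits 0.5 to each endpoint network, so per-network percentages sum to
#' 100. Also returns the networks x networks block grid: the percentage of
#' selected edges falling in each (unordered) network pair, normalized by
#' the total number of selected edges.
#'
#' @param selected Logical mask over edges (e.g. from [threshold_edges()])
#'   or integer edge indices.
#' @param atlas An `fp_atlas` for the same node set.
#' @return A `network_contribution`: list with `network` (tibble: `network`,
#'   `credit`, `percent`) and `blocks` (tibble: `network_a`, `network_b`,
#'   `n_edges`, `percent`).
#' @export
network_contribution <- function(selected, atlas) {
  stopifnot(inherits(atlas, "fp_atlas"))
  emap <- edge_index_map(atlas)
  if (is.logical(selected)) {
    if (length(selected) != nrow(emap)) {
      stop("mask length does not match edge count for this atlas",
           call. = FALSE)
    }
    idx <- which(selected)
  } else {
    idx <- as.integer(selected)
  }
  if (length(idx) == 0L) stop("no edges selected", call. = FALSE)
  sel <- emap[idx, ]
  nets <- atlas_networks(atlas)
  credit <- stats::setNames(numeric(length(nets)), nets)
  for (r in seq_len(nrow(sel))) {
    if (sel$within[r]) {
      credit[sel$network_i[r]] <- credit[sel$network_i[r]] + 1
    } else {
      credit[sel$network_i[r]] <- credit[sel$network_i[r]] + 0.5
      credit[sel$network_j[r]] <- credit[sel$network_j[r]] + 0.5
    }
  }
  net_tbl <- tibble::tibble(network = nets, credit = unname(credit),
                            percent = 100 * unname(credit) / length(idx))
  pair_a <- pmin(match(sel$network_i, nets), match(sel$network_j, nets))
  pair_b <- pmax(match(sel$network_i, nets), match(sel$network_j, nets))
  blocks <- tidyr::complete(
    dplyr::count(tibble::tibble(network_a = nets[pair_a],
                                network_b = nets[pair_b]),
                 .data$network_a, .data$network_b, name = "n_edges"),
    network_a = nets, network_b = nets, fill = list(n_edges = 0L))
  blocks <- dplyr::filter(blocks, match(.data$network_a, nets) <=
                            match(.data$network_b, nets))
  blocks$percent <- 100 * blocks$n_edges / length(idx)
  structure(list(network = net_tbl, blocks = blocks,
                 n_selected = length(idx)),
            class = "network_contribution")
}

#' @export
print.network_contribution <- function(x, ...) {
  cat(sprintf("<network_contribution> %d selected edges\n", x$n_selected))
  print(x$network)
  invisible(x)
}

#' Full edge report for a cohort
#'
#' Convenience wrapper computing per-edge SD (session-1 vectors),
#' consistency and variability masks at the requested percentiles, and
#' differential power from the two sessions.
#'
#' @param s1,s2 Subjects x edges matrices (aligned by subject).
#' @param consistency_pct,variability_pct Percentile thresholds (default 5
#'   and 95).
#' @param atlas Optional `fp_atlas`; adds node/network columns.
#' @return An `edge_report` tibble: `edge`, (`node_i`, `node_j`,
#'   `network_i`, `network_j`, `within` with an atlas), `std`, `dp`,
#'   `consistent`, `variable`.
#' @export
edge_report <- function(s1, s2, consistency_pct = 5, variability_pct = 95,
                        atlas = NULL) {
  A <- stack_vectors(s1)
  stds <- edge_std(A)
  dp <- differential_power(A, stack_vectors(s2))
  cons <- threshold_edges(stds, consistency_pct, "consistency")
  vari <- threshold_edges(stds, variability_pct, "variability")
  base <- if (!is.null(atlas)) edge_index_map(atlas) else
    edge_index_map(nodes_from_edges(length(stds)))
  out <- dplyr::mutate(base, std = stds, dp = dp,
                       consistent = as.logical(cons),
                       variable = as.logical(vari))
  class(out) <- c("edge_report", class(out))
  attr(out, "thresholds") <- c(consistency = attr(cons, "threshold"),
                               variability = attr(vari, "threshold"))
  out
}
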