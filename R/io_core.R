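#' Construct a node time-series matrix
#'
#' The basic container for one run of regional (node) time series: a numeric
#' matrix with rows = time points and columns = nodes, together with the
#' sampling interval (TR, in seconds) and identifying labels.
#'
#' @param values Numeric matrix, T x n (time points x nodes). No missing
#'   values; T >= 2 and n >= 2.
#' @param tr_seconds Positive sampling interval in seconds (e.g. 0.72).
#' @param node_ids Character vector of n unique node identifiers. Defaults to
#'   column names of `values`, or `node_1 ... node_n`.
#' @param subject_id,session_id,run_id Optional opaque labels.
#'
#' @return An object of class `fp_timeseries`: the matrix with attributes
#'   `tr_seconds`, `subject_id`, `session_id`, `run_id`.
#' @export
#' @examples
#' ts <- fp_timeseries(matrix(rnorm(40), 20, 2), tr_seconds = 0.72)
#' n_timepoints(ts)
fp_timeseries <- function(values, tr_seconds, node_ids = NULL,
                          subject_id = NA_character_,
                          session_id = NA_character_,
                          run_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("time-series values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("a time series needs at least 2 time points (T >= 2)", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("a time series needs at least 2 nodes (n >= 2)", call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("time-series values must be finite with no missing cells",
         call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  }
  if (is.null(node_ids)) {
    node_ids <- colnames(values)
    if (is.null(node_ids)) node_ids <- paste0("node_", seq_len(ncol(values)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != ncol(values)) {
    stop("`node_ids` length must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    stop("`node_ids` must be unique", call. = FALSE)
  }
  colnames(values) <- node_ids
  structure(values,
            tr_seconds = as.numeric(tr_seconds),
            subject_id = subject_id, session_id = session_id, run_id = run_id,
            class = c("fp_timeseries", "matrix", "array"))
}

#' @rdname fp_timeseries
#' @param ts An `fp_timeseries`.
#' @export
n_timepoints <- function(ts) nrow(ts)

#' @rdname fp_timeseries
#' @export
n_nodes <- function(ts) ncol(ts)

#' @rdname fp_timeseries
#' @export
tr_seconds <- function(ts) attr(ts, "tr_seconds")

# rebuild an fp_timeseries with new values, keeping metadata
restamp_timeseries <- function(template, values) {
  fp_timeseries(values, tr_seconds = attr(template, "tr_seconds"),
                node_ids = colnames(template),
                subject_id = attr(template, "subject_id"),
                session_id = attr(template, "session_id"),
                run_id = attr(template, "run_id"))
}

#' Construct a network atlas
#'
#' Maps each node to exactly one resting-state network (RSN). Networks are
#' kept in first-appearance order.
#'
#' @param node_ids Character vector of unique node identifiers.
#' @param networks Character vector, same length: the network of each node.
#' @return An `fp_atlas`: a tibble with columns `node_id` and `network`, plus
#'   a `networks` attribute (distinct names, first-appearance order).
#' @export
#' @examples
#' fp_atlas(c("a", "b", "c"), c("DMN", "DMN", "SAL"))
fp_atlas <- function(node_ids, networks) {
  node_ids <- as.character(node_ids)
  networks <- as.character(networks)
  if (length(node_ids) == 0L) stop("atlas is empty", call. = FALSE)
  if (length(node_ids) != length(networks)) {
    stop("`node_ids` and `networks` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    dup <- node_ids[duplicated(node_ids)][1L]
    stop("duplicated node id in atlas: ", dup, call. = FALSE)
  }
  if (anyNA(node_ids) || anyNA(networks)) {
    stop("atlas entries must not be missing", call. = FALSE)
  }
  out <- tibble::tibble(node_id = node_ids, network = networks)
  structure(out, networks = unique(networks),
            class = c("fp_atlas", class(out)))
}

#' @rdname fp_atlas
#' @param atlas An `fp_atlas`.
#' @export
atlas_networks <- function(atlas) attr(atlas, "networks")

#' Construct a functional connectivity matrix
#'
#' A symmetric n x n matrix of Fisher-z edge strengths with a fixed zero
#' diagonal, tagged by the estimator that produced it.
#'
#' @param values Numeric symmetric matrix with finite entries. The diagonal
#'   is forced to exactly 0.
#' @param method_tag One of `"pearson_sfc"`, `"partial_sfc"`, `"dfc_state"`.
#' @param node_ids Optional node identifiers (defaults to dimnames or
#'   `node_1 ...`).
#' @return An `fp_fc` object.
#' @export
fp_fc <- function(values, method_tag = c("pearson_sfc", "partial_sfc",
                                         "dfc_state"),
                  node_ids = NULL) {
  method_tag <- match.arg(method_tag)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2L || ncol(values) != n) {
    stop("FC matrix must be square with n >= 2", call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("FC matrix entries must all be finite", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 0) {
    stop("FC matrix must be exactly symmetric", call. = FALSE)
  }
  diag(values) <- 0
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- paste0("node_", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("`node_ids` must be n unique labels", call. = FALSE)
  }
  dimnames(values) <- list(node_ids, node_ids)
  structure(values, method_tag = method_tag,
            class = c("fp_fc", "matrix", "array"))
}

#' @rdname fp_fc
#' @param fc An `fp_fc`.
#' @export
method_tag <- function(fc) attr(fc, "method_tag")

#' Number of distinct edges for an n-node network
#'
#' The length of the upper-triangle vectorization, n(n-1)/2. For the 90-node
#' parcellation used throughout, this is 4005.
#'
#' @param n Number of nodes (integer >= 2).
#' @return Integer n(n-1)/2.
#' @export
#' @examples
#' n_edges(90) # 4005
n_edges <- function(n) {
  n <- as.integer(n)
  if (any(n < 2L)) stop("need n >= 2 nodes", call. = FALSE)
  (n * (n - 1L)) %/% 2L
}

# invert e = m(m-1)/2; NA when e is not triangular
nodes_from_edges <- function(e) {
  m <- (1 + sqrt(1 + 8 * e)) / 2
  m_int <- round(m)
  ifelse(m_int * (m_int - 1) / 2 == e, m_int, NA_integer_)
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Concatenates the n(n-1)/2 strictly-upper-triangular elements in row-major
#' order over pairs (i, j), i < j: (1,2), (1,3), ..., (1,n), (2,3), ...
#' This fixed ordering is the package-wide edge indexing convention; every
#' downstream statistic is invariant to it, but file round-trips and
#' differential-power edge indices depend on it being frozen.
#'
#' @param fc An `fp_fc` (or plain symmetric matrix with zero diagonal).
#' @return An `fp_fcvec`: numeric vector of length n(n-1)/2 with attributes
#'   `n_nodes`, `node_ids`, `method_tag`.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- .1
#' m[1, 3] <- m[3, 1] <- .2; m[2, 3] <- m[3, 2] <- .3
#' vectorize_upper(fp_fc(m)) # 0.1 0.2 0.3
vectorize_upper <- function(fc) {
  if (!inherits(fc, "fp_fc")) fc <- fp_fc(fc)
  m <- unclass(fc)
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(m)
  v <- tm[lower.tri(tm)]
  structure(v, n_nodes = nrow(m), node_ids = rownames(m),
            method_tag = attr(fc, "method_tag"), class = "fp_fcvec")
}

#' Rebuild an FC matrix from its upper-triangle vector
#'
#' Exact inverse of [vectorize_upper()]: `devectorize(vectorize_upper(fc))`
#' reproduces `fc` bit for bit.
#'
#' @param v Numeric vector whose length is a triangular number m(m-1)/2,
#'   or an `fp_fcvec`.
#' @param method_tag,node_ids Metadata for the result; taken from `v`'s
#'   attributes when present.
#' @return An `fp_fc`.
#' @export
devectorize <- function(v, method_tag = NULL, node_ids = NULL) {
  if (is.null(method_tag)) {
    method_tag <- attr(v, "method_tag") %||% "pearson_sfc"
  }
  if (is.null(node_ids)) node_ids <- attr(v, "node_ids")
  x <- as.numeric(v)
  m <- nodes_from_edges(length(x))
  if (is.na(m)) {
    stop("vector length ", length(x),
         " is not a triangular number m(m-1)/2", call. = FALSE)
  }
  out <- matrix(0, m, m)
  tm <- t(out)
  tm[lower.tri(tm)] <- x
  out <- t(tm)
  out <- out + t(out)
  fp_fc(out, method_tag = method_tag, node_ids = node_ids)
}

#' Edge index map for an n-node network
#'
#' Tabulates the bijection between edge index e (in the frozen row-major
#' upper-triangle order) and node pairs (i, j), i < j. With an atlas, each
#' edge is additionally classified as within-network or between-network.
#'
#' @param x An `fp_atlas`, an `fp_fc`, or an integer node count.
#' @return A tibble with columns `edge`, `i`, `j` and, when an atlas is
#'   supplied, `node_i`, `node_j`, `network_i`, `network_j`, `within`
#'   (logical).
#' @export
#' @examples
#' edge_index_map(4)
edge_index_map <- function(x) {
  atlas <- NULL
  if (inherits(x, "fp_atlas")) {
    atlas <- x
    n <- nrow(atlas)
  } else if (inherits(x, "fp_fc")) {
    n <- nrow(x)
  } else {
    n <- as.integer(x)
  }
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n),
              use.names = FALSE)
  out <- tibble::tibble(edge = seq_along(i), i = i, j = j)
  if (!is.null(atlas)) {
    out$node_i <- atlas$node_id[i]
    out$node_j <- atlas$node_id[j]
    out$network_i <- atlas$network[i]
    out$network_j <- atlas$network[j]
    out$within <- out$network_i == out$network_j
  }
  out
}

#' Read one run of node time series from delimited text
#'
#' Expects a header row of node ids and a numeric body, one row per time
#' point. Tab, comma, or whitespace delimited (auto-detected by extension:
#' `.csv` -> comma, otherwise tab).
#'
#' @param path File path.
#' @param tr_seconds Sampling interval in seconds (metadata, required).
#' @param ... Passed through to [fp_timeseries()] (labels).
#' @return An `fp_timeseries`.
#' @export
read_timeseries <- function(path, tr_seconds, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = readr::cols(),
                      show_col_types = FALSE, progress = FALSE))
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    badrow <- which(!grepl("^\\s*-?[0-9.eE+-]+\\s*$",
                           as.character(df[[bad]])))[1L]
    stop("non-numeric cell in ", path, " (column '", names(df)[bad],
         "', data row ", ifelse(is.na(badrow), "?", badrow), ")",
         call. = FALSE)
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("missing/NaN cell in ", path, " at data row ", idx[1L],
         ", column '", colnames(mat)[idx[2L]], "'", call. = FALSE)
  }
  if (nrow(mat) < 2L) {
    stop("time series in ", path, " has fewer than 2 time points",
         call. = FALSE)
  }
  fp_timeseries(mat, tr_seconds = tr_seconds, node_ids = colnames(mat), ...)
}

#' Write one run of node time series to delimited text
#'
#' @param ts An `fp_timeseries`.
#' @param path Output path (tab-delimited, header of node ids, full double
#'   precision).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(ts)))
  readr::write_delim(df, path, delim = "\t")
  invisible(path)
}

#' Read / write a network atlas
#'
#' Two-column delimited text: node_id, network. Networks keep
#' first-appearance order.
#'
#' @param path File path.
#' @return `read_atlas()`: an `fp_atlas`. `write_atlas()`: `path`, invisibly.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                        show_col_types = FALSE)
  if (nrow(df) == 0L) stop("atlas file is empty: ", path, call. = FALSE)
  if (ncol(df) < 2L) stop("atlas needs two columns (node_id, network)",
                          call. = FALSE)
  fp_atlas(df[[1L]], df[[2L]])
}

#' @rdname read_atlas
#' @param atlas An `fp_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  readr::write_tsv(tibble::tibble(node_id = atlas$node_id,
                                  network = atlas$network), path)
  invisible(path)
}

#' Read / write an FC matrix
#'
#' Tab-delimited text with a one-line metadata header
#' (`#fc method_tag=<tag> n=<n>`), then a header row of node ids and the
#' full symmetric matrix at full double precision.
#'
#' @param fc An `fp_fc`.
#' @param path File path.
#' @return `read_fc()`: an `fp_fc`; `write_fc()`: `path`, invisibly.
#' @export
write_fc <- function(fc, path) {
  stopifnot(inherits(fc, "fp_fc"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fc method_tag=%s n=%d", method_tag(fc), nrow(fc)), con)
  writeLines(paste(rownames(fc), collapse = "\t"), con)
  body <- apply(unclass(fc), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#fc")) {
    stop("not an FC matrix file (missing '#fc' header): ", path,
         call. = FALSE)
  }
  tag <- sub(".*method_tag=(\\S+).*", "\\1", lines[1L])
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", lines[1L]))
  ids <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(ids) != n || length(lines) != n + 2L) {
    stop("FC file shape mismatch (expected n=", n, "): ", path,
         call. = FALSE)
  }
  rows <- lapply(lines[-(1:2)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  if (any(lengths(rows) != n)) {
    stop("FC file shape mismatch (ragged rows): ", path, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("non-numeric cell in FC file: ", path, call. = FALSE)
  fp_fc(m, method_tag = tag, node_ids = ids)
}

#' @export
print.fp_fc <- function(x, ...) {
  cat(sprintf("<fp_fc> %d x %d, method_tag=%s\n", nrow(x), ncol(x),
              method_tag(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
print.fp_timeseries <- function(x, ...) {
  cat(sprintf("<fp_timeseries> T=%d, n=%d nodes, TR=%gs\n", nrow(x), ncol(x),
              tr_seconds(x)))
  invisible(x)
}
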