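#' Segment a time series into non-overlapping windows
#'
#' The series is cut into `N = floor(T / l)` contiguous blocks of `l`
#' volumes starting at the first volume; the trailing `T - N * l` volumes
#' are discarded.
#'
#' @param series A [subject_ts()] or a numeric T x M matrix.
#' @param window_length Window length `l` in volumes (TRs). Must be at
#'   least 3 (a Pearson correlation needs 3 points to be non-degenerate).
#' @return A list of `N` numeric `l x M` matrices.
#' @export
#' @examples
#' x <- matrix(rnorm(200 * 4), 200, 4)
#' length(segment_windows(x, 20))  # 10 windows
segment_windows <- function(series, window_length) {
  mat <- if (inherits(series, "subject_ts")) series$data else as.matrix(series)
  l <- as.integer(window_length)
  if (l < 3) stop("window_length must be >= 3 volumes", call. = FALSE)
  n_win <- nrow(mat) %/% l
  if (n_win < 2) {
    stop(sprintf(
      "T = %d volumes yields N = %d window(s) of length %d; variability needs N >= 2",
      nrow(mat), n_win, l), call. = FALSE)
  }
  lapply(seq_len(n_win), function(i) {
    mat[((i - 1L) * l + 1L):(i * l), , drop = FALSE]
  })
}

#' Per-window functional connectivity matrix
#'
#' Pearson correlation between every pair of node time series within one
#' window. Values are kept signed; no Fisher transform, no thresholding.
#'
#' @param block An `l x M` numeric matrix (one window of the series).
#' @return A symmetric M x M correlation matrix with unit diagonal.
#' @export
window_fc <- function(block) {
  block <- as.matrix(block)
  sds <- apply(block, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance node(s) within window at position(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(block)
  diag(r) <- 1
  r
}

#' Stack of per-window FC matrices for one subject
#'
#' Applies [segment_windows()] then [window_fc()] to every window.
#'
#' @inheritParams segment_windows
#' @param subject_id Identifier (taken from the series if a [subject_ts()]).
#' @param fisher_z If `TRUE`, apply the Fisher z transform
#'   (`atanh`, with |r| clipped at 1 - 1e-7) to off-diagonal FC values
#'   before any variability computation. Off by default: profiles are
#'   correlated on the raw Pearson scale.
#' @param skip_degenerate_windows If `TRUE`, a window containing a
#'   zero-variance node is dropped for all nodes (windows stay aligned
#'   across nodes) and recorded in the `dropped_windows` attribute;
#'   if `FALSE` (default) such a window is a hard error.
#' @return An object of class `fc_stack`: list with `subject_id`,
#'   `window_length`, and `windows`, an `M x M x N` array.
#' @export
fc_window_stack <- function(series, window_length, subject_id = NULL,
                            fisher_z = FALSE,
                            skip_degenerate_windows = FALSE) {
  if (is.null(subject_id)) {
    subject_id <- if (inherits(series, "subject_ts")) series$subject_id
    else "subject"
  }
  blocks <- segment_windows(series, window_length)
  dropped <- integer(0)
  mats <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    sds <- apply(blocks[[i]], 2, stats::sd)
    if (any(sds == 0)) {
      if (skip_degenerate_windows) {
        dropped <- c(dropped, i)
        next
      }
      stop(sprintf(
        "zero-variance node (position %d) within window %d of subject %s",
        which(sds == 0)[1], i, subject_id), call. = FALSE)
    }
    mats[[i]] <- window_fc(blocks[[i]])
  }
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) < 2) {
    stop("fewer than 2 usable windows after dropping degenerate ones",
         call. = FALSE)
  }
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  if (fisher_z) {
    arr <- atanh(pmin(pmax(arr, -(1 - 1e-7)), 1 - 1e-7))
  }
  structure(list(subject_id = subject_id,
                 window_length = as.integer(window_length),
                 fisher_z = fisher_z, windows = arr),
            class = "fc_stack",
            dropped_windows = dropped)
}

#' @export
print.fc_stack <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<fc_stack> %s: %d windows of %d x %d FC (l = %d)\n",
              x$subject_id, d[3], d[1], d[2], x$window_length))
  invisible(x)
}

n_windows <- function(stack) dim(stack$windows)[3]

# Column-standardize to zero mean / unit sum-of-squares; columns with zero
# variance become NA columns (degenerate profiles).
unit_scale_cols <- function(m) {
  cm <- colMeans(m)
  c0 <- m - rep(cm, each = nrow(m))
  ss <- colSums(c0 * c0)
  ss[ss == 0] <- NA_real_
  c0 / rep(sqrt(ss), each = nrow(m))
}

# Mean pairwise Pearson correlation across windows for a matrix whose
# columns are units and whose rows are profile entries, given one matrix
# per window. Uses the identity
#   sum_{i<j} <z_i, z_j> = (||sum_i z_i||^2 - N) / 2
# for unit-norm standardized columns z_i, so cost is O(N * entries).
mean_pairwise_cor <- function(profile_list) {
  n <- length(profile_list)
  z <- lapply(profile_list, unit_scale_cols)
  acc <- Reduce(`+`, z)
  # a profile degenerate in any window poisons that unit (NA propagates)
  pair_sum <- (colSums(acc * acc) - n) / 2
  pair_sum / (n * (n - 1) / 2)
}

profile_matrix_nodal <- function(fc) {
  m <- nrow(fc)
  # symmetric fc: column k of the result = row k of fc with self-entry removed
  matrix(fc[-seq(1L, m * m, by = m + 1L)], m - 1L, m)
}

#' Nodal temporal variability
#'
#' For node k, the connectivity profile in window i is that node's vector
#' of FC values to all other nodes (self-connection excluded). The
#' temporal variability is
#' \deqn{V_k = 1 - \frac{2}{N(N-1)} \sum_{i<j} \mathrm{corr}(F_{i,k}, F_{j,k}),}
#' one minus the average Pearson correlation of the node's profile over
#' all unordered window pairs. Values lie in \[0, 2\]: 0 when the profile
#' is perfectly stable, 2 when consecutive profiles are perfectly
#' anti-correlated.
#'
#' @param stack An [fc_window_stack()].
#' @param nodes Optional integer vector of node positions (defaults to all).
#' @return Numeric vector of V_k, one per requested node. A node whose
#'   profile has zero variance in some window gets `NA` (undefined
#'   correlation), with the offending positions in attribute
#'   `degenerate_nodes`.
#' @export
nodal_variability <- function(stack, nodes = NULL) {
  profs <- lapply(seq_len(n_windows(stack)), function(i) {
    profile_matrix_nodal(stack$windows[, , i])
  })
  v <- 1 - mean_pairwise_cor(profs)
  if (!is.null(nodes)) v <- v[nodes]
  bad <- which(is.na(v))
  if (length(bad) > 0) attr(v, "degenerate_nodes") <- bad
  v
}

module_positions <- function(stack, partition, module) {
  members <- module_members(partition)
  if (!module %in% names(members)) {
    stop("unknown module label: ", module, call. = FALSE)
  }
  if (n_nodes(partition) != dim(stack$windows)[1]) {
    stop("partition size does not match the FC stack", call. = FALSE)
  }
  members[[module]]
}

#' Intra-network temporal variability
#'
#' The within-module connectivity in each window (upper triangle of the
#' module's FC block, diagonal excluded, in a fixed canonical order) is
#' unfolded into one vector; the variability is one minus the mean
#' pairwise Pearson correlation of these vectors across window pairs.
#'
#' @inheritParams nodal_variability
#' @param partition A [network_partition()] matching the stack's nodes.
#' @param module A module label; must have at least 3 nodes.
#' @return Scalar variability in \[0, 2\] (`NA` with a `degenerate`
#'   attribute if the unfolded vector has zero variance in some window).
#' @export
intra_network_variability <- function(stack, partition, module) {
  idx <- module_positions(stack, partition, module)
  if (length(idx) < 3) {
    stop(sprintf("module '%s' has %d node(s); intra-network variability needs >= 3",
                 module, length(idx)), call. = FALSE)
  }
  ut <- upper.tri(diag(length(idx)))
  profs <- lapply(seq_len(n_windows(stack)), function(i) {
    blk <- stack$windows[idx, idx, i]
    matrix(blk[ut], ncol = 1)
  })
  v <- 1 - mean_pairwise_cor(profs)
  if (is.na(v)) attr(v, "degenerate") <- TRUE
  v
}

#' Inter-network temporal variability
#'
#' The full between-module connectivity block (every cross pair once) is
#' unfolded per window; the variability is one minus the mean pairwise
#' Pearson correlation of these vectors across window pairs. Symmetric in
#' its two module arguments.
#'
#' @inheritParams intra_network_variability
#' @param module_a,module_b Distinct module labels with
#'   `|A| * |B| >= 3` cross pairs.
#' @return Scalar variability in \[0, 2\].
#' @export
inter_network_variability <- function(stack, partition, module_a, module_b) {
  if (identical(module_a, module_b)) {
    stop("modules must differ; use intra_network_variability()",
         call. = FALSE)
  }
  labels <- module_labels(partition)
  # canonical orientation so (A,B) and (B,A) are bit-identical
  ord <- order(match(c(module_a, module_b), labels))
  a <- c(module_a, module_b)[ord[1]]
  b <- c(module_a, module_b)[ord[2]]
  ia <- module_positions(stack, partition, a)
  ib <- module_positions(stack, partition, b)
  if (length(ia) * length(ib) < 3) {
    stop(sprintf("block %s x %s has %d cross pair(s); need >= 3",
                 a, b, length(ia) * length(ib)), call. = FALSE)
  }
  profs <- lapply(seq_len(n_windows(stack)), function(i) {
    matrix(as.vector(stack$windows[ia, ib, i]), ncol = 1)
  })
  v <- 1 - mean_pairwise_cor(profs)
  if (is.na(v)) attr(v, "degenerate") <- TRUE
  v
}

#' Full variability set for one subject
#'
#' Computes the nodal variability vector for all nodes plus the K x K
#' module-level matrix (intra-network variability on the diagonal,
#' inter-network variability off it) from one pass over the window stack.
#'
#' @param series A [subject_ts()] or T x M matrix.
#' @param partition A [network_partition()].
#' @param window_length Window length in volumes (default 20).
#' @inheritParams fc_window_stack
#' @return An object of class `variability_set`: list with `subject_id`,
#'   `window_length`, `nodal` (length-M vector named by node index) and
#'   `module_matrix` (K x K symmetric, dimnames = module labels).
#' @export
variability_set <- function(series, partition, window_length = 20,
                            fisher_z = FALSE,
                            skip_degenerate_windows = FALSE) {
  stack <- fc_window_stack(series, window_length, fisher_z = fisher_z,
                           skip_degenerate_windows = skip_degenerate_windows)
  if (dim(stack$windows)[1] != n_nodes(partition)) {
    stop("series width does not match partition size", call. = FALSE)
  }
  nodal <- nodal_variability(stack)
  attributes(nodal) <- NULL
  names(nodal) <- partition$node_index
  labels <- module_labels(partition)
  k <- length(labels)
  mm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    mm[i, i] <- as.numeric(intra_network_variability(stack, partition,
                                                     labels[i]))
    if (i < k) for (j in (i + 1):k) {
      v <- as.numeric(inter_network_variability(stack, partition,
                                                labels[i], labels[j]))
      mm[i, j] <- v
      mm[j, i] <- v
    }
  }
  structure(list(subject_id = stack$subject_id,
                 window_length = stack$window_length,
                 nodal = nodal, module_matrix = mm),
            class = "variability_set")
}

#' @export
print.variability_set <- function(x, ...) {
  cat(sprintf(
    "<variability_set> %s (l = %d): %d nodes, %d modules; nodal mean = %.3f\n",
    x$subject_id, x$window_length, length(x$nodal), nrow(x$module_matrix),
    mean(x$nodal, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a variability set into the long output format
#'
#' @param x A [variability_set()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `level`
#'   (`nodal`/`intra`/`inter`), `unit` (node index, module label, or
#'   `"A|B"`), `window_length`, `value`.
#' @method tidy variability_set
#' @export
tidy.variability_set <- function(x, ...) {
  labels <- rownames(x$module_matrix)
  k <- length(labels)
  inter <- if (k >= 2) {
    idx <- which(upper.tri(x$module_matrix), arr.ind = TRUE)
    tibble::tibble(
      level = "inter",
      unit = paste(labels[idx[, 1]], labels[idx[, 2]], sep = "|"),
      value = x$module_matrix[idx])
  } else tibble::tibble(level = character(), unit = character(),
                        value = numeric())
  out <- dplyr::bind_rows(
    tibble::tibble(level = "nodal", unit = names(x$nodal),
                   value = unname(x$nodal)),
    tibble::tibble(level = "intra", unit = labels,
                   value = diag(x$module_matrix)),
    inter)
  dplyr::mutate(out, subject_id = x$subject_id,
                window_length = x$window_length,
                .before = 1)
}

#' Variability for every subject of a cohort
#'
#' Reads each subject's time series listed in the manifest and computes its
#' [variability_set()], returned in long format.
#'
#' @param manifest A manifest tibble from [read_manifest()] (or any data
#'   frame with `subject_id`, `group`, `path`).
#' @param partition A [network_partition()].
#' @inheritParams variability_set
#' @param tr_seconds Repetition time passed to [read_timeseries()].
#' @return A long tibble: `subject_id`, `group`, `level`, `unit`,
#'   `window_length`, `value`.
#' @export
cohort_variability <- function(manifest, partition, window_length = 20,
                               fisher_z = FALSE,
                               skip_degenerate_windows = FALSE,
                               tr_seconds = 2) {
  purrr::pmap_dfr(
    manifest[, c("subject_id", "group", "path")],
    function(subject_id, group, path) {
      series <- read_timeseries(path, partition, subject_id = subject_id,
                                tr_seconds = tr_seconds)
      vs <- variability_set(series, partition,
                            window_length = window_length,
                            fisher_z = fisher_z,
                            skip_degenerate_windows = skip_degenerate_windows)
      dplyr::mutate(tidy.variability_set(vs), group = group, .after = 1)
    })
}

#' Average variability sets over window lengths
#'
#' Elementwise arithmetic mean of several [variability_set()]s for the
#' same subject and partition, computed at different window lengths.
#' A missing entry propagates as missing unless it is missing at exactly
#' one length, in which case the mean of the present values is used (the
#' number of contributing lengths is recorded in attribute `n_used`).
#'
#' @param sets A list of [variability_set()]s (>= 2) with identical node
#'   and module layouts.
#' @return A [variability_set()] with `window_length = NA` and an
#'   attribute `lengths` listing the averaged window lengths.
#' @export
average_over_lengths <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 window lengths", call. = FALSE)
  base <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(names(s$nodal), names(base$nodal)) ||
        !identical(dimnames(s$module_matrix), dimnames(base$module_matrix))) {
      stop("variability sets have mismatched shapes", call. = FALSE)
    }
  }
  avg_entries <- function(extract) {
    vals <- vapply(sets, extract, extract(base))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    n_miss <- rowSums(is.na(vals))
    out <- rowMeans(vals, na.rm = TRUE)
    out[n_miss > 1] <- NA_real_
    out[is.nan(out)] <- NA_real_
    list(values = out, n_used = ncol(vals) - n_miss)
  }
  nod <- avg_entries(function(s) unname(s$nodal))
  mods <- avg_entries(function(s) as.vector(s$module_matrix))
  mm <- matrix(mods$values, nrow = nrow(base$module_matrix),
               dimnames = dimnames(base$module_matrix))
  nodal <- nod$values
  names(nodal) <- names(base$nodal)
  out <- structure(list(subject_id = base$subject_id,
                        window_length = NA_integer_,
                        nodal = nodal, module_matrix = mm),
                   class = "variability_set")
  attr(out, "lengths") <- vapply(sets, function(s) s$window_length, 1L)
  attr(out, "n_used") <- list(nodal = nod$n_used, module = mods$n_used)
  out
}

#' Window-length robustness sweep
#'
#' Recomputes the variability at every window length in `lengths` and
#' correlates the resulting variability vectors between every pair of
#' lengths. For a single subject the correlation is over units (nodes for
#' the nodal level; the unfolded module matrix for the module level). For
#' a cohort, per-subject correlations are averaged over subjects.
#'
#' @param x A [subject_ts()] (single subject) or a manifest data frame
#'   (cohort; see [cohort_variability()]).
#' @param partition A [network_partition()].
#' @param lengths Integer window lengths to sweep (default 10:20 volumes).
#' @param ... Passed to [variability_set()] / [cohort_variability()].
#' @return An object of class `sweep_result`: list with
#'   `values` (long tibble over subjects, levels, units and lengths),
#'   `cor_nodal` and `cor_module` (L x L correlation matrices, dimnames =
#'   lengths), and `lengths`.
#' @export
window_length_sweep <- function(x, partition, lengths = 10:20, ...) {
  UseMethod("window_length_sweep")
}

#' @export
window_length_sweep.subject_ts <- function(x, partition, lengths = 10:20,
                                           ...) {
  man <- tibble::tibble(subject_id = x$subject_id, group = "control",
                        path = NA_character_)
  sets <- lapply(lengths, function(l) variability_set(x, partition, l, ...))
  sweep_from_sets(list(sets), man, lengths)
}

#' @export
window_length_sweep.data.frame <- function(x, partition, lengths = 10:20,
                                           tr_seconds = 2, ...) {
  per_subject <- purrr::pmap(
    x[, c("subject_id", "group", "path")],
    function(subject_id, group, path) {
      series <- read_timeseries(path, partition, subject_id = subject_id,
                                tr_seconds = tr_seconds)
      lapply(lengths, function(l) variability_set(series, partition, l, ...))
    })
  sweep_from_sets(per_subject, x, lengths)
}

sweep_from_sets <- function(per_subject, manifest, lengths) {
  lengths <- as.integer(lengths)
  nl <- length(lengths)
  values <- purrr::map2_dfr(per_subject, manifest$group, function(sets, grp) {
    dplyr::mutate(purrr::map_dfr(sets, tidy.variability_set),
                  group = grp, .after = 1)
  })
  cor_level <- function(extract) {
    acc <- matrix(0, nl, nl)
    cnt <- matrix(0, nl, nl)
    for (sets in per_subject) {
      vecs <- lapply(sets, extract)
      for (i in seq_len(nl)) for (j in i:nl) {
        r <- stats::cor(vecs[[i]], vecs[[j]], use = "complete.obs")
        if (!is.na(r)) {
          acc[i, j] <- acc[i, j] + r
          cnt[i, j] <- cnt[i, j] + 1
        }
      }
    }
    m <- acc / cnt
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(lengths, lengths)
    m
  }
  cn <- cor_level(function(s) s$nodal)
  cm <- cor_level(function(s) {
    m <- s$module_matrix
    c(diag(m), m[upper.tri(m)])
  })
  structure(list(values = values, cor_nodal = cn, cor_module = cm,
                 lengths = lengths),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  off <- x$cor_nodal[upper.tri(x$cor_nodal)]
  cat(sprintf(
    "<sweep_result> lengths %s; min/median cross-length nodal r = %.4f / %.4f\n",
    paste(range(x$lengths), collapse = "-"), min(off), stats::median(off)))
  invisible(x)
}

#' Minimum cross-length correlation of a sweep
#' @param sweep A [window_length_sweep()] result.
#' @param level `"nodal"` or `"module"`.
#' @return The minimum off-diagonal entry of the cross-length correlation
#'   matrix.
#' @export
sweep_min_correlation <- function(sweep, level = c("nodal", "module")) {
  level <- match.arg(level)
  m <- if (level == "nodal") sweep$cor_nodal else sweep$cor_module
  min(m[upper.tri(m)])
}
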