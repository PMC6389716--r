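#' Construct a network partition
#'
#' A network partition assigns every node (ROI) of a brain parcellation to
#' exactly one functional module (subnetwork). It drives the intra- and
#' inter-network unfolding of windowed connectivity matrices and the
#' module-level reporting of the pipeline.
#'
#' @param nodes A data frame with columns `node_index` (unique positive
#'   integers) and `module` (non-empty module label per node). Optional
#'   columns `x`, `y`, `z` carry MNI coordinates in mm.
#' @param reportable_modules Character vector of module labels used in
#'   reports. Defaults to all labels except `"Uncertain"` when that label
#'   is present (nodes labelled Uncertain are still computed everywhere;
#'   they are only dropped from default reports).
#'
#' @return A tibble of class `network_partition`, sorted by `node_index`,
#'   with attribute `reportable_modules`.
#' @export
#' @examples
#' p <- network_partition(data.frame(node_index = 1:4,
#'                                   module = c("A", "A", "B", "B")))
#' n_nodes(p)
#' module_labels(p)
network_partition <- function(nodes, reportable_modules = NULL) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("node_index", "module") %in% names(nodes))) {
    stop("partition needs columns 'node_index' and 'module'", call. = FALSE)
  }
  idx <- nodes$node_index
  if (anyNA(idx) || any(idx != as.integer(idx)) || any(idx < 1)) {
    stop("node_index must be positive integers", call. = FALSE)
  }
  dup <- idx[duplicated(idx)]
  if (length(dup) > 0) {
    stop("duplicated node_index: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(nodes$module) || any(!nzchar(nodes$module))) {
    stop("every node needs a non-empty module label", call. = FALSE)
  }
  nodes$node_index <- as.integer(idx)
  nodes$module <- as.character(nodes$module)
  nodes <- dplyr::arrange(nodes, .data$node_index)
  labels <- unique(nodes$module)
  if (length(labels) < 2) {
    stop("a partition needs at least 2 distinct modules", call. = FALSE)
  }
  if (is.null(reportable_modules)) {
    reportable_modules <- setdiff(labels, "Uncertain")
    if (length(reportable_modules) == 0) reportable_modules <- labels
  } else if (!all(reportable_modules %in% labels)) {
    stop("reportable_modules must be a subset of the module labels",
         call. = FALSE)
  }
  structure(nodes,
            class = c("network_partition", class(tibble::tibble())),
            reportable_modules = reportable_modules)
}

#' Read a node-to-module partition table
#'
#' Expects a TSV with header columns `node_index` and `module` and optional
#' `x`, `y`, `z` MNI coordinates.
#'
#' @param path Path to the partition TSV.
#' @inheritParams network_partition
#' @return A [network_partition()] tibble.
#' @export
read_partition <- function(path, reportable_modules = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("node_index", "module") %in% names(raw))) {
    stop("partition file must have 'node_index' and 'module' columns: ",
         path, call. = FALSE)
  }
  suppressWarnings(ni <- as.numeric(raw$node_index))
  if (anyNA(ni) || any(ni != round(ni))) {
    stop("non-integer node_index in ", path, call. = FALSE)
  }
  raw$node_index <- as.integer(ni)
  network_partition(raw, reportable_modules = reportable_modules)
}

#' Write a partition table to TSV
#' @param partition A [network_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(tibble::as_tibble(unclass_partition(partition)), path)
  invisible(path)
}

unclass_partition <- function(partition) {
  out <- partition
  class(out) <- setdiff(class(out), "network_partition")
  attr(out, "reportable_modules") <- NULL
  out
}

#' The synthetic 264-node, 13-module partition shipped with the package
#'
#' A stand-in for the public 264-ROI functional parcellation: the 13 module
#' labels and module sizes follow the published layout, but the
#' node-to-module assignment is synthetic (consecutive blocks, no MNI
#' coordinates). Suitable for simulation and pipeline validation, not for
#' anatomical interpretation.
#'
#' @return A [network_partition()] with 264 nodes and 13 modules
#'   (12 reportable; `"Uncertain"` is excluded from reports by default).
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "partition264_synthetic.tsv",
                             package = "dfcvar", mustWork = TRUE))
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d nodes, %d modules (%d reportable)\n",
              nrow(x), length(module_labels(x)),
              length(reportable_modules(x))))
  print(tibble::as_tibble(unclass_partition(x)), ...)
  invisible(x)
}

#' Number of nodes in a partition
#' @param partition A [network_partition()].
#' @return Integer node count.
#' @export
n_nodes <- function(partition) nrow(partition)

#' Module labels of a partition
#' @param partition A [network_partition()].
#' @return Character vector of distinct labels in order of first appearance
#'   (ascending node index).
#' @export
module_labels <- function(partition) unique(partition$module)

#' Reportable module labels
#' @param partition A [network_partition()].
#' @return Character vector of labels used in default reports.
#' @export
reportable_modules <- function(partition) attr(partition, "reportable_modules")

#' Per-module node positions (storage order)
#'
#' Positions are 1-based columns of the time-series matrix, i.e. ranks of
#' ascending `node_index`, not the raw `node_index` values.
#'
#' @param partition A [network_partition()].
#' @return Named list of integer vectors, one per module label.
#' @export
module_members <- function(partition) {
  split(seq_len(nrow(partition)), partition$module)[module_labels(partition)]
}

#' A subject's ROI time-series matrix
#'
#' @param data Numeric T x M matrix: rows are volumes in acquisition order,
#'   columns are nodes in partition (ascending node index) order. No missing
#'   values; every column must vary over the full series.
#' @param subject_id Subject identifier.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @return An object of class `subject_ts`.
#' @export
subject_ts <- function(data, subject_id = "subject", tr_seconds = 2) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data))) colnames(data) <- seq_len(ncol(data))
  if (nrow(data) < 2) stop("time series needs at least 2 volumes", call. = FALSE)
  if (anyNA(data)) stop("time series contains missing values", call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s) at node position(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = tr_seconds),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s: %d volumes x %d nodes, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Read a subject's ROI time series from delimited text
#'
#' The file holds a T x M numeric matrix (rows = volumes, columns = nodes).
#' TSV or CSV is sniffed from the extension (`.csv` comma, otherwise tab).
#' A header row of node indices is optional; when present, columns are
#' reordered to ascending partition node-index order.
#'
#' @param path Path to the matrix file.
#' @param partition A [network_partition()]; column count must match.
#' @param subject_id Identifier stored on the result (defaults to the file
#'   name without extension).
#' @param tr_seconds Repetition time in seconds.
#' @return A [subject_ts()].
#' @export
read_timeseries <- function(path, partition, subject_id = NULL,
                            tr_seconds = 2) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(fields))
  # header iff the first row is non-numeric, or is exactly the set of
  # partition node indices (a data row is real-valued signal, not that)
  has_header <- anyNA(num) ||
    (all(num == round(num)) && setequal(as.integer(num), partition$node_index))
  mat <- as.matrix(utils::read.table(path, sep = sep, header = has_header,
                                     check.names = FALSE))
  storage.mode(mat) <- "double"
  M <- n_nodes(partition)
  if (ncol(mat) != M) {
    stop(sprintf("column count %d does not match partition size %d: %s",
                 ncol(mat), M, path), call. = FALSE)
  }
  if (has_header) {
    hdr <- as.integer(colnames(mat))
    if (anyNA(hdr) || !setequal(hdr, partition$node_index)) {
      stop("header node indices do not match the partition: ", path,
           call. = FALSE)
    }
    mat <- mat[, match(partition$node_index, hdr), drop = FALSE]
  }
  if (anyNA(mat)) stop("missing value(s) in ", path, call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column for node index ",
         paste(partition$node_index[sds == 0], collapse = ", "),
         " in ", path, call. = FALSE)
  }
  colnames(mat) <- partition$node_index
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  subject_ts(mat, subject_id = subject_id, tr_seconds = tr_seconds)
}

#' Write a subject time series as TSV (header row of node indices)
#' @param series A [subject_ts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  df <- as.data.frame(series$data)
  readr::write_tsv(df, path, col_names = TRUE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A TSV with columns `subject_id`, `group` (`control`/`patient`,
#' case-insensitive), `path` (time-series file, absolute or relative to the
#' manifest's directory), `age`, `sex` (`M`/`F`), and clinical scores
#' `updrs3`, `hy` (may be empty, typically for controls). Patients missing
#' `updrs3` are kept but flagged with a warning; they are excluded from the
#' clinical-correlation stage only.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with normalized `group` labels and resolved `path`s.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "group", "path")
  if (!all(req %in% names(man))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age", "sex", "updrs3", "hy")) {
    if (!col %in% names(man)) man[[col]] <- NA
  }
  man$subject_id <- as.character(man$subject_id)
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup) > 0) {
    stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  grp <- tolower(trimws(man$group))
  bad <- setdiff(unique(grp), c("control", "patient"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  man$group <- grp
  man$path <- ifelse(is_absolute_path(man$path), man$path,
                     file.path(dirname(path), man$path))
  missing_files <- man$path[!file.exists(man$path)]
  if (length(missing_files) > 0) {
    stop("manifest path(s) not found: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  n_missing <- sum(man$group == "patient" & is.na(man$updrs3))
  if (n_missing > 0) {
    warning(n_missing, " patient(s) lack updrs3; they are excluded from ",
            "clinical correlation only", call. = FALSE)
  }
  man
}

is_absolute_path <- function(p) {
  grepl("^(/|[A-Za-z]:[\\\\/]|~)", p)
}

#' Enumerate the analysis units defined by a partition
#'
#' Nodal units are single nodes; intra units are modules; inter units are
#' unordered module pairs labelled `"A|B"` with A before B in partition
#' label order. Together the intra pair sets (within-module upper
#' triangles) and inter blocks tile the off-diagonal upper triangle of the
#' M x M grid exactly once.
#'
#' @param partition A [network_partition()].
#' @return A tibble with columns `level` (`nodal`/`intra`/`inter`) and
#'   `unit` (node index as character, module label, or `"A|B"`).
#' @export
partition_units <- function(partition) {
  labels <- module_labels(partition)
  pairs <- if (length(labels) >= 2) {
    utils::combn(labels, 2, FUN = function(ab) paste(ab, collapse = "|"))
  } else character(0)
  dplyr::bind_rows(
    tibble::tibble(level = "nodal", unit = as.character(partition$node_index)),
    tibble::tibble(level = "intra", unit = labels),
    tibble::tibble(level = "inter", unit = pairs)
  )
}
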