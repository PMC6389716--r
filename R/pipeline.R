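pipeline_defaults <- function() {
  list(
    manifest = NULL,
    partition = NULL,
    out_dir = NULL,
    window_length = 20L,
    sweep_lengths = 10:20,
    n_perm = 10000L,
    seed = 1L,
    outlier_sd = 3,
    score_names = c("updrs3", "hy"),
    nodal_threshold = 0.005,
    network_threshold = 0.05,
    network_threshold_strict = 0.005,
    tr_seconds = 2,
    fisher_z = FALSE,
    skip_degenerate_windows = FALSE,
    fdr = FALSE,
    include_uncertain = FALSE)
}

#' Resolve a pipeline configuration
#'
#' Merges, in increasing precedence: the documented defaults, a YAML
#' config file, and direct overrides. Unknown keys are rejected (typo
#' safety) and ranges validated.
#'
#' @param path Optional YAML file whose keys are config fields.
#' @param overrides Named list of overrides (e.g. from CLI flags); takes
#'   precedence over the file.
#' @return A validated named list of class `pipeline_config`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  apply_layer <- function(cfg, layer, origin) {
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(cfg, layer)
  }
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    cfg <- apply_layer(cfg, file_cfg, path)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  for (key in c("nodal_threshold", "network_threshold",
                "network_threshold_strict")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(key, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$window_length < 3) {
    stop("window_length must be >= 3 volumes (Pearson correlation needs ",
         ">= 3 points)", call. = FALSE)
  }
  if (!is.null(cfg$sweep_lengths) && any(cfg$sweep_lengths < 3)) {
    stop("sweep_lengths must all be >= 3 volumes", call. = FALSE)
  }
  if (cfg$n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (cfg$outlier_sd <= 0) stop("outlier_sd must be > 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

add_significance <- function(comparison, cfg) {
  dplyr::mutate(
    comparison,
    significant = dplyr::case_when(
      .data$level == "nodal" ~ .data$p_two_sided < cfg$nodal_threshold,
      TRUE ~ .data$p_two_sided < cfg$network_threshold),
    tier = dplyr::case_when(
      .data$level != "nodal" &
        .data$p_two_sided < cfg$network_threshold_strict ~ "strict",
      .data$significant ~ "standard",
      TRUE ~ "ns"))
}

reportable_units <- function(units_tbl, partition, include_uncertain) {
  if (include_uncertain) return(units_tbl)
  rep_mods <- reportable_modules(partition)
  node_idx <- suppressWarnings(as.integer(units_tbl$unit))
  node_ok <- partition$module[match(node_idx,
                                    partition$node_index)] %in% rep_mods
  mods <- strsplit(units_tbl$unit, "|", fixed = TRUE)
  mod_ok <- vapply(mods, function(m) all(m %in% rep_mods), TRUE)
  keep <- ifelse(units_tbl$level == "nodal", node_ok, mod_ok)
  units_tbl[keep, , drop = FALSE]
}

#' Run the full temporal-variability analysis
#'
#' Executes, in order: per-subject variability at the primary window
#' length, permutation group comparison of every unit, within-group
#' intra- vs inter-network paired tests, Spearman clinical correlation,
#' the window-length robustness sweep, and cross-length averaging. All
#' results are written as TSV under `config$out_dir`, together with a
#' JSON run summary and a timing/accounting log. Deterministic given
#' identical inputs and seed.
#'
#' @param config A [parse_config()] result (or a named list of the same
#'   fields). `manifest`, `partition` and `out_dir` are required.
#' @return The output directory path, invisibly. Key outputs:
#'   `variability.tsv`, `group_comparison.tsv`, `intra_vs_inter.tsv`,
#'   `clinical_correlation.tsv`, `sweep_values.tsv`,
#'   `sweep_correlation.tsv`, `variability_avg.tsv`,
#'   `group_comparison_avg.tsv`, `run_summary.json`, `log.txt`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    parse_config(overrides = config)
  for (key in c("manifest", "partition", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config lacks required field '", key, "'",
                                  call. = FALSE)
  }
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "log.txt")
  status_path <- file.path(out, "run_summary.json")
  if (file.exists(status_path)) unlink(status_path)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("FAILED stage %s: %s", name, conditionMessage(e)))
      writeLines(log_lines, log_path)
      writeLines("INCOMPLETE", file.path(out, "INCOMPLETE"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  partition <- stage("read_partition", read_partition(cfg$partition))
  manifest <- stage("read_manifest", read_manifest(cfg$manifest))

  variability <- stage("variability", cohort_variability(
    manifest, partition, window_length = cfg$window_length,
    fisher_z = cfg$fisher_z,
    skip_degenerate_windows = cfg$skip_degenerate_windows,
    tr_seconds = cfg$tr_seconds))
  readr::write_tsv(variability, file.path(out, "variability.tsv"))

  # unit bookkeeping: M nodal, K intra, K(K-1)/2 inter
  m <- n_nodes(partition)
  k <- length(module_labels(partition))
  unit_counts <- variability |>
    dplyr::distinct(.data$level, .data$unit) |>
    dplyr::count(.data$level)
  expected <- c(inter = k * (k - 1) / 2, intra = k, nodal = m)
  got <- stats::setNames(unit_counts$n, unit_counts$level)[names(expected)]
  if (!identical(unname(as.integer(got)), unname(as.integer(expected)))) {
    stop("unit bookkeeping failed: expected ",
         paste(names(expected), expected, collapse = ", "),
         " got ", paste(got, collapse = ", "), call. = FALSE)
  }

  comparison <- stage("group_comparison", add_significance(
    group_compare(variability, n_perm = cfg$n_perm, seed = cfg$seed), cfg))
  if (cfg$fdr) {
    comparison <- comparison |>
      dplyr::group_by(.data$level) |>
      dplyr::mutate(p_fdr = stats::p.adjust(.data$p_two_sided, "BH")) |>
      dplyr::ungroup()
  }
  readr::write_tsv(comparison, file.path(out, "group_comparison.tsv"))

  ivi <- stage("intra_vs_inter", dplyr::bind_rows(
    intra_vs_inter(variability, "control", n_perm = cfg$n_perm,
                   seed = cfg$seed),
    intra_vs_inter(variability, "patient", n_perm = cfg$n_perm,
                   seed = cfg$seed)))
  readr::write_tsv(ivi, file.path(out, "intra_vs_inter.tsv"))

  clin <- stage("clinical_correlation", {
    scores <- intersect(cfg$score_names, names(manifest))
    purrr::map_dfr(scores, function(sc) {
      n_scored <- sum(manifest$group == "patient" & !is.na(manifest[[sc]]))
      if (n_scored < 5) return(NULL)
      dplyr::mutate(
        clinical_correlation(variability, manifest, score = sc,
                             n_sd = cfg$outlier_sd),
        score = sc, .before = 1)
    })
  })
  readr::write_tsv(clin, file.path(out, "clinical_correlation.tsv"))

  sweep_done <- !is.null(cfg$sweep_lengths) && length(cfg$sweep_lengths) >= 2
  if (sweep_done) {
    sweep <- stage("window_sweep", window_length_sweep(
      manifest, partition, lengths = cfg$sweep_lengths,
      tr_seconds = cfg$tr_seconds, fisher_z = cfg$fisher_z,
      skip_degenerate_windows = cfg$skip_degenerate_windows))
    readr::write_tsv(sweep$values, file.path(out, "sweep_values.tsv"))
    ct <- as.data.frame(sweep$cor_nodal)
    ct <- cbind(tibble::tibble(level = "nodal",
                               length = rownames(sweep$cor_nodal)), ct)
    cm <- as.data.frame(sweep$cor_module)
    cm <- cbind(tibble::tibble(level = "module",
                               length = rownames(sweep$cor_module)), cm)
    readr::write_tsv(rbind(ct, cm), file.path(out, "sweep_correlation.tsv"))

    avg <- stage("average_over_lengths", {
      sweep$values |>
        dplyr::group_by(.data$subject_id, .data$group, .data$level,
                        .data$unit) |>
        dplyr::summarise(
          n_lengths = dplyr::n(),
          n_present = sum(!is.na(.data$value)),
          value = ifelse(dplyr::n() - sum(!is.na(.data$value)) <= 1,
                         mean(.data$value, na.rm = TRUE), NA_real_),
          .groups = "drop") |>
        dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_,
                                     .data$value))
    })
    readr::write_tsv(avg, file.path(out, "variability_avg.tsv"))
    cmp_avg <- stage("group_comparison_avg", add_significance(
      group_compare(avg, n_perm = cfg$n_perm, seed = cfg$seed), cfg))
    readr::write_tsv(cmp_avg, file.path(out, "group_comparison_avg.tsv"))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("dfcvar")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_subjects = nrow(manifest),
    n_control = sum(manifest$group == "control"),
    n_patient = sum(manifest$group == "patient"),
    unit_counts = as.list(expected),
    sweep_done = sweep_done,
    n_significant = as.list(table(comparison$level[comparison$significant])),
    status = "complete")
  jsonlite::write_json(summary, status_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  writeLines(log_lines, log_path)
  invisible(out)
}

#' Render human-readable summary tables from a completed run
#'
#' Produces, under `<run_dir>/report/`: a listing of significantly
#' different units with group means and p-values, the K x K group-mean
#' variability matrix per group, and scatter data (per-patient value vs
#' score) for every unit whose clinical correlation reaches p < 0.05.
#' Modules outside the partition's reportable set (by default the
#' "Uncertain" module) are excluded unless the run was configured with
#' `include_uncertain`; raw run outputs always keep all units.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return The report directory path, invisibly.
#' @export
render_report <- function(run_dir) {
  status_path <- file.path(run_dir, "run_summary.json")
  if (!file.exists(status_path) || file.exists(file.path(run_dir,
                                                         "INCOMPLETE"))) {
    stop("run at ", run_dir, " is incomplete; check log.txt for the ",
         "failed stage", call. = FALSE)
  }
  summary <- jsonlite::read_json(status_path)
  if (!identical(summary$status, "complete")) {
    stop("run summary does not report completion", call. = FALSE)
  }
  cfg <- summary$config
  partition <- read_partition(cfg$partition)
  include_uncertain <- isTRUE(cfg$include_uncertain)
  rep_dir <- file.path(run_dir, "report")
  if (!dir.exists(rep_dir)) dir.create(rep_dir)

  comparison <- readr::read_tsv(file.path(run_dir, "group_comparison.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  comparison <- reportable_units(comparison, partition, include_uncertain)
  sig <- dplyr::filter(comparison, .data$significant) |>
    dplyr::arrange(.data$level, .data$p_two_sided)
  readr::write_tsv(sig, file.path(rep_dir, "significant_units.tsv"))

  variability <- readr::read_tsv(file.path(run_dir, "variability.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
  labels <- module_labels(partition)
  if (!include_uncertain) {
    labels <- intersect(labels, reportable_modules(partition))
  }
  for (grp in unique(variability$group)) {
    mods <- variability |>
      dplyr::filter(.data$group == grp, .data$level != "nodal") |>
      dplyr::group_by(.data$level, .data$unit) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
    mat <- matrix(NA_real_, length(labels), length(labels),
                  dimnames = list(labels, labels))
    intra <- dplyr::filter(mods, .data$level == "intra",
                           .data$unit %in% labels)
    di <- match(intra$unit, labels)
    mat[cbind(di, di)] <- intra$value
    inter <- dplyr::filter(mods, .data$level == "inter")
    ab <- strsplit(inter$unit, "|", fixed = TRUE)
    for (i in seq_along(ab)) {
      a <- ab[[i]][1]; b <- ab[[i]][2]
      if (all(c(a, b) %in% labels)) {
        mat[a, b] <- inter$value[i]
        mat[b, a] <- inter$value[i]
      }
    }
    df <- cbind(tibble::tibble(module = rownames(mat)), as.data.frame(mat))
    readr::write_tsv(df, file.path(rep_dir,
                                   sprintf("module_matrix_%s.tsv", grp)))
  }

  clin_path <- file.path(run_dir, "clinical_correlation.tsv")
  if (file.exists(clin_path) && file.size(clin_path) > 0) {
    clin <- readr::read_tsv(clin_path, show_col_types = FALSE,
                            progress = FALSE)
    if (nrow(clin) > 0) {
      clin <- reportable_units(clin, partition, include_uncertain)
      readr::write_tsv(dplyr::arrange(clin, .data$p),
                       file.path(rep_dir, "clinical_correlation.tsv"))
      hits <- dplyr::filter(clin, .data$p < 0.05)
      if (nrow(hits) > 0) {
        manifest <- read_manifest(cfg$manifest)
        scatter <- purrr::pmap_dfr(
          hits[, c("score", "level", "unit")],
          function(score, level, unit) {
            variability |>
              dplyr::filter(.data$group == "patient",
                            .data$level == !!level, .data$unit == !!unit) |>
              dplyr::inner_join(
                manifest[manifest$group == "patient",
                         c("subject_id", score)], by = "subject_id") |>
              dplyr::transmute(score_name = score, level = !!level,
                               unit = !!unit,
                               subject_id = .data$subject_id,
                               value = .data$value,
                               score = .data[[score]])
          })
        readr::write_tsv(scatter, file.path(rep_dir, "scatter_data.tsv"))
      }
    }
  }
  invisible(rep_dir)
}
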