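#' Permutation test for a group difference in means
#'
#' Non-parametric inference on `mean(patient) - mean(control)`: subjects
#' are randomly reassigned to two groups of the original sizes, the
#' difference of group means is recomputed for each reassignment, and the
#' tail proportions of the resulting null distribution give the p-values.
#' The add-one estimator `(k + 1) / (n_perm + 1)` is used so a Monte-Carlo
#' p-value is never exactly zero.
#'
#' @param values_control,values_patient Numeric vectors (missing values
#'   dropped, with counts recorded).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `perm_test` with fields `observed_diff`,
#'   `p_greater`, `p_smaller`, `p_two_sided`, `n_perm`, `n_control`,
#'   `n_patient`, `n_dropped`, `seed`, and the permutation distribution
#'   summary (`null_mean`, `null_sd`).
#' @export
permutation_group_test <- function(values_control, values_patient,
                                   n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  n_dropped <- sum(is.na(values_control)) + sum(is.na(values_patient))
  vc <- values_control[!is.na(values_control)]
  vp <- values_patient[!is.na(values_patient)]
  if (length(vc) < 2 || length(vp) < 2) {
    stop("need >= 2 non-missing values per group", call. = FALSE)
  }
  pooled <- c(vc, vp)
  n <- length(pooled)
  np <- length(vp)
  observed <- mean(vp) - mean(vc)
  degenerate <- stats::sd(pooled) == 0
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  null_diffs <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, np)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, 1.0)
  new_perm_test(observed, null_diffs, n_perm, seed,
                n_control = length(vc), n_patient = np,
                n_dropped = n_dropped, degenerate = degenerate)
}

new_perm_test <- function(observed, null_diffs, n_perm, seed,
                          ..., degenerate = FALSE) {
  # tie tolerance: a resample reproducing the observed labelling must count
  # in both tails despite floating-point summation-order noise
  eps <- 1e-10 * max(1, abs(observed))
  p_greater <- (sum(null_diffs >= observed - eps) + 1) / (n_perm + 1)
  p_smaller <- (sum(null_diffs <= observed + eps) + 1) / (n_perm + 1)
  structure(list(observed_diff = observed,
                 p_greater = p_greater, p_smaller = p_smaller,
                 p_two_sided = min(1, 2 * min(p_greater, p_smaller)),
                 n_perm = n_perm, seed = as.integer(seed),
                 null_mean = mean(null_diffs),
                 null_sd = stats::sd(null_diffs),
                 degenerate = degenerate, ...),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed diff = %.4g; p_greater = %.4g, p_smaller = %.4g, two-sided = %.4g (%d permutations)%s\n",
    x$observed_diff, x$p_greater, x$p_smaller, x$p_two_sided, x$n_perm,
    if (isTRUE(x$degenerate)) " [degenerate: all values identical]" else ""))
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff,
                 p_greater = x$p_greater, p_smaller = x$p_smaller,
                 p_two_sided = x$p_two_sided)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, seed = x$seed,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 degenerate = isTRUE(x$degenerate))
}

#' Paired sign-flip test for intra- vs inter-network variability
#'
#' Tests whether, within subjects, a module's intra-network variability is
#' lower than its mean inter-network variability with the other modules.
#' The statistic is the mean within-subject difference
#' `intra - mean(inter)`; the null is generated by randomly negating the
#' paired differences. The primary p-value (`p_smaller`) is the one-sided
#' tail for intra < inter.
#'
#' @param intra_values,inter_values Paired per-subject vectors (same
#'   subjects, same order); `inter_values` is typically each subject's
#'   mean inter-network variability for the module.
#' @inheritParams permutation_group_test
#' @return A `perm_test` object (see [permutation_group_test()]); the
#'   observed statistic is the mean paired difference.
#' @export
paired_signflip_test <- function(intra_values, inter_values,
                                 n_perm = 10000, seed = 1L) {
  if (length(intra_values) != length(inter_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  keep <- !(is.na(intra_values) | is.na(inter_values))
  d <- intra_values[keep] - inter_values[keep]
  if (length(d) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  observed <- mean(d)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  flips <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                  length(d), n_perm)
  null_diffs <- as.vector(crossprod(d, flips)) / length(d)
  new_perm_test(observed, null_diffs, n_perm, seed,
                n_pairs = length(d), n_dropped = sum(!keep),
                degenerate = all(d == 0))
}

#' Group comparison of every variability unit
#'
#' Runs the label-permutation test on each unit (node, module, or module
#' pair) of a long cohort-variability table, sharing one set of subject
#' reassignments across all units, as is standard when many network
#' metrics are tested on the same cohort.
#'
#' Units with missing values fall back to a per-unit permutation with the
#' missing subjects dropped (pairwise deletion, counts reported).
#'
#' @param variability Long tibble from [cohort_variability()] /
#'   [cohort_variability_mem()] (columns `subject_id`, `group`, `level`,
#'   `unit`, `value`).
#' @inheritParams permutation_group_test
#' @return A tibble with one row per unit: `level`, `unit`,
#'   `mean_control`, `mean_patient`, `observed_diff`, `p_greater`,
#'   `p_smaller`, `p_two_sided`, `n_missing`.
#' @export
group_compare <- function(variability, n_perm = 10000, seed = 1L) {
  wide <- tidyr::pivot_wider(
    dplyr::distinct(variability, .data$level, .data$unit, .data$subject_id,
                    .data$value),
    names_from = "subject_id", values_from = "value")
  groups <- variability |>
    dplyr::distinct(.data$subject_id, .data$group)
  ids <- setdiff(names(wide), c("level", "unit", "group"))
  grp <- groups$group[match(ids, groups$subject_id)]
  u <- as.matrix(wide[, ids])
  is_pat <- grp == "patient"
  nc <- sum(!is_pat)
  np <- sum(is_pat)
  if (nc < 2 || np < 2) stop("need >= 2 subjects per group", call. = FALSE)
  n <- nc + np
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # one shared reassignment per iteration, encoded as a +-weight matrix
  w <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, np)
    wb <- rep(-1 / nc, n)
    wb[idx] <- 1 / np
    w[, b] <- wb
  }
  complete <- !apply(u, 1, anyNA)
  mean_p <- rowMeans(u[, is_pat, drop = FALSE], na.rm = TRUE)
  mean_c <- rowMeans(u[, !is_pat, drop = FALSE], na.rm = TRUE)
  observed <- mean_p - mean_c
  out <- tibble::tibble(level = wide$level, unit = wide$unit,
                        mean_control = mean_c, mean_patient = mean_p,
                        observed_diff = observed,
                        p_greater = NA_real_, p_smaller = NA_real_,
                        p_two_sided = NA_real_,
                        n_missing = as.integer(rowSums(is.na(u))))
  if (any(complete)) {
    d <- u[complete, , drop = FALSE] %*% w
    obs <- observed[complete]
    eps <- 1e-10 * pmax(1, abs(obs))
    k_ge <- rowSums(d >= obs - eps)
    k_le <- rowSums(d <= obs + eps)
    pg <- (k_ge + 1) / (n_perm + 1)
    ps <- (k_le + 1) / (n_perm + 1)
    out$p_greater[complete] <- pg
    out$p_smaller[complete] <- ps
    out$p_two_sided[complete] <- pmin(1, 2 * pmin(pg, ps))
  }
  for (i in which(!complete)) {
    pt <- permutation_group_test(u[i, !is_pat], u[i, is_pat],
                                 n_perm = n_perm, seed = seed)
    out$p_greater[i] <- pt$p_greater
    out$p_smaller[i] <- pt$p_smaller
    out$p_two_sided[i] <- pt$p_two_sided
  }
  out
}

#' Flag values more than `n_sd` standard deviations from the mean
#'
#' Single-pass rule: a value is an outlier when
#' `|x - mean(x)| > n_sd * sd(x)` (sample SD, n - 1 denominator), with
#' mean and SD computed once on the full vector (no iteration). A
#' zero-SD vector keeps every value.
#'
#' @param values Numeric vector (length >= 3; `NA`s are never kept).
#' @param n_sd Threshold in SD units (default 3).
#' @return Integer vector of kept indices.
#' @export
remove_outliers <- function(values, n_sd = 3) {
  if (sum(!is.na(values)) < 3) stop("need >= 3 values", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(which(!is.na(values)))
  which(!is.na(values) & abs(values - m) <= n_sd * s)
}

#' Spearman correlation with outlier screening
#'
#' Correlates a per-patient variability measure with a clinical score.
#' Pairwise-complete observations are used; values outside `n_sd` SDs of
#' the mean (by default screened on the variability values only) are
#' removed before the correlation, and the unscreened correlation is
#' retained alongside for comparison. Spearman's rho uses mid-ranks for
#' ties; the two-sided p-value is exact for n <= 9 and uses the
#' t-approximation otherwise.
#'
#' @param variability Per-patient variability values.
#' @param scores Paired clinical scores.
#' @param n_sd Outlier threshold in SD units (default 3).
#' @param screen Which variable(s) to screen for outliers:
#'   `"variability"` (default) or `"both"`.
#' @return A one-row tibble: `n_used`, `n_outliers`, `rho`, `p`,
#'   `rho_with_outliers`, `p_with_outliers`.
#' @export
spearman_with_outlier_removal <- function(variability, scores, n_sd = 3,
                                          screen = c("variability", "both")) {
  screen <- match.arg(screen)
  if (length(variability) != length(scores)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  keep0 <- which(!(is.na(variability) | is.na(scores)))
  if (length(keep0) < 5) stop("need >= 5 complete pairs", call. = FALSE)
  v <- variability[keep0]
  s <- scores[keep0]
  kept <- remove_outliers(v, n_sd = n_sd)
  if (screen == "both") kept <- intersect(kept, remove_outliers(s, n_sd = n_sd))
  spearman <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = length(x) <= 9))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  with_out <- spearman(v, s)
  without <- spearman(v[kept], s[kept])
  tibble::tibble(n_used = length(kept),
                 n_outliers = length(v) - length(kept),
                 rho = without["rho"], p = without["p"],
                 rho_with_outliers = with_out["rho"],
                 p_with_outliers = with_out["p"])
}

#' Clinical correlation for every variability unit
#'
#' Joins patient clinical scores from the manifest onto the long
#' variability table and runs [spearman_with_outlier_removal()] per unit.
#' Patients without the requested score are dropped pairwise.
#'
#' @inheritParams group_compare
#' @param manifest Manifest tibble with `subject_id` and the score column.
#' @param score Score column name (default `"updrs3"`).
#' @inheritParams spearman_with_outlier_removal
#' @return A tibble with one row per unit: `level`, `unit`, `n_used`,
#'   `n_outliers`, `rho`, `p`, `rho_with_outliers`, `p_with_outliers`.
#' @export
clinical_correlation <- function(variability, manifest, score = "updrs3",
                                 n_sd = 3,
                                 screen = c("variability", "both")) {
  screen <- match.arg(screen)
  if (!score %in% names(manifest)) {
    stop("manifest lacks score column '", score, "'", call. = FALSE)
  }
  pats <- manifest[manifest$group == "patient",
                   c("subject_id", score)]
  dat <- variability |>
    dplyr::filter(.data$group == "patient") |>
    dplyr::inner_join(pats, by = "subject_id")
  dat |>
    dplyr::group_by(.data$level, .data$unit) |>
    dplyr::group_modify(function(df, key) {
      spearman_with_outlier_removal(df$value, df[[score]],
                                    n_sd = n_sd, screen = screen)
    }) |>
    dplyr::ungroup()
}

#' Chi-square test for a sex-ratio (2 x 2) table
#'
#' Pearson chi-square without continuity correction, the count-based
#' equivalent of a pooled-variance t-test on binary coding at these
#' sample sizes.
#'
#' @param counts A 2 x 2 matrix of counts (groups x sexes), all cells
#'   >= 0 with positive margins.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
sex_ratio_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    stop("counts must be a non-negative 2 x 2 table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in the 2 x 2 table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Two-sample t-test from raw vectors
#'
#' Welch test by default (`var_equal = FALSE`).
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @param var_equal Pool the variances (Student's t) instead of Welch.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  ht <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_x = mean(x, na.rm = TRUE),
                 mean_y = mean(y, na.rm = TRUE))
}

#' Two-sample t-test from printed summary statistics
#'
#' Entry point for checking published mean (SD) / n demographics tables
#' without the raw data.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @param var_equal Pool the variances instead of Welch (default Welch).
#' @return One-row tibble: `t`, `df`, `p_value`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = FALSE) {
  if (min(n1, n2) < 2 || min(sd1, sd2) <= 0) {
    stop("need n >= 2 and SD > 0 per group", call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble::tibble(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Within-group comparison of intra- vs inter-network variability
#'
#' For each module, compares each subject's intra-network variability with
#' that subject's mean inter-network variability (the module against all
#' other modules) using the paired sign-flip test; the reported one-sided
#' p (`p_smaller`) is for intra < inter.
#'
#' @inheritParams group_compare
#' @param group Which group to test (`"control"`, `"patient"`, or
#'   `"all"`).
#' @param modules Module labels to test (default: every module present at
#'   the intra level).
#' @return A tibble with one row per module: `module`, `group`,
#'   `mean_intra`, `mean_inter`, `observed_diff`, `p_smaller`,
#'   `p_greater`, `n_subjects`.
#' @export
intra_vs_inter <- function(variability, group = c("control", "patient", "all"),
                           modules = NULL, n_perm = 10000, seed = 1L) {
  group <- match.arg(group)
  dat <- if (group == "all") variability else
    dplyr::filter(variability, .data$group == !!group)
  intra <- dplyr::filter(dat, .data$level == "intra")
  inter <- dplyr::filter(dat, .data$level == "inter") |>
    tidyr::separate_wider_delim("unit", "|", names = c("a", "b"))
  if (is.null(modules)) modules <- unique(intra$unit)
  purrr::map_dfr(modules, function(mod) {
    vi <- intra |> dplyr::filter(.data$unit == mod)
    ve <- inter |>
      dplyr::filter(.data$a == mod | .data$b == mod) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(inter_mean = mean(.data$value), .groups = "drop")
    merged <- dplyr::inner_join(vi, ve, by = "subject_id")
    pt <- paired_signflip_test(merged$value, merged$inter_mean,
                               n_perm = n_perm, seed = seed)
    tibble::tibble(module = mod, group = group,
                   mean_intra = mean(merged$value),
                   mean_inter = mean(merged$inter_mean),
                   observed_diff = pt$observed_diff,
                   p_smaller = pt$p_smaller, p_greater = pt$p_greater,
                   n_subjects = nrow(merged))
  })
}
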