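#' Specification of a synthetic dFC cohort
#'
#' Describes the generative model used to emulate a resting-state fMRI
#' cohort: per-subject multivariate time series with a modular stationary
#' correlation structure perturbed by switching connectivity states, a
#' patient group whose state reconfiguration is amplified in designated
#' target modules, and a clinical severity score coupled to that
#' amplification.
#'
#' The defaults mirror the data regime the pipeline is designed for:
#' 200 volumes at TR = 2 s over 264 nodes in 13 modules, 40 controls and
#' 42 patients.
#'
#' @param n_control,n_patient Group sizes (defaults 40 and 42).
#' @param partition A [network_partition()]; defaults to
#'   [default_partition()] (264 nodes, 13 modules).
#' @param n_volumes Volumes per subject (default 200).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param n_states Number of connectivity states (default 4).
#' @param mean_dwell Mean state dwell time in volumes (default 25,
#'   i.e. 50 s at TR = 2 s; dwell times are geometric).
#' @param r_within,r_between Baseline correlation inside and across
#'   modules (defaults 0.4 and 0.05; must satisfy
#'   `r_between < r_within < 1`).
#' @param perturb_rank Rank of each state's covariance perturbation
#'   (default 3).
#' @param amp_base,amp_target Row/column amplitude of the state
#'   perturbation for non-target and target-module nodes (defaults 0.08
#'   and 0.25; `amp_base <= amp_target`).
#' @param target_modules Module labels whose reconfiguration is amplified
#'   in patients (default: the simulated analogues of subcortical,
#'   sensorimotor, visual and cerebellar networks).
#' @param group_gain Multiplier (>= 1) on the target amplitude for a
#'   maximally severe patient (default 1.8).
#' @param severity_coupling Fraction (in \[0, 1\]) of the patient gain
#'   driven by the latent severity rather than shared by all patients
#'   (default 0.7).
#' @param score_scale Maximum of the observed severity score, emulating a
#'   UPDRS-III motor scale (default 40; 10% observation noise is added).
#' @param base_jitter_sd Target SD of the cohort-shared heterogeneity of
#'   the off-diagonal base correlation entries (default 0.2), realized as
#'   a low-rank factor component drawn once per cohort from `seed` and
#'   shared by every subject. Without entry-level heterogeneity the
#'   within-block profile has no stable across-entry variance (a Pearson
#'   profile correlation ignores uniform shifts) and state reconfiguration
#'   could not raise intra-/inter-network variability the way patient
#'   cohorts show; making it cohort-shared mirrors real data, where most
#'   entry-level FC structure is common across subjects.
#' @param subject_jitter_sd Target SD of each subject's own deviation from
#'   the cohort connectome (default 0.05), same low-rank construction but
#'   drawn per subject.
#' @param ar_phi AR(1) coefficient in \[0, 1) applied to the state-drawn
#'   innovations, standing in for hemodynamic/band-pass smoothness
#'   (default 0.3).
#' @param noise_sd Overall signal scale (default 1).
#' @param seed Integer seed controlling the whole cohort (required for
#'   [simulate_cohort()]).
#'
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 40, n_patient = 42,
                        partition = default_partition(),
                        n_volumes = 200, tr_seconds = 2,
                        n_states = 4, mean_dwell = 25,
                        r_within = 0.4, r_between = 0.05,
                        perturb_rank = 3,
                        amp_base = 0.08, amp_target = 0.25,
                        target_modules = c("Subcortical", "SMN",
                                           "Visual", "Cerebellum"),
                        group_gain = 1.8, severity_coupling = 0.7,
                        score_scale = 40, base_jitter_sd = 0.2,
                        subject_jitter_sd = 0.05,
                        ar_phi = 0.3, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(partition, "network_partition"))
  counts <- c(n_control = n_control, n_patient = n_patient,
              n_volumes = n_volumes, n_states = n_states,
              perturb_rank = perturb_rank)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  if (n_volumes < 20) {
    stop("n_volumes must cover at least two windows of the shortest ",
         "analysis window length (10 volumes)", call. = FALSE)
  }
  if (!(r_between < r_within && r_within < 1)) {
    stop("need r_between < r_within < 1", call. = FALSE)
  }
  if (amp_base > amp_target) {
    stop("amp_base must not exceed amp_target", call. = FALSE)
  }
  if (any(c(amp_base, amp_target) < 0)) stop("amplitudes must be >= 0",
                                             call. = FALSE)
  if (!all(target_modules %in% module_labels(partition))) {
    stop("target_modules must be module labels of the partition",
         call. = FALSE)
  }
  if (group_gain < 1) stop("group_gain must be >= 1", call. = FALSE)
  if (severity_coupling < 0 || severity_coupling > 1) {
    stop("severity_coupling must be in [0, 1]", call. = FALSE)
  }
  if (ar_phi < 0 || ar_phi >= 1) stop("ar_phi must be in [0, 1)",
                                      call. = FALSE)
  if (base_jitter_sd < 0 || subject_jitter_sd < 0) {
    stop("jitter SDs must be >= 0", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (mean_dwell < 1) stop("mean_dwell must be >= 1 volume", call. = FALSE)
  structure(list(
    n_control = as.integer(n_control), n_patient = as.integer(n_patient),
    partition = partition, n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, n_states = as.integer(n_states),
    mean_dwell = mean_dwell, r_within = r_within, r_between = r_between,
    perturb_rank = as.integer(perturb_rank), amp_base = amp_base,
    amp_target = amp_target, target_modules = target_modules,
    group_gain = group_gain, severity_coupling = severity_coupling,
    score_scale = score_scale, base_jitter_sd = base_jitter_sd,
    subject_jitter_sd = subject_jitter_sd,
    ar_phi = ar_phi, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_spec> %d controls + %d patients; %d volumes x %d nodes ",
           "(%d modules); %d states, mean dwell %g; gain %g on: %s\n"),
    x$n_control, x$n_patient, x$n_volumes, n_nodes(x$partition),
    length(module_labels(x$partition)), x$n_states, x$mean_dwell,
    x$group_gain, paste(x$target_modules, collapse = ", ")))
  invisible(x)
}

base_correlation <- function(spec) {
  p <- spec$partition
  m <- n_nodes(p)
  members <- module_members(p)
  base <- matrix(spec$r_between, m, m)
  for (idx in members) base[idx, idx] <- spec$r_within
  diag(base) <- 1
  base
}

# factor loading matrix giving a low-rank component L L^T whose
# off-diagonal entries have SD ~ sd_target after unit-diagonal
# normalization by (1 + x); returns NULL for sd_target = 0
jitter_loadings <- function(m, sd_target, q = 3L) {
  if (sd_target == 0) return(NULL)
  if (sd_target * sqrt(q) >= 1) {
    stop("jitter SD too large for the factor construction", call. = FALSE)
  }
  x <- sd_target * sqrt(q) / (1 - sd_target * sqrt(q))
  matrix(stats::rnorm(m * q, 0, sqrt(x / q)), m, q)
}

# Heterogeneous baseline connectome: modular block structure plus
# low-rank factor components, renormalized to a correlation matrix
# (base + L L^T is positive definite by construction; a dense Gaussian
# jitter of useful size cannot survive positive-definite repair at
# M = 264, its spectral radius ~ 2*sd*sqrt(M) dwarfs the base spectrum).
# Heterogeneity has two layers, as in real cohorts where most entry-level
# FC structure is shared: cohort-level factors (SD base_jitter_sd, drawn
# from a spec$seed-derived stream, identical for every subject) and a
# smaller subject deviation (SD subject_jitter_sd, drawn from the current
# RNG stream).
subject_base_correlation <- function(spec) {
  base <- base_correlation(spec)
  m <- nrow(base)
  lc <- with_local_seed(cohort_structure_seed(spec),
                        jitter_loadings(m, spec$base_jitter_sd))
  ls <- jitter_loadings(m, spec$subject_jitter_sd)
  sigma <- base
  if (!is.null(lc)) sigma <- sigma + lc %*% t(lc)
  if (!is.null(ls)) sigma <- sigma + ls %*% t(ls)
  if (!is.null(lc) || !is.null(ls)) {
    d <- diag(sigma)
    sigma <- sigma / sqrt(outer(d, d))
    diag(sigma) <- 1
  }
  sigma
}

cohort_structure_seed <- function(spec) {
  as.integer((as.numeric(spec$seed) * 69621 + 7) %% 2147483629)
}

#' State covariance (correlation) matrices for one subject
#'
#' Builds `n_states` correlation matrices: a shared modular base
#' (`r_within` inside modules, `r_between` across) plus, per state, a
#' random zero-mean low-rank perturbation whose row/column amplitude is
#' `amp_target * subject_gain` for nodes in the target modules and
#' `amp_base` elsewhere. Each perturbed matrix is repaired to a valid
#' correlation matrix by clipping eigenvalues at 1e-6 and re-normalizing
#' to unit diagonal.
#'
#' Draws from the current RNG stream; seed upstream (as
#' [simulate_subject()] does) for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param subject_gain Multiplier (>= 1) on the target-module amplitude.
#' @return A list of `n_states` symmetric positive-definite correlation
#'   matrices.
#' @export
build_state_covariances <- function(spec, subject_gain = 1) {
  if (subject_gain < 1) stop("subject_gain must be >= 1", call. = FALSE)
  p <- spec$partition
  m <- n_nodes(p)
  base <- subject_base_correlation(spec)
  amp <- ifelse(p$module %in% spec$target_modules,
                spec$amp_target * subject_gain, spec$amp_base)
  # Connectivity states are cohort-level objects: their perturbation
  # directions come from a stream derived from spec$seed and are shared by
  # every subject (as k-means dFC states are in real cohorts); only the
  # amplitude (and the subject's base jitter above) is subject-specific.
  directions <- with_local_seed(state_direction_seed(spec), {
    lapply(seq_len(spec$n_states), function(s) {
      matrix(stats::rnorm(m * spec$perturb_rank), m, spec$perturb_rank)
    })
  })
  lapply(directions, function(g) {
    u <- amp * g / sqrt(spec$perturb_rank)
    pert <- u %*% t(u)
    if (all(pert == 0)) return(base)
    # off-diagonal perturbation entries are zero-mean products of
    # independent normals; the Gram form keeps base + pert positive
    # definite by construction, so no eigenvalue repair is needed and
    # unit-diagonal renormalization suffices
    sigma <- base + pert
    d <- diag(sigma)
    if (min(d) <= 1e-8) {
      stop("state covariance degenerate; perturbation amplitude too ",
           "large for the requested structure", call. = FALSE)
    }
    sigma <- sigma / sqrt(outer(d, d))
    diag(sigma) <- 1
    sigma
  })
}

state_direction_seed <- function(spec) {
  as.integer((as.numeric(spec$seed) * 48271 + 11) %% 2147483629)
}

# evaluate expr under a temporary seed, restoring the ambient RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

# geometric dwell-time state sequence; uniform jump to a different state
draw_state_sequence <- function(n_states, n_volumes, mean_dwell) {
  if (n_states == 1) return(rep(1L, n_volumes))
  p_leave <- 1 / mean_dwell
  states <- integer(n_volumes)
  t <- 1L
  current <- sample.int(n_states, 1)
  while (t <= n_volumes) {
    dwell <- stats::rgeom(1, p_leave) + 1L
    upper <- min(n_volumes, t + dwell - 1L)
    states[t:upper] <- current
    t <- upper + 1L
    current <- sample(setdiff(seq_len(n_states), current), 1)
  }
  states
}

#' Simulate one subject's ROI time series
#'
#' Draws a geometric-dwell state sequence, samples each volume from the
#' active state's multivariate normal, smooths temporally with an AR(1)
#' recursion (coefficient `ar_phi`), and scales by `noise_sd`. Patients
#' get a gain `1 + (group_gain - 1) * (severity_coupling * severity +
#' (1 - severity_coupling))` on the target-module perturbation amplitude
#' and an observed score `score_scale * severity` plus 10% Gaussian
#' observation noise, truncated at 0. Deterministic given
#' `(spec, group, severity, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @param severity Latent severity in \[0, 1\]; ignored for controls.
#' @param seed Integer seed (required).
#' @return An object of class `simulated_subject`: list with `series`
#'   (a [subject_ts()]), `group`, `severity`, `score` (`NA` for
#'   controls), `gain`, and `state_sequence` (length `n_volumes`).
#' @export
simulate_subject <- function(spec, group = c("control", "patient"),
                             severity = 0, seed) {
  group <- match.arg(group)
  if (missing(seed) || is.null(seed)) {
    stop("simulate_subject() requires an explicit seed", call. = FALSE)
  }
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]",
                                         call. = FALSE)
  gain <- if (group == "patient") {
    1 + (spec$group_gain - 1) *
      (spec$severity_coupling * severity + (1 - spec$severity_coupling))
  } else 1
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  covs <- build_state_covariances(spec, gain)
  chols <- lapply(covs, chol)
  states <- draw_state_sequence(spec$n_states, spec$n_volumes,
                                spec$mean_dwell)
  m <- n_nodes(spec$partition)
  z <- matrix(stats::rnorm(spec$n_volumes * m), spec$n_volumes, m)
  x <- matrix(0, spec$n_volumes, m)
  for (s in unique(states)) {
    rows <- which(states == s)
    x[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
  }
  if (spec$ar_phi > 0) {
    x <- apply(x, 2, function(col) {
      as.numeric(stats::filter(col, spec$ar_phi, method = "recursive"))
    })
  }
  x <- x * spec$noise_sd
  colnames(x) <- spec$partition$node_index
  score <- if (group == "patient") {
    max(0, spec$score_scale * severity +
          stats::rnorm(1, 0, 0.1 * spec$score_scale))
  } else NA_real_
  structure(list(
    series = subject_ts(x, subject_id = sprintf("sim_%s", group),
                        tr_seconds = spec$tr_seconds),
    group = group, severity = if (group == "patient") severity else NA_real_,
    score = score, gain = gain, state_sequence = states),
    class = "simulated_subject")
}

#' @export
print.simulated_subject <- function(x, ...) {
  cat(sprintf(
    "<simulated_subject> %s: gain %.3f, %d state changes%s\n",
    x$group, x$gain, sum(diff(x$state_sequence) != 0),
    if (!is.na(x$score)) sprintf(", score %.1f", x$score) else ""))
  invisible(x)
}

subject_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 10007 + i * 7919) %% 2147483629)
}

#' Simulate a full cohort
#'
#' Generates `n_control + n_patient` subjects. Patient severities are
#' drawn Uniform(0, 1) from `spec$seed`; each subject then gets a derived
#' seed, so the whole cohort is reproducible from the spec alone. When
#' `dir` is given, writes the pipeline input files: one time-series TSV
#' per subject, `manifest.tsv`, `partition.tsv`, and ground-truth
#' sidecars (`ground_truth.tsv` with per-subject gain/severity and
#' `state_sequences.tsv`) intended for validation only.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed), or `NULL` to keep the
#'   cohort in memory only.
#' @return A list of class `simulated_cohort`: `manifest` (tibble),
#'   `subjects` (named list of [simulate_subject()] results),
#'   `ground_truth` (tibble), `spec`, and `dir`.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  n <- spec$n_control + spec$n_patient
  ids <- c(sprintf("ctrl%02d", seq_len(spec$n_control)),
           sprintf("pat%02d", seq_len(spec$n_patient)))
  groups <- rep(c("control", "patient"), c(spec$n_control, spec$n_patient))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(spec$seed)
  severities <- ifelse(groups == "patient", stats::runif(n), 0)
  ages <- round(stats::rnorm(n, 62, 6), 1)
  sexes <- sample(c("M", "F"), n, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  subjects <- vector("list", n)
  names(subjects) <- ids
  for (i in seq_len(n)) {
    subj <- simulate_subject(spec, groups[i], severities[i],
                             seed = subject_seed(spec$seed, i))
    subj$series$subject_id <- ids[i]
    subjects[[i]] <- subj
  }
  scores <- vapply(subjects, function(s) s$score, 1.0)
  hy <- ifelse(groups == "patient", 1 + round(3 * severities), NA_real_)
  manifest <- tibble::tibble(
    subject_id = ids, group = groups,
    path = paste0(ids, ".tsv"), age = ages, sex = sexes,
    updrs3 = round(scores, 1), hy = hy)
  ground_truth <- tibble::tibble(
    subject_id = ids, group = groups,
    severity = ifelse(groups == "patient", severities, NA_real_),
    gain = vapply(subjects, function(s) s$gain, 1.0))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_timeseries(subjects[[i]]$series, file.path(dir, manifest$path[i]))
    }
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    write_partition(spec$partition, file.path(dir, "partition.tsv"))
    readr::write_tsv(ground_truth, file.path(dir, "ground_truth.tsv"))
    states_long <- purrr::imap_dfr(subjects, function(s, id) {
      tibble::tibble(subject_id = id,
                     volume = seq_along(s$state_sequence),
                     state = s$state_sequence)
    })
    readr::write_tsv(states_long, file.path(dir, "state_sequences.tsv"))
  }
  structure(list(manifest = manifest, subjects = subjects,
                 ground_truth = ground_truth, spec = spec, dir = dir),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d controls + %d patients%s\n",
              sum(x$manifest$group == "control"),
              sum(x$manifest$group == "patient"),
              if (!is.null(x$dir)) paste0(" written to ", x$dir) else ""))
  invisible(x)
}

#' In-memory cohort variability (no file round trip)
#'
#' Convenience for simulation studies: computes [variability_set()] for
#' every subject of a [simulate_cohort()] result directly from the
#' in-memory series.
#'
#' @param cohort A `simulated_cohort`.
#' @inheritParams variability_set
#' @return Long tibble as from [cohort_variability()].
#' @export
cohort_variability_mem <- function(cohort, window_length = 20,
                                   fisher_z = FALSE,
                                   skip_degenerate_windows = FALSE) {
  purrr::imap_dfr(cohort$subjects, function(subj, id) {
    vs <- variability_set(subj$series, cohort$spec$partition,
                          window_length = window_length,
                          fisher_z = fisher_z,
                          skip_degenerate_windows = skip_degenerate_windows)
    dplyr::mutate(tidy.variability_set(vs), group = subj$group, .after = 1)
  })
}
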