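# Synthetic block-design cohorts with the statistical structure the analysis
# assumes: a planted group-discriminative region, stimulus responses shared
# across subjects only up to a subject-specific orthonormal map, and optional
# region coupling for connectome recovery.

#' Specify a synthetic cohort
#'
#' The defaults encode the study conditions the package is designed around:
#' 22 anxious vs 23 non-anxious subjects, a 20-region atlas of ~40 voxels per
#' region inside a 12x12x12 grid, two runs of six 15-s task blocks (three
#' fearful, three angry, seeded-random order shared across subjects), TR 2 s,
#' and 35 extracted task time points per subject.
#'
#' Signal structure: anxious subjects receive a mean shift of `group_effect`
#' (in units of the noise SD) on every voxel of `signal_region_id` during task
#' volumes; every subject receives a stimulus term `stim_effect * W_i s_c`
#' inside the signal region, where `s_fear`/`s_anger` are drawn once per
#' cohort and `W_i` is a subject-specific random orthonormal map — the
#' shared-response premise. Regions listed in `shared_signal_regions` (plus
#' the signal region) additionally receive a common task-locked fluctuation of
#' amplitude `coupling`, which plants suprathreshold connectome edges.
#'
#' @param n_anxious,n_control Group sizes (defaults 22 / 23).
#' @param atlas_shape 3-vector of grid dimensions.
#' @param n_regions,voxels_per_region Atlas layout.
#' @param T Task time points retained per subject (default 35; odd, so
#'   subject-level majority votes cannot tie).
#' @param signal_region_id Region carrying the planted group signal.
#' @param group_effect Anxious-group mean shift in noise-SD units.
#' @param k_shared Dimension of the shared stimulus response.
#' @param stim_effect Amplitude of the shared stimulus response.
#' @param noise_sd SD of the i.i.d. Gaussian voxel noise.
#' @param seed Root seed; all sub-draws derive from it deterministically.
#' @param n_runs,blocks_per_condition Block-design layout per run.
#' @param tr_seconds Repetition time.
#' @param hrf_lag_seconds,volumes_per_block Extraction parameters (4 s lag,
#'   3 plateau volumes per block).
#' @param shared_signal_regions Integer vector of regions coupled to the
#'   signal region's task-locked fluctuation (default none).
#' @param coupling Amplitude of the shared fluctuation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_anxious = 22, n_control = 23,
                        atlas_shape = c(12, 12, 12),
                        n_regions = 20, voxels_per_region = 40,
                        T = 35, signal_region_id = 12,
                        group_effect = 2, k_shared = 3, stim_effect = 2,
                        noise_sd = 1, seed = 1,
                        n_runs = 2, blocks_per_condition = 3,
                        tr_seconds = 2, hrf_lag_seconds = 4,
                        volumes_per_block = 3,
                        shared_signal_regions = integer(0), coupling = 1) {
  spec <- list(n_anxious = n_anxious, n_control = n_control,
               atlas_shape = as.integer(atlas_shape),
               n_regions = as.integer(n_regions),
               voxels_per_region = as.integer(voxels_per_region),
               T = as.integer(T), signal_region_id = as.integer(signal_region_id),
               group_effect = group_effect, k_shared = as.integer(k_shared),
               stim_effect = stim_effect, noise_sd = noise_sd,
               seed = as.integer(seed), n_runs = as.integer(n_runs),
               blocks_per_condition = as.integer(blocks_per_condition),
               tr_seconds = tr_seconds, hrf_lag_seconds = hrf_lag_seconds,
               volumes_per_block = as.integer(volumes_per_block),
               shared_signal_regions = as.integer(shared_signal_regions),
               coupling = coupling)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_regions < 2) stop("n_regions must be >= 2", call. = FALSE)
    if (!(signal_region_id %in% seq_len(n_regions)))
      stop("signal_region_id must lie in 1..n_regions", call. = FALSE)
    if (k_shared > voxels_per_region)
      stop("k_shared must be <= voxels_per_region", call. = FALSE)
    if (group_effect < 0 || stim_effect < 0) stop("effects must be >= 0", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
    if (prod(atlas_shape) < n_regions * voxels_per_region)
      stop("atlas grid too small for n_regions * voxels_per_region", call. = FALSE)
    max_t <- n_runs * 2 * blocks_per_condition * volumes_per_block
    if (T > max_t)
      stop("T = ", T, " exceeds the ", max_t,
           " task volumes the design yields", call. = FALSE)
    if (length(shared_signal_regions) &&
        !all(shared_signal_regions %in% seq_len(n_regions)))
      stop("shared_signal_regions must lie in 1..n_regions", call. = FALSE)
  })
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d anxious + %d control subjects, ",
                     "%d regions x %d voxels, T = %d, seed %d\n"),
              x$n_anxious, x$n_control, x$n_regions, x$voxels_per_region,
              x$T, x$seed))
  cat(sprintf("  signal region %d: group_effect %.2g, stim_effect %.2g (k = %d), noise_sd %.2g\n",
              x$signal_region_id, x$group_effect, x$stim_effect, x$k_shared,
              x$noise_sd))
  invisible(x)
}

#' Generate the block-design event tables for a cohort
#'
#' Each run opens and closes with a 16-s fixation block; six 15-s task blocks
#' (three fearful, three angry, order seeded-random) sit in between, separated
#' by 12-s fixation blocks — a 182-s run. The same design is shared by all
#' subjects, which is what keeps the m-th time point condition-aligned across
#' the cohort.
#'
#' @param spec A [cohort_spec()].
#' @param block_seconds,lead_seconds,gap_seconds Block-design durations.
#' @return List of event tables, one per run.
#' @export
make_block_design <- function(spec, block_seconds = 15, lead_seconds = 16,
                              gap_seconds = 12) {
  n_task <- 2L * spec$blocks_per_condition
  lapply(seq_len(spec$n_runs), function(r) {
    order_r <- local_seed(sub_seed(spec$seed, 100L + r), {
      sample(rep(TASK_CONDITIONS, spec$blocks_per_condition))
    })
    onset <- numeric(0); duration <- numeric(0); type <- character(0)
    t0 <- 0
    onset <- c(onset, t0); duration <- c(duration, lead_seconds); type <- c(type, "fixation")
    t0 <- t0 + lead_seconds
    for (b in seq_len(n_task)) {
      onset <- c(onset, t0); duration <- c(duration, block_seconds); type <- c(type, order_r[b])
      t0 <- t0 + block_seconds
      if (b < n_task) {
        onset <- c(onset, t0); duration <- c(duration, gap_seconds); type <- c(type, "fixation")
        t0 <- t0 + gap_seconds
      }
    }
    onset <- c(onset, t0); duration <- c(duration, lead_seconds); type <- c(type, "fixation")
    validate_events(data.frame(onset = onset, duration = duration,
                               trial_type = type, stringsAsFactors = FALSE))
  })
}

build_synthetic_atlas <- function(spec) {
  nvox <- prod(spec$atlas_shape)
  lab <- integer(nvox)
  used <- spec$n_regions * spec$voxels_per_region
  lab[seq_len(used)] <- rep(seq_len(spec$n_regions), each = spec$voxels_per_region)
  labels <- array(lab, dim = spec$atlas_shape)
  coords <- arrayInd(seq_len(nvox), spec$atlas_shape) - 1L   # 0-based voxel mm
  tab <- do.call(rbind, lapply(seq_len(spec$n_regions), function(r) {
    idx <- which(lab == r)
    data.frame(region_id = r, name = sprintf("region_%02d", r),
               x = mean(coords[idx, 1]), y = mean(coords[idx, 2]),
               z = mean(coords[idx, 3]))
  }))
  atlas_parcellation(labels, tab)
}

#' Generate a synthetic cohort
#'
#' Draws the ground truth (shared condition responses, per-subject orthonormal
#' maps, coupling series), then synthesizes every subject's runs as
#' baseline + group term + stimulus term + i.i.d. Gaussian noise. All draws
#' derive from `spec$seed` through a fixed stream scheme, so the same spec
#' always yields a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `runs` (per
#'   subject), `atlas`, `events`, `metadata`, `truth` and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  events <- make_block_design(spec)
  atlas <- build_synthetic_atlas(spec)
  n_sub <- spec$n_anxious + spec$n_control
  subjects <- sprintf("sub-%02d", seq_len(n_sub))
  groups <- c(rep("non_anxious", spec$n_control), rep("anxious", spec$n_anxious))
  metadata <- data.frame(participant_id = subjects, group = groups,
                         stringsAsFactors = FALSE)

  vr <- spec$voxels_per_region
  s_fear <- local_seed(sub_seed(spec$seed, 1L), stats::rnorm(spec$k_shared))
  s_anger <- local_seed(sub_seed(spec$seed, 2L), stats::rnorm(spec$k_shared))
  run_len <- vapply(events, function(ev) {
    max(ev$onset + ev$duration)
  }, numeric(1))
  nvols <- as.integer(round(run_len / spec$tr_seconds))
  coupling_series <- lapply(seq_len(spec$n_runs), function(r) {
    local_seed(sub_seed(spec$seed, 200L + r), stats::rnorm(nvols[r]))
  })
  W <- lapply(seq_len(n_sub), function(i) {
    local_seed(sub_seed(spec$seed, 1000L + i), random_orthonormal(vr, spec$k_shared))
  })
  names(W) <- subjects

  lab_flat <- as.integer(atlas$labels)
  sig_rows <- which(lab_flat == spec$signal_region_id)
  # the task-locked coupling fluctuation only exists when coupled regions are
  # requested; it is then shared by the signal region and those regions
  coupled_ids <- if (length(spec$shared_signal_regions))
    unique(c(spec$signal_region_id, spec$shared_signal_regions)) else integer(0)
  coupled_rows <- which(lab_flat %in% coupled_ids)
  nvox <- prod(spec$atlas_shape)

  # in-block volume indices per run (1-based columns), with condition labels
  block_sel <- lapply(seq_len(spec$n_runs), function(r) {
    shell <- bold_run(array(0, c(spec$atlas_shape, nvols[r])),
                      tr_seconds = spec$tr_seconds)
    extract_task_timepoints(shell, events[[r]], spec$hrf_lag_seconds)
  })

  runs <- lapply(seq_len(n_sub), function(i) {
    subj_runs <- lapply(seq_len(spec$n_runs), function(r) {
      mat <- local_seed(sub_seed(spec$seed, 10000L + i * 10L + r), {
        matrix(stats::rnorm(nvox * nvols[r], sd = spec$noise_sd), nvox, nvols[r])
      })
      if (spec$coupling != 0 && length(coupled_rows))
        mat[coupled_rows, ] <- mat[coupled_rows, ] +
          rep(spec$coupling * coupling_series[[r]], each = length(coupled_rows))
      sel <- block_sel[[r]]
      cols <- sel$indices + 1L
      if (groups[i] == "anxious" && spec$group_effect != 0)
        mat[sig_rows, cols] <- mat[sig_rows, cols] + spec$group_effect
      if (spec$stim_effect != 0) {
        pat <- list(fear = spec$stim_effect * as.vector(W[[i]] %*% s_fear),
                    anger = spec$stim_effect * as.vector(W[[i]] %*% s_anger))
        for (cond in TASK_CONDITIONS) {
          cc <- cols[sel$labels == cond]
          if (length(cc))
            mat[sig_rows, cc] <- mat[sig_rows, cc] + pat[[cond]]
        }
      }
      bold_run(array(mat, c(spec$atlas_shape, nvols[r])),
               tr_seconds = spec$tr_seconds, subject_id = subjects[i],
               run_id = sprintf("run-%02d", r))
    })
    subj_runs
  })
  names(runs) <- subjects

  truth <- list(W = W, s_fear = s_fear, s_anger = s_anger,
                signal_region_id = spec$signal_region_id,
                group_means = c(non_anxious = 0, anxious = spec$group_effect),
                coupling_series = coupling_series,
                coupled_regions = coupled_ids)
  structure(list(runs = runs, atlas = atlas, events = events,
                 metadata = metadata, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d run(s) each, seed %d\n",
              nrow(x$metadata), x$spec$n_runs, x$spec$seed))
  print(x$spec)
  invisible(x)
}

#' Assemble the time-point dataset of a synthetic cohort
#'
#' Applies the spec's extraction parameters (lag, plateau volumes per block,
#' truncation to `spec$T`) so the result matches what [assemble_dataset()]
#' would produce from the written cohort.
#'
#' @param cohort A [generate_cohort()] result.
#' @param standardize Passed to [assemble_dataset()].
#' @return A `timepoint_dataset`.
#' @export
cohort_dataset <- function(cohort, standardize = "run") {
  assemble_dataset(cohort$runs, cohort$atlas, cohort$events, cohort$metadata,
                   hrf_lag_seconds = cohort$spec$hrf_lag_seconds,
                   volumes_per_block = cohort$spec$volumes_per_block,
                   t_target = cohort$spec$T, standardize = standardize)
}

#' Write a cohort as a BIDS-flavoured file tree
#'
#' Layout: `sub-XX/func/sub-XX_task-faces_run-XX_bold.nii.gz` plus matching
#' `*_events.tsv`, a `participants.tsv`, `atlas.nii.gz` and `regions.tsv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.nii.gz"),
              file.path(out_dir, "regions.tsv"))
  utils::write.table(cohort$metadata, file.path(out_dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (s in names(cohort$runs)) {
    fdir <- file.path(out_dir, s, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_along(cohort$runs[[s]])) {
      stem <- sprintf("%s_task-faces_run-%02d", s, r)
      write_bold_nifti(cohort$runs[[s]][[r]],
                       file.path(fdir, paste0(stem, "_bold.nii.gz")))
      write_events_tsv(cohort$events[[r]],
                       file.path(fdir, paste0(stem, "_events.tsv")))
    }
  }
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list (without ground truth).
#' @export
read_cohort <- function(dir) {
  metadata <- utils::read.delim(file.path(dir, "participants.tsv"),
                                stringsAsFactors = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"), file.path(dir, "regions.tsv"))
  runs <- list(); events <- NULL
  for (s in metadata$participant_id) {
    fdir <- file.path(dir, s, "func")
    bolds <- sort(list.files(fdir, pattern = "_bold\\.nii(\\.gz)?$", full.names = TRUE))
    if (!length(bolds)) stop("no BOLD files for subject ", s, call. = FALSE)
    runs[[s]] <- lapply(seq_along(bolds), function(r) {
      read_bold_nifti(bolds[r], subject_id = s, run_id = sprintf("run-%02d", r))
    })
    if (is.null(events)) {
      evs <- sort(list.files(fdir, pattern = "_events\\.tsv$", full.names = TRUE))
      events <- lapply(evs, read_events_tsv)
    }
  }
  structure(list(runs = runs, atlas = atlas, events = events,
                 metadata = metadata, truth = NULL, spec = NULL),
            class = "synthetic_cohort")
}
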