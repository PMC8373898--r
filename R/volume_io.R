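# Readers/writers for the standard formats the pipeline touches, and the
# conversion of volumes + atlas + events into the time-point-by-voxel datasets
# every downstream stage consumes.

#' Construct a BOLD run from an in-memory array
#'
#' A `bold_run` holds one subject's 4D BOLD series (x, y, z, t) together with
#' the repetition time and identifiers. 3D input is treated as a single-volume
#' run.
#'
#' @param data 3D or 4D numeric array of BOLD values.
#' @param tr_seconds Repetition time in seconds (study value 2.0).
#' @param subject_id,run_id Identifiers carried through the pipeline.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds = 2, subject_id = "sub-01", run_id = "run-01") {
  if (!is.numeric(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("BOLD data must be a 3D or 4D numeric array, got dimension ",
         length(dim(data)), call. = FALSE)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  assert_finite(data, "BOLD data")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number", call. = FALSE)
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = as.numeric(tr_seconds), run_id = run_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s %s: %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              x$subject_id, x$run_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Read a BOLD NIfTI file
#'
#' Reads a 3D or 4D NIfTI-1 volume. The repetition time is taken from the
#' header's fourth pixdim entry unless overridden.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tr_seconds Optional repetition-time override in seconds.
#' @param subject_id,run_id Identifiers; default derived from the file name.
#' @return A [bold_run()].
#' @export
read_bold_nifti <- function(path, tr_seconds = NULL, subject_id = NULL, run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!(length(dim(arr)) %in% c(3L, 4L)))
    stop("NIfTI must be 3D or 4D, got ", length(dim(arr)), "D: ", path, call. = FALSE)
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 2
  }
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  bold_run(arr, tr_seconds = tr_seconds,
           subject_id = subject_id %||% base, run_id = run_id %||% base)
}

#' Write a BOLD run as NIfTI
#'
#' @param run A [bold_run()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a parcellation atlas
#'
#' An integer-labeled 3D volume (0 = background, 1..R = region ids) plus a
#' region lookup table with one row per region.
#'
#' @param labels 3D integer array of region labels.
#' @param region_table Data frame with columns `region_id`, `name`, `x`, `y`,
#'   `z` (centroid, voxel mm coordinates).
#' @return An object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(labels, region_table) {
  if (length(dim(labels)) != 3L) stop("atlas labels must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE) || anyNA(labels))
    stop("atlas labels must be non-negative integers", call. = FALSE)
  need <- c("region_id", "name", "x", "y", "z")
  if (!all(need %in% names(region_table)))
    stop("region_table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  region_table$region_id <- as.integer(region_table$region_id)
  if (anyDuplicated(region_table$region_id))
    stop("region ids must be unique", call. = FALSE)
  present <- sort(unique(as.integer(labels[labels > 0L])))
  if (!all(present %in% region_table$region_id))
    stop("labels present in volume but missing from region_table: ",
         paste(setdiff(present, region_table$region_id), collapse = ", "), call. = FALSE)
  empty <- setdiff(region_table$region_id, present)
  if (length(empty))
    stop("regions listed without any voxel in the volume: ",
         paste(empty, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, region_table = region_table),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation> %s grid, %d regions, %d labeled voxels\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$region_table), sum(x$labels > 0)))
  invisible(x)
}

#' Read an atlas (NIfTI labels + TSV region table)
#'
#' @param nifti_path Integer-labeled NIfTI volume.
#' @param table_path TSV with header `region_id  name  x  y  z`.
#' @return An [atlas_parcellation()].
#' @export
read_atlas <- function(nifti_path, table_path) {
  if (!file.exists(nifti_path)) stop("file not found: ", nifti_path, call. = FALSE)
  if (!file.exists(table_path)) stop("file not found: ", table_path, call. = FALSE)
  labels <- as.array(RNifti::readNifti(nifti_path))
  labels <- round(labels)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  atlas_parcellation(labels, tab)
}

#' Write an atlas to NIfTI + TSV
#' @param atlas An [atlas_parcellation()].
#' @param nifti_path,table_path Output paths.
#' @export
write_atlas <- function(atlas, nifti_path, table_path) {
  RNifti::writeNifti(RNifti::asNifti(atlas$labels), nifti_path)
  utils::write.table(atlas$region_table, table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}

TASK_CONDITIONS <- c("fear", "anger")

#' Validate an event table
#'
#' Events are BIDS-style rows (`onset`, `duration`, `trial_type`) with
#' `trial_type` in fixation/fear/anger, sorted by onset and non-overlapping.
#' Event intervals are half-open: `[onset, onset + duration)`.
#'
#' @param events Data frame of events.
#' @return The validated data frame, invisibly usable.
#' @export
validate_events <- function(events) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("event table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(events) == 0) stop("event table is empty", call. = FALSE)
  if (any(events$onset < 0) || any(events$duration <= 0))
    stop("onsets must be non-negative and durations positive", call. = FALSE)
  bad <- setdiff(unique(events$trial_type), c("fixation", TASK_CONDITIONS))
  if (length(bad))
    stop("unknown trial_type in events: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.unsorted(events$onset))
    stop("events must be sorted by onset", call. = FALSE)
  ends <- events$onset + events$duration
  if (nrow(events) > 1 && any(events$onset[-1] < ends[-nrow(events)] - 1e-9))
    stop("events overlap within the run", call. = FALSE)
  events
}

#' Read / write BIDS-style events TSV
#' @param path TSV path with header `onset  duration  trial_type`.
#' @return Data frame of validated events.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_events(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_events_tsv
#' @param events Event data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(validate_events(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a BOLD run into per-region voxel matrices
#'
#' Voxels within a region are ordered by ascending flattened (x-fastest)
#' index, so the column order is a deterministic function of the atlas.
#' Background (label 0) is excluded; the region blocks partition the nonzero
#' mask.
#'
#' @param run A [bold_run()].
#' @param atlas An [atlas_parcellation()] with matching spatial shape.
#' @param region_ids Optional subset of region ids (default: all listed).
#' @return Named list mapping region id to a T x V_r matrix.
#' @export
parcellate <- function(run, atlas, region_ids = NULL) {
  d <- dim(run$data)
  if (!all(d[1:3] == dim(atlas$labels)))
    stop(sprintf("spatial shape mismatch: run %s vs atlas %s",
                 paste(d[1:3], collapse = "x"),
                 paste(dim(atlas$labels), collapse = "x")), call. = FALSE)
  if (is.null(region_ids)) region_ids <- sort(atlas$region_table$region_id)
  missing_ids <- setdiff(region_ids, atlas$region_table$region_id)
  if (length(missing_ids))
    stop("region id(s) absent from atlas: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  lab <- as.integer(atlas$labels)
  nt <- d[4]
  mat <- matrix(run$data, nrow = prod(d[1:3]), ncol = nt)  # rows = flattened voxels
  out <- lapply(region_ids, function(rid) {
    idx <- which(lab == rid)
    t(mat[idx, , drop = FALSE])
  })
  names(out) <- as.character(region_ids)
  out
}

#' Select task time points from a run
#'
#' Returns the 0-based volume indices whose full acquisition interval
#' `[i*TR, (i+1)*TR)` lies inside a fear or anger block after shifting the
#' block by a hemodynamic lag, together with the block's condition label.
#' Fixation volumes are excluded. At TR 2 s every 15-s block contributes
#' exactly 7 volumes, and `volumes_per_block` can cap how many (from the lag
#' onward) are kept, emulating plateau sampling of the evoked response.
#'
#' @param run A [bold_run()].
#' @param events Event table for the run.
#' @param hrf_lag_seconds Hemodynamic lag applied to block onsets (default 4).
#' @param volumes_per_block Optional cap on volumes retained per task block.
#' @return List with `indices` (0-based integer), `labels` (condition per
#'   index) and `block` (task-block ordinal per index).
#' @export
extract_task_timepoints <- function(run, events, hrf_lag_seconds = 4,
                                    volumes_per_block = NULL) {
  events <- validate_events(events)
  tr <- run$tr_seconds
  nt <- dim(run$data)[4]
  run_end <- nt * tr
  task <- events[events$trial_type != "fixation", , drop = FALSE]
  if (nrow(task) == 0)
    stop("empty selection: events contain no fear/anger task blocks", call. = FALSE)
  if (any(task$onset + task$duration > run_end + 1e-9))
    stop("task events extend past the end of the run", call. = FALSE)
  idx <- integer(0); lab <- character(0); blk <- integer(0)
  for (b in seq_len(nrow(task))) {
    a <- task$onset[b] + hrf_lag_seconds
    z <- a + task$duration[b]
    lo <- ceiling(a / tr - 1e-9)            # first volume with i*tr >= a
    hi <- floor(z / tr - 1 + 1e-9)          # last volume with (i+1)*tr <= z
    if (hi >= nt) hi <- nt - 1L
    if (hi < lo) next
    sel <- seq.int(lo, hi)
    if (!is.null(volumes_per_block) && is.finite(volumes_per_block))
      sel <- utils::head(sel, volumes_per_block)
    idx <- c(idx, sel)
    lab <- c(lab, rep(task$trial_type[b], length(sel)))
    blk <- c(blk, rep(b, length(sel)))
  }
  if (length(idx) == 0)
    stop("empty selection: no volume falls fully inside a lag-shifted task block",
         call. = FALSE)
  list(indices = as.integer(idx), labels = lab, block = blk)
}

#' Assemble a time-point dataset from runs, atlas and events
#'
#' Produces the common currency of all classifiers: one T x V matrix per
#' subject over the atlas-labeled voxels, a shared per-time-point stimulus
#' label sequence, per-subject group labels, and a region index mapping each
#' region id to its column slice.
#'
#' Standardization is per voxel within subject. The default (`"run"`) z-scores
#' each voxel over all volumes of its run before task rows are selected, so
#' task activation is measured against the run baseline; `"task"` z-scores
#' over the selected task rows only; `"none"` disables it. Zero-variance
#' voxels standardize to zeros.
#'
#' @param runs Named list (by subject id) of lists of [bold_run()]s.
#' @param atlas An [atlas_parcellation()].
#' @param events List of event tables, one per run (design shared across
#'   subjects, which keeps subjects temporally aligned).
#' @param metadata Data frame with columns `participant_id` and `group`.
#' @param hrf_lag_seconds,volumes_per_block Passed to
#'   [extract_task_timepoints()].
#' @param t_target Optional total time-point count; extra trailing task
#'   volumes are dropped to reach it.
#' @param standardize One of `"run"`, `"task"`, `"none"`.
#' @return An object of class `timepoint_dataset`.
#' @export
assemble_dataset <- function(runs, atlas, events, metadata,
                             hrf_lag_seconds = 4, volumes_per_block = NULL,
                             t_target = NULL,
                             standardize = c("run", "task", "none")) {
  standardize <- match.arg(standardize)
  need <- c("participant_id", "group")
  if (!all(need %in% names(metadata)))
    stop("metadata needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  miss <- setdiff(metadata$participant_id, names(runs))
  if (length(miss))
    stop("subjects in metadata without runs: ", paste(miss, collapse = ", "),
         call. = FALSE)

  region_ids <- sort(atlas$region_table$region_id)
  lab <- as.integer(atlas$labels)
  vox_idx <- unlist(lapply(region_ids, function(r) which(lab == r)))
  voxel_region <- unlist(lapply(region_ids, function(r) rep(r, sum(lab == r))))
  region_index <- split(seq_along(voxel_region), factor(voxel_region, levels = region_ids))

  subjects <- metadata$participant_id
  features <- vector("list", length(subjects))
  names(features) <- subjects
  labels_ref <- NULL

  for (s in subjects) {
    subj_runs <- runs[[s]]
    if (length(subj_runs) != length(events))
      stop("subject ", s, " has ", length(subj_runs), " runs but ",
           length(events), " event tables were supplied", call. = FALSE)
    rows <- list(); labs <- character(0)
    for (r in seq_along(subj_runs)) {
      run <- subj_runs[[r]]
      if (!all(dim(run$data)[1:3] == dim(atlas$labels)))
        stop("run spatial shape does not match atlas for subject ", s, call. = FALSE)
      d <- dim(run$data)
      mat <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
      mat <- t(mat[vox_idx, , drop = FALSE])           # volumes x voxels
      if (standardize == "run") mat <- zscore_cols(mat)
      sel <- extract_task_timepoints(run, events[[r]], hrf_lag_seconds,
                                     volumes_per_block)
      rows[[r]] <- mat[sel$indices + 1L, , drop = FALSE]
      labs <- c(labs, sel$labels)
    }
    x <- do.call(rbind, rows)
    if (!is.null(t_target)) {
      if (nrow(x) < t_target)
        stop("subject ", s, " yields ", nrow(x),
             " task time points, fewer than t_target = ", t_target, call. = FALSE)
      x <- x[seq_len(t_target), , drop = FALSE]
      labs <- labs[seq_len(t_target)]
    }
    if (standardize == "task") x <- zscore_cols(x)
    if (is.null(labels_ref)) {
      labels_ref <- labs
    } else {
      if (length(labs) != length(labels_ref))
        stop("inconsistent time-point count across subjects (", s, ")", call. = FALSE)
      if (!identical(labs, labels_ref))
        stop("stimulus label sequence differs across subjects (", s, ")", call. = FALSE)
    }
    features[[s]] <- x
  }

  groups <- as.character(metadata$group)
  names(groups) <- subjects
  structure(list(features = features,
                 stimulus_labels = labels_ref,
                 group_labels = groups,
                 subject_ids = subjects,
                 region_index = region_index,
                 voxel_region = voxel_region,
                 region_table = atlas$region_table,
                 T = length(labels_ref),
                 V = length(voxel_region)),
            class = "timepoint_dataset")
}

#' @export
print.timepoint_dataset <- function(x, ...) {
  cat(sprintf("<timepoint_dataset> %d subjects, T = %d time points, V = %d voxels, %d regions\n",
              length(x$subject_ids), x$T, x$V, length(x$region_index)))
  cat("  groups: ", paste(sprintf("%s (%d)", names(table(x$group_labels)),
                                  table(x$group_labels)), collapse = ", "), "\n", sep = "")
  cat("  conditions: ", paste(sprintf("%s (%d)", names(table(x$stimulus_labels)),
                                      table(x$stimulus_labels)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# column indices of a region; region 0 is the whole-brain pseudo-region
# (union of all labeled voxels)
region_columns <- function(ds, region_id) {
  if (identical(as.integer(region_id), 0L)) return(seq_len(ds$V))
  cols <- ds$region_index[[as.character(region_id)]]
  if (is.null(cols))
    stop("region id not present in dataset: ", region_id, call. = FALSE)
  if (length(cols) == 0)
    stop("region ", region_id, " has zero voxels", call. = FALSE)
  cols
}
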