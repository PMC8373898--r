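test_that("NIfTI round trip preserves data, shape and TR", {
  arr <- array(rnorm(8 * 8 * 8 * 35), c(8, 8, 8, 35))
  run <- bold_run(arr, tr_seconds = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_bold_nifti(run, f)
  back <- read_bold_nifti(f)
  expect_equal(dim(back$data), c(8, 8, 8, 35))
  expect_equal(as.vector(back$data), as.vector(arr))
  expect_equal(back$tr_seconds, 2)
})

test_that("3D input becomes a single-volume run; NaN input errors with a count", {
  arr3 <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  run <- bold_run(arr3)
  expect_equal(dim(run$data)[4], 1)
  f <- tempfile(fileext = ".nii.gz")
  write_bold_nifti(run, f)
  expect_equal(dim(read_bold_nifti(f)$data)[4], 1)

  bad <- arr3; bad[c(1, 5, 9)] <- NaN
  expect_error(bold_run(bad), "3 non-finite")
  expect_error(read_bold_nifti(tempfile(fileext = ".nii")), "not found")
  expect_error(bold_run(matrix(1, 2, 2)), "3D or 4D")
})

test_that("parcellate partitions the nonzero mask with deterministic voxel order", {
  set.seed(5)
  dims <- c(4, 4, 3)
  lab <- array(0L, dims)
  lab[1:20] <- 1L; lab[21:34] <- 2L
  tab <- data.frame(region_id = 1:2, name = c("a", "b"), x = 0, y = 0, z = 0)
  atlas <- atlas_parcellation(lab, tab)
  arr <- array(rnorm(prod(dims) * 6), c(dims, 6))
  run <- bold_run(arr)
  parts <- parcellate(run, atlas)

  counts <- vapply(parts, ncol, integer(1))
  expect_equal(sum(counts), sum(lab > 0))
  # brute force: voxel (i) belongs to exactly one region block, in flat order
  flat <- matrix(arr, nrow = prod(dims))
  expect_equal(parts[["1"]], t(flat[which(as.integer(lab) == 1), ]))
  expect_equal(parts[["2"]], t(flat[which(as.integer(lab) == 2), ]))

  # constant-value regions give exact region means
  arr2 <- array(0, c(dims, 2))
  arr2[, , , 1][lab == 1] <- 3; arr2[, , , 2][lab == 1] <- 3
  arr2[, , , 1][lab == 2] <- 7; arr2[, , , 2][lab == 2] <- 7
  p2 <- parcellate(bold_run(arr2), atlas)
  expect_equal(unname(rowMeans(p2[["1"]])), c(3, 3))
  expect_equal(unname(rowMeans(p2[["2"]])), c(7, 7))

  # single region covering everything is the identity partition
  lab_all <- array(1L, dims)
  atlas_all <- atlas_parcellation(lab_all, tab[1, ])
  expect_equal(parcellate(run, atlas_all)[["1"]], t(flat))

  expect_error(parcellate(run, atlas, region_ids = 9), "absent")
  expect_error(parcellate(bold_run(array(0, c(2, 2, 2, 3))), atlas), "mismatch")
})

test_that("task time-point extraction follows block membership with lag", {
  run <- bold_run(array(0, c(2, 2, 2, 20)), tr_seconds = 2)
  ev <- data.frame(onset = c(0, 16), duration = c(16, 15),
                   trial_type = c("fixation", "fear"))
  sel <- extract_task_timepoints(run, ev, hrf_lag_seconds = 0)
  expect_equal(sel$indices, 8:14)
  expect_equal(sel$labels, rep("fear", 7))

  # shifting the lag by one TR shifts every index by exactly one
  sel2 <- extract_task_timepoints(run, ev, hrf_lag_seconds = 2)
  expect_equal(sel2$indices, sel$indices + 1L)

  # fixation-only events are an empty selection
  fix_only <- data.frame(onset = 0, duration = 16, trial_type = "fixation")
  expect_error(extract_task_timepoints(run, fix_only), "empty selection")
  # unknown condition labels are rejected
  bad <- data.frame(onset = 16, duration = 15, trial_type = "happy")
  expect_error(extract_task_timepoints(run, bad), "unknown trial_type")
})

test_that("assemble_dataset standardizes voxels and is order-invariant", {
  co <- generate_cohort(tiny_spec())
  ds <- cohort_dataset(co)
  expect_equal(ds$T, 35)
  expect_equal(length(ds$features), 8)
  expect_true(all(vapply(ds$features, nrow, integer(1)) == 35))
  # every voxel column maps to exactly one region
  expect_equal(sort(unlist(ds$region_index, use.names = FALSE)), seq_len(ds$V))

  # permuting metadata rows permutes subjects only
  md2 <- co$metadata[rev(seq_len(nrow(co$metadata))), ]
  ds2 <- assemble_dataset(co$runs, co$atlas, co$events, md2,
                          hrf_lag_seconds = co$spec$hrf_lag_seconds,
                          volumes_per_block = co$spec$volumes_per_block,
                          t_target = co$spec$T)
  expect_equal(ds2$subject_ids, rev(ds$subject_ids))
  expect_equal(ds2$features[["sub-03"]], ds$features[["sub-03"]])
  expect_equal(ds2$stimulus_labels, ds$stimulus_labels)

  # a constant voxel standardizes to zeros under the zero-variance guard
  co3 <- co
  for (s in names(co3$runs)) for (r in seq_along(co3$runs[[s]])) {
    d <- co3$runs[[s]][[r]]$data
    d[1, 1, 1, ] <- 7
    co3$runs[[s]][[r]]$data <- d
  }
  ds3 <- cohort_dataset(co3)
  expect_true(all(ds3$features[["sub-01"]][, 1] == 0))

  # subject listed in metadata but without runs errors
  md_extra <- rbind(co$metadata, data.frame(participant_id = "sub-99",
                                            group = "anxious"))
  expect_error(assemble_dataset(co$runs, co$atlas, co$events, md_extra),
               "without runs")
})
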