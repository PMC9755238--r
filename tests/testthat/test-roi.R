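test_that("label volumes and TBV follow the voxel-count definition", {
  sch <- phantom_scheme()
  g <- claustrumdev:::index_grids(c(10L, 10L, 10L))
  vol <- toy_volume(c(10L, 10L, 10L), paint = list(
    claustrum_left = g$x <= 2,                       # 200 voxels
    claustrum_right = g$x >= 9,                      # 200 voxels
    csf = g$x == 5 & g$y <= 3,
    ventricles = g$x == 6 & g$y <= 2,
    background = g$x == 7 & g$y == 1))
  vox_mm3 <- 0.5^3
  expect_equal(label_volume_mm3(vol, scheme_id(sch, "claustrum_left")),
               200 * vox_mm3)
  expect_equal(label_volume_mm3(vol, scheme_id(sch, "thalamus")), 0)
  expect_error(label_volume_mm3(vol, 99L), "unknown label")

  # brute-force per-label sum oracle for TBV
  counts <- table(factor(vol$grid, levels = sch$id))
  excl <- sch$id[sch$class %in% c("background", "csf", "ventricles")]
  expect_equal(total_brain_volume(vol),
               sum(counts[!sch$id %in% excl]) * vox_mm3)

  # adding a brainstem voxel adds exactly one voxel volume
  vol2 <- vol
  vol2$grid[7, 1, 1] <- scheme_id(sch, "brainstem")
  expect_equal(total_brain_volume(vol2),
               total_brain_volume(vol) + vox_mm3)
  # an all-background grid has zero TBV
  empty <- array(scheme_id(sch, "background"), dim = c(4, 4, 4))
  empty[1, 1, 1] <- scheme_id(sch, "claustrum_left")
  empty[2, 1, 1] <- scheme_id(sch, "claustrum_right")
  ev <- label_volume(empty, scheme = sch)
  expect_equal(total_brain_volume(ev), 2 * vox_mm3)
})

test_that("side combination follows the printed conventions", {
  # mean of sides for absolute volume
  expect_equal(combine_sides(357, 363), 360)
  expect_equal(combine_sides(325, 341), 333)
  expect_equal(combine_sides(5, 5), 5)
  expect_true(is.na(combine_sides(NA, 5)))
  # relative volume sums the sides over TBV
  rel <- relative_volume(left_mm3 = 0.00097 * 1e6, right_mm3 = 0.00098 * 1e6,
                         tbv_mm3 = 1e6)
  expect_equal(rel$total, 0.00195)
  expect_equal(relative_volume(0, 0, 100)$total, 0)
  expect_equal(relative_volume(40, 60, 100)$total, 1)
  expect_error(relative_volume(1, 1, 0), "positive")
})

test_that("roi_mean and gm_average equal exhaustive means", {
  set.seed(3)
  dims <- c(8L, 8L, 8L)
  field <- array(rnorm(prod(dims), 1, 0.2), dim = dims)
  mv <- metric_volume(field, "md")
  mask <- array(runif(prod(dims)) < 0.3, dim = dims)
  expect_equal(roi_mean(mv, mask), sum(field[mask]) / sum(mask))
  expect_true(is.na(roi_mean(mv, array(FALSE, dims))))
  const <- metric_volume(array(0.7, dims), "md")
  expect_equal(roi_mean(const, mask), 0.7)
  expect_error(roi_mean(mv, array(TRUE, c(4, 4, 4))), "shape")

  # weighted GM mean: sizes 10 and 30 with values 1 and 2 -> 1.75
  sch <- phantom_scheme()
  g <- claustrumdev:::index_grids(dims)
  vol <- toy_volume(dims, base = "background", paint = list(
    cortical_gm = g$x == 1 & g$y <= 2 & g$z <= 5,      # 10 voxels
    thalamus = g$x == 2 & g$y <= 5 & g$z <= 6,          # 30 voxels
    claustrum_left = g$x == 5 & g$y == 1 & g$z == 1,
    claustrum_right = g$x == 5 & g$y == 2 & g$z == 1))
  metr <- array(0, dims)
  metr[vol$grid == scheme_id(sch, "cortical_gm")] <- 1
  metr[vol$grid == scheme_id(sch, "thalamus")] <- 2
  metr[vol$grid %in% scheme_id(sch, c("claustrum_left",
                                      "claustrum_right"))] <- 1.75
  expect_equal(gm_average(metric_volume(metr, "md"), vol), 1.75)
  # brute force over GM voxels (claustrum included as subcortical GM)
  gm_ids <- scheme_ids_by_class(sch, c("cortical_gm", "subcortical_gm",
                                       "claustrum_left", "claustrum_right"))
  expect_equal(gm_average(metric_volume(metr, "md"), vol),
               mean(metr[vol$grid %in% gm_ids]))
})

test_that("FA ingest clips out-of-range values with a warning", {
  grid <- array(0.5, c(4, 4, 4))
  grid[1, 1, 1] <- -0.2
  grid[2, 1, 1] <- 1.4
  expect_warning(mv <- metric_volume(grid, "fa"), "clipped 2")
  expect_equal(range(mv$grid), c(0, 1))
  expect_equal(mv$clipped, 2L)
})

test_that("extraction on a noise-free phantom round-trips generator values", {
  pspec <- phantom_spec(md_noise_sd = 0, fa_noise_sd = 0)
  cohort <- generate_cohort(cohort_spec(n_preterm = 1L, n_term = 0L),
                            seed = 21)
  ph <- generate_phantom(pspec, row = cohort[1, ], seed = 1)
  row <- extract_subject_metrics(ph$label, ph$md, ph$fa,
                                 subject_id = cohort$subject_id[1])
  # microstructure fields equal the painted per-side values exactly
  expect_equal(row$claustrum_md_left, cohort$claustrum_md_left[1])
  expect_equal(row$claustrum_md_right, cohort$claustrum_md_right[1])
  expect_equal(row$claustrum_fa_left, cohort$claustrum_fa_left[1])
  expect_equal(row$claustrum_fa_right, cohort$claustrum_fa_right[1])
  expect_equal(row$claustrum_fa_mean, cohort$claustrum_fa_mean[1])
  # interior and frame masks see their constant tissue values exactly
  expect_equal(row$controlled_md_left, cohort$claustrum_md_left[1])
  expect_equal(row$frame_fa_left, pspec$fa_mean[["insular_wm"]])
  expect_equal(row$gm_md,
               gm_average(ph$md, ph$label))
  # macrostructure equals the geometric voxel counts
  sch <- ph$label$scheme
  for (side in c("left", "right")) {
    id <- scheme_id(sch, paste0("claustrum_", side))
    expect_equal(row[[paste0("claustrum_volume_", side)]],
                 sum(ph$label$grid == id) * prod(pspec$voxel_size))
  }
  expect_equal(row$relative_volume_total,
               (row$claustrum_volume_left + row$claustrum_volume_right) /
                 row$tbv)
})

test_that("missing metric volumes flag diffusion fields as missing", {
  ph <- generate_phantom(phantom_spec(), seed = 2)
  row <- extract_subject_metrics(ph$label, md = NULL, fa = ph$fa)
  expect_true(is.na(row$claustrum_md_mean))
  expect_true(is.na(row$gm_md))
  expect_false(is.na(row$claustrum_fa_mean))
  expect_false(is.na(row$claustrum_volume_mean))
  # shape mismatch is rejected before any extraction
  small <- metric_volume(array(1, c(4, 4, 4)), "md")
  expect_error(extract_subject_metrics(ph$label, md = small), "shape")
})

test_that("extraction is invariant to a permuted label scheme", {
  pspec <- phantom_spec(md_noise_sd = 0, fa_noise_sd = 0)
  ph <- generate_phantom(pspec, seed = 3)
  row1 <- extract_subject_metrics(ph$label, ph$md, ph$fa)
  # remap ids 0..14 -> 100..114 (same names/classes)
  sch <- ph$label$scheme
  sch2 <- label_scheme(sch$id + 100L, sch$name, sch$class)
  grid2 <- array(sch2$id[match(ph$label$grid, sch$id)],
                 dim = dim(ph$label$grid))
  vol2 <- label_volume(grid2, voxel_size = ph$label$voxel_size,
                       scheme = sch2)
  row2 <- extract_subject_metrics(vol2, ph$md, ph$fa)
  expect_equal(row1[, -(1:2)], row2[, -(1:2)])
})
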