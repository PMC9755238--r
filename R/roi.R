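#' ROI volumetry and metric extraction
#'
#' Volume of one label in mm^3: voxel count times voxel volume.
#'
#' @param vol a \code{\link{label_volume}}.
#' @param label_id integer label id (must be in the scheme).
#' @return volume in mm^3 (0 when the label is absent from the grid).
#' @export
label_volume_mm3 <- function(vol, label_id) {
  if (!label_id %in% vol$scheme$id)
    stop("unknown label id: ", label_id)
  sum(vol$grid == label_id) * prod(vol$voxel_size)
}

#' Total brain volume
#'
#' All intracranial structures including the brainstem, excluding
#' background, cerebrospinal fluid and ventricles.
#'
#' @param vol a \code{\link{label_volume}}.
#' @return TBV in mm^3.
#' @export
total_brain_volume <- function(vol) {
  excl <- scheme_ids_by_class(vol$scheme, .tbv_excluded_classes)
  sum(!(vol$grid %in% excl)) * prod(vol$voxel_size)
}

#' TBV-relative claustrum volume
#'
#' The combined relative volume is the sum of both sides divided by total
#' brain volume; per-side relative volumes are side / TBV.
#'
#' @param left_mm3,right_mm3 per-side absolute volumes (mm^3).
#' @param tbv_mm3 total brain volume (mm^3), must be positive.
#' @return list with \code{left}, \code{right} and \code{total} ratios.
#' @export
relative_volume <- function(left_mm3, right_mm3, tbv_mm3) {
  if (any(tbv_mm3 <= 0)) stop("total brain volume must be positive")
  list(left = left_mm3 / tbv_mm3,
       right = right_mm3 / tbv_mm3,
       total = (left_mm3 + right_mm3) / tbv_mm3)
}

#' Combine per-side outcomes
#'
#' Absolute volume, MD and FA are combined as the arithmetic mean of right
#' and left claustrum; relative volume is combined by
#' \code{\link{relative_volume}} (sum over TBV). A missing side yields a
#' missing combined value.
#'
#' @param left_value,right_value per-side values.
#' @return combined value, or \code{NA} if either side is missing.
#' @export
combine_sides <- function(left_value, right_value) {
  ifelse(is.na(left_value) | is.na(right_value), NA_real_,
         (left_value + right_value) / 2)
}

#' Mean metric over a mask
#'
#' Arithmetic mean of the metric values at mask voxels. An empty mask
#' yields \code{NA} (missing), never 0.
#'
#' @param metric a \code{\link{metric_volume}}.
#' @param mask a mask object or a 3-D logical array of the same shape.
#' @return scalar mean, or \code{NA} for an empty mask.
#' @export
roi_mean <- function(metric, mask) {
  grid <- if (inherits(mask, "claustrum_mask")) mask$grid else mask
  if (!identical(dim(grid), dim(metric$grid)))
    stop("mask shape does not match metric volume")
  n <- sum(grid)
  if (n == 0L) return(NA_real_)
  sum(metric$grid[grid]) / n
}

#' Grey-matter average of a metric
#'
#' Voxel-weighted mean of the metric over the union of all cortical and
#' subcortical grey-matter labels; the claustrum counts as subcortical GM.
#'
#' @param metric a \code{\link{metric_volume}}.
#' @param vol a co-registered \code{\link{label_volume}}.
#' @return scalar mean.
#' @export
gm_average <- function(metric, vol) {
  check_aligned(vol, metric)
  gm_ids <- scheme_ids_by_class(vol$scheme, .gm_classes)
  mask <- array(vol$grid %in% gm_ids, dim = dim(vol$grid))
  if (!any(mask)) stop("no grey-matter voxels in label volume")
  roi_mean(metric, mask)
}

roi_mean_by_name <- function(metric, vol, name) {
  id <- scheme_id(vol$scheme, name, required = FALSE)
  if (is.na(id)) return(NA_real_)
  roi_mean(metric, label_mask(vol, id))
}

#' Extract all per-subject ROI outcomes
#'
#' Computes the full outcome row for one subject from a label volume and
#' optional co-registered MD and FA volumes: per-side and combined
#' claustrum volume, TBV, TBV-relative volume, MD and FA; the same
#' diffusion metrics for the claustrum-controlled segmentation; frame
#' MD/FA; and control-region values (thalamus and caudate volumes,
#' lentiform and insular-cortex FA, grey-matter mean MD/FA). Metrics whose
#' volume is not supplied, or whose mask is empty, are returned as
#' \code{NA}. Mask invariants (controlled within claustrum, frame disjoint
#' from claustrum) are asserted on every extraction.
#'
#' @param vol a \code{\link{label_volume}}.
#' @param md,fa optional \code{\link{metric_volume}}s, co-registered with
#'   \code{vol} (shape and voxel size are checked).
#' @param subject_id,session_id identifiers copied into the row.
#' @param controlled_fraction neighbourhood fraction for the controlled
#'   segmentation (default 0.9).
#' @param frame_radius dilation radius of the frame (default 2).
#' @return one-row \code{data.frame} (an ROI metrics row).
#' @export
extract_subject_metrics <- function(vol, md = NULL, fa = NULL,
                                    subject_id = NA_character_,
                                    session_id = NA_character_,
                                    controlled_fraction = 0.9,
                                    frame_radius = 2L) {
  if (!is.null(md)) check_aligned(vol, md)
  if (!is.null(fa)) check_aligned(vol, fa)

  ids <- list(left = side_label_id(vol, "left"),
              right = side_label_id(vol, "right"))
  for (s in names(ids))
    if (!any(vol$grid == ids[[s]]))
      stop("claustrum label (", s, ") missing from volume")

  vol_l <- label_volume_mm3(vol, ids$left)
  vol_r <- label_volume_mm3(vol, ids$right)
  tbv <- total_brain_volume(vol)
  rel <- relative_volume(vol_l, vol_r, tbv)

  cla_mask <- list(left = label_mask(vol, ids$left),
                   right = label_mask(vol, ids$right))
  ctrl <- frame <- list()
  for (s in c("left", "right")) {
    ctrl[[s]] <- build_claustrum_controlled(vol, s, controlled_fraction)
    frame[[s]] <- suppressWarnings(
      build_claustrum_frame(vol, s, frame_radius))
    stopifnot(all(!ctrl[[s]]$grid | cla_mask[[s]]$grid),
              !any(frame[[s]]$grid &
                   (cla_mask$left$grid | cla_mask$right$grid)))
  }

  metric_fields <- function(mvol, tag) {
    if (is.null(mvol)) {
      vals <- rep(NA_real_, 9L)
    } else {
      vals <- c(
        roi_mean(mvol, cla_mask$left), roi_mean(mvol, cla_mask$right),
        roi_mean(mvol, ctrl$left), roi_mean(mvol, ctrl$right),
        roi_mean(mvol, frame$left), roi_mean(mvol, frame$right),
        gm_average(mvol, vol),
        roi_mean_by_name(mvol, vol, "lentiform"),
        combine_sides(roi_mean_by_name(mvol, vol, "insular_cortex_left"),
                      roi_mean_by_name(mvol, vol, "insular_cortex_right")))
    }
    names(vals) <- paste0(c("claustrum_", "claustrum_",
                            "controlled_", "controlled_",
                            "frame_", "frame_",
                            "gm_", "lentiform_", "insular_"),
                          tag,
                          c("_left", "_right", "_left", "_right",
                            "_left", "_right", "", "", ""))
    vals
  }
  mdv <- metric_fields(md, "md")
  fav <- metric_fields(fa, "fa")

  thal <- scheme_id(vol$scheme, "thalamus", required = FALSE)
  caud <- scheme_id(vol$scheme, "caudate", required = FALSE)
  row <- data.frame(
    subject_id = subject_id, session_id = session_id,
    claustrum_volume_left = vol_l, claustrum_volume_right = vol_r,
    claustrum_volume_mean = combine_sides(vol_l, vol_r),
    tbv = tbv,
    relative_volume_left = rel$left, relative_volume_right = rel$right,
    relative_volume_total = rel$total,
    claustrum_md_left = mdv[["claustrum_md_left"]],
    claustrum_md_right = mdv[["claustrum_md_right"]],
    claustrum_md_mean = combine_sides(mdv[["claustrum_md_left"]],
                                      mdv[["claustrum_md_right"]]),
    claustrum_fa_left = fav[["claustrum_fa_left"]],
    claustrum_fa_right = fav[["claustrum_fa_right"]],
    claustrum_fa_mean = combine_sides(fav[["claustrum_fa_left"]],
                                      fav[["claustrum_fa_right"]]),
    controlled_md_left = mdv[["controlled_md_left"]],
    controlled_md_right = mdv[["controlled_md_right"]],
    controlled_fa_left = fav[["controlled_fa_left"]],
    controlled_fa_right = fav[["controlled_fa_right"]],
    frame_md_left = mdv[["frame_md_left"]],
    frame_md_right = mdv[["frame_md_right"]],
    frame_fa_left = fav[["frame_fa_left"]],
    frame_fa_right = fav[["frame_fa_right"]],
    frame_fa = combine_sides(fav[["frame_fa_left"]],
                             fav[["frame_fa_right"]]),
    thalamus_volume = if (is.na(thal)) NA_real_
                      else label_volume_mm3(vol, thal),
    caudate_volume = if (is.na(caud)) NA_real_
                     else label_volume_mm3(vol, caud),
    gm_md = mdv[["gm_md"]], gm_fa = fav[["gm_fa"]],
    lentiform_fa = fav[["lentiform_fa"]],
    insular_fa = fav[["insular_fa"]],
    stringsAsFactors = FALSE
  )
  row$thalamus_relative <- row$thalamus_volume / tbv
  row$caudate_relative <- row$caudate_volume / tbv
  row
}
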