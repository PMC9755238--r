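# 3-D binary-mask morphology in voxel index space.
#
# The claustrum control masks need two primitives on 3-D logical grids:
# Chebyshev-ball dilation (iterated 3x3x3 dilation) and 26-neighbourhood
# counting. Both are implemented with vectorised array shifts;
# out-of-bounds voxels count as FALSE (zero padding). Anisotropic voxel
# sizes are deliberately ignored: the operators are defined on indices.

# shift a 3-D array by (dx, dy, dz), padding with `fill`
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
})

#' Dilate a 3-D mask by a Chebyshev ball
#'
#' One iteration adds every voxel whose 26-neighbourhood touches the mask
#' (3x3x3 structuring element); \code{radius} iterations give the Chebyshev
#' ball of that radius in index space. Grid boundaries are zero-padded.
#'
#' @param mask 3-D logical array.
#' @param radius non-negative integer Chebyshev radius.
#' @return 3-D logical array.
#' @export
dilate_chebyshev <- function(mask, radius = 1L) {
  stopifnot(length(dim(mask)) == 3L, radius >= 0)
  out <- mask
  for (i in seq_len(radius)) {
    acc <- out
    for (k in seq_len(nrow(.offsets26))) {
      o <- .offsets26[k, ]
      acc <- acc | shift3d(out, o$dx, o$dy, o$dz)
    }
    out <- acc
  }
  out
}

#' Count 26-neighbourhood members of a mask
#'
#' For every voxel, the number of TRUE voxels among its 26 neighbours
#' (3x3x3 minus centre); out-of-bounds neighbours count as FALSE.
#'
#' @param mask 3-D logical array.
#' @return 3-D integer array of counts in 0..26.
#' @export
neighbor_count26 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  acc <- array(0L, dim = dim(mask))
  for (k in seq_len(nrow(.offsets26))) {
    o <- .offsets26[k, ]
    acc <- acc + shift3d(mask, o$dx, o$dy, o$dz, fill = FALSE)
  }
  acc
}

new_mask <- function(grid, tag) {
  structure(list(grid = grid, tag = tag), class = "claustrum_mask")
}

#' @method print claustrum_mask
#' @export
print.claustrum_mask <- function(x, ...) {
  cat("mask '", x$tag, "': ", sum(x$grid), " voxels of ",
      paste(dim(x$grid), collapse = " x "), "\n", sep = "")
  invisible(x)
}

side_label_id <- function(vol, side = c("left", "right")) {
  side <- match.arg(side)
  vol$scheme$id[vol$scheme$class == paste0("claustrum_", side)]
}

#' Build the white-matter claustrum frame
#'
#' The frame is the insular white-matter shell directly around the
#' claustrum: the claustrum segmentation augmented by about two voxels on
#' all sides (Chebyshev-ball dilation of radius 2 in index space),
#' intersected with insular white matter, minus the claustrum itself. It
#' is used to control claustrum microstructure estimates for the
#' surrounding white matter.
#'
#' @param vol a \code{\link{label_volume}} whose scheme contains the
#'   claustrum side labels and insular WM regions.
#' @param side \code{"left"} or \code{"right"}.
#' @param radius dilation radius in voxels (default 2).
#' @param insular_wm_names scheme region names treated as insular WM for
#'   this side.
#' @return a mask object (3-D logical grid plus provenance tag); disjoint
#'   from every claustrum voxel by construction. Empty insular WM yields an
#'   empty mask with a warning.
#' @export
build_claustrum_frame <- function(vol, side = c("left", "right"),
                                  radius = 2L,
                                  insular_wm_names =
                                    paste0("insular_wm_", side)) {
  side <- match.arg(side)
  cla_id <- side_label_id(vol, side)
  cla <- vol$grid == cla_id
  if (!any(cla)) stop("claustrum (", side, ") has no voxels")
  wm_ids <- scheme_id(vol$scheme, insular_wm_names, required = FALSE)
  wm_ids <- wm_ids[!is.na(wm_ids)]
  wm <- array(FALSE, dim = dim(vol$grid))
  for (id in wm_ids) wm <- wm | (vol$grid == id)
  frame <- dilate_chebyshev(cla, radius) & wm & !cla
  # any-side claustrum voxels can never be part of the frame
  other <- vol$grid == side_label_id(vol, setdiff(c("left", "right"), side))
  frame <- frame & !other
  if (!any(frame))
    warning("claustrum frame (", side, ") is empty")
  new_mask(frame, paste0("frame_", side))
}

#' Build the claustrum-controlled segmentation
#'
#' The interior claustrum mask: claustrum voxels surrounded by other
#' claustrum voxels of the same side for at least \code{fraction} of their
#' 26-neighbourhood (centre excluded; out-of-bounds neighbours count as
#' non-claustrum). With the default fraction 0.9 a voxel needs at least 24
#' of 26 claustrum neighbours. Used to control ROI microstructure for
#' partial-volume effects at the claustrum boundary.
#'
#' @inheritParams build_claustrum_frame
#' @param fraction required neighbourhood fraction in (0, 1].
#' @return a mask object; always a subset of the claustrum mask. May be
#'   empty (flagged by downstream extraction, not an error).
#' @export
build_claustrum_controlled <- function(vol, side = c("left", "right"),
                                       fraction = 0.9) {
  side <- match.arg(side)
  stopifnot(fraction > 0, fraction <= 1)
  cla <- vol$grid == side_label_id(vol, side)
  counts <- neighbor_count26(cla)
  keep <- cla & (counts >= fraction * 26 - 1e-9)
  new_mask(keep, paste0("controlled_", side))
}

#' Mask for a single label id
#' @param vol a \code{label_volume}.
#' @param label_id integer id present in the scheme.
#' @return a mask object.
#' @export
label_mask <- function(vol, label_id) {
  if (!label_id %in% vol$scheme$id)
    stop("unknown label id: ", label_id)
  new_mask(vol$grid == label_id, paste0("label_", label_id))
}
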