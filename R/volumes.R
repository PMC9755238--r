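#' Label and metric volumes
#'
#' Lightweight containers for co-registered 3-D volumes. A
#' \code{label_volume} holds an integer parcellation grid together with its
#' voxel dimensions (mm), an (optional) affine carried for I/O fidelity,
#' and a \code{\link{label_scheme}}. A \code{metric_volume} holds a real
#' grid of MD (10^-3 mm^2/s) or FA (unitless) values. All morphology is
#' done in voxel index space; the affine is never used for computation.
#'
#' @param grid 3-D array.
#' @param voxel_size numeric length 3, mm per axis (positive).
#' @param scheme a \code{label_scheme}; all grid values must be scheme ids.
#' @param affine optional 4x4 matrix.
#' @return an object of class \code{"label_volume"}.
#' @export
label_volume <- function(grid, voxel_size = c(0.5, 0.5, 0.5), scheme,
                         affine = NULL) {
  stopifnot(length(dim(grid)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (!inherits(scheme, "label_scheme")) stop("scheme must be a label_scheme")
  storage.mode(grid) <- "integer"
  stray <- setdiff(unique(as.vector(grid)), scheme$id)
  if (length(stray))
    stop("grid contains ids not in scheme: ", paste(stray, collapse = ", "))
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 scheme = scheme, affine = affine),
            class = "label_volume")
}

#' @param metric \code{"md"} or \code{"fa"}. FA values are clipped to
#'   [0, 1] on ingest; the number of clipped voxels is recorded in the
#'   \code{clipped} field and a warning is raised when it is non-zero.
#' @rdname label_volume
#' @export
metric_volume <- function(grid, metric = c("md", "fa"),
                          voxel_size = c(0.5, 0.5, 0.5), affine = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(dim(grid)) == 3L, all(voxel_size > 0))
  storage.mode(grid) <- "double"
  clipped <- 0L
  if (metric == "fa") {
    out_of_range <- grid < 0 | grid > 1
    clipped <- sum(out_of_range)
    if (clipped > 0L) {
      warning("clipped ", clipped, " FA values to [0, 1]")
      grid[grid < 0] <- 0
      grid[grid > 1] <- 1
    }
  }
  structure(list(grid = grid, metric = metric,
                 voxel_size = as.numeric(voxel_size), affine = affine,
                 clipped = clipped),
            class = "metric_volume")
}

#' @method print label_volume
#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$grid), collapse = " x "),
      "voxels @", paste(x$voxel_size, collapse = " x "), "mm;",
      nrow(x$scheme), "labels in scheme\n")
  invisible(x)
}

#' @method print metric_volume
#' @export
print.metric_volume <- function(x, ...) {
  cat("metric_volume (", toupper(x$metric), "): ",
      paste(dim(x$grid), collapse = " x "), " voxels @ ",
      paste(x$voxel_size, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# shape + voxel-size compatibility check used before any extraction
check_aligned <- function(vol, metric) {
  if (!identical(dim(vol$grid), dim(metric$grid)))
    stop("shape mismatch: label volume is ",
         paste(dim(vol$grid), collapse = "x"), ", metric volume is ",
         paste(dim(metric$grid), collapse = "x"))
  if (max(abs(vol$voxel_size - metric$voxel_size)) > 1e-6)
    stop("voxel size mismatch between label and metric volume")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. Label volumes are written as integer
#' NIfTI, metric volumes as float.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param scheme label scheme to attach on read.
#' @return the volume object (read) or the path, invisibly (write).
#' @export
read_label_volume <- function(path, scheme) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  label_volume(array(as.integer(round(img)), dim = dim(img)[1:3]),
               voxel_size = vox, scheme = scheme,
               affine = RNifti::xform(img))
}

#' @param metric metric name for \code{read_metric_volume}.
#' @rdname read_label_volume
#' @export
read_metric_volume <- function(path, metric = c("md", "fa")) {
  img <- RNifti::readNifti(path)
  metric_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                metric = match.arg(metric),
                voxel_size = RNifti::pixdim(img)[1:3],
                affine = RNifti::xform(img))
}

#' @param vol volume object to write.
#' @rdname read_label_volume
#' @export
write_volume <- function(vol, path) {
  grid <- vol$grid
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(vol, "label_volume")) "int16"
                                else "float")
  invisible(path)
}
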