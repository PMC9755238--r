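# Voxel-level synthetic phantoms.
#
# The phantom is a geometric stand-in for a segmented neonatal brain: an
# ellipsoidal brain with CSF rim, cortical shell, central white matter,
# ventricles, subcortical nuclei, brainstem, and a thin claustrum sheet on
# each side wrapped in an insular white-matter shell and an insular cortex
# ring. Geometry is deterministic given the spec; only the metric noise
# fields consume random numbers.

#' Phantom specification
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_size mm per axis (default 0.5 isotropic).
#' @param claustrum_thickness sheet half-thickness in voxels along x.
#' @param claustrum_extent half-extent of the sheet in y and z (voxels).
#' @param claustrum_offset lateral offset of each sheet centre from the
#'   grid centre along x (voxels).
#' @param wm_shell Chebyshev radius of the insular WM shell around each
#'   sheet (must be >= 2 so the frame operator stays inside insular WM).
#' @param cortex_shell additional Chebyshev radius of the insular cortex
#'   ring outside the WM shell.
#' @param nucleus_radius radii (voxels) of thalamus, caudate and lentiform
#'   spheres.
#' @param md_mean,fa_mean named per-tissue metric levels (MD in 10^-3
#'   mm^2/s, FA unitless); free defaults at plausible neonatal levels.
#' @param md_noise_sd,fa_noise_sd voxel-level Gaussian noise SDs.
#' @return list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 48L),
                         voxel_size = c(0.5, 0.5, 0.5),
                         claustrum_thickness = 1L,
                         claustrum_extent = c(8L, 6L),
                         claustrum_offset = 18L,
                         wm_shell = 3L,
                         cortex_shell = 2L,
                         nucleus_radius = c(thalamus = 5, caudate = 4,
                                            lentiform = 4),
                         md_mean = c(csf = 3.0, ventricles = 3.0,
                                     cortical_gm = 1.20,
                                     insular_cortex = 1.20,
                                     white_matter = 1.30,
                                     insular_wm = 1.30,
                                     claustrum = 1.08,
                                     thalamus = 1.10, caudate = 1.15,
                                     lentiform = 1.10, brainstem = 1.00),
                         fa_mean = c(csf = 0.05, ventricles = 0.05,
                                     cortical_gm = 0.15,
                                     insular_cortex = 0.16,
                                     white_matter = 0.25,
                                     insular_wm = 0.25,
                                     claustrum = 0.22,
                                     thalamus = 0.20, caudate = 0.15,
                                     lentiform = 0.20, brainstem = 0.30),
                         md_noise_sd = 0.05, fa_noise_sd = 0.02) {
  stopifnot(length(shape) == 3L, all(shape > 8), all(voxel_size > 0),
            claustrum_thickness >= 0, wm_shell >= 2,
            md_noise_sd >= 0, fa_noise_sd >= 0)
  out <- list(shape = as.integer(shape), voxel_size = voxel_size,
              claustrum_thickness = as.integer(claustrum_thickness),
              claustrum_extent = as.integer(claustrum_extent),
              claustrum_offset = as.integer(claustrum_offset),
              wm_shell = as.integer(wm_shell),
              cortex_shell = as.integer(cortex_shell),
              nucleus_radius = nucleus_radius,
              md_mean = md_mean, fa_mean = fa_mean,
              md_noise_sd = md_noise_sd, fa_noise_sd = fa_noise_sd)
  class(out) <- "phantom_spec"
  out
}

index_grids <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                 dim = d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d))
}

build_phantom_labels <- function(pspec) {
  d <- pspec$shape
  sch <- phantom_scheme()
  id <- function(nm) scheme_id(sch, nm)
  g <- index_grids(d)
  ctr <- (d + 1) / 2
  semi <- (d - 2) / 2            # brain ellipsoid semi-axes
  edist <- function(cx, cy, cz, ax, ay, az)
    ((g$x - cx) / ax)^2 + ((g$y - cy) / ay)^2 + ((g$z - cz) / az)^2
  brain <- edist(ctr[1], ctr[2], ctr[3], semi[1], semi[2], semi[3]) <= 1

  grid <- array(id("background"), dim = d)
  grid[brain] <- id("csf")
  shrink <- function(k) edist(ctr[1], ctr[2], ctr[3],
                              semi[1] - k, semi[2] - k, semi[3] - k) <= 1
  grid[shrink(1.5)] <- id("cortical_gm")
  grid[shrink(4)] <- id("white_matter")
  # ventricles: small central ellipsoid
  grid[edist(ctr[1], ctr[2], ctr[3] + 2, 3, 5, 3) <= 1] <- id("ventricles")
  # subcortical nuclei around the midline, anterior of the ventricles
  sphere <- function(cx, cy, cz, r) edist(cx, cy, cz, r, r, r) <= 1
  nr <- pspec$nucleus_radius
  grid[sphere(ctr[1], ctr[2] + 9, ctr[3], nr[["thalamus"]])] <- id("thalamus")
  grid[sphere(ctr[1] - 7, ctr[2] - 9, ctr[3], nr[["caudate"]])] <- id("caudate")
  grid[sphere(ctr[1] + 7, ctr[2] - 9, ctr[3], nr[["lentiform"]])] <-
    id("lentiform")
  # brainstem: vertical cylinder descending from the centre
  stem <- ((g$x - ctr[1])^2 + (g$y - ctr[2] - 2)^2 <= 9) &
    g$z < ctr[3] - 6 & brain
  grid[stem] <- id("brainstem")

  # claustrum sheets + insular shells, painted last so the sheets are
  # guaranteed to be wrapped in insular WM
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    cx <- floor(ctr[1]) + sgn * pspec$claustrum_offset
    sheet <- abs(g$x - cx) <= pspec$claustrum_thickness &
      abs(g$y - ctr[2]) <= pspec$claustrum_extent[1] &
      abs(g$z - ctr[3]) <= pspec$claustrum_extent[2]
    if (!any(sheet))
      stop("claustrum sheet (", side, ") has zero voxels for this grid")
    wm_ring <- dilate_chebyshev(sheet, pspec$wm_shell)
    ctx_ring <- dilate_chebyshev(wm_ring, pspec$cortex_shell) & !wm_ring
    grid[ctx_ring] <- id(paste0("insular_cortex_", side))
    grid[wm_ring & !sheet] <- id(paste0("insular_wm_", side))
    grid[sheet] <- id(paste0("claustrum_", side))
  }

  missing <- setdiff(sch$id, unique(as.vector(grid)))
  if (length(missing))
    stop("phantom geometry leaves scheme labels unused: ",
         paste(sch$name[match(missing, sch$id)], collapse = ", "))
  label_volume(grid, voxel_size = pspec$voxel_size, scheme = sch)
}

# tissue mean lookup per label id, with per-side claustrum values from a
# subject row when available
tissue_levels <- function(pspec, metric, row = NULL) {
  sch <- phantom_scheme()
  means <- if (metric == "md") pspec$md_mean else pspec$fa_mean
  lut <- c(background = 0, csf = means[["csf"]],
           ventricles = means[["ventricles"]],
           cortical_gm = means[["cortical_gm"]],
           insular_cortex_left = means[["insular_cortex"]],
           insular_cortex_right = means[["insular_cortex"]],
           insular_wm_left = means[["insular_wm"]],
           insular_wm_right = means[["insular_wm"]],
           claustrum_left = means[["claustrum"]],
           claustrum_right = means[["claustrum"]],
           thalamus = means[["thalamus"]], caudate = means[["caudate"]],
           lentiform = means[["lentiform"]],
           brainstem = means[["brainstem"]],
           white_matter = means[["white_matter"]])
  if (!is.null(row)) {
    for (side in c("left", "right")) {
      col <- paste0("claustrum_", metric, "_", side)
      if (col %in% names(row) && !is.na(row[[col]]))
        lut[[paste0("claustrum_", side)]] <- row[[col]]
    }
  }
  lut[match(sch$name, names(lut))]
}

#' Generate a synthetic phantom bundle
#'
#' Builds the deterministic label geometry plus MD and FA volumes painted
#' with per-tissue means (claustrum voxels take the subject's drawn
#' per-side MD/FA values when a cohort row is supplied) and voxel-level
#' Gaussian noise. Label geometry never consumes random numbers, so two
#' seeds share identical geometry and differ only in the noise fields.
#'
#' @param pspec a \code{\link{phantom_spec}}.
#' @param row optional single cohort row supplying per-side claustrum
#'   MD/FA levels.
#' @param seed integer RNG seed for the noise fields.
#' @return list of class \code{"phantom_bundle"} with elements
#'   \code{label}, \code{md}, \code{fa} and \code{provenance}.
#' @export
generate_phantom <- function(pspec = phantom_spec(), row = NULL,
                             seed = 1L) {
  vol <- build_phantom_labels(pspec)
  set.seed(seed)
  sch <- vol$scheme
  paint <- function(metric, noise_sd) {
    lev <- tissue_levels(pspec, metric, row)
    grid <- array(lev[match(as.vector(vol$grid), sch$id)],
                  dim = dim(vol$grid))
    if (noise_sd > 0)
      grid <- grid + array(stats::rnorm(length(grid), 0, noise_sd),
                           dim = dim(grid))
    if (metric == "fa") grid <- pmin(pmax(grid, 0), 1)
    metric_volume(grid, metric = metric, voxel_size = pspec$voxel_size)
  }
  structure(list(label = vol,
                 md = paint("md", pspec$md_noise_sd),
                 fa = paint("fa", pspec$fa_noise_sd),
                 provenance = list(spec = unclass(pspec), seed = seed,
                                   subject_id = row$subject_id)),
            class = "phantom_bundle")
}

#' Write a phantom bundle to disk
#'
#' Writes the label volume (integer NIfTI), MD and FA volumes (float
#' NIfTI) and a provenance JSON.
#'
#' @param bundle a \code{phantom_bundle}.
#' @param dir output directory (created if needed).
#' @param stem filename stem.
#' @return paths of the written files, invisibly.
#' @export
write_phantom <- function(bundle, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, c("_labels.nii.gz", "_md.nii.gz",
                                         "_fa.nii.gz", ".json")))
  write_volume(bundle$label, paths[1])
  write_volume(bundle$md, paths[2])
  write_volume(bundle$fa, paths[3])
  jsonlite::write_json(bundle$provenance, paths[4], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
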