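#' Label schemes for parcellation volumes
#'
#' A label scheme maps integer label ids in a parcellation volume to region
#' names and tissue classes. Tissue classes drive total-brain-volume
#' accounting (background, CSF and ventricles are excluded), grey-matter
#' averaging (cortical + subcortical GM + claustrum), and the tissue-class
#' summaries of the structural covariance analysis. Real Draw-EM style
#' parcellations can be adapted by supplying a scheme table that maps their
#' ids onto the reserved region names used by the extraction step
#' (\code{claustrum_left}, \code{claustrum_right}, \code{insular_wm_left},
#' \code{insular_wm_right}, \code{insular_cortex_*}, \code{thalamus},
#' \code{caudate}, \code{lentiform}).
#'
#' @param id integer vector of unique label ids.
#' @param name character vector of region names (unique).
#' @param class character vector of tissue classes; one of
#'   \code{"background"}, \code{"csf"}, \code{"ventricles"},
#'   \code{"cortical_gm"}, \code{"subcortical_gm"}, \code{"wm"},
#'   \code{"brainstem"}, \code{"claustrum_left"}, \code{"claustrum_right"}.
#' @return A \code{data.frame} of class \code{"label_scheme"} with columns
#'   \code{id}, \code{name}, \code{class}.
#' @export
label_scheme <- function(id, name, class) {
  id <- as.integer(id)
  name <- as.character(name)
  class <- as.character(class)
  if (anyDuplicated(id)) stop("label ids must be unique")
  if (anyDuplicated(name)) stop("region names must be unique")
  if (length(id) != length(name) || length(id) != length(class))
    stop("id, name and class must have equal length")
  bad <- setdiff(class, .tissue_classes)
  if (length(bad))
    stop("unknown tissue class(es): ", paste(bad, collapse = ", "))
  for (side in c("claustrum_left", "claustrum_right")) {
    if (sum(class == side) != 1L)
      stop("scheme must contain exactly one '", side, "' label")
  }
  out <- data.frame(id = id, name = name, class = class,
                    stringsAsFactors = FALSE)
  class(out) <- c("label_scheme", "data.frame")
  out
}

.tissue_classes <- c("background", "csf", "ventricles", "cortical_gm",
                     "subcortical_gm", "wm", "brainstem",
                     "claustrum_left", "claustrum_right")

# classes excluded from total brain volume
.tbv_excluded_classes <- c("background", "csf", "ventricles")

# classes pooled for the grey-matter average (claustrum counts as
# subcortical GM)
.gm_classes <- c("cortical_gm", "subcortical_gm",
                 "claustrum_left", "claustrum_right")

#' Look up a label id by region name
#'
#' @param scheme a \code{label_scheme}.
#' @param name region name(s).
#' @param required error (TRUE) or return NA (FALSE) when absent.
#' @return integer label id(s).
#' @export
scheme_id <- function(scheme, name, required = TRUE) {
  idx <- match(name, scheme$name)
  if (required && anyNA(idx))
    stop("region(s) not in scheme: ",
         paste(name[is.na(idx)], collapse = ", "))
  scheme$id[idx]
}

#' Label ids belonging to given tissue classes
#' @param scheme a \code{label_scheme}.
#' @param classes tissue class names.
#' @return integer vector of label ids.
#' @export
scheme_ids_by_class <- function(scheme, classes) {
  scheme$id[scheme$class %in% classes]
}

#' Default phantom label scheme
#'
#' The compact scheme used by the synthetic phantom generator. It contains
#' the minimum label set the extraction pipeline needs: background, a CSF
#' rim, ventricles, a cortical GM shell including insular cortex, insular
#' white matter surrounding both claustrum sheets, left/right claustrum,
#' thalamus, caudate and lentiform nuclei, brainstem, and cerebral white
#' matter.
#'
#' @return a \code{label_scheme}.
#' @export
phantom_scheme <- function() {
  label_scheme(
    id = 0:14,
    name = c("background", "csf", "ventricles", "cortical_gm",
             "insular_cortex_left", "insular_cortex_right",
             "insular_wm_left", "insular_wm_right",
             "claustrum_left", "claustrum_right",
             "thalamus", "caudate", "lentiform", "brainstem",
             "white_matter"),
    class = c("background", "csf", "ventricles", "cortical_gm",
              "cortical_gm", "cortical_gm",
              "wm", "wm",
              "claustrum_left", "claustrum_right",
              "subcortical_gm", "subcortical_gm", "subcortical_gm",
              "brainstem",
              "wm")
  )
}

#' Default covariance region scheme
#'
#' The region list used by the structural covariance analysis: 34 cortical
#' grey-matter, 12 subcortical grey-matter and 33 white-matter regions
#' (paired lobar/gyral subdivisions plus the corpus callosum), emulating a
#' neonatal Draw-EM style whole-brain parcellation after removal of the
#' claustra, CSF and background.
#'
#' @return data.frame with columns \code{region} and \code{class}.
#' @export
covariance_regions <- function() {
  ctx <- c("frontal_anterior", "frontal_posterior", "parietal_anterior",
           "parietal_posterior", "temporal_anterior", "temporal_posterior",
           "occipital", "insula", "cingulate_anterior",
           "cingulate_posterior", "parahippocampal", "fusiform",
           "precentral", "postcentral", "superior_temporal",
           "medial_frontal", "lateral_occipital")
  sub <- c("thalamus", "caudate", "lentiform", "subthalamic",
           "hippocampus", "amygdala")
  wm <- c("frontal_anterior_wm", "frontal_posterior_wm",
          "parietal_anterior_wm", "parietal_posterior_wm",
          "temporal_anterior_wm", "temporal_posterior_wm", "occipital_wm",
          "insula_wm", "cingulate_anterior_wm", "cingulate_posterior_wm",
          "parahippocampal_wm", "fusiform_wm", "precentral_wm",
          "postcentral_wm", "superior_temporal_wm", "medial_frontal_wm")
  pair <- function(x) as.vector(rbind(paste0(x, "_left"),
                                      paste0(x, "_right")))
  region <- c(pair(ctx), pair(sub), pair(wm), "corpus_callosum")
  cls <- c(rep("cortical_gm", 2L * length(ctx)),
           rep("subcortical_gm", 2L * length(sub)),
           rep("wm", 2L * length(wm) + 1L))
  data.frame(region = region, class = cls, stringsAsFactors = FALSE)
}

#' Read / write a label scheme as TSV
#'
#' @param path file path; TSV with header columns id, name, class.
#' @return \code{read_scheme}: a \code{label_scheme}.
#' @export
read_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "class")
  if (!all(need %in% names(df)))
    stop("scheme file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  label_scheme(df$id, df$name, df$class)
}

#' @param scheme a \code{label_scheme}.
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
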