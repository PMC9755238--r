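# End-to-end pipeline orchestration: simulate (or load) -> match -> GLMs
# -> longitudinal tests -> covariance comparison -> report.

#' Pipeline configuration
#'
#' @param mode \code{"simulate"} (inputs generated from the specs below;
#'   seed mandatory) or \code{"real-data"} (inputs read from
#'   \code{cohort_path} / \code{regional_paths}).
#' @param seed integer seed for simulate mode.
#' @param spec,effects,cov_spec generator specifications.
#' @param n_term_pool size of the term-born control pool the matched
#'   comparison draws from.
#' @param n_term_spectrum term-spectrum size for the context analysis.
#' @param n_longitudinal preterm subjects scanned twice.
#' @param n_dwi per-group sample size of the diffusion (covariance)
#'   analyses.
#' @param q_threshold FDR significance threshold.
#' @param analyses character subset of
#'   \code{c("context_term", "longitudinal", "main_comparison",
#'   "covariance")}.
#' @param cohort_path,regional_paths input files for real-data mode
#'   (\code{regional_paths}: named list with entries \code{term} and
#'   \code{preterm}).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(mode = c("simulate", "real-data"),
                            seed = 1L,
                            spec = cohort_spec(),
                            effects = effect_params(),
                            cov_spec = regional_cov_spec(),
                            n_term_pool = 377L,
                            n_term_spectrum = 377L,
                            n_longitudinal = 53L,
                            n_dwi = 72L,
                            q_threshold = 0.05,
                            analyses = c("context_term", "longitudinal",
                                         "main_comparison", "covariance"),
                            cohort_path = NULL,
                            regional_paths = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate" && (is.null(seed) || is.na(seed)))
    stop("seed is mandatory in simulate mode")
  if (mode == "real-data") {
    for (p in c(cohort_path, unlist(regional_paths)))
      if (!is.null(p) && !file.exists(p))
        stop("input path does not exist: ", p)
  }
  structure(list(mode = mode, seed = as.integer(seed), spec = spec,
                 effects = effects, cov_spec = cov_spec,
                 n_term_pool = as.integer(n_term_pool),
                 n_term_spectrum = as.integer(n_term_spectrum),
                 n_longitudinal = as.integer(n_longitudinal),
                 n_dwi = as.integer(n_dwi),
                 q_threshold = q_threshold, analyses = analyses,
                 cohort_path = cohort_path,
                 regional_paths = regional_paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat declarative file; recognised keys are the arguments of
#' \code{\link{pipeline_config}} (generator blocks accept the fields of
#' \code{\link{cohort_spec}}).
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (is.null(y$cohort)) cohort_spec()
          else do.call(cohort_spec, y$cohort)
  args <- y[setdiff(names(y), "cohort")]
  args$spec <- spec
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(rapply(unclass(config), unclass,
                                             how = "replace")),
                              auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Load and validate pipeline inputs
#'
#' In simulate mode all inputs are generated from the config (no
#' filesystem reads); in real-data mode the cohort TSV and regional tables
#' are read and schema-checked before any computation.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{cohort} and (optionally) \code{regional} tables.
#' @export
load_inputs <- function(config) {
  if (config$mode == "simulate") {
    spec <- config$spec
    spec$n_term <- config$n_term_pool
    cohort <- generate_cohort(spec, config$effects,
                              seed = config$seed + 1L)
    return(list(cohort = cohort, regional = NULL))
  }
  cohort <- read_cohort_table(config$cohort_path)
  regional <- NULL
  if (!is.null(config$regional_paths))
    regional <- lapply(config$regional_paths, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE))
  list(cohort = cohort, regional = regional)
}

main_outcomes <- function() {
  c("claustrum_volume_mean", "relative_volume_total",
    "claustrum_md_mean", "claustrum_fa_mean",
    "claustrum_volume_right", "claustrum_volume_left",
    "relative_volume_right", "relative_volume_left",
    "claustrum_md_right", "claustrum_md_left",
    "claustrum_fa_right", "claustrum_fa_left")
}

group_summary <- function(table, outcome) {
  s <- function(g) {
    v <- table[[outcome]][table$group == g]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v[!is.na(v)]))
  }
  list(term = s("term"), preterm = s("preterm"))
}

glm_block <- function(table, outcome, covariates = c("scan_age", "sex")) {
  fit <- fit_glm(table, outcome, group = "group", covariates = covariates)
  term <- glm_term(fit, "group")
  gs <- group_summary(table, outcome)
  list(outcome = outcome, n = fit$n, n_dropped = fit$n_dropped,
       term_mean = gs$term[["mean"]], term_sd = gs$term[["sd"]],
       preterm_mean = gs$preterm[["mean"]], preterm_sd = gs$preterm[["sd"]],
       estimate = term$estimate, t = term$t, p = term$p,
       partial_eta2 = term$partial_eta2)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled analyses in study order: context term-spectrum
#' GLMs (scan-age term, corrected for sex and birth age), longitudinal
#' paired tests and random-intercept mixed models, the matched main group
#' comparison with control analyses, and the structural covariance
#' comparison with tissue-class summaries. Deterministic given the seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"run_report"}.
#' @export
run_pipeline <- function(config) {
  report <- list(provenance = list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("claustrumdev"))))
  log <- character(0)

  if ("context_term" %in% config$analyses) {
    spec <- term_spectrum_spec(config$n_term_spectrum)
    tab <- generate_cohort(spec, config$effects, seed = config$seed + 11L)
    blocks <- lapply(c("claustrum_volume_mean", "relative_volume_total",
                       "claustrum_md_mean", "claustrum_fa_mean"),
                     function(oc) {
      fit <- fit_glm(tab, oc, group = NULL,
                     covariates = c("scan_age", "sex", "birth_age"))
      term <- glm_term(fit, "scan_age")
      list(outcome = oc, n = fit$n, slope = term$estimate, t = term$t,
           p = term$p, partial_eta2 = term$partial_eta2)
    })
    report$context_term <- blocks
  }

  if ("longitudinal" %in% config$analyses) {
    tab <- generate_longitudinal_cohort(
      longitudinal_spec(config$n_longitudinal), config$effects,
      seed = config$seed + 12L)
    blocks <- lapply(c("claustrum_volume_mean", "relative_volume_total",
                       "claustrum_md_mean", "claustrum_fa_mean"),
                     function(oc) {
      wide <- merge(tab[tab$session == 1, c("subject_id", oc)],
                    tab[tab$session == 2, c("subject_id", oc)],
                    by = "subject_id")
      pt <- paired_t(wide[[2]], wide[[3]])
      mm <- fit_random_intercept_model(tab, oc)
      slope <- mm$fixed[mm$fixed$term == "scan_age", ]
      list(outcome = oc, paired_t = unclass(pt),
           mixed_slope = slope$estimate, mixed_p = slope$p,
           intercept_sd = mm$intercept_sd, residual_sd = mm$residual_sd)
    })
    report$longitudinal <- blocks
  }

  matched <- NULL
  if (any(c("main_comparison", "covariance") %in% config$analyses)) {
    inputs <- load_inputs(config)
    cohort <- inputs$cohort
    pt_rows <- cohort[cohort$group == "preterm", ]
    ft_pool <- cohort[cohort$group == "term", ]
    m <- withCallingHandlers(
      match_controls(pt_rows, ft_pool),
      warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    matched <- rbind(pt_rows,
                     ft_pool[ft_pool$subject_id %in% m$pairs$term_id, ])
    report$matching <- list(n_pairs = nrow(m$pairs),
                            mean_gap = mean(m$pairs$gap))
  }

  if ("main_comparison" %in% config$analyses) {
    blocks <- lapply(main_outcomes(), function(oc) glm_block(matched, oc))
    controls <- list(
      thalamus_relative = glm_block(matched, "thalamus_relative"),
      caudate_relative = glm_block(matched, "caudate_relative"),
      md_gm_adjusted = glm_block(matched, "claustrum_md_mean",
                                 c("scan_age", "sex", "gm_md")),
      fa_gm_adjusted = glm_block(matched, "claustrum_fa_mean",
                                 c("scan_age", "sex", "gm_fa")),
      fa_insula_adjusted = glm_block(matched, "claustrum_fa_mean",
                                     c("scan_age", "sex", "insular_fa")),
      fa_lentiform_adjusted = glm_block(matched, "claustrum_fa_mean",
                                        c("scan_age", "sex",
                                          "lentiform_fa")),
      fa_frame_adjusted = glm_block(matched, "claustrum_fa_mean",
                                    c("scan_age", "sex", "frame_fa")))
    report$main_comparison <- list(outcomes = blocks, controls = controls)
  }

  if ("covariance" %in% config$analyses) {
    if (config$mode == "simulate") {
      take <- function(g) {
        rows <- matched[matched$group == g, ]
        utils::head(rows, config$n_dwi)
      }
      reg_t <- generate_regional_table(config$cov_spec, take("term"),
                                       seed = config$seed + 13L)
      reg_p <- generate_regional_table(config$cov_spec, take("preterm"),
                                       seed = config$seed + 14L)
    } else {
      reg_t <- load_inputs(config)$regional$term
      reg_p <- load_inputs(config)$regional$preterm
    }
    cov_blocks <- list()
    for (metric in c("volume", "relative_volume", "md", "fa")) {
      entries <- withCallingHandlers(
        compare_covariance(reg_t, reg_p, metric,
                           regions = config$cov_spec$regions,
                           q_threshold = config$q_threshold),
        warning = function(w) {
          log <<- c(log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cov_blocks[[metric]] <- list(entries = entries,
                                   summary = tissue_summary(entries))
    }
    report$covariance <- cov_blocks
  }

  report$log <- log
  class(report) <- "run_report"
  report
}

#' Write a run report to disk
#'
#' Emits a machine-readable JSON report, a group-comparison TSV (one row
#' per outcome: group means and SDs, p, partial eta-squared), a
#' tissue-summary TSV (one row per group, metric and tissue class with the
#' "n_sig/n_total" convention), a per-region covariance export TSV, and a
#' plain-text log. Column order is stable across runs.
#'
#' @param report a \code{run_report}.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(outdir, "report.json"),
             log = file.path(outdir, "run.log"))
  ser <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(ser, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       force = TRUE)
  if (!is.null(report$main_comparison)) {
    tab <- do.call(rbind, lapply(report$main_comparison$outcomes,
                                 as.data.frame))
    paths[["group_comparison"]] <- file.path(outdir,
                                             "group_comparison.tsv")
    write_tsv(tab, paths[["group_comparison"]])
  }
  if (!is.null(report$covariance)) {
    summ <- do.call(rbind, lapply(report$covariance,
                                  function(b) b$summary))
    summ$n_sig_over_total <- paste0(summ$n_significant, "/", summ$n_total)
    paths[["tissue_summary"]] <- file.path(outdir, "tissue_summary.tsv")
    write_tsv(summ, paths[["tissue_summary"]])
    entries <- do.call(rbind, lapply(report$covariance,
                                     function(b) as.data.frame(b$entries)))
    paths[["covariance_regions"]] <- file.path(outdir,
                                               "covariance_regions.tsv")
    write_tsv(entries, paths[["covariance_regions"]])
  }
  writeLines(c(paste("config hash:", report$provenance$config_hash),
               paste("seed:", report$provenance$seed),
               report$log), paths[["log"]])
  invisible(paths)
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat("claustrum analysis run (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  cat(" blocks:", paste(setdiff(names(x), c("provenance", "log")),
                        collapse = ", "), "\n")
  invisible(x)
}
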