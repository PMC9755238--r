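#' Read and validate a cohort table
#'
#' Reads a TSV cohort table (tab-separated, header row) and validates its
#' schema: required columns subject_id, group, birth_age, scan_age, sex;
#' numeric age columns; group in {term, preterm}; sex in {male, female};
#' scan age not below birth age. Errors name the offending column and row.
#'
#' @param path TSV file path.
#' @return validated \code{data.frame}.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "birth_age", "scan_age", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("birth_age", "scan_age")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("cohort table ", path, ": non-numeric ", col, " in row ",
           bad[1])
    df[[col]] <- v
  }
  bad_group <- which(!df$group %in% c("term", "preterm"))
  if (length(bad_group))
    stop("cohort table ", path, ": invalid group in row ", bad_group[1])
  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop("cohort table ", path, ": invalid sex in row ", bad_sex[1])
  bad_age <- which(df$scan_age < df$birth_age)
  if (length(bad_age))
    stop("cohort table ", path, ": scan_age below birth_age in row ",
         bad_age[1])
  df
}

#' Write a table as TSV
#'
#' Tab-separated, UTF-8, header row, no quoting or row names.
#' @param table data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
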