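# Cohort CSV with a fixed, validated schema. Missing values use the token
# "NA"; the abnormal-EEG composite invariant is re-checked on every read.

#' Write / read a cohort table
#'
#' `write_cohort()` writes the per-subject table as CSV using the schema
#' from [cohort_schema()] (missing token `NA`). `read_cohort()` reads it
#' back with declared column types and runs [validate_cohort()], so a file
#' violating the schema or the abnormal-EEG composite invariant is
#' rejected at load time.
#'
#' @param coh a cohort `data.frame`.
#' @param path CSV file path.
#' @return `write_cohort()`: the path, invisibly. `read_cohort()`: the
#'   validated `data.frame`.
#' @export
write_cohort <- function(coh, path) {
  coh <- validate_cohort(coh)
  write.csv(coh, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- cohort_schema()
  coh <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = NA)
  validate_cohort(coh)
  for (col in names(schema)) {
    coh[[col]] <- switch(
      schema[[col]],
      character = as.character(coh[[col]]),
      logical = as.logical(coh[[col]]),
      integer = as.integer(coh[[col]]),
      numeric = as.numeric(coh[[col]])
    )
  }
  validate_cohort(coh)
}
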