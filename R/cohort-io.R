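## Cohort tables travel as plain CSV (one row per pair, empty cell = missing)
## with a JSON sidecar recording the generating spec and seed when known.

#' Read and write twin cohort tables
#'
#' Cohorts are stored as CSV with columns `family_id`, `zygosity`, `sex_1`,
#' `sex_2`, `age` and one `<trait>_1` / `<trait>_2` pair of columns per trait;
#' an empty cell encodes a missing value. `write_cohort()` also writes a
#' `<path>.json` sidecar with the generating specification and seed when the
#' cohort carries one.
#'
#' @param cohort a `twin_cohort` (or compatible data frame).
#' @param path CSV file path.
#' @return `read_cohort()` returns a `twin_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  spec <- attr(cohort, "gen_spec")
  if (!is.null(spec)) {
    side <- unclass(spec)
    side$spec_class <- class(spec)[1]
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("family_id", "zygosity", "sex_1", "sex_2", "age")
  missing_cols <- setdiff(needed, names(df))
  check_that(length(missing_cols) == 0,
             paste("cohort file lacks required columns:",
                   paste(missing_cols, collapse = ", ")))
  check_that(all(df$zygosity %in% c("MZ", "DZ")),
             "zygosity labels must be 'MZ' or 'DZ'")
  traits <- cohort_traits(df)
  finish_cohort(df, traits, NULL)
}

## Infer trait names from paired <name>_1 / <name>_2 value columns.
cohort_traits <- function(df) {
  vals <- setdiff(names(df), c("family_id", "zygosity", "sex_1", "sex_2", "age"))
  t1 <- sub("_1$", "", vals[grepl("_1$", vals)])
  t2 <- sub("_2$", "", vals[grepl("_2$", vals)])
  intersect(t1, t2)
}

## n x 2 matrix of a trait's per-twin values for one zygosity group.
trait_matrix <- function(cohort, trait, zygosity = NULL) {
  df <- as.data.frame(cohort)
  if (!is.null(zygosity)) df <- df[df$zygosity == zygosity, , drop = FALSE]
  cols <- paste0(trait, "_", 1:2)
  check_that(all(cols %in% names(df)),
             sprintf("trait '%s' not present in cohort", trait))
  as.matrix(df[cols])
}
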