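#' @keywords internal
"_PACKAGE"

# accepted spellings for the two sex categories (case-insensitive)
.sex_codes <- c(female = "female", f = "female", w = "female",
                woman = "female", women = "female",
                male = "male", m = "male", man = "male", men = "male")

canonical_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.sex_codes[key])
  bad <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(bad)) {
    stop("unrecognized sex coding: ", paste(unique(key[bad]), collapse = ", "),
         " (accepted: ", paste(names(.sex_codes), collapse = ", "), ")")
  }
  factor(out, levels = c("female", "male"))
}

#' Construct and validate a cohort table
#'
#' A cohort table is a data frame with one row per individual: a unique `id`,
#' a `sex` factor with levels female/male, chronological `age` in years, and
#' zero or more numeric biomarker columns (missing values allowed). All
#' analysis functions in the package operate on this structure.
#'
#' @param df data frame with at least `id`, `sex`, `age` columns.
#' @param registry biomarker registry used to recognize biomarker columns;
#'   columns that are neither mandatory nor in the registry are kept but
#'   reported with a warning.
#' @return A validated data frame of class `ba_cohort`.
#' @export
as_cohort <- function(df, registry = biomarker_registry()) {
  mandatory <- c("id", "sex", "age")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop_schema("cohort is missing mandatory column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in cohort: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  df$sex <- canonical_sex(df$sex)
  df$age <- as.numeric(df$age)
  if (any(is.na(df$age)) || any(df$age <= 0 | df$age >= 130)) {
    stop("chronological age must be a number in (0, 130) for every record")
  }
  value_cols <- setdiff(names(df), mandatory)
  # "map" is the package's own derived variable (see add_map); always known
  unknown <- setdiff(value_cols, c(registry$name, "map"))
  if (length(unknown)) {
    warning("cohort columns not in the biomarker registry (kept as-is): ",
            paste(unknown, collapse = ", "))
  }
  for (cl in value_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("biomarker column '", cl, "' is not numeric after validation")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("ba_cohort", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' Expects a comma-separated, "."-decimal, UTF-8 file with a header row
#' containing `id`, `sex`, `age` plus biomarker columns named as in the
#' registry. Empty cells and the literal `NA` are read as missing. Sex may be
#' coded as female/male, F/M, W/M, or women/men (case-insensitive).
#'
#' @param path path to a CSV file.
#' @param registry biomarker registry; see [biomarker_registry()].
#' @return A validated [as_cohort()] data frame.
#' @export
read_cohort <- function(path, registry = biomarker_registry()) {
  if (!file.exists(path)) stop_io("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  mandatory <- c("id", "sex", "age")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop_schema("cohort file is missing mandatory column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(names(raw), c("id", "sex"))
  for (cl in num_cols) {
    cell <- trimws(raw[[cl]])
    cell[cell == "" | toupper(cell) == "NA"] <- NA_character_
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(parsed))
    if (length(bad)) {
      stop("unparseable numeric value(s) in column '", cl, "', data row(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(cell[bad]), collapse = ", "))
    }
    raw[[cl]] <- parsed
  }
  as_cohort(raw, registry = registry)
}

#' Write a cohort CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round-trip reproduces the cohort exactly; missing values are
#' written as empty fields.
#'
#' @param cohort a `ba_cohort` data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort, stringsAsFactors = FALSE)
  for (cl in names(out)) {
    v <- out[[cl]]
    if (is.numeric(v)) {
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- ""
      out[[cl]] <- s
    } else {
      s <- as.character(v)
      s[is.na(s)] <- ""
      out[[cl]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write cohort to '", path, "': ",
                           conditionMessage(ok))
  invisible(path)
}

#' Add a derived mean arterial pressure column
#'
#' Computes `map = sbp/3 + 2*dbp/3` from the systolic and diastolic pressure
#' columns and appends it to the cohort (see [derive_map()]).
#'
#' @param cohort a `ba_cohort` with `sbp` and `dbp` columns.
#' @return The cohort with a `map` column added.
#' @export
add_map <- function(cohort) {
  if (!all(c("sbp", "dbp") %in% names(cohort))) {
    stop("cohort must contain 'sbp' and 'dbp' columns to derive MAP")
  }
  cohort$map <- derive_map(cohort$sbp, cohort$dbp)
  cohort
}

#' @export
print.ba_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d individuals (%d female, %d male), ages %.1f-%.1f, %d biomarker columns>\n",
              nrow(x), sum(x$sex == "female"), sum(x$sex == "male"),
              min(x$age), max(x$age), ncol(x) - 3L))
  NextMethod()
}
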