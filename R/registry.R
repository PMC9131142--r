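#' Candidate biomarker registry
#'
#' Returns the panel of 32 candidate physiological biomarkers of healthy
#' aging together with their reference-cohort summary statistics: pooled mean
#' and SD, and the per-year linear age slope with its 95% confidence
#' interval, as published for the reference cohort of 100 healthy adults
#' (18-65 y). Units are metadata only; no unit conversion is ever performed.
#'
#' The `direction` column encodes the expected direction of change with age:
#' it is derived from the slope confidence interval (`increases_with_age`
#' when the CI lies above 0, `decreases_with_age` when below, otherwise
#' `unknown`). `priority_rank` is a unique rank used as a deterministic
#' tie-break; clinical priority for redundancy pruning is supplied separately
#' (see [redundancy_prune()]).
#'
#' @return A data frame of class `ba_registry` with one row per biomarker and
#'   columns `name`, `label`, `category`, `units`, `mean`, `sd`, `slope`,
#'   `slope_low`, `slope_high`, `priority_rank`, `direction`.
#' @seealso [registry_quality_flags()] for published values that are
#'   internally inconsistent, [registry_to_json()] for a user-editable export.
#' @export
#' @examples
#' reg <- biomarker_registry()
#' reg[reg$name == "waist", ]
biomarker_registry <- function() {
  # name, label, category, units, mean, sd, slope, slope_low, slope_high
  rows <- list(
    list("weight",          "Weight",                  "body_composition", "kg",          75.7,  13.1,   0.03,   -0.2,    0.2),
    list("waist",           "Waist circumference",     "body_composition", "cm",          83.4,   9.8,   0.2,     0.05,   0.3),
    list("hip",             "Hip circumference",       "body_composition", "cm",         101.4,   7.1,  -0.001,  -0.1,    0.1),
    list("waist_hip_ratio", "Waist/hip ratio",         "body_composition", "ratio",        0.8,   0.07,  0.002,   0.001,  0.003),
    list("fat_mass",        "Fat mass",                "body_composition", "%",           26.8,   8.3,   0.09,   -0.03,   0.2),
    list("muscle_mass",     "Muscle mass",             "body_composition", "kg",          52.8,  10.9,  -0.05,   -0.2,    0.1),
    list("fbg",             "Fasting blood glucose",   "metabolic",        "mmol/l",       5.1,   0.4,   0.01,    0.004,  0.015),
    list("hba1c",           "HbA1c",                   "metabolic",        "mmol/mol",    32.8,   3.2,   0.12,    0.08,   0.16),
    list("ages",            "Advanced glycation end products", "metabolic", "AU",          1.8,   0.5,   0.027,   0.022,  0.031),
    list("insulin",         "Insulin",                 "metabolic",        "pmol/l",      44.4,  25.3,   0.05,   -0.32,   0.42),
    list("triglycerides",   "Triglycerides",           "metabolic",        "mmol/l",       0.9,   0.4,   0.002,  -0.004,  0.008),
    list("ffa",             "Free fatty acids",        "metabolic",        "umol/l",     440,   212,     2.36,   -0.72,   5.46),
    list("leptin",          "Leptin",                  "metabolic",        "pg/ml",     8411,  9472,   -60.0,  -199.8,   79.9),
    list("adiponectin",     "Adiponectin",             "metabolic",        "mg/ml",    11515,  6490,   106.6,    13.4,  199.8),
    list("hdl",             "HDL cholesterol",         "metabolic",        "mmol/l",       1.5,   0.4,   0.01,    0.006,  0.017),
    list("ldl",             "LDL cholesterol",         "metabolic",        "mmol/l",       2.8,   0.8,   0.02,    0.01,   0.03),
    list("tc",              "Total cholesterol",       "metabolic",        "mmol/l",       4.5,   0.9,   0.03,    0.02,   0.04),
    list("tc_hdl_ratio",    "TC/HDL ratio",            "metabolic",        "ratio",        3.1,   0.9,   0.003,  -0.01,   0.02),
    list("crp",             "C-reactive protein",      "immune",           "mg/l",         1.6,   3.4,  -0.04,   -0.09,   0.01),
    list("supar",           "suPAR",                   "immune",           "ng/ml",        2.09,  0.5,   0.01,    0.003,  0.017),
    list("hemoglobin",      "Hemoglobin",              "blood_count",      "mmol/l",       8.7,   0.8,   0.004,  -0.01,   0.02),
    list("hematocrit",      "Hematocrit",              "blood_count",      "%",           41.6,   3.8,   0.03,   -0.03,   0.09),
    list("dbp",             "Diastolic blood pressure","cardiorespiratory","mmHg",        78.0,  10.1,   0.4,     0.3,    0.5),
    list("sbp",             "Systolic blood pressure", "cardiorespiratory","mmHg",       124.2,  16.7,   0.6,     0.3,    0.8),
    list("fev1",            "FEV1",                    "cardiorespiratory","L",            3.9,   0.9,  -0.02,   -0.04,  -0.01),
    list("fvc",             "FVC",                     "cardiorespiratory","L",            4.9,   1.0,  -0.02,   -0.04,  -0.01),
    list("fev1_fvc_ratio",  "FEV1/FVC ratio",          "cardiorespiratory","%",           77.8,  11.6,  -0.13,   -0.20,  -0.05),
    list("vo2max",          "VO2max",                  "physical_capacity","ml/min/kg",   39.3,   8.11, -0.18,   -0.28,  -0.06),
    list("sts",             "30-s sit-to-stand",       "physical_capacity","stands",      23.4,   5.2,  -0.07,   -0.14,   0.01),
    list("handgrip",        "Handgrip strength",       "physical_capacity","kg",          36.0,   9.4,  -0.8,    -0.2,    0.1),
    list("biceps",          "Biceps strength",         "physical_capacity","kg",          35.0,  11.5,  -0.1,    -0.3,    0.03),
    list("quadriceps",      "Quadriceps strength",     "physical_capacity","Nm",         152.4,  51.3,  -0.7,    -1.4,    0.1)
  )
  reg <- data.frame(
    name       = vapply(rows, `[[`, character(1), 1L),
    label      = vapply(rows, `[[`, character(1), 2L),
    category   = vapply(rows, `[[`, character(1), 3L),
    units      = vapply(rows, `[[`, character(1), 4L),
    mean       = vapply(rows, `[[`, numeric(1), 5L),
    sd         = vapply(rows, `[[`, numeric(1), 6L),
    slope      = vapply(rows, `[[`, numeric(1), 7L),
    slope_low  = vapply(rows, `[[`, numeric(1), 8L),
    slope_high = vapply(rows, `[[`, numeric(1), 9L),
    stringsAsFactors = FALSE
  )
  reg$priority_rank <- seq_len(nrow(reg))
  reg$direction <- ifelse(reg$slope_low > 0, "increases_with_age",
                   ifelse(reg$slope_high < 0, "decreases_with_age", "unknown"))
  class(reg) <- c("ba_registry", "data.frame")
  reg
}

#' Report internally inconsistent registry entries
#'
#' The published summary table contains one entry whose slope point estimate
#' lies outside its own confidence interval (handgrip strength, slope -0.8
#' with CI -0.2 to 0.1). The registry stores such values exactly as
#' published; this function surfaces them so users are aware of the data
#' quality issue instead of the value being silently "corrected".
#'
#' @param registry a biomarker registry, see [biomarker_registry()].
#' @return Data frame with columns `name` and `issue`; zero rows when all
#'   entries are consistent.
#' @export
registry_quality_flags <- function(registry = biomarker_registry()) {
  bad <- registry$slope < registry$slope_low | registry$slope > registry$slope_high
  data.frame(
    name = registry$name[bad],
    issue = rep("slope point estimate outside its own confidence interval", sum(bad)),
    stringsAsFactors = FALSE
  )
}

#' Export / import a biomarker registry as JSON
#'
#' The JSON form is intended for user editing (adding biomarkers or adjusting
#' reference statistics) and round-trips losslessly.
#'
#' @param registry a biomarker registry data frame.
#' @param path file path to write to; when `NULL` the JSON string is returned.
#' @return `registry_to_json()` returns the path (or JSON string) invisibly;
#'   `registry_from_json()` returns a `ba_registry` data frame.
#' @export
registry_to_json <- function(registry, path = NULL) {
  doc <- list(schema = "bioage/registry@1",
              biomarkers = registry[, setdiff(names(registry), character(0))])
  txt <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$schema) || !identical(doc$schema, "bioage/registry@1")) {
    stop_schema("registry document has missing or unsupported schema version")
  }
  reg <- as.data.frame(doc$biomarkers, stringsAsFactors = FALSE)
  validate_registry(reg)
  class(reg) <- c("ba_registry", "data.frame")
  reg
}

validate_registry <- function(reg) {
  needed <- c("name", "mean", "sd", "slope", "slope_low", "slope_high",
              "priority_rank", "direction")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols)) {
    stop_schema("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$name)) stop("duplicate biomarker names in registry")
  if (any(reg$sd <= 0)) stop("registry SDs must be strictly positive")
  if (anyDuplicated(reg$priority_rank)) stop("priority_rank must be unique")
  ci_sign <- ifelse(reg$slope_low > 0, "increases_with_age",
             ifelse(reg$slope_high < 0, "decreases_with_age", "unknown"))
  bad <- ci_sign != "unknown" & reg$direction != "unknown" & reg$direction != ci_sign
  if (any(bad)) {
    stop("expected_direction inconsistent with slope CI for: ",
         paste(reg$name[bad], collapse = ", "))
  }
  invisible(reg)
}

# classed error helpers shared across modules
stop_schema <- function(...) {
  stop(structure(class = c("bioage_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("bioage_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_usage <- function(...) {
  stop(structure(class = c("bioage_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
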