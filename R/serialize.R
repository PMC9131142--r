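#' Serialize / deserialize a biological age model
#'
#' Writes a `ba_model` to a versioned JSON document at full numeric
#' precision (lossless round-trip), or reads one back. Documents carry a
#' `schema` field; a missing or mismatching version is an error, and a
#' truncated document fails to parse rather than producing a partial model.
#'
#' @param model a `ba_model`.
#' @param path file path; for `serialize_model()`, `NULL` returns the JSON
#'   string instead of writing.
#' @return `serialize_model()` returns the path or JSON string invisibly;
#'   `deserialize_model()` returns a `ba_model`.
#' @export
serialize_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "ba_model"))
  doc <- list(
    schema = model$schema,
    sex_label = model$sex_label,
    standardize = model$standardize,
    printed = model$printed,
    w0 = model$w0,
    w = as.list(model$w),
    sigma_ca = model$sigma_ca,
    mean_ca = model$mean_ca,
    b_slope = model$b_slope,
    corrected_coefficients = list(
      intercept = model$corrected_coefficients$intercept,
      coef = as.list(model$corrected_coefficients$coef),
      ca_coef = model$corrected_coefficients$ca_coef),
    pc1 = list(
      biomarkers = model$pc1$biomarkers,
      loadings = as.list(model$pc1$loadings),
      eigenvalue = model$pc1$eigenvalue,
      explained_variance = model$pc1$explained_variance,
      mean = as.list(model$pc1$mean),
      sd = as.list(model$pc1$sd),
      sign_anchor = model$pc1$sign_anchor,
      n = model$pc1$n,
      rows = model$pc1$rows)
  )
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       null = "null", na = "null"))
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @param doc for `deserialize_model()`: a file path or a JSON string.
#' @rdname serialize_model
#' @export
deserialize_model <- function(doc) {
  txt <- if (length(doc) == 1 && file.exists(doc)) {
    paste(readLines(doc, warn = FALSE), collapse = "\n")
  } else {
    doc
  }
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                     error = function(e) {
                       stop_schema("cannot parse model document: ",
                                   conditionMessage(e))
                     })
  if (is.null(parsed$schema) || !identical(parsed$schema, "bioage/ba_model@1")) {
    stop_schema("model document has missing or unsupported schema version: ",
                if (is.null(parsed$schema)) "<none>" else parsed$schema)
  }
  num <- function(x) {
    if (is.null(x)) return(NULL)
    v <- unlist(x)
    stats::setNames(as.numeric(v), names(v))
  }
  pc1 <- structure(list(
    biomarkers = as.character(parsed$pc1$biomarkers),
    loadings = num(parsed$pc1$loadings),
    eigenvalue = parsed$pc1$eigenvalue,
    explained_variance = parsed$pc1$explained_variance,
    mean = num(parsed$pc1$mean),
    sd = num(parsed$pc1$sd),
    sign_anchor = parsed$pc1$sign_anchor,
    n = parsed$pc1$n,
    rows = if (is.null(parsed$pc1$rows)) NULL else as.integer(parsed$pc1$rows)),
    class = "pc1_model")
  structure(list(
    pc1 = pc1,
    w0 = parsed$w0,
    w = num(parsed$w),
    sigma_ca = parsed$sigma_ca,
    mean_ca = parsed$mean_ca,
    b_slope = parsed$b_slope,
    corrected_coefficients = list(
      intercept = parsed$corrected_coefficients$intercept,
      coef = num(parsed$corrected_coefficients$coef),
      ca_coef = parsed$corrected_coefficients$ca_coef),
    sex_label = parsed$sex_label,
    standardize = parsed$standardize,
    printed = parsed$printed,
    schema = parsed$schema), class = "ba_model")
}
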