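#' Fit the first principal component of a biomarker panel
#'
#' Standardizes the chosen columns to zero mean and unit SD (sample SD, n-1
#' denominator) so every biomarker enters with equal weight, then extracts
#' the leading eigenvector of their correlation matrix. Because eigenvectors
#' are sign-ambiguous, the orientation is anchored: the loading of
#' `sign_anchor` is forced non-negative (default anchor: chronological age
#' when `include_ca = TRUE`, otherwise total cholesterol, which rises with
#' age in the reference cohort).
#'
#' @param cohort a `ba_cohort` data frame.
#' @param biomarkers names of the biomarker columns to include.
#' @param include_ca also include chronological age as a column (used to
#'   check that the first component is an aging axis).
#' @param sign_anchor column whose loading is forced `>= 0`.
#' @return An object of class `pc1_model`: ordered `biomarkers`, unit-norm
#'   `loadings`, `eigenvalue`, `explained_variance` (eigenvalue / number of
#'   columns), training `mean` and `sd` per column, `sign_anchor`, `n`, and
#'   the complete-case row indices used (`rows`).
#' @export
fit_pc1 <- function(cohort, biomarkers, include_ca = FALSE, sign_anchor = NULL) {
  missing_cols <- setdiff(biomarkers, names(cohort))
  if (length(missing_cols)) {
    stop("biomarkers not present in cohort: ", paste(missing_cols, collapse = ", "))
  }
  cols <- if (include_ca) c("age", biomarkers) else biomarkers
  X <- as.matrix(cohort[, cols, drop = FALSE])
  rows <- which(stats::complete.cases(X))
  if (length(rows) < length(cols) + 2) {
    na_counts <- colSums(is.na(X))
    stop("too few complete records (", length(rows), ") for ", length(cols),
         " columns; missing per column: ",
         paste(sprintf("%s=%d", cols, na_counts), collapse = ", "))
  }
  X <- X[rows, , drop = FALSE]
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    stop("zero-variance column(s): ", paste(cols[sdev == 0], collapse = ", "))
  }
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] <= 0) stop("degenerate input: no positive leading eigenvalue")
  a <- e$vectors[, 1]
  names(a) <- cols
  if (is.null(sign_anchor)) {
    sign_anchor <- if (include_ca) "age" else if ("tc" %in% cols) "tc" else cols[1]
  }
  if (!sign_anchor %in% cols) stop("sign_anchor '", sign_anchor, "' not among fitted columns")
  if (a[sign_anchor] < 0) a <- -a
  structure(list(biomarkers = cols, loadings = a, eigenvalue = e$values[1],
                 explained_variance = e$values[1] / length(cols),
                 mean = mu, sd = sdev, sign_anchor = sign_anchor,
                 n = length(rows), rows = rows),
            class = "pc1_model")
}

#' @export
print.pc1_model <- function(x, ...) {
  cat(sprintf("<first principal component: %d columns, n = %d, eigenvalue %.4f (%.1f%% of variance)>\n",
              length(x$biomarkers), x$n, x$eigenvalue, 100 * x$explained_variance))
  print(round(x$loadings, 4))
  invisible(x)
}

#' Percentage contribution of each biomarker to the first component
#'
#' Contribution of biomarker n is `100 * a_n^2 / sum(a_k^2)`, where `a` are
#' the first-component loadings. Contributions sum to 100 and are invariant
#' under a global sign flip of the loadings.
#'
#' @param x a `pc1_model` or a (named) numeric vector of loadings.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' pc1_contributions(c(a = 1, b = 1))  # 50, 50
pc1_contributions <- function(x) {
  a <- if (inherits(x, "pc1_model")) x$loadings else x
  if (!is.numeric(a) || !length(a)) stop("loadings must be a non-empty numeric vector")
  100 * a^2 / sum(a^2)
}

#' Score coefficients from a first-component fit
#'
#' Converts the unit-norm loadings into coefficients on the raw biomarker
#' scale: `w_n = a_n / sd_n` and `w0 = -sum(w_n * mean_n)`, so that the
#' standardized biological age score `BAS = w0 + sum(w_n x_n)` has mean 0
#' over the training sample (and SD equal to the square root of the
#' eigenvalue).
#'
#' @param pc1 a `pc1_model` fitted without chronological age among the
#'   columns.
#' @return List with `w0` (scalar) and `w` (named vector).
#' @export
fit_bas <- function(pc1) {
  stopifnot(inherits(pc1, "pc1_model"))
  if ("age" %in% pc1$biomarkers) {
    stop("score coefficients require a component fitted without chronological age")
  }
  w <- pc1$loadings / pc1$sd
  list(w0 = -sum(w * pc1$mean), w = w)
}

#' T-scale conversion of a score to years
#'
#' Maps a biological age score onto the year scale of the training cohort:
#' the score is first standardized to unit variance by dividing by the
#' square root of the first-component eigenvalue, then scaled by the cohort
#' SD of chronological age and shifted to its mean:
#' `BA = (bas / sqrt(lambda)) * sigma_ca + mean_ca`. The resulting BA has
#' the same mean and SD as chronological age over the training sample.
#' `standardize = FALSE` gives the literal unscaled variant
#' `BA = bas * sigma_ca + mean_ca` for comparison; the published model
#' coefficients are only consistent with the standardized form (see the
#' methods vignette).
#'
#' @param bas score value(s).
#' @param sigma_ca SD of chronological age (years).
#' @param mean_ca mean chronological age (years).
#' @param lambda first-component eigenvalue (> 0).
#' @param standardize divide by `sqrt(lambda)` first (default `TRUE`).
#' @return Biological age in years.
#' @export
tscale <- function(bas, sigma_ca, mean_ca, lambda, standardize = TRUE) {
  if (lambda <= 0) stop("lambda must be positive")
  z <- if (standardize) bas / sqrt(lambda) else bas
  z * sigma_ca + mean_ca
}

#' Regression-to-the-mean correction slope
#'
#' Ordinary-least-squares slope of biological age on chronological age. When
#' BA is constructed so its training SD equals the SD of chronological age,
#' this slope equals the Pearson correlation between BA and CA.
#'
#' @param ba biological ages (years).
#' @param ca chronological ages (years).
#' @return The slope `b`.
#' @export
fit_correction <- function(ba, ca) {
  if (length(ba) != length(ca)) stop("ba and ca must have equal length")
  if (length(ca) < 3) stop("need at least 3 records")
  if (stats::sd(ca) == 0) stop("chronological age has zero variance")
  unname(stats::coef(stats::lm(ba ~ ca))[2])
}

#' Fit the complete biological age model
#'
#' End-to-end training on a cohort: first principal component of the
#' standardized biomarkers, score coefficients, T-scale constants (mean and
#' SD of chronological age over the complete-case training rows), the
#' regression-to-the-mean slope `b`, and the expanded corrected-equation
#' coefficients on the raw biomarker scale
#' (`coef_n = w_n * sigma_ca / sqrt(lambda)`, chronological-age coefficient
#' `1 - b`, intercept `w0 * sigma_ca / sqrt(lambda) + b * mean_ca`).
#'
#' @param cohort a `ba_cohort` data frame.
#' @param biomarkers biomarker columns forming the model panel.
#' @param sex optional `"female"` or `"male"`: fit on that stratum only.
#'   Sex-stratified fitting is the intended use; pooled fitting (the
#'   default `NULL`) warns.
#' @param sign_anchor passed to [fit_pc1()].
#' @param standardize passed to [tscale()].
#' @return An object of class `ba_model`.
#' @export
fit_ba_model <- function(cohort, biomarkers, sex = NULL, sign_anchor = NULL,
                         standardize = TRUE) {
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    cohort <- cohort[cohort$sex == sex, , drop = FALSE]
    sex_label <- sex
  } else {
    warning("fitting pooled across sexes; sex-stratified fitting is recommended")
    sex_label <- "pooled"
  }
  pc1 <- fit_pc1(cohort, biomarkers, include_ca = FALSE, sign_anchor = sign_anchor)
  sc <- fit_bas(pc1)
  ca <- cohort$age[pc1$rows]
  mean_ca <- mean(ca)
  sigma_ca <- stats::sd(ca)
  X <- as.matrix(cohort[pc1$rows, biomarkers, drop = FALSE])
  bas <- drop(sc$w0 + X %*% sc$w)
  ba <- tscale(bas, sigma_ca, mean_ca, pc1$eigenvalue, standardize = standardize)
  b <- fit_correction(ba, ca)
  new_ba_model(pc1 = pc1, w0 = sc$w0, w = sc$w, sigma_ca = sigma_ca,
               mean_ca = mean_ca, b_slope = b, sex_label = sex_label,
               standardize = standardize)
}

new_ba_model <- function(pc1, w0, w, sigma_ca, mean_ca, b_slope, sex_label,
                         standardize = TRUE, printed = NULL) {
  scale_f <- if (standardize) sigma_ca / sqrt(pc1$eigenvalue) else sigma_ca
  corrected <- list(
    intercept = w0 * scale_f + b_slope * mean_ca,
    coef = w * scale_f,
    ca_coef = 1 - b_slope
  )
  structure(list(pc1 = pc1, w0 = w0, w = w, sigma_ca = sigma_ca,
                 mean_ca = mean_ca, b_slope = b_slope,
                 corrected_coefficients = corrected,
                 sex_label = sex_label, standardize = standardize,
                 printed = printed, schema = "bioage/ba_model@1"),
            class = "ba_model")
}

#' @export
print.ba_model <- function(x, ...) {
  cat(sprintf("<biological age model (%s): %d biomarkers, eigenvalue %.3f, b = %.3f, CA scale %.1f +/- %.1f y>\n",
              x$sex_label, length(x$w), x$pc1$eigenvalue, x$b_slope,
              x$mean_ca, x$sigma_ca))
  invisible(x)
}

#' Predict corrected biological age
#'
#' Evaluates a fitted or published biological age model on new records:
#' the standardized score `BAS = w0 + sum(w_n x_n)`, the T-scaled
#' `BA` in years, and the corrected
#' `BAc = BA + (CA - mean_ca) * (1 - b)`, which removes the
#' regression-toward-the-mean bias (overestimation of the young,
#' underestimation of the old). Also returns `age_diff = CA - BAc`;
#' positive values indicate a biologically younger profile.
#'
#' @param model a `ba_model`.
#' @param newdata a `ba_cohort` (or data frame with `age` and the model's
#'   biomarker columns). Missing biomarker values are an error naming the
#'   offending biomarkers.
#' @param parameterization `"score"` (default) evaluates the full-precision
#'   score pathway; `"corrected"` evaluates the expanded corrected-equation
#'   coefficients directly (identical for fitted models, but reproduces the
#'   published rounded equations when used on a published model).
#' @return Data frame with columns `id` (if present), `sex` (if present),
#'   `ca`, `bas`, `ba`, `bac`, `age_diff`.
#' @export
predict_bac <- function(model, newdata,
                        parameterization = c("score", "corrected")) {
  stopifnot(inherits(model, "ba_model"))
  parameterization <- match.arg(parameterization)
  bm <- names(model$w)
  missing_cols <- setdiff(c(bm, "age"), names(newdata))
  if (length(missing_cols)) {
    stop("newdata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(newdata[, bm, drop = FALSE])
  if (anyNA(X)) {
    bad <- bm[colSums(is.na(X)) > 0]
    stop("missing biomarker value(s) for: ", paste(bad, collapse = ", "))
  }
  ca <- newdata$age
  bas <- drop(model$w0 + X %*% model$w)
  ba <- tscale(bas, model$sigma_ca, model$mean_ca, model$pc1$eigenvalue,
               standardize = model$standardize)
  if (parameterization == "score") {
    bac <- ba + (ca - model$mean_ca) * (1 - model$b_slope)
  } else {
    cc <- model$corrected_coefficients
    bac <- drop(cc$intercept + X %*% cc$coef + cc$ca_coef * ca)
  }
  out <- data.frame(ca = ca, bas = bas, ba = ba, bac = bac,
                    age_diff = ca - bac, stringsAsFactors = FALSE)
  if ("sex" %in% names(newdata)) out <- cbind(sex = newdata$sex, out)
  if ("id" %in% names(newdata)) out <- cbind(id = newdata$id, out)
  rownames(out) <- NULL
  out
}

#' Correlation between corrected biological age and chronological age
#' implied by the model construction
#'
#' When BA is scaled to the chronological-age SD and corrected with slope
#' `b`, the training-sample correlation between corrected BA and CA is
#' exactly `1 / sqrt(2 - b^2)`: the correction adds `(1-b)(CA - mean)` to a
#' score whose covariance with CA is `b sigma^2`, giving covariance
#' `sigma^2` and variance `sigma^2 (2 - b^2)`.
#'
#' @param b_slope regression slope of BA on CA, with `|b| <= 1`.
#' @return The implied correlation.
#' @export
#' @examples
#' implied_corr_bac_ca(0.80)  # 0.857..., the female headline correlation
implied_corr_bac_ca <- function(b_slope) {
  if (any(abs(b_slope) > 1)) stop("|b_slope| must not exceed 1")
  1 / sqrt(2 - b_slope^2)
}
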