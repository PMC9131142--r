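#' Default age-bin design
#'
#' Ten equal-width bins covering 18-65 years (width 4.7 y). Balancing equal
#' numbers of each sex in each bin and drawing ages uniformly within bins
#' yields a design with mean age 41.5 y and SD 13.6 y, matching the scale
#' constants of the reference cohort (mean 41.3/41.1, SD 13.6/13.8 for
#' women/men).
#'
#' @param low,high overall age range in years.
#' @param n_bins number of equal-width bins.
#' @return A two-column matrix of bin bounds `(low, high)`.
#' @export
default_age_bins <- function(low = 18, high = 65, n_bins = 10) {
  edges <- seq(low, high, length.out = n_bins + 1)
  cbind(low = edges[-length(edges)], high = edges[-1])
}

#' Default male-female biomarker offsets
#'
#' Additive male-minus-female mean differences for the final model panel
#' (waist, FEV1, VO2max, HDL, adiponectin, and the two blood pressures that
#' feed mean arterial pressure). Magnitudes are package defaults chosen to be
#' physiologically plausible sex differences; the reference summary table is
#' pooled across sexes, so no published sex-specific marginals exist. Offsets
#' are applied symmetrically (+offset/2 for males, -offset/2 for females) so
#' pooled marginal means still match the registry means.
#'
#' @return Named numeric vector of male-minus-female differences in registry
#'   units.
#' @export
default_sex_offsets <- function() {
  c(waist = 8, fev1 = 0.8, vo2max = 6, hdl = -0.25,
    adiponectin = -3500, sbp = 4, dbp = 2)
}

#' Default residual correlation matrix
#'
#' Identity except for the systolic-diastolic blood pressure pair, set to
#' 0.81 (the published SBP-DBP intercorrelation, r = 0.8135, rounded). All
#' other residual correlations default to zero: correlations between
#' biomarkers then arise solely through their shared linear age trends.
#'
#' @param registry biomarker registry defining the variable set and order.
#' @return Symmetric correlation matrix with dimnames `registry$name`.
#' @export
default_residual_correlation <- function(registry = biomarker_registry()) {
  p <- nrow(registry)
  R <- diag(p)
  dimnames(R) <- list(registry$name, registry$name)
  if (all(c("sbp", "dbp") %in% registry$name)) {
    R["sbp", "dbp"] <- R["dbp", "sbp"] <- 0.81
  }
  R
}

#' Simulation configuration
#'
#' Bundles and validates everything [simulate_cohort()] needs: the per-cell
#' sample size (per sex per age bin), the age-bin design, the biomarker
#' registry providing means/SDs/age slopes, the residual correlation matrix,
#' male-female offsets, and the random seed.
#'
#' @param n_per_sex_per_bin individuals of each sex drawn in each age bin
#'   (default 5, giving 100 individuals under the default 10-bin design).
#' @param age_bins two-column matrix of `(low, high)` year intervals,
#'   non-overlapping and ascending.
#' @param registry biomarker registry (see [biomarker_registry()]).
#' @param residual_correlation positive semi-definite correlation matrix over
#'   the registry biomarkers (unit diagonal, entries in \[-1, 1\]).
#' @param sex_offsets named vector of male-minus-female mean differences.
#' @param reference_age age (years) at which biomarker means equal the
#'   registry means; defaults to 41.2, the pooled mean age of the reference
#'   cohort.
#' @param seed integer seed making the simulation deterministic.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_sex_per_bin = 5,
                       age_bins = default_age_bins(),
                       registry = biomarker_registry(),
                       residual_correlation = NULL,
                       sex_offsets = default_sex_offsets(),
                       reference_age = 41.2,
                       seed = 1L) {
  validate_registry(registry)
  if (is.null(residual_correlation)) {
    residual_correlation <- default_residual_correlation(registry)
  }
  R <- residual_correlation
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("residual_correlation must be square")
  if (is.null(dimnames(R))) dimnames(R) <- list(registry$name, registry$name)
  if (!identical(rownames(R), registry$name)) {
    stop("residual_correlation dimnames must match registry biomarker names")
  }
  if (max(abs(R - t(R))) > 1e-12) stop("residual_correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("residual_correlation diagonal must be exactly 1")
  if (any(R < -1 - 1e-12 | R > 1 + 1e-12)) stop("residual_correlation entries must lie in [-1, 1]")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("residual_correlation must be positive semi-definite")
  }
  bins <- as.matrix(age_bins)
  if (ncol(bins) != 2 || any(bins[, 1] >= bins[, 2])) {
    stop("age_bins must be a two-column matrix of (low, high) with low < high")
  }
  if (nrow(bins) > 1 && any(bins[-1, 1] < bins[-nrow(bins), 2])) {
    stop("age_bins must be ascending and non-overlapping")
  }
  if (n_per_sex_per_bin < 1) stop("n_per_sex_per_bin must be >= 1")
  off <- sex_offsets
  if (length(off) && (is.null(names(off)) || !all(names(off) %in% registry$name))) {
    stop("sex_offsets names must be registry biomarker names")
  }
  structure(list(n_per_sex_per_bin = as.integer(n_per_sex_per_bin),
                 age_bins = bins, registry = registry,
                 residual_correlation = R, sex_offsets = off,
                 reference_age = reference_age, seed = as.integer(seed)),
            class = "sim_config")
}

# variance of the age distribution implied by the design:
# equal weight per bin, uniform within each bin
design_age_moments <- function(bins) {
  mids <- (bins[, 1] + bins[, 2]) / 2
  widths <- bins[, 2] - bins[, 1]
  m <- mean(mids)
  v <- mean(mids^2 + widths^2 / 12) - m^2
  c(mean = m, var = v)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort with the statistical structure assumed by the biological
#' age model: counts balanced by sex within age bins, ages uniform within
#' bins, and each biomarker generated as
#' `mean + sex_shift + slope * (age - reference_age) + residual`, with the
#' residual vector multivariate normal under the configured correlation. The
#' per-biomarker residual SD is chosen so that the marginal SD over the age
#' design equals the registry SD (residual variance = sd^2 - slope^2 *
#' var(age), floored at 10% of sd^2 with a warning when the floor binds).
#' Physiologically impossible non-positive values are resampled rather than
#' clipped (at most 100 redraws per record).
#'
#' @param config a [sim_config()] object.
#' @return A validated `ba_cohort` data frame; deterministic given
#'   `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reg <- config$registry
  bins <- config$age_bins
  npb <- config$n_per_sex_per_bin
  set.seed(config$seed)

  ages <- c(); sexes <- c()
  for (b in seq_len(nrow(bins))) {
    for (sx in c("female", "male")) {
      ages <- c(ages, stats::runif(npb, bins[b, 1], bins[b, 2]))
      sexes <- c(sexes, rep(sx, npb))
    }
  }
  n <- length(ages)
  p <- nrow(reg)

  v_age <- design_age_moments(bins)[["var"]]
  resid_var <- reg$sd^2 - reg$slope^2 * v_age
  floor_var <- 0.1 * reg$sd^2
  floored <- resid_var < floor_var
  if (any(floored)) {
    warning("residual variance floored at 10% of the marginal variance for: ",
            paste(reg$name[floored], collapse = ", "),
            " (age slope explains more variance than the registry SD allows)")
  }
  resid_sd <- sqrt(pmax(resid_var, floor_var))

  off <- rep(0, p); names(off) <- reg$name
  if (length(config$sex_offsets)) {
    off[names(config$sex_offsets)] <- config$sex_offsets
  }
  sex_sign <- ifelse(sexes == "male", 0.5, -0.5)

  mu <- matrix(reg$mean, n, p, byrow = TRUE) +
    outer(sex_sign, off) +
    outer(ages - config$reference_age, reg$slope)

  Sigma <- diag(resid_sd) %*% config$residual_correlation %*% diag(resid_sd)
  eps <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  vals <- mu + eps

  # resample whole residual vectors for records with impossible (<= 0) values
  for (attempt in seq_len(100)) {
    bad <- which(apply(vals <= 0, 1, any))
    if (!length(bad)) break
    eps_new <- MASS::mvrnorm(length(bad), mu = rep(0, p), Sigma = Sigma)
    if (length(bad) == 1) eps_new <- matrix(eps_new, nrow = 1)
    vals[bad, ] <- mu[bad, , drop = FALSE] + eps_new
  }
  if (length(which(apply(vals <= 0, 1, any)))) {
    stop("failed to draw physiologically positive biomarker vectors after 100 resamples")
  }

  df <- data.frame(id = sprintf("S%04d", seq_len(n)), sex = sexes, age = ages,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(vals)
  names(vals) <- reg$name
  as_cohort(cbind(df, vals), registry = reg)
}

#' Summarize a cohort in registry format
#'
#' Per-biomarker mean, SD, and ordinary-least-squares age slope with 95%
#' confidence interval, mirroring the layout of the registry so simulated
#' cohorts can be compared directly with their generating parameters.
#'
#' @param cohort a `ba_cohort` data frame.
#' @param biomarkers biomarker columns to summarize; defaults to every
#'   non-mandatory column.
#' @return Data frame with columns `name`, `n`, `mean`, `sd`, `slope`,
#'   `slope_low`, `slope_high`. Biomarkers with fewer than 3 non-missing
#'   values are excluded with a warning.
#' @export
summarize_cohort <- function(cohort, biomarkers = NULL) {
  if (is.null(biomarkers)) {
    biomarkers <- setdiff(names(cohort), c("id", "sex", "age"))
  }
  out <- lapply(biomarkers, function(bm) {
    v <- cohort[[bm]]
    ok <- !is.na(v) & !is.na(cohort$age)
    if (sum(ok) < 3) return(NULL)
    fit <- stats::lm(v[ok] ~ cohort$age[ok])
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))[2, ]
    ci[is.na(ci)] <- stats::coef(fit)[2]  # exact fit: zero-width interval
    data.frame(name = bm, n = sum(ok), mean = mean(v[ok]), sd = stats::sd(v[ok]),
               slope = unname(stats::coef(fit)[2]),
               slope_low = unname(ci[1]), slope_high = unname(ci[2]),
               stringsAsFactors = FALSE)
  })
  dropped <- biomarkers[vapply(out, is.null, logical(1))]
  if (length(dropped)) {
    warning("excluded from summary (fewer than 3 non-missing values): ",
            paste(dropped, collapse = ", "))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
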