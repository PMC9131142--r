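#' Mean arterial pressure
#'
#' MAP = SBP/3 + 2 DBP/3. Used to collapse the highly intercorrelated
#' systolic and diastolic pressures into a single circulatory biomarker.
#'
#' @param sbp systolic blood pressure (mmHg), must be >= `dbp`.
#' @param dbp diastolic blood pressure (mmHg), must be > 0.
#' @return Mean arterial pressure in mmHg (vectorized).
#' @export
#' @examples
#' derive_map(124.2, 78.0)  # 93.4
derive_map <- function(sbp, dbp) {
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(dbp[ok] <= 0)) stop("diastolic pressure must be positive")
  if (any(dbp[ok] > sbp[ok])) stop("diastolic pressure cannot exceed systolic pressure")
  sbp / 3 + 2 * dbp / 3
}

#' Flag values outside a 99% reference interval
#'
#' For each biomarker, computes the reference interval mean +/- 2.96 SD from
#' the cohort itself and flags values strictly outside it. Flags are
#' advisory: age-related extremes within the healthy aging spectrum may be
#' legitimate, so records are never removed automatically — each flagged
#' value is meant to be assessed individually.
#'
#' @param cohort a `ba_cohort` data frame.
#' @param biomarkers biomarker columns to screen; defaults to all.
#' @param k half-width of the interval in SD units (default 2.96).
#' @return Long data frame (`id`, `biomarker`, `value`, `low`, `high`,
#'   `flagged`) of class `ba_outlier_report`. Biomarkers with zero SD
#'   produce no flags.
#' @export
reference_interval_flags <- function(cohort, biomarkers = NULL, k = 2.96) {
  if (is.null(biomarkers)) {
    biomarkers <- setdiff(names(cohort), c("id", "sex", "age"))
  }
  out <- lapply(biomarkers, function(bm) {
    v <- cohort[[bm]]
    ok <- !is.na(v)
    if (sum(ok) < 2) stop("need at least 2 non-missing values for '", bm, "'")
    m <- mean(v[ok]); s <- stats::sd(v[ok])
    low <- m - k * s; high <- m + k * s
    flagged <- if (s == 0) rep(FALSE, sum(ok)) else (v[ok] < low | v[ok] > high)
    data.frame(id = cohort$id[ok], biomarker = bm, value = v[ok],
               low = low, high = high, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ba_outlier_report", "data.frame")
  res
}

#' Age-correlation gate
#'
#' Pearson correlation of each candidate biomarker with chronological age on
#' complete pairs. A candidate passes the gate when `|r| > r_min` (strict)
#' and the two-sided p value from the t transform with n-2 degrees of
#' freedom satisfies `p <= alpha` (inclusive).
#'
#' @param cohort a `ba_cohort` data frame.
#' @param candidates candidate biomarker names; defaults to all biomarker
#'   columns.
#' @param r_min minimum absolute correlation (strict), default 0.15.
#' @param alpha significance level (inclusive), default 0.05.
#' @return Data frame (`biomarker`, `n`, `r`, `p`, `passed_gate`,
#'   `exclusion_reason`) of class `ba_screen`. Constant biomarkers have
#'   undefined r, fail the gate, and raise a warning.
#' @export
correlation_screen <- function(cohort, candidates = NULL,
                               r_min = 0.15, alpha = 0.05) {
  if (is.null(candidates)) {
    candidates <- setdiff(names(cohort), c("id", "sex", "age"))
  }
  missing_cols <- setdiff(candidates, names(cohort))
  if (length(missing_cols)) {
    stop("candidates not present in cohort: ", paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(candidates, function(bm) {
    v <- cohort[[bm]]
    ok <- !is.na(v) & !is.na(cohort$age)
    if (sum(ok) < 4) stop("need at least 4 complete (age, value) pairs for '", bm, "'")
    if (stats::sd(v[ok]) == 0) {
      warning("biomarker '", bm, "' is constant; correlation undefined, gate failed")
      return(data.frame(biomarker = bm, n = sum(ok), r = NA_real_, p = NA_real_,
                        passed_gate = FALSE, exclusion_reason = "weak_age_correlation",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v[ok], cohort$age[ok], method = "pearson",
                          alternative = "two.sided")
    passed <- abs(ct$estimate) > r_min && ct$p.value <= alpha
    data.frame(biomarker = bm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, passed_gate = passed,
               exclusion_reason = if (passed) "none" else "weak_age_correlation",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("ba_screen", "data.frame")
  res
}

#' Redundancy pruning of gated biomarkers
#'
#' Builds a graph on the gated biomarkers with edges wherever the absolute
#' pairwise Pearson correlation is at least `r_cluster` (inclusive); each
#' connected component is a redundancy cluster. Within each cluster one
#' representative is selected: the earliest cluster member appearing in the
#' `priority` list (clinical priority), otherwise the member with the
#' largest absolute correlation with age. `manual_overrides` force a
#' biomarker in (`TRUE`) or out (`FALSE`) regardless of the rule.
#'
#' @param cohort a `ba_cohort` data frame.
#' @param gated character vector of gated biomarker names.
#' @param r_cluster clustering threshold on `|r|` (inclusive), default 0.7.
#' @param priority ordered character vector of clinically prioritized names;
#'   earlier entries win.
#' @param manual_overrides named logical vector; every name must be in
#'   `gated`.
#' @return Data frame (`biomarker`, `r_age`, `cluster_id`, `selected`,
#'   `exclusion_reason`) of class `ba_prune`. Idempotent: pruning its own
#'   selection changes nothing.
#' @export
redundancy_prune <- function(cohort, gated, r_cluster = 0.7,
                             priority = character(0),
                             manual_overrides = NULL) {
  missing_cols <- setdiff(gated, names(cohort))
  if (length(missing_cols)) {
    stop("gated biomarkers not present in cohort: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(manual_overrides)) {
    bad <- setdiff(names(manual_overrides), gated)
    if (length(bad)) {
      stop("manual override names an un-gated biomarker: ",
           paste(bad, collapse = ", "))
    }
  }
  X <- as.matrix(cohort[, gated, drop = FALSE])
  r_age <- vapply(gated, function(bm) {
    ok <- !is.na(cohort[[bm]]) & !is.na(cohort$age)
    stats::cor(cohort[[bm]][ok], cohort$age[ok])
  }, numeric(1))

  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  adj <- !is.na(C) & abs(C) >= r_cluster
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  selected <- logical(length(gated)); names(selected) <- gated
  reason <- rep("redundant", length(gated)); names(reason) <- gated
  for (cid in unique(comp)) {
    members <- gated[comp == cid]
    in_priority <- members[members %in% priority]
    rep_bm <- if (length(in_priority)) {
      in_priority[which.min(match(in_priority, priority))]
    } else {
      members[which.max(abs(r_age[members]))]
    }
    selected[rep_bm] <- TRUE
    reason[rep_bm] <- "none"
  }
  if (!is.null(manual_overrides)) {
    for (bm in names(manual_overrides)) {
      selected[bm] <- isTRUE(manual_overrides[[bm]])
      reason[bm] <- "manual"
    }
  }
  res <- data.frame(biomarker = gated, r_age = unname(r_age),
                    cluster_id = unname(comp[gated]),
                    selected = unname(selected),
                    exclusion_reason = ifelse(unname(selected), "none",
                                              unname(reason)),
                    stringsAsFactors = FALSE)
  class(res) <- c("ba_prune", "data.frame")
  res
}

#' Full systematic biomarker screening pipeline
#'
#' Chains the screening stages: optional eligibility filter (a logical
#' `eligible` column, modelling disease-history exclusions), the
#' age-correlation gate, the optional replacement of systolic/diastolic
#' pressure by mean arterial pressure when both pass the gate and cluster
#' together, and redundancy pruning.
#'
#' @param cohort a `ba_cohort` data frame.
#' @param candidates candidate names; defaults to all registry biomarkers
#'   present in the cohort except the AGE-reader variable (`ages`), which is
#'   excluded up front for measurement-reliability reasons.
#' @param r_min,alpha gate parameters, see [correlation_screen()].
#' @param r_cluster pruning threshold, see [redundancy_prune()].
#' @param priority clinical-priority list; defaults to waist circumference
#'   (preferred over waist/hip ratio for its clinical utility).
#' @param manual_overrides named logical vector of forced decisions.
#' @param replace_bp_with_map synthesize MAP and retire SBP/DBP when both
#'   pass the gate and are mutually clustered (default `TRUE`).
#' @return List of class `ba_screening` with elements `screen`
#'   (gate results, including MAP when synthesized), `prune` (pruning
#'   results), `selected` (character vector of selected biomarkers), and
#'   `cohort` (the cohort, augmented with `map` if synthesized).
#' @export
screen_biomarkers <- function(cohort, candidates = NULL,
                              r_min = 0.15, alpha = 0.05, r_cluster = 0.7,
                              priority = c("waist"),
                              manual_overrides = NULL,
                              replace_bp_with_map = TRUE) {
  if ("eligible" %in% names(cohort)) {
    cohort <- cohort[as.logical(cohort$eligible) %in% TRUE, , drop = FALSE]
  }
  if (is.null(candidates)) {
    candidates <- setdiff(intersect(biomarker_registry()$name, names(cohort)),
                          "ages")
  }
  screen <- correlation_screen(cohort, candidates, r_min = r_min, alpha = alpha)
  gated <- screen$biomarker[screen$passed_gate]

  if (replace_bp_with_map && all(c("sbp", "dbp") %in% gated)) {
    ok <- !is.na(cohort$sbp) & !is.na(cohort$dbp)
    r_bp <- stats::cor(cohort$sbp[ok], cohort$dbp[ok])
    if (abs(r_bp) >= r_cluster) {
      cohort <- add_map(cohort)
      map_screen <- correlation_screen(cohort, "map", r_min = r_min, alpha = alpha)
      screen <- rbind(screen, map_screen)
      class(screen) <- c("ba_screen", "data.frame")
      if (map_screen$passed_gate) {
        gated <- c(setdiff(gated, c("sbp", "dbp")), "map")
        screen$exclusion_reason[screen$biomarker %in% c("sbp", "dbp")] <- "redundant"
        screen$passed_gate[screen$biomarker %in% c("sbp", "dbp")] <- FALSE
      }
    }
  }

  prune <- redundancy_prune(cohort, gated, r_cluster = r_cluster,
                            priority = priority,
                            manual_overrides = manual_overrides)
  structure(list(screen = screen, prune = prune,
                 selected = prune$biomarker[prune$selected],
                 cohort = cohort),
            class = "ba_screening")
}

#' @export
print.ba_screening <- function(x, ...) {
  cat(sprintf("<biomarker screening: %d candidates, %d passed gate, %d selected>\n",
              nrow(x$screen), sum(x$screen$passed_gate), length(x$selected)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
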