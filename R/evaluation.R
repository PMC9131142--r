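#' Regression of corrected biological age on chronological age
#'
#' Ordinary least squares of BAc on CA with the standard error of the
#' estimate, `SEE = sqrt(sum(residuals^2) / (n - 2))`, the usual summary of
#' scatter around the aging trajectory.
#'
#' @param bac corrected biological ages (years).
#' @param ca chronological ages (years).
#' @return List with `n`, `slope`, `intercept`, `r`, `r_squared`, `see`.
#' @export
regress_bac_on_ca <- function(bac, ca) {
  if (length(bac) != length(ca)) stop("bac and ca must have equal length")
  if (length(ca) < 3) stop("need at least 3 records")
  if (stats::sd(ca) == 0) stop("chronological age has zero variance")
  fit <- stats::lm(bac ~ ca)
  res <- stats::residuals(fit)
  r <- stats::cor(bac, ca)
  list(n = length(ca),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2,
       see = sqrt(sum(res^2) / (length(ca) - 2)))
}

#' Bland-Altman agreement between chronological and biological age
#'
#' Differences are taken as `d = ca - bac` (positive = biologically
#' younger). Bias is the mean difference; limits of agreement are
#' `bias +/- 1.96 sd(d)` by the universal convention.
#'
#' @param ca chronological ages (years).
#' @param bac corrected biological ages (years).
#' @param loa_mult limits-of-agreement multiplier (default 1.96).
#' @return List with `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(ca, bac, loa_mult = 1.96) {
  if (length(ca) != length(bac)) stop("ca and bac must have equal length")
  if (length(ca) < 2) stop("need at least 2 records")
  d <- ca - bac
  bias <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), bias = bias, sd_diff = s,
       loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s)
}

#' Paired t test of chronological versus biological age
#'
#' Standard two-sided paired t test on `ca - bac`. When the differences have
#' zero variance the test statistic is undefined; the result is reported as
#' degenerate with `p = 1` when the common difference is 0 and `p = 0`
#' otherwise (the limiting behaviour).
#'
#' @param ca chronological ages (years).
#' @param bac corrected biological ages (years).
#' @return List with `n`, `t`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(ca, bac) {
  if (length(ca) != length(bac)) stop("ca and bac must have equal length")
  if (length(ca) < 2) stop("need at least 2 records")
  d <- ca - bac
  if (stats::sd(d) == 0) {
    return(list(n = length(d), t = NA_real_,
                p = if (isTRUE(all.equal(mean(d), 0))) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(ca, bac, paired = TRUE, alternative = "two.sided")
  list(n = length(d), t = unname(tt$statistic), p = tt$p.value,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Full agreement report
#'
#' Combines the BAc~CA regression, Bland-Altman analysis, and the paired t
#' test into a single report, the standard battery for judging whether a
#' biological age model tracks chronological age without bias in a healthy
#' reference sample.
#'
#' @param ca chronological ages (years).
#' @param bac corrected biological ages (years).
#' @return List of class `agreement_report` with fields `n`, `slope`,
#'   `intercept`, `r`, `r_squared`, `see`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `paired_t_stat`, `paired_t_p`, `degenerate_t`.
#' @export
agreement_report <- function(ca, bac) {
  reg <- regress_bac_on_ca(bac, ca)
  balt <- bland_altman(ca, bac)
  tt <- paired_t(ca, bac)
  structure(list(n = reg$n, slope = reg$slope, intercept = reg$intercept,
                 r = reg$r, r_squared = reg$r_squared, see = reg$see,
                 bias = balt$bias, sd_diff = balt$sd_diff,
                 loa_low = balt$loa_low, loa_high = balt$loa_high,
                 paired_t_stat = tt$t, paired_t_p = tt$p,
                 degenerate_t = tt$degenerate),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement report, n = %d>\n",
    "  BAc ~ CA: slope %.3f, intercept %.2f y, r %.3f, R^2 %.3f, SEE %.2f y\n",
    "  Bland-Altman: bias %.3f y, limits of agreement [%.2f, %.2f] y\n",
    "  paired t: p %s\n"),
    x$n, x$slope, x$intercept, x$r, x$r_squared, x$see,
    x$bias, x$loa_low, x$loa_high,
    if (x$degenerate_t) paste0(format(x$paired_t_p), " (degenerate)")
    else format(signif(x$paired_t_p, 3))))
  invisible(x)
}

#' Evaluation plots
#'
#' Writes the two standard agreement figures for a prediction table:
#' the BAc~CA regression with the identity line, and the Bland-Altman plot
#' with bias and limits of agreement.
#'
#' @param predictions data frame with `ca` and `bac` columns (see
#'   [predict_bac()]).
#' @param dir output directory; created if needed.
#' @param prefix file-name prefix.
#' @return Character vector of the two PDF paths, invisibly.
#' @export
plot_agreement <- function(predictions, dir, prefix = "agreement") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ca <- predictions$ca; bac <- predictions$bac
  rep <- agreement_report(ca, bac)

  f1 <- file.path(dir, paste0(prefix, "_regression.pdf"))
  grDevices::pdf(f1, width = 6, height = 6)
  plot(ca, bac, xlab = "Chronological age (y)",
       ylab = "Corrected biological age (y)",
       main = sprintf("slope %.2f, r %.2f, SEE %.1f y",
                      rep$slope, rep$r, rep$see))
  graphics::abline(0, 1, lty = 2, col = "red")
  graphics::abline(rep$intercept, rep$slope)
  grDevices::dev.off()

  f2 <- file.path(dir, paste0(prefix, "_bland_altman.pdf"))
  grDevices::pdf(f2, width = 6, height = 6)
  plot((ca + bac) / 2, ca - bac, xlab = "Mean of CA and BAc (y)",
       ylab = "CA - BAc (y)",
       main = sprintf("bias %.3f y, LoA [%.1f, %.1f] y",
                      rep$bias, rep$loa_low, rep$loa_high))
  graphics::abline(h = rep$bias, lty = 2, col = "red")
  graphics::abline(h = c(rep$loa_low, rep$loa_high), lty = 3)
  grDevices::dev.off()

  invisible(c(f1, f2))
}
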