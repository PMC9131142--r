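test_that("two perfectly correlated columns give loadings 1/sqrt(2) and eigenvalue 2", {
  n <- 30
  age <- seq(20, 60, length.out = n)
  v <- sin(seq_len(n)) + 5
  ch <- as_cohort(data.frame(id = as.character(1:n), sex = "F", age = age,
                             tc = v, hdl = 2 * v + 1))
  pc1 <- fit_pc1(ch, c("tc", "hdl"))
  expect_equal(unname(abs(pc1$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(pc1$eigenvalue, 2, tolerance = 1e-9)
  expect_equal(pc1$explained_variance, 1, tolerance = 1e-9)
  expect_true(pc1$loadings["tc"] >= 0)  # anchored on total cholesterol
})

test_that("for independent columns the leading eigenvalue approaches 1", {
  set.seed(3)
  n <- 5000
  df <- data.frame(id = as.character(1:n), sex = "M",
                   age = runif(n, 18, 65))
  for (k in 1:6) df[[paste0("b", k)]] <- rnorm(n)
  ch <- suppressWarnings(as_cohort(df))
  pc1 <- fit_pc1(ch, paste0("b", 1:6), sign_anchor = "b1")
  expect_equal(pc1$eigenvalue, 1, tolerance = 0.1)
  expect_equal(pc1$explained_variance, 1 / 6, tolerance = 0.05)
})

test_that("eigen solution matches a power-iteration oracle on random panels", {
  set.seed(17)
  for (i in 1:10) {
    n <- 60
    X <- matrix(rnorm(n * 9), n, 9) %*% matrix(rnorm(81), 9, 9)
    df <- data.frame(id = as.character(1:n), sex = "F",
                     age = runif(n, 18, 65))
    nm <- paste0("b", 1:9)
    for (k in 1:9) df[[nm[k]]] <- X[, k]
    ch <- suppressWarnings(as_cohort(df))
    pc1 <- fit_pc1(ch, nm, sign_anchor = "b1")
    oracle <- power_iteration_leading(cor(X))
    expect_equal(pc1$eigenvalue, oracle$value, tolerance = 1e-8)
    ov <- oracle$vector * sign(oracle$vector[1])
    expect_equal(unname(pc1$loadings), ov, tolerance = 1e-6)
  }
})

test_that("loadings are a unit vector, orientation follows the sign anchor, and explained variance is eigenvalue/N", {
  ch <- default_cohort_with_map(seed = 2)
  pc1 <- fit_pc1(ch, model_panel(), sign_anchor = "tc")
  expect_equal(sum(pc1$loadings^2), 1, tolerance = 1e-9)
  expect_gte(pc1$loadings["tc"], 0)
  expect_equal(pc1$explained_variance, pc1$eigenvalue / 9, tolerance = 1e-12)
  flipped <- fit_pc1(ch, model_panel(), sign_anchor = "vo2max")
  expect_equal(unname(flipped$loadings), -unname(pc1$loadings), tolerance = 1e-9)
})

test_that("including chronological age yields a positive age loading on the first component", {
  ch <- default_cohort_with_map(seed = 4)
  pc1 <- fit_pc1(ch[ch$sex == "female", ], model_panel(), include_ca = TRUE)
  expect_equal(pc1$sign_anchor, "age")
  expect_gt(pc1$loadings["age"], 0.2)
})

test_that("degenerate and under-determined inputs error informatively", {
  ch <- toy_cohort(8)
  ch$tc[1:6] <- NA
  expect_error(fit_pc1(ch, c("tc", "hdl", "vo2max")), "complete records")
  ch2 <- toy_cohort(20)
  ch2$flat <- 3
  expect_error(fit_pc1(ch2, c("tc", "flat")), "zero-variance")
})

test_that("contributions: square-loading shares, sum to 100, sign-flip invariant", {
  expect_equal(unname(pc1_contributions(c(a = 1))), 100)
  a <- c(x = 0.6, y = -0.8)
  expect_equal(unname(pc1_contributions(a)), c(36, 64))
  expect_equal(pc1_contributions(a), pc1_contributions(-a))
  ch <- default_cohort_with_map(seed = 5)
  pc1 <- fit_pc1(ch, model_panel())
  expect_equal(sum(pc1_contributions(pc1)), 100, tolerance = 1e-9)
})

test_that("score coefficients give a single-variable score of (x - mean)/sd scaled by the loading", {
  n <- 25
  ch <- as_cohort(data.frame(id = as.character(1:n), sex = "F",
                             age = seq(20, 60, length.out = n),
                             tc = rep(c(8, 12), length.out = n) + 0.001 * (1:n)))
  # single biomarker: loading 1, so w = 1/sd, w0 = -mean/sd
  pc1 <- fit_pc1(ch, "tc")
  sc <- fit_bas(pc1)
  expect_equal(unname(sc$w), 1 / pc1$sd[["tc"]], tolerance = 1e-12)
  expect_equal(sc$w0, -pc1$mean[["tc"]] / pc1$sd[["tc"]], tolerance = 1e-12)
  # constructed case: a = 1, sd = 2, mean = 10 -> w = 0.5, w0 = -5, BAS(12) = 1
  w <- 1 / 2; w0 <- -10 / 2
  expect_equal(w0 + w * 12, 1)
})

test_that("training score has mean 0 and SD sqrt(eigenvalue)", {
  ch <- default_cohort_with_map(seed = 6)
  for (sx in c("female", "male")) {
    sub <- ch[ch$sex == sx, ]
    pc1 <- fit_pc1(sub, model_panel())
    sc <- fit_bas(pc1)
    X <- as.matrix(sub[pc1$rows, model_panel()])
    bas <- drop(sc$w0 + X %*% sc$w)
    expect_equal(mean(bas), 0, tolerance = 1e-9)
    expect_equal(sd(bas), sqrt(pc1$eigenvalue), tolerance = 1e-9)
  }
  expect_error(fit_bas(fit_pc1(ch, model_panel(), include_ca = TRUE)),
               "without chronological age")
})

test_that("T-scale maps score 0 to the mean age and reproduces published corrected coefficients", {
  expect_equal(tscale(0, 13.6, 41.3, 2.79), 41.3)
  # published male equation: score coefficients scaled by sigma/sqrt(lambda)
  expect_equal(round(0.103 * 13.8 / sqrt(2.25), 2), 0.95)  # HbA1c
  expect_equal(round(0.067 * 13.8 / sqrt(2.25), 2), 0.62)  # VO2max
  # literal (non-standardized) variant
  expect_equal(tscale(1, 13.6, 41.3, 2.79, standardize = FALSE), 54.9)
  expect_equal(tscale(1, 13.6, 41.3, 2.79), 13.6 / sqrt(2.79) + 41.3)
  expect_error(tscale(0, 13.6, 41.3, 0), "positive")
})

test_that("correction slope is the OLS slope of BA on CA", {
  ca <- seq(20, 60, 2)
  expect_equal(fit_correction(ca, ca), 1, tolerance = 1e-12)
  set.seed(31)
  ba_noise <- rnorm(5000, 40, 13)
  ca_big <- runif(5000, 18, 65)
  expect_equal(fit_correction(ba_noise, ca_big), 0, tolerance = 0.06)
  expect_error(fit_correction(ca, rep(40, length(ca))), "zero variance")
  # published chronological-age coefficients imply b = 0.80 (women), 0.68 (men)
  expect_equal(1 - published_model("female")$corrected_coefficients$ca_coef, 0.80)
  expect_equal(1 - published_model("male")$corrected_coefficients$ca_coef, 0.68)
})

test_that("corrected biological age obeys the constructional identities on any fit", {
  for (s in c(3, 11)) {
    ch <- default_cohort_with_map(seed = s)
    for (sx in c("female", "male")) {
      m <- fit_ba_model(ch, model_panel(), sex = sx)
      pred <- predict_bac(m, ch[ch$sex == sx, ][m$pc1$rows, ])
      expect_equal(mean(pred$ba), m$mean_ca, tolerance = 1e-9)
      expect_equal(sd(pred$ba), m$sigma_ca, tolerance = 1e-9)
      expect_equal(mean(pred$bac), m$mean_ca, tolerance = 1e-9)
      expect_equal(unname(coef(lm(pred$bac ~ pred$ca))[2]), 1, tolerance = 1e-9)
      expect_equal(cor(pred$bac, pred$ca),
                   implied_corr_bac_ca(m$b_slope), tolerance = 1e-9)
      # corrected-equation evaluation agrees with the score pathway exactly
      pred2 <- predict_bac(m, ch[ch$sex == sx, ][m$pc1$rows, ],
                           parameterization = "corrected")
      expect_equal(pred2$bac, pred$bac, tolerance = 1e-9)
    }
  }
})

test_that("correction vanishes at the mean age and under b = 1", {
  ch <- default_cohort_with_map(seed = 7)
  m <- fit_ba_model(ch, model_panel(), sex = "female")
  rec <- ch[ch$sex == "female", ][1, ]
  rec$age <- m$mean_ca
  p <- predict_bac(m, rec)
  expect_equal(p$bac, p$ba, tolerance = 1e-12)

  m1 <- m
  m1$b_slope <- 1
  p_all <- predict_bac(m1, ch[ch$sex == "female", ])
  expect_equal(p_all$bac, p_all$ba, tolerance = 1e-12)
})

test_that("prediction refuses records with missing model biomarkers, naming them", {
  ch <- default_cohort_with_map(seed = 8)
  m <- fit_ba_model(ch, model_panel(), sex = "male")
  bad <- ch[ch$sex == "male", ]
  bad$hba1c[2] <- NA
  expect_error(predict_bac(m, bad), "hba1c")
  expect_error(predict_bac(m, bad[, setdiff(names(bad), "supar")]), "supar")
})

test_that("pooled fitting warns; sex-stratified is silent", {
  ch <- default_cohort_with_map(seed = 9)
  expect_warning(fit_ba_model(ch, model_panel()), "pooled")
  expect_silent(fit_ba_model(ch, model_panel(), sex = "female"))
})

test_that("implied correlation between corrected age and chronological age", {
  expect_equal(implied_corr_bac_ca(1), 1)
  expect_equal(round(implied_corr_bac_ca(0.80), 2), 0.86)
  expect_equal(round(implied_corr_bac_ca(0.68), 2), 0.81)
  expect_error(implied_corr_bac_ca(1.2), "exceed")
})

test_that("published model fixtures carry the printed equations verbatim", {
  f <- published_model("female")
  expect_equal(unname(f$w[c("hdl", "tc", "supar")]), c(0.909, 0.500, 0.400))
  expect_equal(f$w0, -11.04)
  expect_equal(f$sigma_ca, 13.6)
  expect_equal(f$mean_ca, 41.3)
  expect_equal(f$pc1$eigenvalue, 2.79)
  m <- published_model("male")
  expect_equal(m$corrected_coefficients$ca_coef, 0.32)
  expect_equal(m$corrected_coefficients$intercept, -70.37)  # printed, known inconsistency
  expect_equal(m$pc1$eigenvalue, 2.25)
  expect_equal(m$pc1$explained_variance, 0.25)
  # a record at the female means with mean age gives a finite corrected age
  rec <- data.frame(id = "x", sex = "female", age = 41.3,
                    map = 93.4, hba1c = 32.8, waist = 83.4, fev1 = 3.9,
                    vo2max = 39.3, adiponectin = 11515, hdl = 1.5, tc = 4.5,
                    supar = 2.09)
  p <- predict_bac(f, rec)
  expect_true(is.finite(p$bac))
  expect_true(p$bac > 0 && p$bac < 130)
})

test_that("the audit reconstructs corrected coefficients and flags only the male intercept", {
  au_m <- audit_published_model("male")
  coef_rows <- au_m[au_m$term != "intercept", ]
  expect_true(all(coef_rows$abs_diff <= 0.01))
  expect_false(any(coef_rows$flagged))
  expect_true(au_m$flagged[au_m$term == "intercept"])
  expect_equal(au_m$derived[au_m$term == "intercept"], -75.4, tolerance = 0.1)
  # rounded to 2 dp the key reconstructions are exact
  d <- setNames(au_m$derived, au_m$term)
  expect_equal(round(unname(d[c("map", "hba1c", "vo2max")]), 2),
               c(0.34, 0.95, -0.62))
  # the female expansion reproduces its printed intercept within rounding
  au_f <- audit_published_model("female")
  expect_lt(abs(au_f$derived[au_f$term == "intercept"] - (-56.67)), 0.5)
})

test_that("model serialization round-trips losslessly", {
  f <- published_model("female")
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(f, path)
  back <- deserialize_model(path)
  expect_equal(back$w, f$w)
  expect_equal(back$corrected_coefficients, f$corrected_coefficients)
  expect_equal(back$pc1$loadings, f$pc1$loadings)
  expect_equal(back$b_slope, f$b_slope)
  expect_equal(back$schema, f$schema)

  ch <- default_cohort_with_map(seed = 15)
  m <- fit_ba_model(ch, model_panel(), sex = "male")
  p2 <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, p2)
  m2 <- deserialize_model(p2)
  newd <- default_cohort_with_map(seed = 16)
  expect_equal(predict_bac(m2, newd), predict_bac(m, newd), tolerance = 1e-12)

  # truncated document: parse error, no partial model
  txt <- readLines(p2)
  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 200), p3)
  expect_error(deserialize_model(p3), class = "bioage_schema_error")
  p4 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema":"bioage/ba_model@99"}', p4)
  expect_error(deserialize_model(p4), class = "bioage_schema_error")
})
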