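# Independent brute-force oracles used for cross-checking; deliberately
# naive and separate from the implementation paths they verify.

# leading eigenpair by plain power iteration
power_iteration_leading <- function(C, iters = 5000, tol = 1e-14) {
  v <- rep(1, ncol(C)) / sqrt(ncol(C))
  lambda <- 0
  for (i in seq_len(iters)) {
    v_new <- drop(C %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    lambda_new <- drop(t(v_new) %*% C %*% v_new)
    if (abs(lambda_new - lambda) < tol) {
      lambda <- lambda_new; v <- v_new; break
    }
    lambda <- lambda_new; v <- v_new
  }
  list(value = lambda, vector = v)
}

# two-pass Pearson correlation from covariance sums
pearson_twopass <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# SEE from explicit normal-equation OLS residuals
see_bruteforce <- function(y, x) {
  n <- length(x)
  b <- (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
  a <- mean(y) - b * mean(x)
  sqrt(sum((y - a - b * x)^2) / (n - 2))
}

# random correlation matrix: correlation of n draws from a random loading
# structure, guaranteed valid
random_corr_matrix <- function(p, n = 200) {
  X <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p)
  stats::cor(X)
}

# sign-flip permutation p-value for the paired test
paired_perm_p <- function(x, y, n_perm = 4000) {
  d <- x - y
  obs <- abs(mean(d))
  hits <- 0
  for (i in seq_len(n_perm)) {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    if (abs(mean(s * d)) >= obs - 1e-15) hits <- hits + 1
  }
  hits / n_perm
}

# the 9-biomarker model panel (MAP derived from sbp/dbp)
model_panel <- function() {
  c("map", "hba1c", "waist", "fev1", "vo2max", "adiponectin", "hdl", "tc", "supar")
}

default_cohort_with_map <- function(seed = 1, n_per_bin = 5) {
  ch <- suppressWarnings(simulate_cohort(sim_config(n_per_sex_per_bin = n_per_bin,
                                                    seed = seed)))
  add_map(ch)
}

# tiny hand-built cohort for unit tests
toy_cohort <- function(n = 20, seed = 42) {
  set.seed(seed)
  age <- seq(20, 60, length.out = n)
  as_cohort(data.frame(
    id = sprintf("T%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age = age,
    tc = 3 + 0.03 * age + rnorm(n, 0, 0.3),
    hdl = 1.2 + 0.01 * age + rnorm(n, 0, 0.1),
    vo2max = 50 - 0.2 * age + rnorm(n, 0, 2),
    stringsAsFactors = FALSE
  ))
}
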