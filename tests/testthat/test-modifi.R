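make_series <- function(c0, sigma, delta, noise_sd = 0, seed = NULL,
                        times = c(48, 72, 96), n_per_cond = 4) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(rep = seq_len(n_per_cond), time_hr = times, trt = 0:1)
  g$pi <- c0 + sigma * g$time_hr + delta * g$trt +
    rnorm(nrow(g), 0, noise_sd)
  g
}

test_that("noiseless series are recovered exactly", {
  s <- make_series(0.2, -0.01, 0.5)
  fit <- fit_modifi(s$pi, s$time_hr, s$trt)
  expect_equal(fit$coefficients, c(c = 0.2, sigma = -0.01, delta = 0.5),
               tolerance = 1e-10)
  expect_true(fit$converged)
  expect_true(all(fit$weights > 0 & fit$weights <= 1))
})

test_that("the Huber IRLS agrees with MASS::rlm and with OLS limits", {
  skip_if_not_installed("MASS")
  s <- make_series(0.3, 0.02, -0.8, noise_sd = 0.4, seed = 27)
  s$pi[5] <- s$pi[5] + 6  # one gross outlier
  fit <- fit_modifi(s$pi, s$time_hr, s$trt)
  ref <- MASS::rlm(pi ~ time_hr + trt, data = s, k = 1.345, maxit = 100)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-3)
  # no outliers + huge tuning constant: OLS
  s2 <- make_series(0.3, 0.02, -0.8, noise_sd = 0.4, seed = 28)
  fit2 <- fit_modifi(s2$pi, s2$time_hr, s2$trt, huber_k = 1e6)
  ols <- lm(pi ~ time_hr + trt, data = s2)
  expect_equal(unname(fit2$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  fit3 <- fit_modifi(s2$pi, s2$time_hr, s2$trt, method = "ols")
  expect_equal(unname(fit3$coefficients), unname(coef(ols)), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with a named factor", {
  s <- make_series(0, 0, 0, times = c(48, 48))
  expect_error(fit_modifi(s$pi, s$time_hr, s$trt), "one time point")
  s2 <- make_series(0, 0, 0)
  expect_error(fit_modifi(s2$pi, s2$time_hr, rep(0, nrow(s2))),
               "one treatment")
  expect_error(fit_modifi(c(1, 2), c(48, 72), c(0, 1)), "at least 4")
})

test_that("fits are equivariant under shifts and time rescaling", {
  s <- make_series(0.1, 0.005, 0.4, noise_sd = 0.3, seed = 29)
  f1 <- fit_modifi(s$pi, s$time_hr, s$trt)
  f2 <- fit_modifi(s$pi + 2, s$time_hr, s$trt)
  expect_equal(f2$coefficients[["c"]], f1$coefficients[["c"]] + 2,
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["sigma"]], f1$coefficients[["sigma"]],
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["delta"]], f1$coefficients[["delta"]],
               tolerance = 1e-6)
  f3 <- fit_modifi(s$pi, s$time_hr / 24, s$trt)  # days instead of hours
  expect_equal(f3$coefficients[["sigma"]], f1$coefficients[["sigma"]] * 24,
               tolerance = 1e-6)
})

test_that("robust F-test is calibrated under the null and consistent", {
  # strong effect: p collapses
  s <- make_series(0, 0, 3, noise_sd = 0.2, seed = 30)
  fit <- fit_modifi(s$pi, s$time_hr, s$trt)
  expect_lt(robust_f_test(fit, "treatment")$p, 1e-6)
  expect_gt(robust_f_test(fit, "time")$p, 0.01)
  # null calibration: p approximately uniform
  set.seed(31)
  pvals <- replicate(400, {
    s <- make_series(0, 0, 0, noise_sd = 1)
    robust_f_test(fit_modifi(s$pi, s$time_hr, s$trt), "treatment")$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 0.05)
})

test_that("robust fits resist gross outliers better than OLS", {
  set.seed(32)
  err_rob <- err_ols <- numeric(100)
  for (i in 1:100) {
    s <- make_series(0, 0.01, 1, noise_sd = 0.3)
    out <- sample(nrow(s), 2)
    s$pi[out] <- s$pi[out] + 10
    err_rob[i] <- fit_modifi(s$pi, s$time_hr, s$trt)$coefficients[["delta"]] - 1
    err_ols[i] <- fit_modifi(s$pi, s$time_hr, s$trt,
                             method = "ols")$coefficients[["delta"]] - 1
  }
  expect_lt(sqrt(mean(err_rob^2)), sqrt(mean(err_ols^2)))
})

test_that("classification follows the FDR taxonomy", {
  cl <- classify_interaction(
    delta = c(0.4, 0, -0.5, 0, 0),
    mean_pi = c(0.1, -1, 0.2, 1, 0.3),
    fdr_time = c(0.5, 0.05, 0.01, 0.5, 0.6),
    fdr_treat = c(0.05, 0.5, 0.02, 0.2, 0.9))
  expect_equal(as.character(cl$class),
               c("positive_sensitive", "aggravating_insensitive",
                 "negative_sensitive", "not_significant", "not_significant"))
  expect_equal(cl$time_dependent, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # constant interactions need the per-condition interaction call
  cl2 <- classify_interaction(0, -2, 0.9, 0.9, fdr_interaction = 0.01)
  expect_equal(as.character(cl2$class), "aggravating_insensitive")
  expect_false(cl2$time_dependent)
})

test_that("run_modifi handles empty cubes and permuted time labels", {
  empty <- data.frame(target_gene = character(), query_gene = character(),
                      feature = character(), treatment = character(),
                      time_hr = numeric(), replicate = integer(),
                      pi = numeric())
  expect_equal(nrow(run_modifi(empty)), 0)
  # planted time effects disappear when time labels are shuffled
  ints <- data.frame(target = paste0("T", 1:10), query = "Q1",
                     feature = "f", c_true = 0,
                     sigma_true = 0.03, delta_true = 0)
  nulls <- data.frame(target = paste0("T", 11:60), query = "Q1",
                      feature = "f", c_true = 0, sigma_true = 0,
                      delta_true = 0)
  cube <- simulate_pi_cube(rbind(ints, nulls), noise_sd = 0.3, seed = 33)
  res <- run_modifi(cube)
  expect_gt(sum(res$fdr_time < 0.1 & res$target_gene %in% ints$target), 8)
  cmp <- compare_models(cube, c("serial_rlm", "randomized_times"), seed = 34)
  counts <- cmp$counts
  rnd <- cmp$detail[cmp$detail$strategy == "randomized_times", ]
  expect_lt(sum(rnd$fdr_treat < 0.1), 5)
  expect_error(compare_models(cube, "nonsense"), "unknown strategy")
})

test_that("strategy comparison finds no hits on zero-noise null data", {
  nulls <- null_interactions(30)
  cube <- simulate_pi_cube(nulls, noise_sd = 1e-9, seed = 35)
  cmp <- compare_models(cube, c("serial_rlm", "endpoint_welch",
                                "pooled_times"))
  expect_true(all(cmp$counts$n_fdr == 0))
})

test_that("serial modeling outpowers endpoint tests on sensitive pairs", {
  set.seed(36)
  ints <- data.frame(target = paste0("S", 1:10), query = "Q1", feature = "f",
                     c_true = 0, sigma_true = 0, delta_true = 1.2)
  nulls <- data.frame(target = paste0("T", 1:90), query = "Q1", feature = "f",
                      c_true = 0, sigma_true = 0, delta_true = 0)
  cube <- simulate_pi_cube(rbind(ints, nulls), noise_sd = 1, seed = 37)
  cmp <- compare_models(cube, c("serial_rlm", "endpoint_rlm",
                                "endpoint_welch", "endpoint_limma"))
  hits <- function(st) {
    d <- cmp$detail[cmp$detail$strategy == st, ]
    sum(d$fdr_treat < 0.1 & d$target_gene %in% ints$target, na.rm = TRUE)
  }
  expect_gte(hits("serial_rlm"), hits("endpoint_rlm"))
  expect_gte(hits("serial_rlm"), hits("endpoint_welch"))
  expect_gte(hits("serial_rlm"), hits("endpoint_limma"))
})

test_that("model adequacy flags a misspecified trajectory", {
  good <- data.frame(target = paste0("T", 1:40), query = "Q1", feature = "f",
                     c_true = rnorm(40, 0, 0.5), sigma_true = 0.01,
                     delta_true = rnorm(40, 0, 0.5))
  cube <- simulate_pi_cube(good, noise_sd = 0.3, seed = 38)
  res <- run_modifi(cube)
  adq <- model_adequacy(res, cube)
  expect_equal(adq$per_feature$mean_ratio, 1, tolerance = 0.25)
  # inject a time x treatment interaction the model cannot absorb
  bad_cube <- cube
  sel <- bad_cube$treatment != "control"
  bad_cube$pi[sel] <- bad_cube$pi[sel] + 0.06 *
    (bad_cube$time_hr[sel] - 48)
  adq2 <- model_adequacy(run_modifi(bad_cube), bad_cube)
  expect_gt(adq2$per_feature$mean_ratio, adq$per_feature$mean_ratio * 1.5)
})

test_that("empirical treatment differences track the archetype trajectories", {
  ints <- data.frame(target = c("A", "B", "C"), query = "Q1", feature = "f",
                     c_true = c(-1, 0, 0), sigma_true = c(0, 0, 0.01),
                     delta_true = c(0, 0.5, 0.5))
  cube <- simulate_pi_cube(ints, noise_sd = 0.02, seed = 39)
  d <- empirical_treatment_difference(cube)
  expect_equal(d$diff[d$target_gene == "A"], rep(0, 3), tolerance = 0.1)
  expect_equal(d$diff[d$target_gene == "B"], rep(0.5, 3), tolerance = 0.1)
  expect_equal(d$diff[d$target_gene == "C"], rep(0.5, 3), tolerance = 0.1)
  expect_equal(sum(d$initial), 3)
  expect_true(all(d$time_hr[d$initial] == 48))
})
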