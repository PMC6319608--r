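test_that("delta profiles concatenate queries across features", {
  res <- expand.grid(target_gene = c("A", "B"), query_gene = paste0("q", 1:5),
                     feature = c("f1", "f2"), stringsAsFactors = FALSE)
  res$delta <- seq_len(nrow(res)) / 10
  res$fdr_treat <- 0.5
  p1 <- delta_profiles(res, features = "f1")
  expect_equal(dim(p1), c(2, 5))
  p2 <- delta_profiles(res)
  expect_equal(dim(p2), c(2, 10))
  # identical archetypes across queries give identical rows
  res$delta <- rep(c(1, 1), nrow(res) / 2)
  expect_equal(unname(delta_profiles(res)[1, ]),
               unname(delta_profiles(res)[2, ]))
})

test_that("profile correlations carry the asymptotic p of the t transform", {
  set.seed(50)
  base <- rnorm(76)
  m <- rbind(a = base, b = base, c = -base, d = rnorm(76))
  pc <- profile_correlation(m)
  expect_equal(pc$r["a", "b"], 1)
  expect_lt(pc$p["a", "b"], 1e-12)
  expect_equal(pc$r["a", "c"], -1)
  expect_equal(pc$r, t(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 4))
  # closed form at r = 0.5, n = 76: t = 0.5 sqrt(74 / 0.75)
  r <- 0.5; n <- 76
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tt, 4.966555, tolerance = 1e-6)
  x <- rnorm(n); y <- r * x + sqrt(1 - r^2) * rnorm(n)
  pc2 <- profile_correlation(rbind(x = x, y = y))
  robs <- pc2$r["x", "y"]
  texp <- robs * sqrt((n - 2) / (1 - robs^2))
  expect_equal(pc2$p["x", "y"], 2 * pt(-abs(texp), n - 2))
})

test_that("network thresholding is monotone and respects bounds", {
  set.seed(51)
  m <- matrix(rnorm(5 * 30), 5, dimnames = list(letters[1:5], NULL))
  pc <- profile_correlation(m)
  none <- build_network(pc, threshold = 1.01, min_overlap = 3)
  expect_equal(sum(none$kept), 0)
  all_e <- build_network(pc, threshold = -1.01, min_overlap = 3)
  expect_equal(sum(all_e$kept), choose(5, 2))
  expect_false(any(all_e$gene_a == all_e$gene_b))
  th <- seq(-1, 1, by = 0.25)
  kept_n <- vapply(th, function(t)
    sum(build_network(pc, t, min_overlap = 3)$kept), 1)
  expect_true(all(diff(kept_n) <= 0))
})

test_that("two-block screens resolve into their modules", {
  skip_if_not_installed("mclust")
  set.seed(52)
  blockA <- paste0("A", 1:5); blockB <- paste0("B", 1:5)
  ints <- rbind(
    expand.grid(target = blockA, query = paste0("q", 1:4),
                stringsAsFactors = FALSE),
    expand.grid(target = blockB, query = paste0("q", 5:8),
                stringsAsFactors = FALSE))
  ints$feature <- "f"
  ints$c_true <- 0; ints$sigma_true <- 0
  ints$delta_true <- 1.5 + rnorm(nrow(ints), 0, 0.2)
  nulls <- expand.grid(target = c(blockA, blockB), query = paste0("q", 1:8),
                       stringsAsFactors = FALSE)
  nulls <- nulls[!paste(nulls$target, nulls$query) %in%
                   paste(ints$target, ints$query), ]
  nulls$feature <- "f"; nulls$c_true <- 0; nulls$sigma_true <- 0
  nulls$delta_true <- 0
  cube <- simulate_pi_cube(rbind(ints, nulls), noise_sd = 0.3, seed = 53)
  res <- run_modifi(cube)
  prof <- delta_profiles(res)
  edges <- build_network(profile_correlation(prof), threshold = 0.5,
                         min_overlap = 3)
  comp <- network_components(edges)
  truth <- ifelse(startsWith(names(comp), "A"), 1, 2)
  expect_equal(length(comp), 10)
  expect_gte(mclust::adjustedRandIndex(comp, truth), 0.9)
})

test_that("between-condition correlation drops for rewired genes", {
  set.seed(54)
  base <- matrix(rnorm(4 * 30), 4, dimnames = list(paste0("g", 1:4), NULL))
  condA <- base + matrix(rnorm(120, 0, 0.1), 4)
  condB <- base + matrix(rnorm(120, 0, 0.1), 4)
  out <- compare_profile_correlations(list(A = condA, B = condB))
  # no rewiring: within and between agree
  expect_lt(max(abs(out$difference)), 0.2)
  condB["g2", ] <- -condB["g2", ]  # treatment flips this gene's profile
  out2 <- compare_profile_correlations(list(A = condA, B = condB))
  self <- out2$gene_a == out2$gene_b
  flipped <- self & out2$gene_a == "g2"
  # the rewired gene shows the largest within-vs-between drop
  expect_equal(out2$gene_a[1], "g2")
  expect_gt(out2$difference[flipped], 1.5)
  expect_lt(max(out2$difference[self & !flipped]), 0.2)
  expect_error(compare_profile_correlations(list(A = condA)), "at least 2")
})

test_that("binomial enrichment matches the exact tail oracle", {
  cc <- data.frame(pathway = c("at_expectation", "enriched", "empty"),
                   count = c(3, 20, 0), n = c(30, 30, 0))
  out <- enrichment_binomial(cc, background_rate = 0.1)
  expect_equal(nrow(out), 2)  # empty pathway skipped
  expect_gt(out$p[1], 0.5)
  # oracle: sum of binomial masses at least as extreme as the observation
  d <- dbinom(0:30, 30, 0.1)
  oracle <- sum(d[d <= dbinom(20, 30, 0.1) * (1 + 1e-7)])
  expect_equal(out$p[2], oracle, tolerance = 1e-9)
  expect_true(all(out$fdr >= out$p))
  zero <- enrichment_binomial(data.frame(pathway = "x", count = 0, n = 5),
                              background_rate = 0)
  expect_equal(zero$p, 1)
})

test_that("group sensitivity KS test matches the ECDF-gap oracle", {
  set.seed(55)
  all_d <- rnorm(400)
  expect_equal(group_sensitivity_test(all_d, all_d)$statistic, 0)
  expect_equal(group_sensitivity_test(all_d, all_d)$p, 1)
  shifted <- rnorm(50, 1)
  expect_lt(group_sensitivity_test(shifted, all_d)$p, 1e-4)
  same_val <- rep(0.31, 5)
  stat <- group_sensitivity_test(same_val, all_d)$statistic
  ecdf_gap <- max(abs(ecdf(same_val)(sort(c(same_val, all_d))) -
                        ecdf(all_d)(sort(c(same_val, all_d)))))
  expect_equal(stat, ecdf_gap)
})

test_that("group summaries stratify sigma by biological process", {
  res <- data.frame(target_gene = rep(c("g1", "g2", "g3", "g4"), each = 5),
                    query_gene = "q", feature = "f",
                    sigma = c(rnorm(10, 0, 0.001), rnorm(10, 0.02, 0.001)),
                    delta = 0, fdr_time = 0.01, fdr_treat = 0.5)
  res$initial_difference <- 0
  grouping <- data.frame(gene = c("g1", "g2", "g3", "g4", "zz"),
                         group = c("flat", "flat", "ramp", "ramp", "other"))
  s <- summarize_by_group(res, grouping, "sigma")
  expect_equal(s$n, c(10, 10))
  expect_lt(s$median[s$group == "flat"], 0.005)
  expect_gt(s$median[s$group == "ramp"], 0.015)
  # single group equals the global summary
  g1 <- data.frame(gene = unique(res$target_gene), group = "all")
  s1 <- summarize_by_group(res, g1, "sigma")
  expect_equal(s1$median, median(res$sigma))
  none <- summarize_by_group(res[res$fdr_time > 1, ], grouping, "sigma")
  expect_equal(nrow(none), 0)
})
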