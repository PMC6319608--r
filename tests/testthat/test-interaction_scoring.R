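test_that("median polish matches the sweep-by-sweep oracle and reconstructs", {
  # additive matrices leave zero residuals
  addv <- outer(c(1, 4, 2), c(0, 3, 5, 1), "+")
  fit <- median_polish(addv)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_equal(median_polish(matrix(1:4, 2, 2))$residuals,
               matrix(0, 2, 2), tolerance = 1e-12, ignore_attr = TRUE)
  # a single spiked cell carries (almost all of) its own spike
  M <- outer(1:4, 1:4, "+")
  M[2, 3] <- M[2, 3] + 10
  fit <- median_polish(M)
  expect_equal(fit$residuals[2, 3], 10, tolerance = 1e-6)
  others <- fit$residuals
  others[2, 3] <- 0
  expect_lt(max(abs(others)), 1e-6)
  # random matrices with missing cells: oracle agreement + exact identity
  set.seed(13)
  for (i in 1:20) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    M <- matrix(rnorm(nr * nc), nr, nc)
    if (i %% 3 == 0) M[sample(length(M), 2)] <- NA
    fit <- median_polish(M, max_iter = 200, tol = 1e-10)
    ref <- reference_median_polish(M)
    expect_equal(fit$residuals, ref$residuals, tolerance = 1e-8,
                 ignore_attr = TRUE)
    recon <- fit$overall + outer(fit$row_effects, fit$col_effects, "+") +
      fit$residuals
    expect_equal(recon[!is.na(M)], M[!is.na(M)], tolerance = 1e-12)
  }
})

test_that("anchoring replaces main effects and leaves residuals untouched", {
  M <- outer(c(0, 1, 2), c(0, 2, 4), "+") + matrix(rnorm(9, 0, 0.01), 3)
  fit <- median_polish(M)
  # anchors equal to fitted effects: no-op
  same <- anchor_main_effects(fit, fit$row_effects, fit$col_effects)
  expect_equal(same$row_effects, fit$row_effects)
  expect_equal(same$overall, fit$overall)
  # shifting all anchors by +1 shifts main effects by +1, residuals equal
  up <- anchor_main_effects(fit, fit$row_effects + 1, fit$col_effects + 1)
  expect_equal(up$row_effects, fit$row_effects + 1)
  expect_equal(up$col_effects, fit$col_effects + 1)
  expect_equal(up$residuals, fit$residuals)
  # missing anchors leave that margin unshifted and flagged
  part <- anchor_main_effects(fit, c(NA, 5, 5), fit$col_effects)
  expect_equal(part$row_effects[1], fit$row_effects[1])
  expect_false(part$row_anchored[1])
})

test_that("anchored main effects recover single-knockdown truth", {
  des <- tiny_design(10, 5)
  tr <- simulate_truth(des, noise_sd = 0.05, plate_effect_sd = 0,
                       reagent_effect_sd = 0, seed = 14)
  tab <- simulate_screen(des, tr, seed = 15)$table
  sub <- tab[tab$treatment == "control" & tab$time_hr == 48 &
               tab$replicate == 1, ]
  trg <- sort(unique(sub$target_reagent[is.na(sub$control_role)]))
  qry <- sort(unique(sub$query_gene[is.na(sub$control_role)]))
  M <- matrix(NA_real_, length(trg), length(qry),
              dimnames = list(trg, qry))
  combo <- sub[is.na(sub$control_role), ]
  M[cbind(match(combo$target_reagent, trg), match(combo$query_gene, qry))] <-
    combo$cell_number
  anch_t <- sub[!is.na(sub$control_role) & sub$control_role == "single_target", ]
  anch_q <- sub[!is.na(sub$control_role) & sub$control_role == "single_query", ]
  fit <- anchor_main_effects(median_polish(M),
                             anch_t$cell_number[match(trg, anch_t$target_reagent)],
                             anch_q$cell_number[match(qry, anch_q$query_gene)])
  truth_m <- tr$main_effects[sub("_d[0-9]+$", "", trg), "cell_number"]
  expect_equal(unname(fit$row_effects), unname(truth_m), tolerance = 0.2)
})

test_that("pi-scores vanish on additive data and are scale invariant", {
  des <- tiny_design()
  tr <- simulate_truth(des, noise_sd = 0.01, plate_effect_sd = 0,
                       reagent_effect_sd = 0, seed = 16)
  tab <- simulate_screen(des, tr, seed = 17)$table
  cube <- pi_scores(tab, "cell_number")
  # no interactions: pi-scores stay in the noise band (MAD units)
  expect_lt(max(abs(cube$pi), na.rm = TRUE), 10)
  tab2 <- tab
  tab2$cell_number <- tab2$cell_number * 2
  cube2 <- pi_scores(tab2, "cell_number")
  expect_equal(cube2$pi, cube$pi, tolerance = 1e-3)
  # self-pairs excluded by default, retained on request
  expect_false(any(cube$target_gene == cube$query_gene))
  cube_self <- pi_scores(tab, "cell_number", exclude_self = FALSE)
  expect_true(any(cube_self$target_gene == cube_self$query_gene))
})

test_that("an interacting pair stands out of the pi distribution", {
  des <- tiny_design(10, 5)
  ints <- data.frame(target = "T7", query = "T2", class = "I", magnitude = 2)
  tr <- simulate_truth(des, interactions = ints, noise_sd = 0.1, seed = 18)
  tab <- simulate_screen(des, tr, seed = 19)$table
  cube <- pi_scores(tab, "cell_number")
  hit <- cube$target_gene == "T7" & cube$query_gene == "T2"
  expect_lt(max(cube$pi[hit]), min(-3, quantile(cube$pi[!hit], 0.01)))
})

test_that("moderated t matches limma and its degenerate limits", {
  set.seed(20)
  n_int <- 120
  mat <- matrix(rnorm(n_int * 4, 0, 1), n_int, 4)
  mat[1:10, ] <- mat[1:10, ] + 2
  x <- as.vector(t(mat))
  g <- rep(paste0("i", seq_len(n_int)), each = 4)
  res <- moderated_t(x, g)
  ebfit <- limma::eBayes(limma::lmFit(mat, matrix(1, 4, 1)))
  expect_equal(res$t, unname(ebfit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(ebfit$p.value[, 1]), tolerance = 1e-8)
  # prior_df = 0: ordinary one-sample t
  res0 <- moderated_t(x, g, prior_df = 0)
  pt1 <- t.test(mat[1, ])$p.value
  expect_equal(res0$p[1], pt1, tolerance = 1e-10)
  # all replicates equal to 2 with a known shrunk sd: t = 2 sqrt(4) / s
  res4 <- suppressWarnings(  # zero sample variance in the constant group
    moderated_t(c(rep(2, 4), rnorm(4 * 50)),
                rep(paste0("j", 0:50), each = 4)))
  s <- sqrt(res4$s2_post[1])
  expect_equal(res4$t[1], 2 * 2 / s)
})

test_that("null pi-scores give uniform moderated-t p-values", {
  set.seed(21)
  x <- rnorm(300 * 4)
  g <- rep(paste0("i", 1:300), each = 4)
  res <- moderated_t(x, g)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    oracle <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
    expect_equal(bh_adjust(p), oracle)
  }
})

test_that("per-condition interaction calls find the planted interactions", {
  des <- tiny_design(10, 5)
  ints <- data.frame(target = c("T6", "T8"), query = c("T1", "T3"),
                     class = c("I", "II"), magnitude = 1.5)
  tr <- simulate_truth(des, interactions = ints, noise_sd = 0.2, seed = 23)
  tab <- simulate_screen(des, tr, seed = 24)$table
  calls <- call_interactions(pi_scores(tab, "cell_number"))
  hit <- paste(calls$target_gene, calls$query_gene) %in% c("T6 T1", "T8 T3")
  expect_true(all(calls$fdr[hit] < 0.1))
  expect_lt(mean(calls$fdr[!hit] < 0.1), 0.05)
  expect_true(all(calls$fdr >= calls$p, na.rm = TRUE))
})
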