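#' Median polish of a double-perturbation matrix
#'
#' Tukey's median polish: alternating subtraction of row and column medians
#' until the largest adjustment falls below `tol` or `max_iter` sweeps have
#' run. Decomposes M into overall + row effect + column effect + residual;
#' the reconstruction identity holds cell-exactly at every iteration. Row
#' sweeps run first.
#'
#' @param M Numeric matrix (>= 2x2); `NA` allowed and ignored in medians.
#' @param max_iter Maximum sweep iterations (default 100).
#' @param tol Convergence tolerance on the largest median adjustment
#'   (default 1e-6).
#' @return Object of class `polish_fit`: list with `overall`, `row_effects`,
#'   `col_effects`, `residuals`, `n_iter`, `converged`.
#' @examples
#' median_polish(outer(1:3, 1:4, "+"))$residuals  # all zero: additive matrix
#' @export
median_polish <- function(M, max_iter = 100L, tol = 1e-6) {
  stopifnot(is.matrix(M), nrow(M) >= 2, ncol(M) >= 2)
  med0 <- function(x) {
    m <- stats::median(x, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }
  nr <- nrow(M); nc <- ncol(M)
  overall <- 0
  r <- numeric(nr); cl <- numeric(nc)
  R <- M
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rdelta <- apply(R, 1L, med0)
    R <- R - rdelta
    r <- r + rdelta
    d <- med0(cl)
    cl <- cl - d; overall <- overall + d
    cdelta <- apply(R, 2L, med0)
    R <- sweep(R, 2L, cdelta)
    cl <- cl + cdelta
    d <- med0(r)
    r <- r - d; overall <- overall + d
    if (max(abs(rdelta), abs(cdelta)) < tol) { converged <- TRUE; break }
  }
  all_na_row <- apply(M, 1L, function(x) all(is.na(x)))
  all_na_col <- apply(M, 2L, function(x) all(is.na(x)))
  r[all_na_row] <- NA_real_
  cl[all_na_col] <- NA_real_
  structure(list(overall = overall, row_effects = r, col_effects = cl,
                 residuals = R, n_iter = iter, converged = converged),
            class = "polish_fit")
}

#' Anchor polish main effects to single-knockdown phenotypes
#'
#' The "lifting" step of the modified median polish: the fitted row (target)
#' and column (query) effects are replaced by the measured single-knockdown
#' phenotypes of the corresponding reagents (their value when paired with a
#' non-targeting control), so that main effects are on the single-knockdown
#' scale. Residuals are untouched; the median offset between fitted and
#' anchored effects is absorbed into the overall term. Rows/columns without
#' an anchor are left unshifted and flagged.
#'
#' @param fit A `polish_fit`.
#' @param row_anchors Numeric vector of single-knockdown values, one per row
#'   (`NA` where unavailable).
#' @param col_anchors As `row_anchors`, per column.
#' @return The anchored `polish_fit` with added fields `row_anchored`,
#'   `col_anchored` (logical flags).
#' @export
anchor_main_effects <- function(fit, row_anchors, col_anchors) {
  stopifnot(inherits(fit, "polish_fit"),
            length(row_anchors) == length(fit$row_effects),
            length(col_anchors) == length(fit$col_effects))
  row_ok <- !is.na(row_anchors)
  col_ok <- !is.na(col_anchors)
  shift <- stats::median(fit$row_effects[row_ok] - row_anchors[row_ok],
                         na.rm = TRUE)
  shift_c <- stats::median(fit$col_effects[col_ok] - col_anchors[col_ok],
                           na.rm = TRUE)
  if (is.na(shift)) shift <- 0
  if (is.na(shift_c)) shift_c <- 0
  fit$row_effects[row_ok] <- row_anchors[row_ok]
  fit$col_effects[col_ok] <- col_anchors[col_ok]
  fit$overall <- fit$overall + shift + shift_c
  fit$row_anchored <- row_ok
  fit$col_anchored <- col_ok
  fit
}

#' Interaction scores (pi-scores) for a normalized well table
#'
#' For every (feature, treatment, time, replicate) the double-perturbation
#' matrix (target reagents x query genes) is median-polished, optionally
#' anchored to single-knockdown wells (wells where the partner reagent is the
#' non-targeting control), and residuals are scaled by their median absolute
#' deviation to give pi-scores.
#'
#' @param table Normalized well table with columns `target_gene`,
#'   `query_gene`, `target_reagent`, `query_reagent`, `control_role`,
#'   `treatment`, `time_hr`, `replicate` and feature columns.
#' @param features Feature column names to score.
#' @param anchor Lift main effects to single-knockdown anchors
#'   (default TRUE).
#' @param exclude_self Drop pairs with target gene == query gene from the
#'   output (default TRUE); they stay in the polish.
#' @param mad_constant MAD consistency constant.
#' @return Object of class `pi_cube`: long data frame with columns
#'   `target_gene`, `target_reagent`, `query_gene`, `feature`, `treatment`,
#'   `time_hr`, `replicate`, `pi`, plus attribute `scales` (per-matrix MAD).
#' @export
pi_scores <- function(table, features, anchor = TRUE, exclude_self = TRUE,
                      mad_constant = 1.4826) {
  need <- c("target_gene", "query_gene", "target_reagent", "query_reagent",
            "control_role", "treatment", "time_hr", "replicate")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("well table lacks columns: ", paste(miss, collapse = ", "))
  is_ctrl <- !is.na(table$control_role)
  combo <- table[!is_ctrl, , drop = FALSE]
  anchors <- table[is_ctrl & table$control_role %in%
                     c("single_target", "single_query"), , drop = FALSE]
  strata <- unique(combo[, c("treatment", "time_hr", "replicate")])
  out <- vector("list", nrow(strata) * length(features))
  scales <- vector("list", length(out))
  k <- 0L
  for (s in seq_len(nrow(strata))) {
    sel <- combo$treatment == strata$treatment[s] &
      combo$time_hr == strata$time_hr[s] &
      combo$replicate == strata$replicate[s]
    sub <- combo[sel, , drop = FALSE]
    asel <- anchors$treatment == strata$treatment[s] &
      anchors$time_hr == strata$time_hr[s] &
      anchors$replicate == strata$replicate[s]
    asub <- anchors[asel, , drop = FALSE]
    trg <- sort(unique(sub$target_reagent))
    qry <- sort(unique(sub$query_gene))
    ridx <- match(sub$target_reagent, trg)
    cidx <- match(sub$query_gene, qry)
    for (f in features) {
      M <- matrix(NA_real_, length(trg), length(qry),
                  dimnames = list(trg, qry))
      M[cbind(ridx, cidx)] <- sub[[f]]
      fit <- median_polish(M)
      if (anchor && nrow(asub)) {
        ra <- asub[asub$control_role == "single_target", , drop = FALSE]
        ca <- asub[asub$control_role == "single_query", , drop = FALSE]
        row_anchors <- ra[[f]][match(trg, ra$target_reagent)]
        col_anchors <- ca[[f]][match(qry, ca$query_gene)]
        fit <- anchor_main_effects(fit, row_anchors, col_anchors)
      }
      s_mad <- stats::mad(fit$residuals, constant = mad_constant, na.rm = TRUE)
      k <- k + 1L
      scales[[k]] <- data.frame(treatment = strata$treatment[s],
                                time_hr = strata$time_hr[s],
                                replicate = strata$replicate[s],
                                feature = f, mad = s_mad)
      pi_mat <- if (is.finite(s_mad) && s_mad > 0) fit$residuals / s_mad else
        matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
      df <- data.frame(
        target_reagent = rep(trg, times = length(qry)),
        query_gene = rep(qry, each = length(trg)),
        pi = as.vector(pi_mat))
      df$target_gene <- sub("_d[0-9]+$", "", df$target_reagent)
      tg_map <- unique(sub[, c("target_reagent", "target_gene")])
      m <- match(df$target_reagent, tg_map$target_reagent)
      df$target_gene[!is.na(m)] <- tg_map$target_gene[m[!is.na(m)]]
      df$feature <- f
      df$treatment <- strata$treatment[s]
      df$time_hr <- strata$time_hr[s]
      df$replicate <- strata$replicate[s]
      out[[k]] <- df
    }
  }
  cube <- do.call(rbind, out)
  if (exclude_self)
    cube <- cube[cube$target_gene != cube$query_gene, , drop = FALSE]
  rownames(cube) <- NULL
  cube <- cube[, c("target_gene", "target_reagent", "query_gene", "feature",
                   "treatment", "time_hr", "replicate", "pi")]
  attr(cube, "scales") <- do.call(rbind, scales[seq_len(k)])
  class(cube) <- c("pi_cube", "data.frame")
  cube
}

#' Empirical-Bayes moderated one-sample t-test of interaction scores
#'
#' Tests, per interaction, whether the mean pi-score over its replicate
#' measurements differs from zero. Sample variances are shrunk toward a
#' common prior estimated across all interactions of the stratum
#' (empirical-Bayes variance moderation as in limma), stabilizing tests based
#' on few replicates.
#'
#' @param pi_values Numeric vector of pi-scores.
#' @param group Factor (or vector coercible to one) identifying the
#'   interaction each value belongs to; all groups in the call form the
#'   shrinkage ensemble and should come from one (feature, condition) stratum.
#' @param prior_df Optional prior degrees of freedom; `NULL` (default)
#'   estimates prior df and scale from the data; `0` gives the ordinary
#'   unmoderated t-test.
#' @return Data frame, one row per group: `n`, `mean_pi`, `var`, `s2_post`,
#'   `df_total`, `t`, `p`.
#' @export
moderated_t <- function(pi_values, group, prior_df = NULL) {
  group <- factor(group, levels = unique(group))
  ok <- !is.na(pi_values)
  n <- as.vector(tapply(ok, group, sum, default = 0L))
  mean_pi <- as.vector(tapply(pi_values[ok], group[ok], mean))
  v <- as.vector(tapply(pi_values[ok], group[ok], stats::var))
  df_resid <- pmax(n - 1L, 0L)
  usable <- df_resid > 0 & !is.na(v)
  if (!any(usable)) stop("no interaction has >= 2 replicate pi-scores")
  if (is.null(prior_df)) {
    sq <- limma::squeezeVar(v[usable], df = df_resid[usable])
    s2_post <- rep(NA_real_, length(v))
    s2_post[usable] <- sq$var.post
    d0 <- sq$df.prior
  } else if (prior_df == 0) {
    s2_post <- v
    d0 <- 0
  } else {
    s2_prior <- stats::median(v[usable], na.rm = TRUE)
    s2_post <- (prior_df * s2_prior + df_resid * v) / (prior_df + df_resid)
    d0 <- prior_df
  }
  # total df capped at the pooled residual df of the ensemble
  df_total <- pmin(df_resid + ifelse(is.finite(d0), d0, Inf),
                   sum(df_resid[usable]))
  tstat <- mean_pi / sqrt(s2_post / n)
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(tstat), df_total),
              2 * stats::pnorm(-abs(tstat)))
  data.frame(group = levels(group), n = n, mean_pi = mean_pi, var = v,
             s2_post = s2_post, df_total = df_total, t = tstat, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; adjusted
#' values are monotone in p and capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1] (`NA` allowed).
#' @return Adjusted values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-condition interaction calls
#'
#' Runs the moderated t-test within every (feature, treatment, time) stratum
#' of a pi-cube, pooling the 2 dsRNA designs x 2 biological replicates of
#' each pair as its replicate measurements, and BH-adjusts p-values within
#' the stratum.
#'
#' @param cube A `pi_cube` from [pi_scores()].
#' @param fdr_scope "stratum" (default: BH within each feature x condition) or
#'   "pooled" (one BH over everything).
#' @param prior_df Passed to [moderated_t()].
#' @return Data frame: one row per (pair, feature, treatment, time) with
#'   `mean_pi`, `t`, `p`, `fdr`.
#' @export
call_interactions <- function(cube, fdr_scope = c("stratum", "pooled"),
                              prior_df = NULL) {
  fdr_scope <- match.arg(fdr_scope)
  strata <- unique(cube[, c("feature", "treatment", "time_hr")])
  res <- lapply(seq_len(nrow(strata)), function(s) {
    sel <- cube$feature == strata$feature[s] &
      cube$treatment == strata$treatment[s] &
      cube$time_hr == strata$time_hr[s]
    sub <- cube[sel, , drop = FALSE]
    pair <- paste(sub$target_gene, sub$query_gene, sep = ":")
    mt <- moderated_t(sub$pi, pair, prior_df = prior_df)
    pg <- strsplit(mt$group, ":", fixed = TRUE)
    data.frame(target_gene = vapply(pg, `[`, "", 1L),
               query_gene = vapply(pg, `[`, "", 2L),
               feature = strata$feature[s],
               treatment = strata$treatment[s],
               time_hr = strata$time_hr[s],
               n = mt$n, mean_pi = mt$mean_pi, t = mt$t, p = mt$p)
  })
  res <- do.call(rbind, res)
  if (fdr_scope == "pooled") {
    res$fdr <- bh_adjust(res$p)
  } else {
    key <- paste(res$feature, res$treatment, res$time_hr)
    res$fdr <- ave(res$p, key, FUN = bh_adjust)
  }
  res
}
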