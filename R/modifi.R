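#' Fit the MODIFI model to one interaction's score series
#'
#' Fits pi = c + sigma*time + delta*treatment + error for a single
#' (gene pair, feature) across all its condition-level measurements, by a
#' Huber M-estimate computed with iteratively reweighted least squares. The
#' residual scale is re-estimated each iteration as the rescaled MAD of
#' residuals about zero. With `method = "ols"` (or `huber_k = Inf`) the fit
#' reduces to ordinary least squares.
#'
#' Time enters in hours, uncentered, so the intercept `c` is the extrapolated
#' interaction score at time 0. Treatment must be coded 0 (control) /
#' 1 (drug): a positive `delta` means the interaction score is higher under
#' drug.
#'
#' @param pi Numeric vector of pi-scores (the response).
#' @param time_hr Numeric vector of times (hours post-treatment).
#' @param treatment Numeric 0/1 treatment code.
#' @param huber_k Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param method "huber" (default) or "ols".
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   largest coefficient change.
#' @param mad_constant MAD consistency constant for the scale estimate.
#' @return Object of class `modifi_fit`: coefficients `c`, `sigma`, `delta`,
#'   robust `scale`, final IRLS `weights`, `residuals`, `n_obs`, `converged`.
#' @examples
#' t <- rep(c(48, 72, 96), each = 2); trt <- rep(0:1, 3)
#' fit_modifi(0.2 - 0.01 * t + 0.5 * trt, t, trt)$coefficients
#' @export
fit_modifi <- function(pi, time_hr, treatment, huber_k = 1.345,
                       method = c("huber", "ols"), max_iter = 50L,
                       tol = 1e-8, mad_constant = 1.4826) {
  method <- match.arg(method)
  ok <- is.finite(pi) & is.finite(time_hr) & is.finite(treatment)
  pi <- pi[ok]; time_hr <- time_hr[ok]; treatment <- treatment[ok]
  n <- length(pi)
  if (length(unique(time_hr)) < 2L)
    stop("rank-deficient design: only one time point present")
  if (length(unique(treatment)) < 2L)
    stop("rank-deficient design: only one treatment level present")
  if (!all(treatment %in% c(0, 1)))
    stop("treatment must be coded 0 (control) / 1 (drug)")
  if (n < 4L) stop("need at least 4 observations for 3 coefficients + scale")
  X <- cbind(intercept = 1, time = time_hr, treatment = treatment)
  b <- stats::lm.fit(X, pi)$coefficients
  w <- rep(1, n)
  r <- pi - drop(X %*% b)
  s <- stats::mad(r, center = 0, constant = mad_constant)
  converged <- TRUE
  if (method == "huber" && is.finite(huber_k)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      r <- pi - drop(X %*% b)
      s <- stats::mad(r, center = 0, constant = mad_constant)
      if (s < 1e-10) { w <- rep(1, n); converged <- TRUE; break }
      u <- r / s
      w <- ifelse(abs(u) <= huber_k, 1, huber_k / abs(u))
      b_new <- stats::lm.wfit(X, pi, w)$coefficients
      if (max(abs(b_new - b)) < tol) { b <- b_new; converged <- TRUE; break }
      b <- b_new
    }
    r <- pi - drop(X %*% b)
    s <- stats::mad(r, center = 0, constant = mad_constant)
  } else {
    s <- sqrt(sum(r^2) / max(n - ncol(X), 1L))
  }
  structure(list(coefficients = c(c = unname(b[1]), sigma = unname(b[2]),
                                  delta = unname(b[3])),
                 scale = s, weights = w, residuals = r,
                 X = X, y = pi, n_obs = n, method = method,
                 huber_k = huber_k, converged = converged),
            class = "modifi_fit")
}

#' Robust F-test for a MODIFI coefficient
#'
#' Wald-type test of H0: coefficient = 0 against an F(1, df) reference
#' (df as described in Details). For Huber fits the coefficient covariance
#' is the standard
#' M-estimation form: `scale^2 * K^2 * [sum psi(u)^2 / (n - p)] /
#' [mean psi'(u)]^2 * (X'X)^-1`, with the small-sample correction
#' `K = 1 + (p/n) var(psi')/mean(psi')^2`. For OLS fits the classical
#' covariance is used.
#'
#' @param fit A `modifi_fit`.
#' @param term "time" or "treatment".
#' @param scale2 Optional squared residual scale replacing the fit's own
#'   (used by [run_modifi()] to plug in an empirical-Bayes moderated scale).
#' @param extra_df Additional denominator degrees of freedom accompanying a
#'   moderated scale (the prior df).
#' @return List with `statistic` (F), `p`, `se`, `df` (denominator df);
#'   `p = NA` (flagged) for a non-converged fit.
#' @details The denominator degrees of freedom are the number of
#'   observations carrying full Huber weight minus the number of
#'   coefficients (an effective-sample-size adjustment; equal to n - p for
#'   an OLS fit or a fit without downweighted points), plus `extra_df`.
#' @export
robust_f_test <- function(fit, term = c("time", "treatment"),
                          scale2 = NULL, extra_df = 0) {
  term <- match.arg(term)
  if (!isTRUE(fit$converged))
    return(list(statistic = NA_real_, p = NA_real_, se = NA_real_,
                df = NA_real_, converged = FALSE))
  X <- fit$X
  n <- fit$n_obs
  p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  df_den <- n - p
  if (fit$method == "huber" && is.finite(fit$huber_k) && fit$scale > 1e-10) {
    k <- fit$huber_k
    u <- fit$residuals / fit$scale
    psi <- pmax(-k, pmin(k, u))
    psip <- as.numeric(abs(u) <= k)
    m1 <- mean(psip)
    K <- 1 + (p / n) * stats::var(psip) / m1^2
    s2 <- if (is.null(scale2)) fit$scale^2 else scale2
    stddev2 <- K^2 * s2 * sum(psi^2) / (n - p) / m1^2
    df_den <- max(1L, sum(psip) - p) + extra_df
  } else {
    stddev2 <- if (is.null(scale2)) sum(fit$residuals^2) / (n - p) else
      scale2 * (n / (n - p))
    df_den <- df_den + extra_df
  }
  j <- match(term, c("intercept", "time", "treatment"))
  se <- sqrt(stddev2 * XtXinv[j, j])
  # coefficient order: c, sigma, delta <-> intercept, time, treatment
  bj <- fit$coefficients[[c("c", "sigma", "delta")[j]]]
  Fstat <- (bj / se)^2
  pval <- stats::pf(Fstat, 1, df_den, lower.tail = FALSE)
  list(statistic = Fstat, p = pval, se = se, df = df_den, converged = TRUE)
}

#' Classify a fitted interaction
#'
#' Applies the FDR-based taxonomy: treatment-sensitive if the treatment-term
#' FDR is below `alpha` (sign from delta: positive means lifted by drug),
#' otherwise aggravating/alleviating treatment-insensitive if the time term
#' is significant (sign from the mean pi-score), otherwise (optionally)
#' aggravating/alleviating insensitive-constant if the per-condition
#' moderated-t interaction FDR is below `alpha`, else not significant.
#' Time dependence is carried as a separate flag (a sensitive interaction can
#' also be time dependent).
#'
#' @param delta,mean_pi,fdr_time,fdr_treat Vectors (one element per fit).
#' @param alpha Significance threshold on the FDR scale (default 0.1).
#' @param fdr_interaction Optional vector of per-pair interaction FDRs from
#'   [call_interactions()] (minimum across conditions); enables calling
#'   constant interactions whose time and treatment terms are both null.
#' @return Data frame with `class` (factor) and `time_dependent` (logical).
#' @export
classify_interaction <- function(delta, mean_pi, fdr_time, fdr_treat,
                                 alpha = 0.1, fdr_interaction = NULL) {
  n <- length(delta)
  if (is.null(fdr_interaction)) fdr_interaction <- rep(NA_real_, n)
  sens <- !is.na(fdr_treat) & fdr_treat < alpha
  timed <- !is.na(fdr_time) & fdr_time < alpha
  const <- !is.na(fdr_interaction) & fdr_interaction < alpha
  cls <- rep("not_significant", n)
  cls[const & mean_pi < 0] <- "aggravating_insensitive"
  cls[const & mean_pi >= 0] <- "alleviating_insensitive"
  cls[timed & mean_pi < 0] <- "aggravating_insensitive"
  cls[timed & mean_pi >= 0] <- "alleviating_insensitive"
  cls[sens & delta > 0] <- "positive_sensitive"
  cls[sens & delta <= 0] <- "negative_sensitive"
  data.frame(class = factor(cls, levels = c(
    "aggravating_insensitive", "alleviating_insensitive",
    "positive_sensitive", "negative_sensitive", "not_significant")),
    time_dependent = timed)
}

#' Fit MODIFI across a pi-cube
#'
#' One robust fit and one pair of robust F-tests per (gene pair, feature),
#' using all condition-level pi-score measurements of the pair (by default
#' 2 designs x 2 replicates x 3 times x 2 treatments = 24 observations).
#' BH FDR is computed per term, within each feature by default.
#'
#' @param cube A `pi_cube` from [pi_scores()] (or any data frame with its
#'   columns).
#' @param control_label Treatment label coded 0 (default "control"); all
#'   other labels are coded 1.
#' @param alpha FDR threshold for classification.
#' @param fdr_scope "feature" (BH within feature, default) or "pooled".
#' @param interaction_calls Optional result of [call_interactions()] used to
#'   label constant (time- and treatment-insensitive) interactions.
#' @param method,huber_k Passed to [fit_modifi()].
#' @param moderate_scale Shrink each fit's squared residual scale toward a
#'   screen-wide empirical-Bayes prior (per feature) before testing, adding
#'   the prior df to the test's denominator df (default TRUE). Stabilizes
#'   per-pair scale estimates exactly as the moderated t-test stabilizes
#'   replicate variances; `FALSE` tests each fit on its own scale.
#' @return Data frame, one row per (pair, feature): coefficients, scale,
#'   p/FDR per term, mean pi, class label, `time_dependent`, `n_obs`,
#'   `converged`. Pairs with insufficient data are reported in
#'   `attr(, "skipped")`.
#' @export
run_modifi <- function(cube, control_label = "control", alpha = 0.1,
                       fdr_scope = c("feature", "pooled"),
                       interaction_calls = NULL,
                       method = "huber", huber_k = 1.345,
                       moderate_scale = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  if (nrow(cube) == 0L)
    return(data.frame(target_gene = character(), query_gene = character(),
                      feature = character()))
  trt_code <- as.numeric(cube$treatment != control_label)
  key <- paste(cube$target_gene, cube$query_gene, cube$feature, sep = "\r")
  idx <- split(seq_len(nrow(cube)), key)
  skipped <- character()
  rows <- vector("list", length(idx))
  fits <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    y <- cube$pi[ii]
    ok <- is.finite(y)
    parts <- strsplit(names(idx)[i], "\r", fixed = TRUE)[[1]]
    if (sum(ok) < 6L ||
        length(unique(cube$time_hr[ii][ok])) < 2L ||
        length(unique(trt_code[ii][ok])) < 2L) {
      skipped <- c(skipped, paste(parts, collapse = ":"))
      next
    }
    fit <- fit_modifi(y[ok], cube$time_hr[ii][ok], trt_code[ii][ok],
                      method = method, huber_k = huber_k)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      target_gene = parts[1], query_gene = parts[2], feature = parts[3],
      c = fit$coefficients[["c"]], sigma = fit$coefficients[["sigma"]],
      delta = fit$coefficients[["delta"]], scale = fit$scale,
      mean_pi = mean(y[ok]), n_obs = fit$n_obs,
      p_time = NA_real_, p_treat = NA_real_,
      se_time = NA_real_, se_treat = NA_real_,
      converged = fit$converged)
  }
  keep <- !vapply(rows, is.null, TRUE)
  rows <- rows[keep]
  fits <- fits[keep]
  # per-feature empirical-Bayes moderation of the squared residual scales
  feat_of <- vapply(rows, function(r) r$feature, "")
  scale2 <- vapply(fits, function(f) f$scale^2, 1)
  df_of <- vapply(fits, function(f) f$n_obs - 3, 1)
  s2_post <- scale2
  d0 <- rep(0, length(fits))
  if (moderate_scale && length(fits) >= 10L) {
    for (f in unique(feat_of)) {
      sel <- feat_of == f & scale2 > 0
      if (sum(sel) >= 10L) {
        sq <- limma::squeezeVar(scale2[sel], df = df_of[sel])
        s2_post[sel] <- sq$var.post
        d0[sel] <- min(sq$df.prior, sum(df_of[sel]))
      }
    }
  }
  for (i in seq_along(rows)) {
    ft <- robust_f_test(fits[[i]], "time", scale2 = s2_post[i],
                        extra_df = d0[i])
    fd <- robust_f_test(fits[[i]], "treatment", scale2 = s2_post[i],
                        extra_df = d0[i])
    rows[[i]]$p_time <- ft$p
    rows[[i]]$p_treat <- fd$p
    rows[[i]]$se_time <- ft$se
    rows[[i]]$se_treat <- fd$se
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame()
  if (nrow(res)) {
    grp <- if (fdr_scope == "feature") res$feature else rep("all", nrow(res))
    res$fdr_time <- ave(res$p_time, grp, FUN = bh_adjust)
    res$fdr_treat <- ave(res$p_treat, grp, FUN = bh_adjust)
    fdr_int <- NULL
    if (!is.null(interaction_calls)) {
      k1 <- paste(res$target_gene, res$query_gene, res$feature)
      agg <- stats::aggregate(fdr ~ target_gene + query_gene + feature,
                              data = interaction_calls, FUN = min)
      k2 <- paste(agg$target_gene, agg$query_gene, agg$feature)
      fdr_int <- agg$fdr[match(k1, k2)]
    }
    cl <- classify_interaction(res$delta, res$mean_pi, res$fdr_time,
                               res$fdr_treat, alpha = alpha,
                               fdr_interaction = fdr_int)
    res$class <- cl$class
    res$time_dependent <- cl$time_dependent
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "alpha") <- alpha
  res
}

#' Summarize interaction counts by class
#'
#' @param results Output of [run_modifi()].
#' @param by Optional additional grouping column name (e.g. "feature").
#' @return Data frame of class counts.
#' @export
count_classes <- function(results, by = "feature") {
  if (nrow(results) == 0L) return(data.frame())
  tab <- as.data.frame(table(results[[by]], results$class))
  names(tab) <- c(by, "class", "n")
  tab
}

#' Compare interaction-calling strategies on identical data
#'
#' Runs several treatment-effect detection strategies on the same pi-cube:
#' the serial robust model over all time points (`serial_rlm`), its OLS twin
#' (`serial_lm`), endpoint-only strategies at the last time point
#' (`endpoint_rlm`: robust fit on treatment alone; `endpoint_limma`:
#' moderated t on paired drug-control differences; `endpoint_welch`: Welch
#' t-test between treatment groups), a model treating all times as replicates
#' (`pooled_times`) and a negative control with permuted time labels
#' (`randomized_times`).
#'
#' @param cube A `pi_cube`.
#' @param strategies Subset of the strategy names above.
#' @param alpha FDR threshold for the significance counts.
#' @param control_label Treatment label coded 0.
#' @param seed Seed for the time-label permutation.
#' @return List with `detail` (long data frame: strategy, pair, feature,
#'   p_treat, fdr_treat) and `counts` (per strategy: tests, n_fdr
#'   significant, n_p significant at raw alpha).
#' @export
compare_models <- function(cube,
                           strategies = c("serial_rlm", "serial_lm",
                                          "endpoint_rlm", "endpoint_limma",
                                          "endpoint_welch", "pooled_times",
                                          "randomized_times"),
                           alpha = 0.1, control_label = "control",
                           seed = 1L) {
  known <- c("serial_rlm", "serial_lm", "endpoint_rlm", "endpoint_limma",
             "endpoint_welch", "pooled_times", "randomized_times")
  bad <- setdiff(strategies, known)
  if (length(bad)) stop("unknown strategy: ", paste(bad, collapse = ", "))
  t_max <- max(cube$time_hr)
  end_cube <- cube[cube$time_hr == t_max, , drop = FALSE]
  trt1 <- unique(cube$treatment[cube$treatment != control_label])
  detail <- list()
  serial_like <- function(cc, method) {
    res <- run_modifi(cc, control_label = control_label, alpha = alpha,
                      method = method)
    data.frame(target_gene = res$target_gene, query_gene = res$query_gene,
               feature = res$feature, p_treat = res$p_treat,
               fdr_treat = res$fdr_treat)
  }
  two_group <- function(cc, f) {
    key <- paste(cc$target_gene, cc$query_gene, cc$feature, sep = "\r")
    idx <- split(seq_len(nrow(cc)), key)
    out <- lapply(names(idx), function(k) {
      ii <- idx[[k]]
      a <- cc$pi[ii][cc$treatment[ii] == control_label]
      b <- cc$pi[ii][cc$treatment[ii] != control_label]
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      data.frame(target_gene = parts[1], query_gene = parts[2],
                 feature = parts[3], p_treat = f(a, b))
    })
    out <- do.call(rbind, out)
    out$fdr_treat <- ave(out$p_treat, out$feature, FUN = bh_adjust)
    out
  }
  for (st in strategies) {
    d <- switch(st,
      serial_rlm = serial_like(cube, "huber"),
      serial_lm = serial_like(cube, "ols"),
      pooled_times =
        # all time points enter as exchangeable replicates: treatment-only fit
        two_group(cube, function(a, b) {
          a <- a[is.finite(a)]; b <- b[is.finite(b)]
          if (length(a) < 2 || length(b) < 2) return(NA_real_)
          huber_two_group_p(a, b)
        }),
      randomized_times = {
        cc <- cube
        set.seed(seed)
        key <- paste(cc$target_gene, cc$query_gene, cc$feature, sep = "\r")
        for (ii in split(seq_len(nrow(cc)), key))
          cc$time_hr[ii] <- sample(cc$time_hr[ii])
        serial_like(cc, "huber")
      },
      endpoint_rlm = two_group(end_cube, function(a, b) {
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) return(NA_real_)
        huber_two_group_p(a, b)
      }),
      endpoint_welch = two_group(end_cube, function(a, b) {
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) return(NA_real_)
        stats::t.test(b, a)$p.value
      }),
      endpoint_limma = {
        dd <- endpoint_differences(end_cube, control_label)
        strata <- split(seq_len(nrow(dd)), dd$feature)
        out <- lapply(strata, function(ii) {
          mt <- moderated_t(dd$diff[ii],
                            paste(dd$target_gene[ii], dd$query_gene[ii],
                                  sep = ":"))
          pg <- strsplit(mt$group, ":", fixed = TRUE)
          data.frame(target_gene = vapply(pg, `[`, "", 1L),
                     query_gene = vapply(pg, `[`, "", 2L),
                     feature = dd$feature[ii][1], p_treat = mt$p)
        })
        out <- do.call(rbind, out)
        out$fdr_treat <- ave(out$p_treat, out$feature, FUN = bh_adjust)
        rownames(out) <- NULL
        out
      })
    d$strategy <- st
    detail[[st]] <- d
  }
  detail <- do.call(rbind, c(detail, make.row.names = FALSE))
  counts <- do.call(rbind, lapply(split(detail, detail$strategy), function(d)
    data.frame(strategy = d$strategy[1], tests = sum(!is.na(d$p_treat)),
               n_fdr = sum(d$fdr_treat < alpha, na.rm = TRUE),
               n_p = sum(d$p_treat < alpha, na.rm = TRUE))))
  rownames(counts) <- NULL
  list(detail = detail, counts = counts)
}

# Robust two-group comparison: Huber fit of y ~ treatment with the same
# Wald/F machinery as the serial model (denominator df n - 2).
huber_two_group_p <- function(a, b, huber_k = 1.345) {
  y <- c(a, b)
  g <- c(rep(0, length(a)), rep(1, length(b)))
  X <- cbind(intercept = 1, treatment = g)
  n <- length(y)
  bcoef <- stats::lm.fit(X, y)$coefficients
  for (it in 1:50) {
    r <- y - drop(X %*% bcoef)
    s <- stats::mad(r, center = 0)
    if (s < 1e-10) break
    u <- r / s
    w <- ifelse(abs(u) <= huber_k, 1, huber_k / abs(u))
    bn <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(bn - bcoef)) < 1e-8) { bcoef <- bn; break }
    bcoef <- bn
  }
  r <- y - drop(X %*% bcoef)
  s <- stats::mad(r, center = 0)
  XtXinv <- chol2inv(chol(crossprod(X)))
  df_den <- n - 2
  if (s < 1e-10) {
    stddev2 <- sum(r^2) / (n - 2)
  } else {
    u <- r / s
    psi <- pmax(-huber_k, pmin(huber_k, u))
    psip <- as.numeric(abs(u) <= huber_k)
    m1 <- mean(psip)
    K <- 1 + (2 / n) * stats::var(psip) / m1^2
    stddev2 <- K^2 * s^2 * sum(psi^2) / (n - 2) / m1^2
    df_den <- max(1L, sum(psip) - 2)
  }
  se <- sqrt(stddev2 * XtXinv[2, 2])
  stats::pf((bcoef[[2]] / se)^2, 1, df_den, lower.tail = FALSE)
}

# Paired drug-control differences at one time point, matched by
# (target reagent, replicate).
endpoint_differences <- function(cc, control_label) {
  ctl <- cc[cc$treatment == control_label, ]
  drg <- cc[cc$treatment != control_label, ]
  key <- function(d) paste(d$target_reagent, d$query_gene, d$feature,
                           d$replicate, sep = "\r")
  m <- match(key(ctl), key(drg))
  ok <- !is.na(m)
  data.frame(target_gene = ctl$target_gene[ok],
             query_gene = ctl$query_gene[ok],
             feature = ctl$feature[ok], replicate = ctl$replicate[ok],
             diff = drg$pi[m[ok]] - ctl$pi[ok])
}

#' Model adequacy: fit residuals versus replicate variance
#'
#' Compares each fit's mean squared (unweighted) residual with the purely
#' experimental replicate variance of the same pair (variance over the
#' replicate measurements within each condition, pooled). If the linear
#' time/treatment model is adequate, the two agree.
#'
#' @param results Output of [run_modifi()].
#' @param cube The `pi_cube` the results were fitted on.
#' @param control_label Treatment label coded 0.
#' @return List with `per_fit` (pair, feature, residual_ms, replicate_var)
#'   and `per_feature` (correlation and R-squared between the two, plus the
#'   mean residual_ms / replicate_var ratio).
#' @export
model_adequacy <- function(results, cube, control_label = "control") {
  trt <- as.numeric(cube$treatment != control_label)
  pred_key <- paste(results$target_gene, results$query_gene, results$feature,
                    sep = "\r")
  m <- match(paste(cube$target_gene, cube$query_gene, cube$feature,
                   sep = "\r"), pred_key)
  ok <- !is.na(m) & is.finite(cube$pi)
  fitted_vals <- results$c[m[ok]] + results$sigma[m[ok]] * cube$time_hr[ok] +
    results$delta[m[ok]] * trt[ok]
  resid2 <- (cube$pi[ok] - fitted_vals)^2
  kf <- pred_key[m[ok]]
  residual_ms <- tapply(resid2, kf, mean)
  cond_key <- paste(kf, cube$treatment[ok], cube$time_hr[ok])
  cond_var <- tapply(cube$pi[ok], cond_key, function(x)
    if (sum(is.finite(x)) >= 2) stats::var(x) else NA_real_)
  cond_fit <- sub(" [^\r]*$", "", names(cond_var))
  cond_fit <- sub(" [^\r]*$", "", cond_fit)
  replicate_var <- tapply(unname(cond_var), cond_fit, mean, na.rm = TRUE)
  keys <- intersect(names(residual_ms), names(replicate_var))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  per_fit <- data.frame(
    target_gene = vapply(parts, `[`, "", 1L),
    query_gene = vapply(parts, `[`, "", 2L),
    feature = vapply(parts, `[`, "", 3L),
    residual_ms = unname(residual_ms[keys]),
    replicate_var = unname(replicate_var[keys]))
  per_feature <- do.call(rbind, lapply(split(per_fit, per_fit$feature),
    function(d) {
      okd <- is.finite(d$residual_ms) & is.finite(d$replicate_var)
      r <- if (sum(okd) >= 3) stats::cor(d$residual_ms[okd],
                                         d$replicate_var[okd]) else NA_real_
      data.frame(feature = d$feature[1], cor = r, r_squared = r^2,
                 mean_ratio = mean(d$residual_ms[okd]) /
                   mean(d$replicate_var[okd]))
    }))
  rownames(per_feature) <- NULL
  list(per_fit = per_fit, per_feature = per_feature)
}

#' Empirical per-time treatment differences
#'
#' Median pi-score per treatment (over replicate measurements), differenced
#' drug minus control at each time point. The value at the earliest time is
#' the "initial difference" summary.
#'
#' @param cube A `pi_cube`.
#' @param control_label Treatment label coded 0.
#' @return Data frame: pair, feature, time_hr, `diff` (drug - control) and
#'   `initial` flag marking the earliest time point.
#' @export
empirical_treatment_difference <- function(cube, control_label = "control") {
  key <- paste(cube$target_gene, cube$query_gene, cube$feature, cube$time_hr,
               sep = "\r")
  idx <- split(seq_len(nrow(cube)), key)
  out <- lapply(names(idx), function(k) {
    ii <- idx[[k]]
    a <- cube$pi[ii][cube$treatment[ii] == control_label]
    b <- cube$pi[ii][cube$treatment[ii] != control_label]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    d <- if (!sum(is.finite(a)) || !sum(is.finite(b))) NA_real_ else
      stats::median(b, na.rm = TRUE) - stats::median(a, na.rm = TRUE)
    data.frame(target_gene = parts[1], query_gene = parts[2],
               feature = parts[3], time_hr = as.numeric(parts[4]), diff = d)
  })
  out <- do.call(rbind, out)
  out$initial <- out$time_hr == min(out$time_hr)
  rownames(out) <- NULL
  out
}
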