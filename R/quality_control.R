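#' Z'-factor between positive and negative controls
#'
#' `1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values approaching 1
#' indicate a well-separated assay; below ~0.3 the plate is conventionally
#' considered unreliable.
#'
#' @param pos,neg Numeric control values (>= 2 each).
#' @return List with `z_prime` (`-Inf` with `degenerate = TRUE` when the
#'   group means coincide) and `degenerate`.
#' @examples
#' z_prime(c(0.9, 1.1), c(-0.1, 0.1))
#' @export
z_prime <- function(pos, neg) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  d <- abs(mean(pos) - mean(neg))
  if (d == 0) return(list(z_prime = -Inf, degenerate = TRUE))
  list(z_prime = 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / d,
       degenerate = FALSE)
}

#' Multivariate Z'-factor of control profiles
#'
#' Projects multiparametric control profiles onto the unit vector through the
#' two group means and returns the univariate Z'-factor of the projections.
#' Invariant to duplicating features (the projection axis is normalized).
#'
#' @param pos_profiles,neg_profiles Matrices (profiles in rows, shared
#'   feature columns), >= 2 rows each.
#' @return As [z_prime()].
#' @export
multivariate_z_prime <- function(pos_profiles, neg_profiles) {
  pos_profiles <- as.matrix(pos_profiles)
  neg_profiles <- as.matrix(neg_profiles)
  stopifnot(nrow(pos_profiles) >= 2, nrow(neg_profiles) >= 2,
            ncol(pos_profiles) == ncol(neg_profiles))
  axis <- colMeans(pos_profiles) - colMeans(neg_profiles)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) return(list(z_prime = -Inf, degenerate = TRUE))
  axis <- axis / nrm
  z_prime(drop(pos_profiles %*% axis), drop(neg_profiles %*% axis))
}

#' Replicate correlation per unit
#'
#' Pearson correlation between the two biological replicates of each unit
#' (typically each feature, across all non-control wells; or each reagent
#' pair across features). Wells are matched on all annotation columns other
#' than `replicate`.
#'
#' @param table Well table with a `replicate` column holding exactly two
#'   levels.
#' @param features Feature columns to correlate.
#' @param by "feature" (default): one PCC per feature across matched wells;
#'   or "plate": one PCC per plate pair (using the first feature), matching
#'   the per-plate cell-number QC gate.
#' @return Data frame with `unit` and `pcc` (`NA` when < 3 matched pairs).
#' @export
replicate_correlation <- function(table, features, by = c("feature", "plate")) {
  by <- match.arg(by)
  reps <- sort(unique(table$replicate))
  if (length(reps) != 2L) stop("need exactly 2 replicate levels")
  key <- paste(table$target_reagent, table$query_reagent, table$treatment,
               table$time_hr, sep = "\r")
  a <- table[table$replicate == reps[1], , drop = FALSE]
  b <- table[table$replicate == reps[2], , drop = FALSE]
  ka <- key[table$replicate == reps[1]]
  kb <- key[table$replicate == reps[2]]
  m <- match(ka, kb)
  ok <- !is.na(m)
  safe_cor <- function(x, y) {
    fin <- is.finite(x) & is.finite(y)
    if (sum(fin) < 3L) return(NA_real_)
    stats::cor(x[fin], y[fin])
  }
  if (by == "feature") {
    pcc <- vapply(features, function(f)
      safe_cor(a[[f]][ok], b[[f]][m[ok]]), numeric(1))
    return(data.frame(unit = features, pcc = unname(pcc)))
  }
  # per plate (of replicate 1): PCC of its wells against their replicate-2
  # partners, first feature
  f <- features[1]
  plates <- unique(a$plate[ok])
  pcc <- vapply(plates, function(pl) {
    sel <- ok & a$plate == pl
    safe_cor(a[[f]][sel], b[[f]][m[sel]])
  }, numeric(1))
  data.frame(unit = plates, pcc = unname(pcc))
}

#' Plate-level quality report
#'
#' Computes, per plate, the Z'-factor between the lethal (positive) and
#' non-targeting (negative) control wells and the between-replicate Pearson
#' correlation of its wells for the reference feature, and flags plates
#' failing both gates (the correlation gate alone cannot localize which
#' replicate of a pair failed).
#'
#' @param table Well table (additive scale).
#' @param feature Reference feature for both gates (conventionally the cell
#'   count).
#' @param pos_role,neg_role Control roles used as positive/negative controls.
#' @param z_threshold,pcc_threshold Masking thresholds (defaults 0.3 / 0.6).
#' @return A `qc_report` data frame: plate, z_prime, replicate_pcc, masked.
#' @export
qc_plates <- function(table, feature, pos_role = "lethal",
                      neg_role = "non_targeting",
                      z_threshold = 0.3, pcc_threshold = 0.6) {
  plates <- sort(unique(table$plate))
  zp <- vapply(plates, function(pl) {
    sel <- table$plate == pl & !is.na(table$control_role)
    pos <- table[[feature]][sel & table$control_role == pos_role]
    neg <- table[[feature]][sel & table$control_role == neg_role]
    if (length(pos) < 2 || length(neg) < 2) return(NA_real_)
    z_prime(pos, neg)$z_prime
  }, numeric(1))
  rc <- replicate_correlation(table, feature, by = "plate")
  # propagate each replicate-pair PCC to both plates of the pair
  reps <- sort(unique(table$replicate))
  mate <- function(pl) {
    r1 <- table[table$plate == pl, ][1, ]
    cand <- unique(table$plate[table$treatment == r1$treatment &
                                 table$time_hr == r1$time_hr &
                                 table$replicate != r1$replicate])
    cand
  }
  pcc <- rc$pcc[match(plates, rc$unit)]
  for (i in which(is.na(pcc))) {
    mates <- mate(plates[i])
    hit <- rc$pcc[rc$unit %in% mates]
    pcc[i] <- if (length(hit)) hit[1] else NA_real_
  }
  # a plate is masked when it fails BOTH gates: the replicate PCC is shared
  # by the two plates of a replicate pair, so the Z'-factor localizes which
  # replicate actually failed
  masked <- (!is.na(zp) & zp < z_threshold) & (!is.na(pcc) & pcc < pcc_threshold)
  out <- data.frame(plate = plates, z_prime = zp, replicate_pcc = pcc,
                    masked = masked)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Mask failing plates
#'
#' Removes wells on plates flagged by the quality report; values are never
#' altered, only membership. Downstream scores on the masked table equal
#' those on a table with the failing plates pre-deleted.
#'
#' @param table Well table.
#' @param qc A `qc_report` from [qc_plates()].
#' @return List with `table` (masked) and `masked_fraction`.
#' @export
mask_plates <- function(table, qc) {
  bad <- qc$plate[qc$masked]
  list(table = table[!table$plate %in% bad, , drop = FALSE],
       masked_fraction = mean(table$plate %in% bad),
       masked_plates = bad)
}

#' Correlation-based feature selection
#'
#' Reduces a redundant feature set to a non-redundant one: features failing
#' the replicate-reproducibility gate are dropped; the seed feature is kept;
#' remaining features are visited in order of decreasing reproducibility
#' (ties broken lexicographically) and kept only if their interaction-profile
#' correlation with every already-kept feature stays at or below the
#' redundancy threshold.
#'
#' @param profiles Numeric matrix: rows are units (e.g. gene pairs, wells),
#'   columns are features; correlations are computed between columns with
#'   pairwise-complete observations.
#' @param replicate_pcc Named numeric vector of per-feature replicate
#'   correlations.
#' @param seed_feature Feature kept first (e.g. "cell_number").
#' @param redundancy_threshold Maximum allowed PCC between kept features
#'   (default 0.7).
#' @param reproducibility_threshold Minimum replicate PCC (default 0.6).
#' @param use_absolute Use |PCC| for the redundancy gate (default FALSE:
#'   signed, as printed).
#' @return Data frame of features with `kept`, `kept_rank`, `replicate_pcc`,
#'   `reason`.
#' @export
select_features <- function(profiles, replicate_pcc, seed_feature,
                            redundancy_threshold = 0.7,
                            reproducibility_threshold = 0.6,
                            use_absolute = FALSE) {
  feats <- colnames(profiles)
  stopifnot(!is.null(feats), all(names(replicate_pcc) %in% feats) ||
              all(feats %in% names(replicate_pcc)))
  if (!seed_feature %in% feats) stop("seed feature not present: ", seed_feature)
  rp <- replicate_pcc[feats]
  if (is.na(rp[seed_feature]) || rp[seed_feature] < reproducibility_threshold)
    stop("seed feature fails the reproducibility gate")
  reproducible <- !is.na(rp) & rp >= reproducibility_threshold
  cm <- suppressWarnings(stats::cor(profiles, use = "pairwise.complete.obs"))
  if (use_absolute) cm <- abs(cm)
  kept <- character()
  reason <- stats::setNames(rep("", length(feats)), feats)
  reason[!reproducible] <- "irreproducible"
  order_idx <- order(-rp, feats)
  candidates <- feats[order_idx]
  candidates <- candidates[reproducible[candidates]]
  candidates <- c(seed_feature, setdiff(candidates, seed_feature))
  for (f in candidates) {
    r <- cm[f, kept]
    if (length(kept) == 0L || all(is.na(r) | r <= redundancy_threshold)) {
      kept <- c(kept, f)
      reason[f] <- "kept"
    } else {
      reason[f] <- "redundant"
    }
  }
  data.frame(feature = feats, replicate_pcc = unname(rp),
             kept = feats %in% kept,
             kept_rank = match(feats, kept), reason = unname(reason[feats]))
}
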