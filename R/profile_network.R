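#' Treatment-sensitivity (delta) profiles per target gene
#'
#' One row per target gene, columns the fitted delta coefficients against
#' every query gene, concatenated across the requested features. All fitted
#' deltas enter by default; set `significant_only` to restrict to
#' treatment-sensitive calls (others become `NA`).
#'
#' @param results Output of [run_modifi()].
#' @param features Features to include (default: all present).
#' @param significant_only Keep only deltas with `fdr_treat < alpha`.
#' @param alpha FDR threshold for `significant_only`.
#' @return Numeric matrix (targets x query-by-feature columns); targets
#'   without any fitted pair are omitted and reported in
#'   `attr(, "omitted")`.
#' @export
delta_profiles <- function(results, features = NULL, significant_only = FALSE,
                           alpha = 0.1) {
  if (is.null(features)) features <- sort(unique(results$feature))
  res <- results[results$feature %in% features, , drop = FALSE]
  if (significant_only)
    res$delta[is.na(res$fdr_treat) | res$fdr_treat >= alpha] <- NA_real_
  targets <- sort(unique(res$target_gene))
  queries <- sort(unique(res$query_gene))
  cols <- expand.grid(query = queries, feature = features,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  M <- matrix(NA_real_, length(targets), nrow(cols),
              dimnames = list(targets,
                              paste(cols$query, cols$feature, sep = "|")))
  idx_r <- match(res$target_gene, targets)
  idx_c <- match(paste(res$query_gene, res$feature, sep = "|"),
                 colnames(M))
  M[cbind(idx_r, idx_c)] <- res$delta
  empty <- rowSums(!is.na(M)) == 0
  out <- M[!empty, , drop = FALSE]
  attr(out, "omitted") <- targets[empty]
  out
}

#' Pairwise profile correlations with asymptotic p-values
#'
#' Pearson correlation between the rows of a profile matrix
#' (pairwise-complete observations) and the asymptotic p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` against a t distribution with n - 2
#' degrees of freedom (two-sided).
#'
#' @param profiles Numeric matrix, one profile per row.
#' @param min_overlap Minimum shared non-missing columns (default 3; entries
#'   below it are `NA`).
#' @return List of matrices `r`, `p`, `n` (shared observations).
#' @export
profile_correlation <- function(profiles, min_overlap = 3L) {
  profiles <- as.matrix(profiles)
  g <- nrow(profiles)
  r <- n <- p <- matrix(NA_real_, g, g,
                        dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(g)) {
    r[i, i] <- 1; p[i, i] <- 0
    n[i, i] <- sum(is.finite(profiles[i, ]))
    for (j in seq_len(g)) {
      if (j <= i) next
      ok <- is.finite(profiles[i, ]) & is.finite(profiles[j, ])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < min_overlap) next
      rij <- stats::cor(profiles[i, ok], profiles[j, ok])
      r[i, j] <- r[j, i] <- rij
      if (!is.na(rij)) {
        if (abs(rij) >= 1) {
          p[i, j] <- p[j, i] <- 0
        } else {
          tt <- rij * sqrt((nn - 2) / (1 - rij^2))
          p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), nn - 2)
        }
      }
    }
  }
  list(r = r, p = p, n = n)
}

#' Build the profile-correlation network
#'
#' Edges connect gene pairs whose profiles correlate above the threshold
#' (signed PCC by default). The full weighted edge list is retained with a
#' `kept` flag so re-thresholding needs no recomputation.
#'
#' @param corr Output of [profile_correlation()] (or a correlation matrix).
#' @param threshold Correlation threshold for kept edges (default 0.5).
#' @param min_overlap Minimum shared observations for an edge to be eligible
#'   (default 10).
#' @return Data frame of undirected edges: `gene_a`, `gene_b`, `pcc`,
#'   `p_asymptotic`, `n`, `kept`.
#' @export
build_network <- function(corr, threshold = 0.5, min_overlap = 10L) {
  if (is.matrix(corr)) corr <- list(r = corr, p = NA * corr, n = NA * corr)
  r <- corr$r
  genes <- rownames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                      pcc = r[ut], p_asymptotic = corr$p[ut], n = corr$n[ut])
  edges <- edges[!is.na(edges$pcc), , drop = FALSE]
  eligible <- is.na(edges$n) | edges$n >= min_overlap
  edges$kept <- eligible & edges$pcc > threshold
  rownames(edges) <- NULL
  edges
}

#' Connected components of the kept network
#'
#' @param edges Edge list from [build_network()].
#' @return Named integer vector: component membership per gene with at least
#'   one kept edge.
#' @export
network_components <- function(edges) {
  kept <- edges[edges$kept, , drop = FALSE]
  if (nrow(kept) == 0L) return(stats::setNames(integer(), character()))
  gr <- igraph::graph_from_data_frame(kept[, c("gene_a", "gene_b")],
                                      directed = FALSE)
  comp <- igraph::components(gr)$membership
  stats::setNames(as.integer(comp), names(comp))
}

#' Export a network as GraphML
#'
#' @param edges Edge list from [build_network()].
#' @param path Output file.
#' @param kept_only Write only kept edges (default TRUE).
#' @return Invisibly, the path.
#' @export
write_graphml <- function(edges, path, kept_only = TRUE) {
  if (kept_only) edges <- edges[edges$kept, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "pcc")], directed = FALSE)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Within- versus between-condition profile correlations
#'
#' For each gene pair, compares the correlation of their interaction
#' profiles computed within the same condition with the correlation across
#' conditions; genes whose between-condition correlation collapses while
#' within-condition correlation stays high have condition-rewired
#' interaction profiles.
#'
#' @param profiles_by_condition Named list (>= 2 conditions) of profile
#'   matrices with identical row (gene) and column sets.
#' @return Data frame per gene pair (self-pairs included: for a gene against
#'   itself, `within_r` is 1 and `between_r` is the gene's profile
#'   correlation across conditions -- the direct readout of rewiring):
#'   `within_r` (mean over conditions), `between_r` (mean over ordered
#'   condition pairs), `difference`, ranked by the correlation drop.
#' @export
compare_profile_correlations <- function(profiles_by_condition) {
  if (length(profiles_by_condition) < 2L)
    stop("need profiles for at least 2 conditions")
  genes <- rownames(profiles_by_condition[[1]])
  for (m in profiles_by_condition)
    stopifnot(identical(rownames(m), genes))
  conds <- names(profiles_by_condition)
  within <- lapply(profiles_by_condition,
                   function(m) profile_correlation(m)$r)
  pairs <- which(upper.tri(diag(length(genes)), diag = TRUE), arr.ind = TRUE)
  within_r <- rowMeans(sapply(within, function(r) r[pairs]), na.rm = TRUE)
  cross <- list()
  for (a in seq_along(conds)) for (b in seq_along(conds)) {
    if (a == b) next
    ma <- profiles_by_condition[[a]]
    mb <- profiles_by_condition[[b]]
    cr <- matrix(NA_real_, length(genes), length(genes))
    for (i in seq_along(genes)) for (j in seq_along(genes)) {
      if (i > j) next
      ok <- is.finite(ma[i, ]) & is.finite(mb[j, ])
      if (sum(ok) >= 3)
        cr[i, j] <- stats::cor(ma[i, ok], mb[j, ok])
    }
    cross[[length(cross) + 1L]] <- cr[pairs]
  }
  between_r <- rowMeans(do.call(cbind, cross), na.rm = TRUE)
  out <- data.frame(gene_a = genes[pairs[, 1]], gene_b = genes[pairs[, 2]],
                    within_r = within_r, between_r = between_r,
                    difference = within_r - between_r)
  out <- out[order(-out$difference), ]
  rownames(out) <- NULL
  out
}

#' Binomial enrichment of interaction classes per pathway
#'
#' Two-sided exact binomial test of each pathway's count of a class against
#' the background class rate, BH-adjusted.
#'
#' @param class_counts Data frame with columns `pathway`, `count` (pairs of
#'   the class in the pathway), `n` (tested pairs in the pathway).
#' @param background_rate Overall proportion of the class among all tested
#'   pairs.
#' @return `class_counts` with `expected`, `p`, `fdr`; pathways with `n == 0`
#'   are dropped.
#' @export
enrichment_binomial <- function(class_counts, background_rate) {
  stopifnot(background_rate >= 0, background_rate <= 1)
  cc <- class_counts[class_counts$n > 0, , drop = FALSE]
  cc$expected <- cc$n * background_rate
  cc$p <- vapply(seq_len(nrow(cc)), function(i) {
    if (background_rate == 0) return(if (cc$count[i] == 0) 1 else 0)
    if (background_rate == 1) return(if (cc$count[i] == cc$n[i]) 1 else 0)
    stats::binom.test(cc$count[i], cc$n[i], background_rate)$p.value
  }, numeric(1))
  cc$fdr <- bh_adjust(cc$p)
  rownames(cc) <- NULL
  cc
}

#' Kolmogorov-Smirnov test of a gene group's delta distribution
#'
#' Two-sample two-sided KS test of the group's treatment-sensitivity values
#' against the full set of measured values.
#'
#' @param group_deltas Delta values of the group (>= 3).
#' @param all_deltas All delta values (the background, may include the
#'   group).
#' @return List with `statistic` and `p`.
#' @export
group_sensitivity_test <- function(group_deltas, all_deltas) {
  group_deltas <- group_deltas[is.finite(group_deltas)]
  all_deltas <- all_deltas[is.finite(all_deltas)]
  stopifnot(length(group_deltas) >= 3)
  kt <- suppressWarnings(stats::ks.test(group_deltas, all_deltas))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Group-level summaries of fitted interaction terms
#'
#' Distribution summaries (median, quartiles) of sigma, delta or the
#' empirical initial difference over significant interactions, stratified by
#' an annotation grouping.
#'
#' @param results Output of [run_modifi()] (for `initial_difference`, merge
#'   in a column of that name first, e.g. from
#'   [empirical_treatment_difference()]).
#' @param grouping Data frame `gene` -> `group`; a pair belongs to the
#'   groups of its target gene.
#' @param statistic "sigma", "delta" or "initial_difference".
#' @param alpha Keep interactions with either term FDR below this.
#' @return Data frame per group: `n`, `q25`, `median`, `q75`; unknown group
#'   labels are reported via `attr(, "unknown_genes")`.
#' @export
summarize_by_group <- function(results, grouping,
                               statistic = c("sigma", "delta",
                                             "initial_difference"),
                               alpha = 0.1) {
  statistic <- match.arg(statistic)
  sig <- results[(!is.na(results$fdr_time) & results$fdr_time < alpha) |
                   (!is.na(results$fdr_treat) & results$fdr_treat < alpha), ,
                 drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(group = character(), n = integer(), q25 = numeric(),
                      median = numeric(), q75 = numeric()))
  grp <- grouping$group[match(sig$target_gene, grouping$gene)]
  unknown <- unique(sig$target_gene[is.na(grp)])
  x <- sig[[statistic]]
  keep <- !is.na(grp) & is.finite(x)
  out <- do.call(rbind, lapply(split(x[keep], grp[keep]), function(v)
    data.frame(n = length(v), q25 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v), q75 = unname(stats::quantile(v, 0.75)))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "unknown_genes") <- unknown
  out
}
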