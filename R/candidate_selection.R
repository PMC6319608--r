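#' Euclidean distance between phenotypic profiles
#'
#' @param a,b Numeric feature vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @examples
#' profile_distance(c(0, 0), c(3, 4))  # 5
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profile length mismatch")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Knowledge sum from weighted ontology annotations
#'
#' Sums evidence-code weights over a gene's ontology annotations; used as a
#' proxy for how well characterized a gene is (experimentally supported
#' annotations weigh more than computational ones). Candidate ranking prefers
#' low knowledge sums to avoid over-enriching well-studied genes.
#'
#' @param annotations Data frame with columns `term` and `evidence_code`
#'   (one row per annotation of one gene).
#' @param weights Named numeric vector: evidence code -> weight.
#' @return The summed weight.
#' @examples
#' knowledge_sum(data.frame(term = c("a", "b", "c"),
#'                          evidence_code = c("EXP", "EXP", "IEA")),
#'               c(EXP = 5, IEA = 1))  # 11
#' @export
knowledge_sum <- function(annotations, weights) {
  if (nrow(annotations) == 0L) return(0)
  unknown <- setdiff(unique(annotations$evidence_code), names(weights))
  if (length(unknown))
    stop("unknown evidence codes: ", paste(unknown, collapse = ", "))
  sum(weights[annotations$evidence_code])
}

#' Quality metrics for combinatorial-screen candidates
#'
#' Computes the per-gene screening-candidate metrics from genome-wide
#' single-knockdown profiles: Q1 profile strength (Euclidean distance to the
#' non-targeting control profile, Z-scored across genes), Q2 the unscaled
#' distance (effect size), Q3 the treatment shift (distance between the
#' gene's drug and control profiles), Q4 the PCC between its two
#' sequence-independent dsRNA designs, Q5 the PCC of one design across
#' screen replicates, Q6 expression (log-normalized count > 0), Q7 the
#' knowledge sum.
#'
#' Distances are computed on per-gene mean profiles; Z-scoring is applied to
#' the distances across genes (not to their inputs).
#'
#' @param profiles Data frame: columns `gene`, `design`, `replicate`,
#'   `treatment` plus feature columns.
#' @param features Feature column names.
#' @param control_gene Gene used as the non-targeting reference.
#' @param control_label Treatment label of the solvent control.
#' @param expression Optional named numeric vector of log-normalized counts.
#' @param annotations Optional data frame `gene`, `term`, `evidence_code`.
#' @param weights Named evidence-code weight vector (required with
#'   `annotations`).
#' @return Data frame of Q1-Q7 per gene.
#' @export
compute_q_scores <- function(profiles, features, control_gene,
                             control_label = "control", expression = NULL,
                             annotations = NULL, weights = NULL) {
  stopifnot(all(features %in% names(profiles)))
  if (!control_gene %in% profiles$gene)
    stop("control gene not in profiles: ", control_gene)
  mean_profile <- function(sel) {
    colMeans(as.matrix(profiles[sel, features, drop = FALSE]), na.rm = TRUE)
  }
  genes <- sort(unique(profiles$gene))
  ctrl_prof <- mean_profile(profiles$gene == control_gene &
                              profiles$treatment == control_label)
  q2 <- q3 <- q4 <- q5 <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    sel_ctl <- profiles$gene == g & profiles$treatment == control_label
    sel_drg <- profiles$gene == g & profiles$treatment != control_label
    pg <- mean_profile(sel_ctl)
    q2[i] <- profile_distance(pg, ctrl_prof)
    if (any(sel_drg)) q3[i] <- profile_distance(mean_profile(sel_drg), pg)
    designs <- unique(profiles$design[sel_ctl])
    if (length(designs) >= 2) {
      p1 <- mean_profile(sel_ctl & profiles$design == designs[1])
      p2 <- mean_profile(sel_ctl & profiles$design == designs[2])
      q4[i] <- stats::cor(p1, p2)
    }
    reps <- unique(profiles$replicate[sel_ctl])
    if (length(reps) >= 2) {
      d1 <- designs[1]
      r1 <- mean_profile(sel_ctl & profiles$design == d1 &
                           profiles$replicate == reps[1])
      r2 <- mean_profile(sel_ctl & profiles$design == d1 &
                           profiles$replicate == reps[2])
      q5[i] <- stats::cor(r1, r2)
    }
  }
  q1 <- (q2 - mean(q2, na.rm = TRUE)) / stats::sd(q2, na.rm = TRUE)
  q6 <- if (is.null(expression)) rep(NA, length(genes)) else
    unname(expression[genes] > 0)
  q7 <- rep(NA_real_, length(genes))
  if (!is.null(annotations)) {
    if (is.null(weights)) stop("annotations supplied without weights")
    ann <- split(annotations, annotations$gene)
    q7 <- vapply(genes, function(g)
      if (g %in% names(ann)) knowledge_sum(ann[[g]], weights) else 0,
      numeric(1))
  }
  data.frame(gene = genes, q1_profile_strength = q1, q2_effect_size = q2,
             q3_treatment_shift = q3, q4_design_pcc = q4, q5_screen_pcc = q5,
             q6_expressed = q6, q7_knowledge_sum = q7)
}

#' Rank combinatorial-screen candidates
#'
#' Flags each gene by the selection criteria (design reproducibility
#' Q4 > 0.5, screen reproducibility Q5 > 0.5, deviation from controls,
#' differential phenotype, expressed) and ranks: passers before failers,
#' then lower knowledge sum (Q7), then gene name.
#'
#' @param scores Output of [compute_q_scores()].
#' @param q1_min Minimum Z-scored profile strength (default 0: above-average
#'   phenotype).
#' @param q3_min Minimum treatment shift (default 0).
#' @param q4_min,q5_min Minimum design / screen replicate PCC (default 0.5).
#' @return `scores` with pass/fail flag columns, `n_pass`, and `rank`,
#'   ordered by rank.
#' @export
rank_candidates <- function(scores, q1_min = 0, q3_min = 0,
                            q4_min = 0.5, q5_min = 0.5) {
  flag <- function(x, thr) !is.na(x) & x > thr
  scores$pass_strength <- flag(scores$q1_profile_strength, q1_min)
  scores$pass_shift <- flag(scores$q3_treatment_shift, q3_min)
  scores$pass_design <- flag(scores$q4_design_pcc, q4_min)
  scores$pass_screen <- flag(scores$q5_screen_pcc, q5_min)
  scores$pass_expressed <- !is.na(scores$q6_expressed) & scores$q6_expressed
  scores$n_pass <- scores$pass_strength + scores$pass_shift +
    scores$pass_design + scores$pass_screen + scores$pass_expressed
  scores$eligible <- scores$pass_expressed
  q7 <- ifelse(is.na(scores$q7_knowledge_sum), Inf, scores$q7_knowledge_sum)
  o <- order(-scores$eligible, -scores$n_pass, q7, scores$gene)
  scores <- scores[o, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}
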