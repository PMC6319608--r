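#' Interaction archetypes
#'
#' Constructs the coefficient triple (c, sigma, delta) of one of the six
#' interaction trajectory classes: constant interactions insensitive to
#' treatment (I aggravating, II alleviating), treatment-sensitive constant
#' interactions (III), time-forming treatment-insensitive interactions
#' (IV aggravating, V alleviating), treatment-sensitive time-forming
#' interactions (VI), or the null (no interaction).
#'
#' Timed classes ramp at `magnitude / ramp_hr` score units per hour, so the
#' interaction reaches `magnitude` after `ramp_hr` hours.
#'
#' @param class_id One of "I", "II", "III", "IV", "V", "VI", "null".
#' @param magnitude Positive effect size in pi-score units.
#' @param direction "positive" or "negative": sign of delta for the
#'   treatment-sensitive classes (III, VI).
#' @param ramp_hr Hours over which timed classes accrue one `magnitude`
#'   (default 48).
#' @return An `interaction_archetype`: list with `class_id`, `c_true`,
#'   `sigma_true`, `delta_true`.
#' @examples
#' make_archetype("II", 0.5)   # c = +0.5, sigma = 0, delta = 0
#' @export
make_archetype <- function(class_id, magnitude = 1,
                           direction = c("positive", "negative"),
                           ramp_hr = 48) {
  direction <- match.arg(direction)
  if (!class_id %in% c("I", "II", "III", "IV", "V", "VI", "null"))
    stop("unknown archetype class: ", class_id)
  if (class_id != "null" && magnitude <= 0) stop("magnitude must be > 0")
  sgn <- if (direction == "positive") 1 else -1
  rate <- magnitude / ramp_hr
  co <- switch(class_id,
    null = c(0, 0, 0),
    I = c(-magnitude, 0, 0),
    II = c(magnitude, 0, 0),
    III = c(0, 0, sgn * magnitude),
    IV = c(0, -rate, 0),
    V = c(0, rate, 0),
    VI = c(0, sgn * rate, sgn * magnitude))
  structure(list(class_id = class_id, c_true = co[1], sigma_true = co[2],
                 delta_true = co[3]),
            class = "interaction_archetype")
}

#' Evaluate an archetype's true interaction score
#'
#' @param arch An `interaction_archetype` (or data frame row with `c_true`,
#'   `sigma_true`, `delta_true`).
#' @param time_hr Time in hours.
#' @param treatment 0/1 treatment code.
#' @return True pi-score before noise.
#' @export
true_pi <- function(arch, time_hr, treatment) {
  arch$c_true + arch$sigma_true * time_hr + arch$delta_true * treatment
}

#' Generate ground truth for a synthetic screen
#'
#' Draws per-gene main effects (on one or more latent phenotype factors that
#' are mixed into observed features by a loading matrix, inducing
#' feature-feature correlation), per-reagent design offsets, and assigns
#' interaction archetypes to gene pairs. All unassigned pairs are null.
#'
#' @param design A [screen_design()].
#' @param features Character vector of feature names.
#' @param feature_loadings Numeric matrix (features x factors); default one
#'   shared factor with unit loadings, making features correlated copies of
#'   the same latent phenotype plus feature-specific noise.
#' @param interactions `NULL` (all null) or a data frame with columns
#'   `target`, `query`, `class`, and optionally `magnitude`, `direction`,
#'   `factor` (latent factor index the interaction acts on, default 1).
#' @param main_effect_sd SD of per-gene latent main effects.
#' @param noise_sd Per-feature measurement noise SD (recycled).
#' @param plate_effect_sd SD of shared per-plate offsets.
#' @param reagent_effect_sd SD of per-target-reagent (design) offsets.
#' @param lethal_effect Latent main effect of the lethal control (factor 1).
#' @param pathway_effect Absolute latent effect of the pathway controls.
#' @param seed Integer seed.
#' @return A `ground_truth` object.
#' @export
simulate_truth <- function(design, features = c("cell_number", "eccentricity"),
                           feature_loadings = NULL, interactions = NULL,
                           main_effect_sd = 1, noise_sd = 0.3,
                           plate_effect_sd = 0.1, reagent_effect_sd = 0.1,
                           lethal_effect = -3, pathway_effect = 1.5,
                           seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  set.seed(seed)
  nf <- length(features)
  if (is.null(feature_loadings))
    feature_loadings <- matrix(1, nf, 1)
  stopifnot(nrow(feature_loadings) == nf)
  k <- ncol(feature_loadings)
  rownames(feature_loadings) <- features
  genes <- union(design$genes$target_genes, design$genes$query_genes)
  main_latent <- matrix(stats::rnorm(length(genes) * k, 0, main_effect_sd),
                        length(genes), k, dimnames = list(genes, NULL))
  main_effects <- main_latent %*% t(feature_loadings)  # genes x features
  combos <- enumerate_reagent_combinations(design$genes, design$lib)
  trg_reagents <- unique(combos$target_reagent)
  reagent_effects <- stats::setNames(
    stats::rnorm(length(trg_reagents), 0, reagent_effect_sd), trg_reagents)
  pairs <- enumerate_gene_pairs(design$genes)
  pair_key <- paste(pairs$target, pairs$query)
  arch_latent <- array(0, dim = c(nrow(pairs), k, 3))
  cls <- matrix("null", nrow(pairs), k)
  if (!is.null(interactions)) {
    if (!all(c("target", "query", "class") %in% names(interactions)))
      stop("interactions needs columns target, query, class")
    if (is.null(interactions$magnitude)) interactions$magnitude <- 1
    if (is.null(interactions$direction)) interactions$direction <- "positive"
    if (is.null(interactions$factor)) interactions$factor <- 1L
    idx <- match(paste(interactions$target, interactions$query), pair_key)
    if (anyNA(idx))
      stop("interaction assigned to a pair outside the design: ",
           paste(interactions$target[is.na(idx)],
                 interactions$query[is.na(idx)], collapse = ", "))
    for (i in seq_len(nrow(interactions))) {
      a <- make_archetype(interactions$class[i], interactions$magnitude[i],
                          interactions$direction[i])
      arch_latent[idx[i], interactions$factor[i], ] <-
        c(a$c_true, a$sigma_true, a$delta_true)
      cls[idx[i], interactions$factor[i]] <- a$class_id
    }
  }
  # expand latent interactions to features via the loading matrix
  long <- expand.grid(pair = seq_len(nrow(pairs)), feature = features,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  L <- feature_loadings[long$feature, , drop = FALSE]
  co <- vapply(1:3, function(j) {
    A <- matrix(arch_latent[, , j], ncol = k)[long$pair, , drop = FALSE]
    rowSums(L * A)
  }, numeric(nrow(long)))
  co <- matrix(co, ncol = 3)
  int_df <- data.frame(target = pairs$target[long$pair],
                       query = pairs$query[long$pair],
                       feature = long$feature,
                       class_id = apply(cls[long$pair, , drop = FALSE], 1L,
                                        function(z) {
                                          nz <- z[z != "null"]
                                          if (length(nz)) nz[1] else "null"
                                        }),
                       c_true = co[, 1], sigma_true = co[, 2],
                       delta_true = co[, 3])
  structure(list(features = features, feature_loadings = feature_loadings,
                 main_latent = main_latent, main_effects = main_effects,
                 interactions = int_df, reagent_effects = reagent_effects,
                 noise_sd = rep_len(noise_sd, nf),
                 plate_effect_sd = plate_effect_sd,
                 reagent_effect_sd = reagent_effect_sd,
                 lethal_effect = lethal_effect,
                 pathway_effect = pathway_effect, seed = seed),
            class = "ground_truth")
}

#' Simulate a combinatorial RNAi screen well table
#'
#' Runs the additive interaction model forward: every well value is
#' main(target) + main(query) + true pi(time, treatment) + plate effect +
#' reagent (design) offset + Gaussian noise, on the post-transform additive
#' scale. Per plate, single-knockdown anchor wells (each target reagent and
#' each query paired with the non-targeting control) and control wells
#' (non-targeting, lethal, pathway positive/negative) are included.
#'
#' @param design A [screen_design()].
#' @param truth A `ground_truth` from [simulate_truth()].
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @param output_scale "additive" (default; the scale the interaction model
#'   lives on) or "raw": additive values are mapped through an inverse
#'   generalized logarithm (`glog_inverse(mu + s * value, c)`) to emulate
#'   untransformed feature data for exercising the preprocessing chain.
#' @param raw_mu,raw_s,raw_c Location, spread and glog offset of the raw-scale
#'   export.
#' @param control_wells_per_role Control wells per plate for each of the four
#'   assay-control roles (default 3).
#' @return List with `table` (well table data frame), `truth`, and
#'   `plate_effects`.
#' @export
simulate_screen <- function(design, truth, seed = 1L,
                            output_scale = c("additive", "raw"),
                            raw_mu = 6, raw_s = 0.5, raw_c = 20,
                            control_wells_per_role = 3L) {
  stopifnot(inherits(design, "screen_design"), inherits(truth, "ground_truth"))
  output_scale <- match.arg(output_scale)
  set.seed(seed)
  grid <- design$grid
  plan <- plan_plates(design$plan, grid)$plates
  combos <- enumerate_reagent_combinations(design$genes, design$lib)
  nt <- design$lib$control_reagents[["non_targeting"]]
  conds <- expand.grid(replicate = seq_len(grid$biological_replicates),
                       time_hr = grid$times_hr, treatment = grid$treatments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layout <- vector("list", nrow(conds))
  for (s in seq_len(nrow(conds))) {
    cn <- conds[s, ]
    cond_plates <- plan$plate[plan$treatment == cn$treatment &
                                plan$time_hr == cn$time_hr &
                                plan$replicate == cn$replicate]
    if (!length(cond_plates))
      stop("no plates planned for condition ", paste(cn, collapse = "/"))
    # pair combos round-robin over this condition's plates
    cw <- data.frame(target_gene = combos$target,
                     query_gene = combos$query,
                     target_reagent = combos$target_reagent,
                     query_reagent = combos$query_reagent,
                     control_role = NA_character_)
    cw$plate <- rep_len(cond_plates, nrow(cw))
    # single-knockdown anchors: each target reagent and each query vs NT
    anch_t <- data.frame(target_gene = combos$target[!duplicated(combos$target_reagent)],
                         query_gene = "CTRL_NT",
                         target_reagent = unique(combos$target_reagent),
                         query_reagent = nt, control_role = "single_target")
    qg <- unique(combos$query)
    anch_q <- data.frame(target_gene = "CTRL_NT", query_gene = qg,
                         target_reagent = nt,
                         query_reagent = paste0(qg, "_d1"),
                         control_role = "single_query")
    anch <- rbind(anch_t, anch_q)
    anch$plate <- rep_len(cond_plates, nrow(anch))
    # per-plate assay controls (several wells per role so per-plate control
    # statistics such as the Z'-factor are defined)
    roles <- c("non_targeting", "lethal", "pathway_pos", "pathway_neg")
    ctrl <- data.frame(
      target_gene = paste0("CTRL_", c("NT", "LETHAL", "POS", "NEG")),
      query_gene = "CTRL_NT",
      target_reagent = unname(design$lib$control_reagents[
        c("non_targeting", "lethal", "pathway_pos", "pathway_neg")]),
      query_reagent = nt, control_role = roles)
    nctrl <- 4L * control_wells_per_role
    ctrl <- ctrl[rep(seq_len(4L), control_wells_per_role * length(cond_plates)), ]
    ctrl$plate <- rep(cond_plates, each = nctrl)
    w <- rbind(cw, anch, ctrl)
    w$treatment <- cn$treatment
    w$time_hr <- cn$time_hr
    w$replicate <- cn$replicate
    layout[[s]] <- w
  }
  tab <- do.call(rbind, layout)
  tab$batch <- plan$batch[match(tab$plate, plan$plate)]
  tab$well <- stats::ave(seq_len(nrow(tab)), tab$plate, FUN = seq_along)
  tab <- tab[order(tab$plate, tab$well), ]
  rownames(tab) <- NULL
  plates <- sort(unique(tab$plate))
  plate_eff <- stats::setNames(
    stats::rnorm(length(plates), 0, truth$plate_effect_sd), plates)
  # per-gene main effects (genes x features); controls have fixed effects
  trt_code <- as.numeric(tab$treatment != grid$treatments[1])
  L1 <- truth$feature_loadings[, 1]
  main_of <- function(gene, feature) {
    m <- rep(0, length(gene))
    known <- gene %in% rownames(truth$main_effects)
    m[known] <- truth$main_effects[cbind(gene[known], feature[known])]
    m[gene == "CTRL_LETHAL"] <- truth$lethal_effect * L1[feature[gene == "CTRL_LETHAL"]]
    m[gene == "CTRL_POS"] <- truth$pathway_effect * L1[feature[gene == "CTRL_POS"]]
    m[gene == "CTRL_NEG"] <- -truth$pathway_effect * L1[feature[gene == "CTRL_NEG"]]
    m  # CTRL_NT stays 0
  }
  int_key <- paste(truth$interactions$target, truth$interactions$query,
                   truth$interactions$feature)
  for (fi in seq_along(truth$features)) {
    f <- truth$features[fi]
    fvec <- rep(f, nrow(tab))
    v <- main_of(tab$target_gene, fvec) + main_of(tab$query_gene, fvec)
    m <- match(paste(tab$target_gene, tab$query_gene, f), int_key)
    has_int <- !is.na(m) & is.na(tab$control_role)
    if (any(has_int)) {
      tr <- truth$interactions[m[has_int], ]
      v[has_int] <- v[has_int] + tr$c_true + tr$sigma_true *
        tab$time_hr[has_int] + tr$delta_true * trt_code[has_int]
    }
    v <- v + plate_eff[as.character(tab$plate)]
    re <- truth$reagent_effects[tab$target_reagent]
    v <- v + ifelse(is.na(re), 0, re)
    v <- v + stats::rnorm(nrow(tab), 0, truth$noise_sd[fi])
    if (output_scale == "raw")
      v <- glog_inverse(raw_mu + raw_s * v, raw_c)
    tab[[f]] <- v
  }
  list(table = tab, truth = truth, plate_effects = plate_eff)
}

#' Spike additional control wells into a well table
#'
#' Appends per-plate control wells with the configured role effects (plate
#' effect + noise only for non-targeting; fixed strong effects for lethal and
#' pathway controls). Control wells are flagged via `control_role` and never
#' enter the gene-pair matrix.
#'
#' @param table A simulated well table.
#' @param truth The `ground_truth` used for the table.
#' @param roles Control roles to add; zero-length leaves the table unchanged.
#' @param wells_per_role Wells per plate and role.
#' @param plate_effects Optional named vector of per-plate offsets (as
#'   returned by [simulate_screen()]) so spiked wells share their plate's
#'   effect.
#' @param seed Integer seed.
#' @return The extended well table.
#' @export
spike_controls <- function(table, truth,
                           roles = c("non_targeting", "lethal"),
                           wells_per_role = 1L, plate_effects = NULL,
                           seed = 1L) {
  if (length(roles) == 0L || wells_per_role == 0L) return(table)
  set.seed(seed)
  features <- truth$features
  L1 <- truth$feature_loadings[, 1]
  eff <- c(non_targeting = 0, lethal = truth$lethal_effect,
           pathway_pos = truth$pathway_effect,
           pathway_neg = -truth$pathway_effect)
  plates <- unique(table[, c("plate", "batch", "treatment", "time_hr",
                             "replicate")])
  new <- plates[rep(seq_len(nrow(plates)), each = length(roles) * wells_per_role), ]
  new$control_role <- rep(rep(roles, each = wells_per_role), nrow(plates))
  new$target_gene <- paste0("CTRL_SPIKE_", toupper(new$control_role))
  new$query_gene <- "CTRL_NT"
  new$target_reagent <- new$target_gene
  new$query_reagent <- "CTRL_NT"
  new$well <- stats::ave(new$plate, new$plate, FUN = seq_along) +
    max(table$well)
  pe <- if (is.null(plate_effects)) rep(0, nrow(new)) else
    plate_effects[as.character(new$plate)]
  for (fi in seq_along(features)) {
    f <- features[fi]
    base <- eff[new$control_role] * L1[f] + pe
    new[[f]] <- base + stats::rnorm(nrow(new), 0, truth$noise_sd[fi])
  }
  rbind(table, new[, names(table)])
}

#' Simulate a pi-score cube directly from interaction coefficients
#'
#' Generates condition-level pi-score measurements straight from the linear
#' interaction trajectories (skipping the well/polish stages): for every
#' (pair, feature), pi = c + sigma*time + delta*treatment + Gaussian noise,
#' one measurement per (design x biological replicate, time, treatment).
#' Useful for benchmarking the modeling stages under exactly known effect
#' sizes.
#'
#' @param interactions Data frame with columns `target`, `query`, `feature`,
#'   `c_true`, `sigma_true`, `delta_true` (e.g. the `interactions` element of
#'   a `ground_truth`).
#' @param grid A [condition_grid()].
#' @param designs Number of dsRNA designs per target (default 2; together
#'   with the replicates this gives 4 measurements per condition).
#' @param noise_sd Measurement noise SD in pi-score units.
#' @param seed Integer seed.
#' @return A `pi_cube`-shaped data frame.
#' @export
simulate_pi_cube <- function(interactions, grid = condition_grid(),
                             designs = 2L, noise_sd = 0.3, seed = 1L) {
  stopifnot(all(c("target", "query", "feature", "c_true", "sigma_true",
                  "delta_true") %in% names(interactions)))
  set.seed(seed)
  conds <- expand.grid(design = seq_len(designs),
                       replicate = seq_len(grid$biological_replicates),
                       time_hr = grid$times_hr,
                       treatment = grid$treatments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_int <- nrow(interactions)
  n_cond <- nrow(conds)
  idx <- rep(seq_len(n_int), each = n_cond)
  cc <- conds[rep(seq_len(n_cond), times = n_int), ]
  trt <- as.numeric(cc$treatment != grid$treatments[1])
  pi_true <- interactions$c_true[idx] + interactions$sigma_true[idx] *
    cc$time_hr + interactions$delta_true[idx] * trt
  cube <- data.frame(
    target_gene = interactions$target[idx],
    target_reagent = paste0(interactions$target[idx], "_d", cc$design),
    query_gene = interactions$query[idx],
    feature = interactions$feature[idx],
    treatment = cc$treatment, time_hr = cc$time_hr,
    replicate = cc$replicate,
    pi = pi_true + stats::rnorm(length(pi_true), 0, noise_sd))
  class(cube) <- c("pi_cube", "data.frame")
  cube
}
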