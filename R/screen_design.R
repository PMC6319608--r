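#' Combinatorial screen design
#'
#' Constructors and enumeration helpers for the combinatorial RNAi screen
#' layout: which genes are targets and queries, how many sequence-independent
#' dsRNA designs each has, which treatment/time/replicate conditions are
#' screened, and how plates are organised into batches.
#'
#' @name screen_design
NULL

#' Define the target and query gene sets
#'
#' @param target_genes Character vector of target gene identifiers (rows of
#'   the double-perturbation matrix).
#' @param query_genes Character vector of query gene identifiers (columns).
#'   Queries may (and in the reference design do) overlap the targets.
#' @return A `gene_set` object (list with `target_genes`, `query_genes`).
#' @examples
#' gs <- gene_set(paste0("t", 1:3), paste0("q", 1:2))
#' @export
gene_set <- function(target_genes, query_genes) {
  target_genes <- as.character(target_genes)
  query_genes <- as.character(query_genes)
  if (anyDuplicated(target_genes)) stop("duplicate target gene identifiers")
  if (anyDuplicated(query_genes)) stop("duplicate query gene identifiers")
  structure(list(target_genes = target_genes, query_genes = query_genes),
            class = "gene_set")
}

#' Describe the dsRNA reagent library
#'
#' @param designs_per_target Number of sequence-independent dsRNA designs per
#'   target gene (reference design: 2).
#' @param designs_per_query Designs per query gene (reference design: 1).
#' @param control_reagents Named character vector mapping control roles
#'   (`non_targeting`, `lethal`, `pathway_pos`, `pathway_neg`) to reagent names.
#' @return A `reagent_library` object.
#' @export
reagent_library <- function(designs_per_target = 2L, designs_per_query = 1L,
                            control_reagents = c(non_targeting = "RLUC",
                                                 lethal = "Diap1",
                                                 pathway_pos = "Dsor1",
                                                 pathway_neg = "RasGAP1")) {
  if (designs_per_target < 1L || designs_per_query < 1L)
    stop("design counts must be >= 1")
  structure(list(designs_per_target = as.integer(designs_per_target),
                 designs_per_query = as.integer(designs_per_query),
                 control_reagents = control_reagents),
            class = "reagent_library")
}

#' Define the condition grid
#'
#' Treatments are coded numerically as control = 0, drug = 1 so that a positive
#' treatment coefficient means the interaction score is higher under drug.
#' Times are hours after compound addition, carried uncentered: the model
#' intercept is then the extrapolated interaction score at time 0.
#'
#' @param treatments Character vector of treatment labels, control first.
#' @param times_hr Strictly increasing numeric vector of fixation times in
#'   hours after compound addition.
#' @param biological_replicates Number of biological replicates.
#' @return A `condition_grid` object with a `treatment_code` mapping.
#' @export
condition_grid <- function(treatments = c("control", "drug"),
                           times_hr = c(48, 72, 96),
                           biological_replicates = 2L) {
  if (length(treatments) < 1L) stop("need at least one treatment")
  if (length(times_hr) < 2L)
    stop("need at least two time points for time-coefficient identifiability")
  if (any(diff(times_hr) <= 0)) stop("times_hr must be strictly increasing")
  code <- seq_along(treatments) - 1L
  names(code) <- treatments
  structure(list(treatments = treatments, treatment_code = code,
                 times_hr = as.numeric(times_hr),
                 biological_replicates = as.integer(biological_replicates)),
            class = "condition_grid")
}

#' Define the plate batching plan
#'
#' @param plates_per_batch Plates in one screening batch (reference: 80).
#' @param batches Number of batches (reference: 12).
#' @param wells_per_plate Wells per plate (reference: 384).
#' @param control_plates_per_batch Per-batch plates carrying only single
#'   knockdowns/controls (reference: 2).
#' @return A `batch_plan` object.
#' @export
batch_plan <- function(plates_per_batch = 80L, batches = 12L,
                       wells_per_plate = 384L, control_plates_per_batch = 2L) {
  if (plates_per_batch < 1L || batches < 1L) stop("counts must be >= 1")
  structure(list(plates_per_batch = as.integer(plates_per_batch),
                 batches = as.integer(batches),
                 wells_per_plate = as.integer(wells_per_plate),
                 control_plates_per_batch = as.integer(control_plates_per_batch)),
            class = "batch_plan")
}

#' Enumerate all target-query gene pairs
#'
#' Deterministic target-major, query-minor order. Pairs with target == query
#' are retained and flagged as self-pairs (excluded from interaction
#' statistics downstream by default).
#'
#' @param genes A [gene_set()].
#' @return Data frame with columns `target`, `query`, `self_pair`.
#' @examples
#' nrow(enumerate_gene_pairs(gene_set(paste0("g", 1:168), paste0("g", 1:76))))
#' @export
enumerate_gene_pairs <- function(genes) {
  stopifnot(inherits(genes, "gene_set"))
  if (length(genes$target_genes) == 0L || length(genes$query_genes) == 0L)
    return(data.frame(target = character(), query = character(),
                      self_pair = logical()))
  df <- expand.grid(query = genes$query_genes, target = genes$target_genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("target", "query")]
  df$self_pair <- df$target == df$query
  rownames(df) <- NULL
  df
}

#' Enumerate dsRNA design combinations
#'
#' Expands gene pairs into reagent-level combinations. Reagent names follow
#' the convention `<gene>_d<design>`.
#'
#' @param genes A [gene_set()].
#' @param lib A [reagent_library()].
#' @return Data frame with columns `target`, `query`, `target_reagent`,
#'   `query_reagent`, `self_pair`.
#' @export
enumerate_reagent_combinations <- function(genes, lib) {
  stopifnot(inherits(genes, "gene_set"), inherits(lib, "reagent_library"))
  pairs <- enumerate_gene_pairs(genes)
  if (nrow(pairs) == 0L)
    return(cbind(pairs[0, ],
                 data.frame(target_reagent = character(),
                            query_reagent = character())))
  td <- seq_len(lib$designs_per_target)
  qd <- seq_len(lib$designs_per_query)
  grid <- expand.grid(qdes = qd, tdes = td, row = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE)
  out <- pairs[grid$row, c("target", "query", "self_pair")]
  out$target_reagent <- paste0(out$target, "_d", grid$tdes)
  out$query_reagent <- paste0(out$query, "_d", grid$qdes)
  rownames(out) <- NULL
  out[, c("target", "query", "target_reagent", "query_reagent", "self_pair")]
}

#' Enumerate condition-level interaction measurements
#'
#' @param pairs Data frame of gene pairs from [enumerate_gene_pairs()].
#' @param grid A [condition_grid()].
#' @return Data frame with one row per (pair, treatment, time).
#' @export
enumerate_measurements <- function(pairs, grid) {
  stopifnot(inherits(grid, "condition_grid"))
  if (nrow(pairs) == 0L)
    return(data.frame(target = character(), query = character(),
                      treatment = character(), time_hr = numeric()))
  cond <- expand.grid(time_hr = grid$times_hr, treatment = grid$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- expand.grid(cond_row = seq_len(nrow(cond)),
                     pair_row = seq_len(nrow(pairs)), KEEP.OUT.ATTRS = FALSE)
  out <- cbind(pairs[idx$pair_row, c("target", "query"), drop = FALSE],
               cond[idx$cond_row, c("treatment", "time_hr"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Assign plates to batches and conditions
#'
#' Each batch is dedicated to a single (treatment, time, replicate) condition;
#' batches must divide evenly over the condition grid.
#'
#' @param plan A [batch_plan()].
#' @param grid A [condition_grid()].
#' @return List with `total_plates` and a data frame `plates` mapping
#'   plate -> (batch, treatment, time_hr, replicate).
#' @export
plan_plates <- function(plan, grid) {
  stopifnot(inherits(plan, "batch_plan"), inherits(grid, "condition_grid"))
  n_cond <- length(grid$treatments) * length(grid$times_hr) *
    grid$biological_replicates
  if (plan$batches %% n_cond != 0L)
    stop(sprintf("batches (%d) not divisible across the %d-cell condition grid",
                 plan$batches, n_cond))
  cond <- expand.grid(replicate = seq_len(grid$biological_replicates),
                      time_hr = grid$times_hr, treatment = grid$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  batches_per_cond <- plan$batches %/% n_cond
  batch_cond <- cond[rep(seq_len(nrow(cond)), each = batches_per_cond), ]
  plates <- data.frame(
    plate = seq_len(plan$batches * plan$plates_per_batch),
    batch = rep(seq_len(plan$batches), each = plan$plates_per_batch))
  plates <- cbind(plates, batch_cond[plates$batch, , drop = FALSE])
  rownames(plates) <- NULL
  list(total_plates = nrow(plates),
       plates = plates[, c("plate", "batch", "treatment", "time_hr", "replicate")])
}

#' Full screen design bundle
#'
#' Convenience constructor tying gene set, reagent library, condition grid and
#' batch plan together; used by the simulator and the pipeline driver.
#'
#' @param genes A [gene_set()].
#' @param lib A [reagent_library()].
#' @param grid A [condition_grid()].
#' @param plan Optional [batch_plan()]; if `NULL` a minimal plan with one
#'   plate per condition is derived.
#' @return A `screen_design` object.
#' @export
screen_design <- function(genes, lib = reagent_library(),
                          grid = condition_grid(), plan = NULL) {
  if (is.null(plan)) {
    n_cond <- length(grid$treatments) * length(grid$times_hr) *
      grid$biological_replicates
    plan <- batch_plan(plates_per_batch = 1L, batches = n_cond,
                       wells_per_plate = 384L, control_plates_per_batch = 0L)
  }
  structure(list(genes = genes, lib = lib, grid = grid, plan = plan),
            class = "screen_design")
}
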