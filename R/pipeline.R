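#' Read a well-level feature table
#'
#' Reads delimited text (TSV by default, CSV accepted) with the required
#' annotation columns `plate`, `well`, `target_reagent`, `query_reagent`,
#' `treatment`, `time_hr`, `replicate`; `control_role`, `batch`,
#' `target_gene`, `query_gene` are optional (gene columns are derived from
#' the reagent naming convention `<gene>_d<design>` when absent). All other
#' numeric columns are treated as features.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) infers from the extension.
#' @return Well table data frame with attribute `features`.
#' @export
read_well_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("plate", "well", "target_reagent", "query_reagent",
                "treatment", "time_hr", "replicate")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("well table is missing required column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(tab$plate, tab$well)
  if (anyDuplicated(key))
    stop("duplicated (plate, well) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!"control_role" %in% names(tab)) tab$control_role <- NA_character_
  tab$control_role[tab$control_role %in% c("", "NA")] <- NA_character_
  if (!"batch" %in% names(tab)) tab$batch <- 1L
  if (!"target_gene" %in% names(tab))
    tab$target_gene <- sub("_d[0-9]+$", "", tab$target_reagent)
  if (!"query_gene" %in% names(tab))
    tab$query_gene <- sub("_d[0-9]+$", "", tab$query_reagent)
  meta <- c(required, "control_role", "batch", "target_gene", "query_gene")
  feats <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                   c(meta, "time_hr", "replicate", "plate", "well", "batch"))
  attr(tab, "features") <- feats
  tab
}

#' Write a well table (or any pipeline table) as TSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_well_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param alpha FDR threshold for significance and classification.
#' @param z_threshold,pcc_threshold Plate QC gates.
#' @param redundancy_threshold,reproducibility_threshold Feature selection
#'   gates.
#' @param network_threshold Profile-correlation edge threshold.
#' @param fdr_scope "feature" or "pooled".
#' @param qc_feature Reference feature for plate QC (default: first feature).
#' @param seed Integer seed recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.1, z_threshold = 0.3, pcc_threshold = 0.6,
                       redundancy_threshold = 0.7,
                       reproducibility_threshold = 0.6,
                       network_threshold = 0.5, fdr_scope = "feature",
                       qc_feature = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, z_threshold = z_threshold,
                 pcc_threshold = pcc_threshold,
                 redundancy_threshold = redundancy_threshold,
                 reproducibility_threshold = reproducibility_threshold,
                 network_threshold = network_threshold,
                 fdr_scope = fdr_scope, qc_feature = qc_feature,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a normalized well table
#'
#' Stages: plate QC and masking -> feature selection inputs (replicate
#' correlation) -> pi-scores -> per-condition moderated-t interaction calls
#' -> MODIFI fits and classification -> delta-profile correlation network.
#' Every artifact carries the seed and thresholds used.
#'
#' @param table Normalized (additive-scale) well table.
#' @param features Feature columns to analyze; default from
#'   `attr(table, "features")`.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   as TSV/JSON/GraphML.
#' @return List with `qc`, `masked_fraction`, `pi_cube`, `interaction_calls`,
#'   `modifi`, `edges`, `config`.
#' @export
run_pipeline <- function(table, features = NULL, config = run_config(),
                         out_dir = NULL) {
  if (is.null(features)) features <- attr(table, "features")
  if (is.null(features) || !length(features))
    stop("stage preprocess: no feature columns identified")
  qc_feature <- if (is.null(config$qc_feature)) features[1] else
    config$qc_feature
  qc <- tryCatch(
    qc_plates(table, qc_feature, z_threshold = config$z_threshold,
              pcc_threshold = config$pcc_threshold),
    error = function(e) stop("stage qc: ", conditionMessage(e)))
  masked <- mask_plates(table, qc)
  cube <- tryCatch(
    pi_scores(masked$table, features),
    error = function(e) stop("stage pi: ", conditionMessage(e)))
  calls <- tryCatch(
    call_interactions(cube),
    error = function(e) stop("stage pi: ", conditionMessage(e)))
  fdr_scope <- if (config$fdr_scope == "pooled") "pooled" else "feature"
  res <- tryCatch(
    run_modifi(cube, alpha = config$alpha, fdr_scope = fdr_scope,
               interaction_calls = calls),
    error = function(e) stop("stage modifi: ", conditionMessage(e)))
  prof <- delta_profiles(res)
  edges <- if (nrow(prof) >= 2) {
    corr <- profile_correlation(prof)
    build_network(corr, threshold = config$network_threshold)
  } else data.frame()
  out <- list(qc = qc, masked_fraction = masked$masked_fraction,
              pi_cube = cube, interaction_calls = calls, modifi = res,
              edges = edges, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_well_table(qc, file.path(out_dir, "qc_report.tsv"))
    write_well_table(as.data.frame(cube), file.path(out_dir, "pi_scores.tsv"))
    write_well_table(calls, file.path(out_dir, "interaction_calls.tsv"))
    write_well_table(res, file.path(out_dir, "modifi_results.tsv"))
    if (nrow(edges))
      write_well_table(edges, file.path(out_dir, "network_edges.tsv"))
    meta <- c(unclass(config),
              list(features = features, qc_feature = qc_feature,
                   masked_fraction = masked$masked_fraction,
                   n_pairs = length(unique(paste(res$target_gene,
                                                 res$query_gene)))))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
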