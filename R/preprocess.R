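#' Trimmed-mean aggregation of single-cell values
#'
#' Aggregates the cells of one well into a robust per-well summary: the mean
#' over values with the lowest and highest `q` fractions removed, and the
#' standard deviation over the same trimmed set. Trimming guards against
#' segmentation outliers.
#'
#' @param values Numeric vector (single-cell measurements of one well).
#' @param q Trim fraction in [0, 0.5); default 0.01.
#' @return List with `mean` and `sd` (both `NA` for an empty input).
#' @export
trimmed_mean_aggregate <- function(values, q = 0.01) {
  stopifnot(q >= 0, q < 0.5)
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(list(mean = NA_real_, sd = NA_real_))
  n <- length(values)
  k <- floor(n * q)
  kept <- sort(values)
  if (k > 0L) kept <- kept[(k + 1L):(n - k)]
  list(mean = mean(kept), sd = stats::sd(kept))
}

#' Generalized logarithm
#'
#' Variance-stabilizing transform `ln((x + sqrt(x^2 + c^2)) / 2)`, defined for
#' all real x, monotone increasing, tending to `ln(x)` for x >> c.
#'
#' @param x Numeric vector.
#' @param c Non-negative offset; conventionally the 3% quantile of the
#'   feature's value distribution.
#' @return Transformed vector.
#' @examples
#' glog(3, 4)  # log(4)
#' @export
glog <- function(x, c) {
  stopifnot(all(c >= 0))
  log((x + sqrt(x^2 + c^2)) / 2)
}

#' Inverse of the generalized logarithm
#'
#' @param y Values on the glog scale.
#' @param c Offset used in the forward transform.
#' @return Raw-scale values such that `glog(glog_inverse(y, c), c) == y`.
#' @export
glog_inverse <- function(y, c) {
  # x = e^y - c^2 / (4 e^y)
  e <- exp(y)
  e - c^2 / (4 * e)
}

#' Robust Z transformation
#'
#' Centers by the median and scales by the median absolute deviation:
#' `(x - median(x)) / mad(x)`.
#'
#' @param values Numeric vector; `NA` dropped from center/scale estimation.
#' @param mad_constant MAD consistency constant (default 1.4826, consistent
#'   with the Gaussian standard deviation).
#' @return List with `values` (standardized vector, `NA` if degenerate),
#'   `center`, `scale`, `degenerate` flag (MAD == 0).
#' @export
robust_z <- function(values, mad_constant = 1.4826) {
  ctr <- stats::median(values, na.rm = TRUE)
  scl <- stats::mad(values, constant = mad_constant, na.rm = TRUE)
  if (!is.finite(scl) || scl == 0)
    return(list(values = rep(NA_real_, length(values)),
                center = ctr, scale = scl, degenerate = TRUE))
  list(values = (values - ctr) / scl, center = ctr, scale = scl,
       degenerate = FALSE)
}

#' Per-plate normalization against non-targeting controls
#'
#' Divides each feature on each plate by the median of that plate's
#' non-targeting control wells. A plate whose control median is zero is left
#' unscaled and flagged.
#'
#' @param table A well table (see [read_well_table()]); control wells are the
#'   rows whose `control_role` equals `control_role`.
#' @param features Character vector of feature column names.
#' @param control_role Role label of the normalizing controls
#'   (default "non_targeting").
#' @return List with `table` (normalized) and `flags` (data frame of
#'   plate x feature combinations with zero control median).
#' @export
control_normalize <- function(table, features, control_role = "non_targeting") {
  stopifnot(all(features %in% names(table)))
  flags <- list()
  for (pl in unique(table$plate)) {
    on_plate <- table$plate == pl
    is_ctrl <- on_plate & !is.na(table$control_role) &
      table$control_role == control_role
    if (!any(is_ctrl))
      stop(sprintf("plate '%s' has no %s control wells", pl, control_role))
    for (f in features) {
      med <- stats::median(table[[f]][is_ctrl], na.rm = TRUE)
      if (is.na(med) || med == 0) {
        flags[[length(flags) + 1L]] <- data.frame(plate = pl, feature = f)
      } else {
        table[[f]][on_plate] <- table[[f]][on_plate] / med
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(plate = character(), feature = character())
  list(table = table, flags = flags)
}

#' B-score normalization of a plate matrix
#'
#' Median-polish residuals of the (row x column) plate layout divided by their
#' median absolute deviation; removes additive row/column (edge) artifacts and
#' scales to MAD units.
#'
#' @param plate_matrix Numeric matrix of well values (rows x columns of one
#'   plate, one feature); `NA` allowed.
#' @param mad_constant MAD consistency constant.
#' @param ... Passed to [median_polish()].
#' @return Matrix of B-scores (same dimensions).
#' @export
b_score <- function(plate_matrix, mad_constant = 1.4826, ...) {
  stopifnot(is.matrix(plate_matrix), nrow(plate_matrix) >= 2,
            ncol(plate_matrix) >= 2)
  fit <- median_polish(plate_matrix, ...)
  s <- stats::mad(fit$residuals, constant = mad_constant, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate plate: residual MAD is zero")
  fit$residuals / s
}

#' Normalize a raw well table to the additive analysis scale
#'
#' Applies the combinatorial-screen normalization chain per feature:
#' per-plate division by the non-targeting control median, generalized
#' logarithm with `c` the 3% quantile of the feature's values, then a robust Z
#' transformation (per plate by default).
#'
#' @param table Raw well table.
#' @param features Feature column names.
#' @param glog_quantile Quantile defining the glog offset `c` (default 0.03).
#' @param z_scope Scope of the robust Z step: "plate" (default) or "screen".
#' @param mad_constant MAD consistency constant.
#' @return List with `table` (normalized), `params` (a `transform_params`
#'   list: per-feature glog offsets, per-scope centers/scales),
#'   `flags` (control-median flags), `degenerate` (features with MAD 0).
#' @export
preprocess_well_table <- function(table, features,
                                  glog_quantile = 0.03,
                                  z_scope = c("plate", "screen"),
                                  mad_constant = 1.4826) {
  z_scope <- match.arg(z_scope)
  cn <- control_normalize(table, features)
  table <- cn$table
  glog_c <- vapply(features, function(f)
    max(0, stats::quantile(table[[f]], glog_quantile, na.rm = TRUE,
                           names = FALSE)), numeric(1))
  degenerate <- character()
  centers <- list()
  for (f in features) {
    table[[f]] <- glog(table[[f]], glog_c[[f]])
    if (z_scope == "screen") {
      z <- robust_z(table[[f]], mad_constant)
      if (z$degenerate) degenerate <- c(degenerate, f)
      table[[f]] <- z$values
      centers[[f]] <- data.frame(scope = "screen", center = z$center,
                                 scale = z$scale)
    } else {
      rows <- split(seq_len(nrow(table)), table$plate)
      cc <- lapply(names(rows), function(pl) {
        idx <- rows[[pl]]
        z <- robust_z(table[[f]][idx], mad_constant)
        table[[f]][idx] <<- z$values
        data.frame(scope = pl, center = z$center, scale = z$scale,
                   degenerate = z$degenerate)
      })
      cc <- do.call(rbind, cc)
      if (any(cc$degenerate)) degenerate <- c(degenerate, f)
      centers[[f]] <- cc
    }
  }
  params <- list(glog_c = glog_c, z_scope = z_scope,
                 mad_constant = mad_constant, centers = centers)
  class(params) <- "transform_params"
  list(table = table, params = params, flags = cn$flags,
       degenerate = unique(degenerate))
}

#' Genome-wide screen transform preset
#'
#' Alternative normalization used for single-knockdown genome-wide screens:
#' the feature's minimum is added to each value before `log(x + 1)`, then
#' each plate matrix is B-score normalized.
#'
#' @param values Numeric vector (one feature across the screen).
#' @return Shifted-log transformed vector.
#' @export
shift_log_transform <- function(values) {
  m <- min(values, na.rm = TRUE)
  log1p(values + m)
}
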