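#' Replicate outlier analysis
#'
#' Identifies aberrant records within each (strain, phenotype, plate) group.
#' All well x replicate curves of a group are interpolated to the group's
#' common grid, the pairwise Pearson correlation matrix is computed, and each
#' member is scored by the median of its correlations with every other
#' member. Members with a median correlation below the threshold are flagged.
#' The group-level median of all pairwise correlations is reported alongside
#' for reference.
#'
#' Groups of size 1 are skipped with a warning (no pairwise correlation
#' exists). A zero-variance (flat) member has undefined Pearson correlation;
#' it is reported with \code{degenerate = TRUE}, \code{median_correlation =
#' NA}, and flagged: a flat replicate among growing replicates is aberrant by
#' definition.
#'
#' @param rs A non-empty \code{\link{record_set}}.
#' @param threshold Pearson correlation threshold in [-1, 1]; members with a
#'   median correlation strictly below it are flagged. Default 0.5.
#' @return Object of class \code{outlier_report}: a data frame with columns
#'   \code{strain}, \code{phenotype}, \code{plate}, \code{well},
#'   \code{replicate}, \code{median_correlation}, \code{group_median},
#'   \code{degenerate}, \code{flagged}.
#' @export
outlier_analysis <- function(rs, threshold = 0.5) {
  stopifnot(inherits(rs, "record_set"))
  if (length(rs) == 0L) stop("empty record set")
  if (!is.numeric(threshold) || threshold < -1 || threshold > 1)
    stop("threshold must be a Pearson correlation in [-1, 1]")
  key <- with(rs$meta, paste(strain, phenotype, plate, sep = "|"))
  groups <- split(seq_len(length(rs)), factor(key, levels = unique(key)))
  singletons <- names(groups)[lengths(groups) == 1L]
  if (length(singletons) > 0L) {
    warning(length(singletons),
            " group(s) of size 1 skipped (no pairwise correlation): ",
            paste(utils::head(singletons, 5L), collapse = "; "),
            if (length(singletons) > 5L) " ..." else "")
    groups <- groups[lengths(groups) > 1L]
  }
  rows <- lapply(groups, function(idx) {
    curves <- rs$curves[idx]
    grid <- common_grid(curves)
    m <- resample_matrix(curves, grid)        # members x time
    sds <- apply(m, 1, stats::sd)
    degen <- sds == 0
    cm <- suppressWarnings(stats::cor(t(m)))  # members x members
    med <- vapply(seq_along(idx), function(i) {
      if (degen[i]) return(NA_real_)
      stats::median(cm[i, -i], na.rm = TRUE)
    }, numeric(1))
    off <- cm[upper.tri(cm)]
    grp_med <- if (all(is.na(off))) NA_real_ else
      stats::median(off, na.rm = TRUE)
    data.frame(rs$meta[idx, c("strain", "phenotype", "plate", "well",
                              "replicate")],
               median_correlation = med,
               group_median = grp_med,
               degenerate = degen,
               flagged = degen | (!is.na(med) & med < threshold),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    out <- data.frame(strain = character(), phenotype = character(),
                      plate = character(), well = character(),
                      replicate = integer(),
                      median_correlation = numeric(),
                      group_median = numeric(), degenerate = logical(),
                      flagged = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("outlier_report", class(out))
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier analysis: %d records in %d groups, threshold %g\n",
              nrow(x), length(unique(paste(x$strain, x$phenotype, x$plate))),
              attr(x, "threshold")))
  cat(sprintf("  flagged: %d (%d degenerate)\n", sum(x$flagged),
              sum(x$degenerate)))
  if (sum(x$flagged) > 0L) print.data.frame(x[x$flagged, ], row.names = FALSE)
  invisible(x)
}

#' Negative-control quantile analysis
#'
#' Estimates the inherent noise band of the assay from negative-control
#' wells. All control curves are resampled to their common grid and, for each
#' requested quantile level, the empirical quantile across the controls is
#' computed at every time point (linear interpolation between order
#' statistics, the R default, type 7). The maximum of each quantile curve
#' over time is reported as a candidate signal/noise threshold; no automatic
#' boundary is chosen. Non-negative control wells, if provided, get the same
#' quantile curves for overlay.
#'
#' @param neg Non-empty \code{\link{record_set}} of negative-control wells.
#' @param non_neg Optional \code{record_set} of non-negative-control wells.
#' @param levels Quantile levels, all in (0, 1). Default
#'   \code{c(0.05, 0.25, 0.5, 0.75, 0.95)}, bracketing the noise band.
#' @return Object of class \code{quantile_curves}: list with \code{grid},
#'   \code{levels}, \code{curves} (matrix, levels x time),
#'   \code{candidate_thresholds} (per level, max over time), \code{n_controls}
#'   and optionally \code{non_neg} (the overlay's \code{curves} matrix).
#' @export
negative_controls_analysis <- function(neg, non_neg = NULL,
                                       levels = c(0.05, 0.25, 0.5,
                                                  0.75, 0.95)) {
  stopifnot(inherits(neg, "record_set"))
  if (length(neg) == 0L) stop("empty negative-control set")
  if (any(levels <= 0 | levels >= 1)) stop("quantile levels must be in (0,1)")
  levels <- sort(levels)
  if (length(neg) == 1L)
    warning("single negative control: all quantile curves equal that curve")
  grid <- common_grid(neg$curves)
  m <- resample_matrix(neg$curves, grid)  # controls x time
  qc <- apply(m, 2, stats::quantile, probs = levels, names = FALSE, type = 7)
  qc <- matrix(qc, nrow = length(levels),
               dimnames = list(paste0("q", levels), NULL))
  out <- list(grid = grid, levels = levels, curves = qc,
              candidate_thresholds = apply(qc, 1, max),
              n_controls = length(neg))
  if (!is.null(non_neg) && length(non_neg) > 0L) {
    mn <- resample_matrix(non_neg$curves, grid)
    qn <- apply(mn, 2, stats::quantile, probs = levels, names = FALSE,
                type = 7)
    out$non_neg <- matrix(qn, nrow = length(levels),
                          dimnames = list(paste0("q", levels), NULL))
  }
  structure(out, class = "quantile_curves")
}

#' @export
print.quantile_curves <- function(x, ...) {
  cat(sprintf(
    "Negative-control quantile curves: %d controls, %d time points\n",
    x$n_controls, length(x$grid)))
  cat("candidate signal/noise thresholds (max over time per level):\n")
  print(round(x$candidate_thresholds, 4))
  invisible(x)
}

#' Quantile curves as a report table
#'
#' @param qc A \code{\link{negative_controls_analysis}} result.
#' @return Data frame: \code{time_minutes} plus one column per level.
#' @export
quantile_table <- function(qc) {
  stopifnot(inherits(qc, "quantile_curves"))
  df <- data.frame(time_minutes = as.numeric(qc$grid), t(qc$curves))
  names(df)[-1] <- rownames(qc$curves)
  df
}
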