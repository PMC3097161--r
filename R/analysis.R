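record_labels <- function(rs) {
  with(rs$meta, paste(strain, phenotype, plate, well, replicate, sep = "|"))
}

#' Pairwise Pearson correlation matrix of kinetic profiles
#'
#' Computes the full symmetric Pearson correlation matrix between all
#' selected strain/phenotype/plate/well/replicate profiles, after
#' interpolating every curve to the joint common grid. Zero-variance records
#' have undefined correlation: their row and column are \code{NA} and a
#' warning is raised.
#'
#' @param rs A \code{\link{record_set}} with at least 2 records and
#'   overlapping time ranges.
#' @return Object of class \code{correlation_matrix}: list with
#'   \code{labels} (record keys, \code{strain|phenotype|plate|well|replicate})
#'   and \code{matrix} (square, symmetric, diagonal 1 for non-degenerate
#'   records).
#' @export
correlation_matrix <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  if (length(rs) < 2L) stop("need at least 2 records for a correlation matrix")
  grid <- common_grid(rs$curves)
  m <- resample_matrix(rs$curves, grid)
  degen <- apply(m, 1, stats::sd) == 0
  if (any(degen))
    warning(sum(degen), " zero-variance record(s); their rows/columns are NA")
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[degen, ] <- NA_real_
  cm[, degen] <- NA_real_
  diag(cm)[!degen] <- 1
  labels <- record_labels(rs)
  dimnames(cm) <- list(labels, labels)
  structure(list(labels = labels, matrix = cm, degenerate = degen),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d profiles", nrow(x$matrix),
              ncol(x$matrix)))
  if (any(x$degenerate)) cat(sprintf(" (%d degenerate)", sum(x$degenerate)))
  cat("\n")
  if (nrow(x$matrix) <= 8L) print(round(x$matrix, 3))
  invisible(x)
}

#' Correlation matrix as a report table
#'
#' @param cm A \code{\link{correlation_matrix}}.
#' @return Data frame with a leading \code{record} label column.
#' @export
correlation_table <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  df <- data.frame(record = cm$labels, as.data.frame(cm$matrix),
                   check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the exact t-transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} referred to the t-distribution with
#' \eqn{n-2} degrees of freedom (two-sided). Perfect correlation
#' (\eqn{|r| = 1}) returns \eqn{p = 0}.
#'
#' @param x,y Numeric vectors of equal length \eqn{n \ge 3}, both
#'   non-constant.
#' @return List with elements \code{r} and \code{p}.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Growth-profile pattern
#'
#' A user-defined target shape over time, given as anchor points and treated
#' as piecewise linear between them (and resampled like any curve).
#'
#' @param times Anchor times in minutes, strictly increasing, length >= 2.
#' @param values Target intensity at each anchor.
#' @return Object of class \code{profile_pattern} (also a
#'   \code{kinetic_curve}).
#' @export
profile_pattern <- function(times, values) {
  kc <- kinetic_curve(times, values, .validate_nonneg = FALSE)
  class(kc) <- c("profile_pattern", class(kc))
  kc
}

#' Search records for a growth-profile pattern
#'
#' Compares every selected record against a user-defined profile pattern.
#' The record set's common grid is restricted to the pattern's time range;
#' pattern and records are resampled onto it and each record is scored by
#' \code{\link{pearson_with_p}} against the pattern. Raw (unscaled)
#' intensities are compared by default.
#'
#' @param rs A non-empty \code{\link{record_set}}.
#' @param pattern A \code{\link{profile_pattern}}.
#' @param scale If \code{TRUE}, z-score scale pattern and records before
#'   correlating (Pearson r is unchanged; provided for plotting on a common
#'   scale).
#' @return Object of class \code{profile_matches}: a data frame with columns
#'   \code{strain}, \code{phenotype}, \code{plate}, \code{well},
#'   \code{replicate}, \code{r}, \code{p}, \code{rank}, ordered by descending
#'   r; degenerate (flat) records get \code{r = NA} and sort last.
#' @export
profile_search <- function(rs, pattern, scale = FALSE) {
  stopifnot(inherits(rs, "record_set"), inherits(pattern, "profile_pattern"))
  if (length(rs) == 0L) stop("empty record set")
  grid <- as.numeric(common_grid(rs$curves))
  keep <- grid >= min(pattern$times) & grid <= max(pattern$times)
  if (sum(keep) < 3L)
    stop("pattern time range overlaps fewer than 3 grid points")
  grid <- grid[keep]
  pv <- resample(pattern, grid)$values
  if (scale) pv <- as.numeric(scale(pv))
  res <- lapply(rs$curves, function(k) {
    v <- resample(k, grid)$values
    if (stats::sd(v) == 0 || stats::sd(pv) == 0)
      return(list(r = NA_real_, p = NA_real_))
    pearson_with_p(if (scale) as.numeric(scale(v)) else v, pv)
  })
  out <- data.frame(rs$meta[, c("strain", "phenotype", "plate", "well",
                                "replicate")],
                    r = vapply(res, `[[`, numeric(1), "r"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  ord <- order(-out$r, na.last = TRUE)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "pattern") <- pattern
  attr(out, "grid") <- grid
  attr(out, "records") <- rs[ord]
  class(out) <- c("profile_matches", class(out))
  out
}

#' @export
print.profile_matches <- function(x, ...) {
  cat(sprintf("Profile search: %d records against a %d-anchor pattern\n",
              nrow(x), length(attr(x, "pattern")$times)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE, digits = 4)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' K-means clustering of kinetic profiles
#'
#' Interpolates all curves to the common grid, z-score scales each profile,
#' and partitions the scaled vectors into \code{k} clusters by k-means
#' (Euclidean distance). The best of \code{restarts} independent runs (by
#' within-cluster sum of squares) is kept; results are deterministic given
#' \code{seed}. Zero-variance records cannot be scaled and are excluded with
#' a warning.
#'
#' @param rs A \code{\link{record_set}} with at least \code{k} non-degenerate
#'   records.
#' @param k Number of clusters (>= 1).
#' @param seed Random seed (default 42); recorded in the result.
#' @param restarts Number of random restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per run (default 300).
#' @return Object of class \code{cluster_result}: list with \code{k},
#'   \code{labels} (data frame: record key fields, \code{cluster},
#'   \code{r_to_centroid}), \code{centroids} (k x time matrix of z-scored
#'   profiles; each row is the mean of its members' scaled vectors),
#'   \code{grid}, \code{scaled} (records x time matrix), \code{objective}
#'   (total within-cluster sum of squares), \code{seed}, and
#'   \code{excluded} (labels of degenerate records, if any).
#' @export
kmeans_cluster <- function(rs, k, seed = 42L, restarts = 10L,
                           iter_max = 300L) {
  stopifnot(inherits(rs, "record_set"))
  if (k < 1L) stop("k must be >= 1")
  grid <- common_grid(rs$curves)
  m <- resample_matrix(rs$curves, grid)
  degen <- apply(m, 1, stats::sd) == 0
  excluded <- character(0)
  if (any(degen)) {
    warning(sum(degen), " zero-variance record(s) excluded from clustering")
    excluded <- record_labels(rs)[degen]
  }
  keep <- which(!degen)
  if (length(keep) < k)
    stop("k = ", k, " exceeds the ", length(keep), " usable records")
  z <- t(apply(m[keep, , drop = FALSE], 1, function(v)
    (v - mean(v)) / stats::sd(v)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fit <- stats::kmeans(z, centers = k, nstart = restarts,
                       iter.max = iter_max)
  labels <- data.frame(rs$meta[keep, c("strain", "phenotype", "plate",
                                       "well", "replicate")],
                       cluster = fit$cluster,
                       stringsAsFactors = FALSE)
  labels$r_to_centroid <- vapply(seq_len(nrow(z)), function(i)
    stats::cor(z[i, ], fit$centers[fit$cluster[i], ]), numeric(1))
  rownames(labels) <- NULL
  structure(list(k = k, labels = labels, centroids = fit$centers,
                 grid = grid, scaled = z, objective = fit$tot.withinss,
                 seed = seed, excluded = excluded),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "K-means clustering: %d profiles into k = %d (seed %d, WSS %.4g)\n",
    nrow(x$labels), x$k, x$seed, x$objective))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}
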