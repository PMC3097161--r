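#' Common time grid for a set of curves
#'
#' Builds the evenly spaced grid onto which curves are interpolated before any
#' cross-curve calculation (correlation, clustering, averaging). The grid
#' spans the intersection of the curves' time ranges -- from the largest
#' minimum to the smallest maximum, so no curve is ever extrapolated -- and
#' has as many points as the longest member, retaining maximal resolution.
#'
#' @param curves A list of \code{\link{kinetic_curve}} objects, or a
#'   \code{\link{record_set}}.
#' @return Numeric vector of class \code{common_grid}: evenly spaced times in
#'   minutes.
#' @export
common_grid <- function(curves) {
  if (inherits(curves, "record_set")) curves <- curves$curves
  if (inherits(curves, "kinetic_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("need at least one curve")
  stopifnot(all(vapply(curves, inherits, logical(1), "kinetic_curve")))
  lo <- vapply(curves, function(k) min(k$times), numeric(1))
  hi <- vapply(curves, function(k) max(k$times), numeric(1))
  t_lo <- max(lo)
  t_hi <- min(hi)
  if (t_lo >= t_hi) {
    bad <- c(which.max(lo), which.min(hi))
    stop("curves have non-overlapping time ranges (curves ",
         paste(sort(bad), collapse = " and "), ")")
  }
  n <- max(vapply(curves, function(k) length(k$times), integer(1)))
  structure(seq(t_lo, t_hi, length.out = n), class = "common_grid")
}

#' Resample a curve onto a grid by linear interpolation
#'
#' Values are linearly interpolated between bracketing observations; grid
#' points coinciding with original times reproduce the original values
#' exactly. Extrapolation is refused.
#'
#' @param curve A \code{\link{kinetic_curve}}.
#' @param grid A \code{\link{common_grid}} or numeric vector of times
#'   (minutes) within the curve's observed range.
#' @return A \code{kinetic_curve} on the grid.
#' @export
resample <- function(curve, grid) {
  stopifnot(inherits(curve, "kinetic_curve"))
  grid <- as.numeric(grid)
  if (min(grid) < min(curve$times) || max(grid) > max(curve$times))
    stop(sprintf(
      "grid [%g, %g] extends outside the curve's time range [%g, %g]",
      min(grid), max(grid), min(curve$times), max(curve$times)))
  v <- stats::approx(curve$times, curve$values, xout = grid,
                     method = "linear", ties = "ordered")$y
  kinetic_curve(grid, v, .validate_nonneg = FALSE)
}

resample_matrix <- function(curves, grid) {
  # rows = curves, columns = grid time points
  t(vapply(curves, function(k) resample(k, grid)$values,
           numeric(length(grid))))
}

#' Average replicate records
#'
#' Resamples the group members to their common grid and takes the pointwise
#' arithmetic mean. All members must share the replicate-group key (strain,
#' phenotype, plate, well, temperature); the result inherits that key and has
#' \code{replicate = NA} with attribute \code{averaged = TRUE}.
#'
#' @param group A \code{\link{record_set}} (one replicate group) or list of
#'   \code{\link{well_record}}s.
#' @return A single averaged \code{well_record}.
#' @export
average_replicates <- function(group) {
  if (is.list(group) && !inherits(group, "record_set") &&
      all(vapply(group, inherits, logical(1), "well_record")))
    group <- record_set(group)
  stopifnot(inherits(group, "record_set"))
  if (length(group) < 1L) stop("empty replicate group")
  key_fields <- c("project", "species", "strain", "phenotype", "plate",
                  "well", "temperature")
  for (f in key_fields) {
    u <- unique(group$meta[[f]])
    if (length(u) > 1L)
      stop("mixed replicate group: field '", f, "' has values ",
           paste(u, collapse = ", "))
  }
  grid <- common_grid(group$curves)
  m <- resample_matrix(group$curves, grid)
  avg <- kinetic_curve(as.numeric(grid), colMeans(m),
                       .validate_nonneg = FALSE)
  rec <- well_record(group$meta$project[1], group$meta$species[1],
                     group$meta$strain[1], group$meta$phenotype[1],
                     group$meta$plate[1], group$meta$well[1],
                     NA_integer_, group$meta$temperature[1], avg)
  attr(rec, "averaged") <- TRUE
  rec
}

#' Z-score scale a curve
#'
#' Centres and scales the intensity values to mean 0 and sample standard
#' deviation 1 (denominator n - 1). A zero-variance (flat) curve maps to all
#' zeros and carries attribute \code{degenerate = TRUE}.
#'
#' @param curve A \code{\link{kinetic_curve}}.
#' @return A \code{kinetic_curve} of scaled values (negative values allowed).
#' @export
zscore_scale <- function(curve) {
  stopifnot(inherits(curve, "kinetic_curve"))
  s <- stats::sd(curve$values)
  if (s == 0) {
    out <- kinetic_curve(curve$times, rep(0, length(curve$times)),
                         .validate_nonneg = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  kinetic_curve(curve$times, (curve$values - mean(curve$values)) / s,
                .validate_nonneg = FALSE)
}

#' Scalar summary of a kinetic curve
#'
#' Reduces a curve to a single growth statistic:
#' \describe{
#'   \item{auc}{trapezoid integral of intensity over time
#'     (intensity x minutes) -- the default, integrating the whole kinetic
#'     response;}
#'   \item{max}{maximum intensity reached;}
#'   \item{endpoint}{intensity at the last time point.}
#' }
#'
#' @param curve A \code{\link{kinetic_curve}}.
#' @param method One of \code{"auc"}, \code{"max"}, \code{"endpoint"}.
#' @return A scalar.
#' @export
curve_summary <- function(curve, method = c("auc", "max", "endpoint")) {
  stopifnot(inherits(curve, "kinetic_curve"))
  method <- match.arg(method)
  switch(method,
         auc = {
           t <- curve$times; v <- curve$values; n <- length(t)
           sum(diff(t) * (v[-1] + v[-n]) / 2)
         },
         max = max(curve$values),
         endpoint = curve$values[length(curve$values)])
}
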