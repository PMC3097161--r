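#' Figure output specification
#'
#' @param path Output file path.
#' @param format Vector-graphic format: \code{"pdf"} (default), \code{"ps"}
#'   or \code{"svg"}. Multi-panel outputs go to a single multi-page file for
#'   pdf/ps; the svg device writes one file per page (a \code{\%03d} page
#'   counter is added to the name).
#' @param shading Categorical shading of panels/traces:
#'   \code{"by_phenotype"} (default), \code{"by_strain"} or \code{"by_both"}.
#' @param per_page Panels per page as \code{c(rows, cols)}; default 2 x 2.
#' @return Object of class \code{plot_spec}.
#' @export
plot_spec <- function(path, format = c("pdf", "ps", "svg"),
                      shading = c("by_phenotype", "by_strain", "by_both"),
                      per_page = c(2L, 2L)) {
  format <- match.arg(format)
  shading <- match.arg(shading)
  stopifnot(length(per_page) == 2L, all(per_page >= 1L))
  structure(list(path = path, format = format, shading = shading,
                 per_page = as.integer(per_page)), class = "plot_spec")
}

open_device <- function(spec, width = 8, height = 6) {
  switch(spec$format,
         pdf = grDevices::pdf(spec$path, width = width, height = height,
                              onefile = TRUE),
         ps = grDevices::postscript(spec$path, width = width,
                                    height = height, paper = "special",
                                    horizontal = FALSE, onefile = TRUE),
         svg = {
           p <- sub("\\.svg$", "_%03d.svg", spec$path)
           if (identical(p, spec$path)) p <- paste0(spec$path, "_%03d.svg")
           grDevices::svg(p, width = width, height = height)
         })
}

shade_groups <- function(meta, shading) {
  f <- switch(shading,
              by_phenotype = meta$phenotype,
              by_strain = meta$strain,
              by_both = paste(meta$strain, meta$phenotype, sep = " / "))
  factor(f, levels = unique(f))
}

shade_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2L), palette = "Dark 3")[seq_len(n)]
}

panel_title <- function(meta_row) {
  sprintf("%s %s  %s/%s rep %s", meta_row$strain, meta_row$phenotype,
          meta_row$plate, meta_row$well,
          ifelse(is.na(meta_row$replicate), "avg", meta_row$replicate))
}

#' Bar plots of kinetic profiles
#'
#' One panel per record, one bar per time point with height equal to the
#' intensity reading -- the classic raw growth-profile view. All panels go
#' into a single multi-page vector file, shaded by phenotype, strain or both.
#'
#' @param rs A non-empty \code{\link{record_set}}.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
bar_plots <- function(rs, spec) {
  stopifnot(inherits(rs, "record_set"), inherits(spec, "plot_spec"))
  if (length(rs) == 0L) stop("empty record set")
  groups <- shade_groups(rs$meta, spec$shading)
  cols <- shade_palette(nlevels(groups))
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = spec$per_page, mar = c(3.5, 3.5, 2.5, 0.5),
                mgp = c(2.2, 0.7, 0))
  for (i in seq_len(length(rs))) {
    k <- rs$curves[[i]]
    graphics::barplot(k$values, col = cols[as.integer(groups[i])],
                      border = NA, space = 0,
                      names.arg = NULL, xlab = "time (h)",
                      ylab = "intensity")
    nt <- length(k$times)
    at <- pretty(c(1, nt))
    at <- at[at >= 1 & at <= nt]
    graphics::axis(1, at = at - 0.5, labels = round(k$times[at] / 60, 1))
    graphics::title(main = panel_title(rs$meta[i, ]), cex.main = 0.9)
  }
  invisible(spec$path)
}

#' Plot negative-control quantile curves
#'
#' One trace per quantile level across time, with a horizontal line at each
#' candidate signal/noise threshold (the per-level maximum over time) and,
#' if present, dashed overlays for the non-negative controls.
#'
#' @param qc A \code{\link{negative_controls_analysis}} result.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
plot_quantiles <- function(qc, spec) {
  stopifnot(inherits(qc, "quantile_curves"), inherits(spec, "plot_spec"))
  cols <- shade_palette(length(qc$levels))
  open_device(spec)
  on.exit(grDevices::dev.off())
  h <- as.numeric(qc$grid) / 60
  ylim <- range(qc$curves, qc$non_neg)
  graphics::matplot(h, t(qc$curves), type = "l", lty = 1, col = cols,
                    xlab = "time (h)", ylab = "intensity", ylim = ylim,
                    main = sprintf("Negative-control quantile curves (n = %d)",
                                   qc$n_controls))
  graphics::abline(h = qc$candidate_thresholds, col = cols, lty = 3)
  if (!is.null(qc$non_neg))
    graphics::matlines(h, t(qc$non_neg), lty = 2, col = cols)
  graphics::legend("topleft", legend = paste0("q = ", qc$levels), col = cols,
                   lty = 1, cex = 0.8, bty = "n")
  invisible(spec$path)
}

#' Correlation-matrix intensity plot
#'
#' @param cm A \code{\link{correlation_matrix}}.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
plot_correlation_intensity <- function(cm, spec) {
  stopifnot(inherits(cm, "correlation_matrix"), inherits(spec, "plot_spec"))
  n <- nrow(cm$matrix)
  open_device(spec, width = 7.5, height = 7)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(cm$matrix[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("Pairwise Pearson correlation (%d profiles)",
                                 n))
  if (n <= 40L) {
    graphics::axis(1, at = seq_len(n), labels = cm$labels, las = 2,
                   cex.axis = 0.5)
    graphics::axis(2, at = seq_len(n), labels = rev(cm$labels), las = 2,
                   cex.axis = 0.5)
  }
  graphics::box()
  invisible(spec$path)
}

#' Plot profile-search matches
#'
#' One panel per record overlaying the record's curve and the user-defined
#' pattern on the search grid, annotated with the Pearson r and p-value.
#'
#' @param pm A \code{\link{profile_search}} result.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
plot_profile_matches <- function(pm, spec) {
  stopifnot(inherits(pm, "profile_matches"), inherits(spec, "plot_spec"))
  if (nrow(pm) == 0L) stop("empty profile-search result")
  rs <- attr(pm, "records")
  grid <- attr(pm, "grid")
  pat <- resample(attr(pm, "pattern"), grid)
  groups <- shade_groups(rs$meta, spec$shading)
  cols <- shade_palette(nlevels(groups))
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = spec$per_page, mar = c(3.5, 3.5, 2.5, 0.5),
                mgp = c(2.2, 0.7, 0))
  for (i in seq_len(nrow(pm))) {
    v <- resample(rs$curves[[i]], grid)$values
    graphics::plot(grid / 60, v, type = "l",
                   col = cols[as.integer(groups[i])], lwd = 2,
                   xlab = "time (h)", ylab = "intensity",
                   ylim = range(v, pat$values))
    graphics::lines(grid / 60, pat$values, lty = 2)
    graphics::title(main = sprintf("%s  r = %.3f, p = %.3g",
                                   panel_title(rs$meta[i, ]),
                                   pm$r[i], pm$p[i]), cex.main = 0.8)
  }
  invisible(spec$path)
}

#' Plot k-means clusters of z-scored profiles
#'
#' One panel per cluster: the members' z-score scaled curves in a light
#' shade with the cluster centroid overlaid.
#'
#' @param cr A \code{\link{kmeans_cluster}} result.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
plot_clusters <- function(cr, spec) {
  stopifnot(inherits(cr, "cluster_result"), inherits(spec, "plot_spec"))
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = spec$per_page, mar = c(3.5, 3.5, 2.5, 0.5),
                mgp = c(2.2, 0.7, 0))
  h <- as.numeric(cr$grid) / 60
  cols <- shade_palette(cr$k)
  for (cl in seq_len(cr$k)) {
    idx <- which(cr$labels$cluster == cl)
    graphics::matplot(h, t(cr$scaled[idx, , drop = FALSE]), type = "l",
                      lty = 1, col = "grey70",
                      xlab = "time (h)", ylab = "z-scored intensity",
                      main = sprintf("cluster %d (n = %d)", cl, length(idx)))
    graphics::lines(h, cr$centroids[cl, ], col = cols[cl], lwd = 3)
  }
  invisible(spec$path)
}

#' Strain-comparison heat map
#'
#' One page per test strain in the standard layout: rows are the 96 wells
#' (A01 at the top through H12), columns are the plates, cell colour encodes
#' the signed fold change through the symmetric transform
#' \eqn{sign(fc) \log_2 |fc|} on a diverging scale centred at no change,
#' with a fold-change colour bar at the bottom. Reported numbers are always
#' the fold changes themselves; the transform is colour mapping only.
#'
#' @param cmp A \code{\link{heatmap_compare}} result.
#' @param spec A \code{\link{plot_spec}}.
#' @return The output path, invisibly.
#' @export
plot_heatmap <- function(cmp, spec) {
  stopifnot(inherits(cmp, "comparison_result"), inherits(spec, "plot_spec"))
  if (nrow(cmp$cells) == 0L) stop("empty comparison result")
  wells <- plate_wells()
  open_device(spec, width = 8, height = 10)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(101, "Green-Brown", rev = TRUE)
  for (strain in unique(cmp$cells$test_strain)) {
    cells <- cmp$cells[cmp$cells$test_strain == strain, ]
    plates <- unique(cells$plate)
    m <- matrix(NA_real_, nrow = length(wells), ncol = length(plates),
                dimnames = list(wells, plates))
    val <- sign(cells$fc) * log2(abs(cells$fc))
    m[cbind(match(cells$well, wells), match(cells$plate, plates))] <- val
    lim <- max(abs(m), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    graphics::layout(matrix(1:2, nrow = 2), heights = c(9, 1.3))
    graphics::par(mar = c(2.5, 4, 3, 1))
    graphics::image(seq_along(plates), seq_along(wells),
                    t(m[length(wells):1, , drop = FALSE]),
                    zlim = c(-lim, lim), col = pal, axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("%s vs %s (%s fold change)", strain,
                                   cmp$parent_strain, cmp$summary_method))
    graphics::axis(1, at = seq_along(plates), labels = plates, las = 2,
                   cex.axis = 0.6)
    keep <- seq(1, length(wells), by = 8)
    graphics::axis(2, at = length(wells) + 1 - keep, labels = wells[keep],
                   las = 2, cex.axis = 0.6)
    graphics::box()
    # fold-change colour bar
    graphics::par(mar = c(2.5, 4, 0.5, 1))
    bx <- seq(-lim, lim, length.out = 101)
    graphics::image(bx, 1, matrix(bx, ncol = 1), zlim = c(-lim, lim),
                    col = pal, axes = FALSE, xlab = "", ylab = "")
    at <- pretty(c(-lim, lim))
    fc_lab <- ifelse(at >= 0, 2^at, -2^(-at))
    graphics::axis(1, at = at, labels = sprintf("%.2g", fc_lab),
                   cex.axis = 0.7)
    graphics::mtext("fold change", side = 1, line = 1.6, cex = 0.7)
    graphics::box()
  }
  invisible(spec$path)
}
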