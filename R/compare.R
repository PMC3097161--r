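#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom:
#' \deqn{t = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}, \quad
#'   df = \frac{(s_a^2/n_a + s_b^2/n_b)^2}
#'             {\frac{(s_a^2/n_a)^2}{n_a-1} + \frac{(s_b^2/n_b)^2}{n_b-1}}}
#' with sample variances and a two-sided p-value. Degenerate inputs are
#' defined: both groups zero-variance with equal means gives \eqn{t = 0,
#' p = 1}; both zero-variance with unequal means gives \eqn{p = 0} with a
#' degeneracy flag.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (d == 0) return(list(t = 0, df = na + nb - 2, p = 1,
                            degenerate = FALSE))
    return(list(t = sign(d) * Inf, df = na + nb - 2, p = 0,
                degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df),
       degenerate = FALSE)
}

#' Signed fold change
#'
#' Converts a positive test/parent ratio to the signed fold-change
#' convention: \code{fc = ratio} when \code{ratio >= 1}, \code{fc = -1/ratio}
#' when \code{ratio < 1}, so \code{|fc| >= 1} always and the sign encodes
#' direction (negative means the test strain is lower than the parent).
#' A ratio of exactly 1 maps to +1.
#'
#' @param ratio Positive finite ratio(s) of test to parent summary.
#' @return Signed fold change(s).
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be positive and finite")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Heat-map comparison of test strains against a parent strain
#'
#' The strain-contrast analysis behind the comparison heat map. For every
#' (strain, plate, well), each replicate curve is reduced to a scalar growth
#' summary (\code{\link{curve_summary}}, AUC by default). Then, per test
#' strain and well: the ratio of the mean test summary to the mean parent
#' summary, its signed fold change, and Welch's t-test between the test and
#' parent replicate summaries. Cells passing \code{p < p_max} and
#' \code{|fc| >= fc_min} form the filtered subset (defaults reproduce the
#' conventional p < 0.05 and two-fold-change screen).
#'
#' Wells with a non-positive parent mean summary are incomputable
#' (\code{NA}, warned). Wells with fewer than 2 replicates in either strain
#' report the fold change but no p-value (warned).
#'
#' @param rs A \code{\link{record_set}} containing the parent strain and at
#'   least one other strain.
#' @param parent_strain Label of the parent (reference) strain.
#' @param summary_method Curve summary statistic: \code{"auc"} (default),
#'   \code{"max"} or \code{"endpoint"}.
#' @param p_max P-value cutoff for the filtered subset (default 0.05).
#' @param fc_min Minimum absolute signed fold change for the filtered subset
#'   (default 2).
#' @param p_adjust Multiple-testing adjustment applied before filtering:
#'   \code{"none"} (default, raw p-values as in the conventional screen) or
#'   any method of \code{\link[stats]{p.adjust}} (e.g. \code{"BH"}). When
#'   set, a \code{p_adj} column is added and the filter uses it.
#' @return Object of class \code{comparison_result}: list with \code{cells}
#'   (data frame: \code{test_strain}, \code{parent_strain}, \code{plate},
#'   \code{well}, \code{phenotype}, \code{ratio}, \code{fc}, \code{t},
#'   \code{df}, \code{p}), \code{filtered} (the significant subset),
#'   and the parameters used.
#' @export
heatmap_compare <- function(rs, parent_strain,
                            summary_method = c("auc", "max", "endpoint"),
                            p_max = 0.05, fc_min = 2, p_adjust = "none") {
  stopifnot(inherits(rs, "record_set"))
  summary_method <- match.arg(summary_method)
  p_adjust <- match.arg(p_adjust, stats::p.adjust.methods)
  strains <- unique(rs$meta$strain)
  if (!(parent_strain %in% strains))
    stop("parent strain '", parent_strain, "' not present in the record set")
  tests <- setdiff(strains, parent_strain)
  if (length(tests) == 0L)
    stop("need at least one test strain besides the parent")

  summ <- vapply(rs$curves, curve_summary, numeric(1),
                 method = summary_method)
  key <- with(rs$meta, paste(strain, plate, well, sep = "|"))
  by_key <- split(seq_len(length(rs)), key)

  well_tab <- unique(rs$meta[rs$meta$strain != parent_strain,
                             c("strain", "plate", "well", "phenotype")])
  n_lowrep <- 0L; n_badparent <- 0L
  rows <- vector("list", nrow(well_tab))
  for (i in seq_len(nrow(well_tab))) {
    w <- well_tab[i, ]
    ti <- by_key[[paste(w$strain, w$plate, w$well, sep = "|")]]
    pi <- by_key[[paste(parent_strain, w$plate, w$well, sep = "|")]]
    ts <- summ[ti]; ps <- summ[pi]
    ratio <- fc <- t <- df <- p <- NA_real_
    if (length(ps) > 0L) {
      if (mean(ps) <= 0) {
        n_badparent <- n_badparent + 1L
      } else {
        ratio <- mean(ts) / mean(ps)
        if (ratio > 0) fc <- signed_fold_change(ratio)
        if (length(ts) >= 2L && length(ps) >= 2L) {
          wt <- welch_t_test(ts, ps)
          t <- wt$t; df <- wt$df; p <- wt$p
        } else n_lowrep <- n_lowrep + 1L
      }
    }
    rows[[i]] <- data.frame(test_strain = w$strain,
                            parent_strain = parent_strain,
                            plate = w$plate, well = w$well,
                            phenotype = w$phenotype,
                            ratio = ratio, fc = fc, t = t, df = df, p = p,
                            stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  if (n_badparent > 0L)
    warning(n_badparent, " cell(s) incomputable (parent mean summary <= 0)")
  if (n_lowrep > 0L)
    warning(n_lowrep, " cell(s) without p-value (fewer than 2 replicates)")
  p_screen <- cells$p
  if (p_adjust != "none") {
    cells$p_adj <- stats::p.adjust(cells$p, method = p_adjust)
    p_screen <- cells$p_adj
  }
  filtered <- cells[!is.na(p_screen) & !is.na(cells$fc) &
                      p_screen < p_max & abs(cells$fc) >= fc_min, ]
  rownames(filtered) <- NULL
  structure(list(cells = cells, filtered = filtered,
                 parent_strain = parent_strain,
                 summary_method = summary_method,
                 p_max = p_max, fc_min = fc_min, p_adjust = p_adjust),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "Strain comparison vs parent '%s' (%s summaries): %d cells\n",
    x$parent_strain, x$summary_method, nrow(x$cells)))
  cat(sprintf("  significant at p < %g, |FC| >= %g: %d\n",
              x$p_max, x$fc_min, nrow(x$filtered)))
  if (nrow(x$filtered) > 0L)
    print.data.frame(utils::head(
      x$filtered[order(x$filtered$p), ], 10L), row.names = FALSE, digits = 4)
  invisible(x)
}
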