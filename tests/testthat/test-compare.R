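test_that("Welch's t-test matches the reference implementation and handles degeneracy", {
  same <- welch_t_test(c(3, 5, 7), c(3, 5, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- welch_t_test(a, b)
  ref <- t.test(a, b)  # Welch by default
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  # antisymmetry: swapping groups negates t, preserves p
  swp <- welch_t_test(b, a)
  expect_equal(swp$t, -got$t)
  expect_equal(swp$p, got$p)

  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), sd = 2)
    g <- welch_t_test(x, y); r <- t.test(x, y)
    expect_equal(g$t, unname(r$statistic), tolerance = 1e-10)
    expect_equal(g$df, unname(r$parameter), tolerance = 1e-10)
    expect_equal(g$p, r$p.value, tolerance = 1e-10)
  }

  # both groups zero variance
  eq <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(eq$p, 1); expect_false(eq$degenerate)
  ne <- welch_t_test(c(2, 2), c(5, 5))
  expect_equal(ne$p, 0); expect_true(ne$degenerate)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("signed fold change follows the reciprocal convention", {
  expect_equal(signed_fold_change(2), 2)
  expect_equal(signed_fold_change(0.5), -2)
  expect_equal(signed_fold_change(1), 1)
  expect_equal(signed_fold_change(c(4, 0.25)), c(4, -4))
  expect_error(signed_fold_change(0), "positive")
  expect_error(signed_fold_change(-2), "positive")
  expect_error(signed_fold_change(Inf), "positive")

  # exchange property: fc(1/r) = -fc(r) for r != 1, and |fc| >= 1 always
  r <- c(0.1, 0.37, 2.2, 9)
  expect_equal(signed_fold_change(1 / r), -signed_fold_change(r))
  expect_true(all(abs(signed_fold_change(c(r, 1))) >= 1))
})

null_two_strain_rs <- function(n_wells = 3, reps = 2) {
  # test replicates identical to parent replicates for every well
  t <- seq(0, 600, by = 60)
  recs <- list()
  set.seed(81)
  for (w in seq_len(n_wells)) {
    curves <- lapply(seq_len(reps), function(r)
      kc(logistic_vals(t, A = 50 * w) + runif(length(t)), times = t))
    for (s in c("WT", "MUT"))
      for (r in seq_len(reps))
        recs <- c(recs, list(wr(strain = s, phenotype = paste0("P", w),
                                well = plate_wells()[w], replicate = r,
                                curve = curves[[r]])))
  }
  record_set(recs)
}

test_that("a null contrast yields fc = 1, p = 1 and an empty filtered set", {
  cmp <- heatmap_compare(null_two_strain_rs(), "WT")
  expect_equal(cmp$cells$fc, rep(1, 3))
  expect_equal(cmp$cells$ratio, rep(1, 3))
  expect_equal(cmp$cells$p, rep(1, 3))
  expect_equal(nrow(cmp$filtered), 0L)
})

test_that("fold change is scale invariant and strain exchange flips its sign", {
  exp <- generate_experiment(list(plates = "PM01", wells_per_plate = 6L,
                                  replicates = 3L, duration_h = 24,
                                  planted_ratios = data.frame(
                                    plate = "PM01", well = "A02",
                                    ratio = 3)),
                             seed = 5)
  rs <- exp$records
  cmp <- heatmap_compare(rs, "WT")

  # scaling every curve by c > 0 changes neither fc nor p
  rs_scaled <- rs
  rs_scaled$curves <- lapply(rs$curves, function(k)
    kinetic_curve(k$times, k$values * 7.3))
  cmp_s <- heatmap_compare(rs_scaled, "WT")
  expect_equal(cmp_s$cells$fc, cmp$cells$fc, tolerance = 1e-10)
  expect_equal(cmp_s$cells$p, cmp$cells$p, tolerance = 1e-10)

  # exchanging test and parent maps fc -> -fc and preserves p
  cmp_x <- heatmap_compare(rs, "MUT")
  m <- match(paste(cmp$cells$plate, cmp$cells$well),
             paste(cmp_x$cells$plate, cmp_x$cells$well))
  fc_a <- cmp$cells$fc
  fc_b <- cmp_x$cells$fc[m]
  expect_equal(fc_b, ifelse(abs(fc_a) == 1, fc_a, -fc_a), tolerance = 1e-9)
  expect_equal(cmp_x$cells$p[m], cmp$cells$p, tolerance = 1e-9)
})

test_that("planted summary ratios are recovered with the signed convention", {
  plant <- data.frame(plate = "PM01", well = c("A02", "A03"),
                      ratio = c(4, 0.25))
  exp <- generate_experiment(list(plates = "PM01", wells_per_plate = 8L,
                                  replicates = 3L,
                                  planted_ratios = plant),
                             seed = 13)
  cmp <- heatmap_compare(exp$records, "WT")
  up <- cmp$cells[cmp$cells$well == "A02", ]
  dn <- cmp$cells[cmp$cells$well == "A03", ]
  expect_gt(up$fc, 3.5); expect_lt(up$fc, 4.5)
  expect_gt(dn$fc, -4.6); expect_lt(dn$fc, -3.5)

  # only the planted wells pass the significance filter
  expect_setequal(cmp$filtered$well, c("A02", "A03"))

  # tightening either threshold never adds cells
  loose <- heatmap_compare(exp$records, "WT", p_max = 0.1, fc_min = 1.5)
  tight <- heatmap_compare(exp$records, "WT", p_max = 0.01, fc_min = 3)
  key <- function(x) paste(x$filtered$plate, x$filtered$well)
  expect_true(all(key(tight) %in% key(loose)))
  expect_true(all(key(cmp) %in% key(loose)))

  # Benjamini-Hochberg screening can only shrink the filtered set
  bh <- heatmap_compare(exp$records, "WT", p_adjust = "BH")
  expect_true(all(bh$cells$p_adj >= bh$cells$p - 1e-15))
  expect_true(all(paste(bh$filtered$plate, bh$filtered$well) %in%
                    key(cmp)))

  expect_error(heatmap_compare(exp$records, "NOPE"), "parent strain")
  wt_only <- filter_records(exp$records, strain = "WT")
  expect_error(heatmap_compare(wt_only, "WT"), "test strain")
})
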