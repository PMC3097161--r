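test_that("median correlations follow the hand-enumerated pairwise values", {
  t <- seq(0, 90, by = 10)
  up <- kc(seq(0, 100, length.out = 10), times = t)
  down <- kc(seq(100, 0, length.out = 10), times = t)

  # three identical curves: all medians 1, none flagged
  rs <- make_group_rs(list(up, up, up))
  rep1 <- outlier_analysis(rs, threshold = 0.9)
  expect_equal(rep1$median_correlation, rep(1, 3))
  expect_false(any(rep1$flagged))

  # two ramps + one reversed: pairwise r = (1, -1, -1);
  # ramp members get median(1, -1) = 0, reversed member median(-1, -1) = -1
  rs2 <- make_group_rs(list(up, up, down))
  rep2 <- outlier_analysis(rs2, threshold = 0.5)
  expect_equal(rep2$median_correlation, c(0, 0, -1))
  expect_true(all(rep2$flagged))
  expect_equal(rep2$group_median, rep(-1, 3))  # median of {1, -1, -1}

  # group of 2: each member's median is the single pairwise r (oracle)
  set.seed(7)
  a <- kc(runif(10), times = t); b <- kc(runif(10), times = t)
  rep3 <- outlier_analysis(make_group_rs(list(a, b)), threshold = 0.5)
  expect_equal(rep3$median_correlation,
               rep(pearson_oracle(a$values, b$values), 2),
               tolerance = 1e-12)
})

test_that("degenerate and singleton groups are handled as defined", {
  t <- seq(0, 90, by = 10)
  up <- kc(seq(0, 100, length.out = 10), times = t)
  flat <- kc(rep(5, 10), times = t)
  rep <- outlier_analysis(make_group_rs(list(up, up, flat)), threshold = 0.5)
  expect_true(rep$degenerate[3])
  expect_true(rep$flagged[3])
  expect_true(is.na(rep$median_correlation[3]))
  expect_false(any(rep$flagged[1:2]))  # flat member's NA r is ignored

  single <- record_set(list(wr()))
  expect_warning(out <- outlier_analysis(single), "size 1")
  expect_equal(nrow(out), 0L)
  expect_error(outlier_analysis(record_set()), "empty")
})

test_that("outlier flags are monotone in threshold and permutation invariant", {
  set.seed(17)
  t <- seq(0, 300, by = 15)
  curves <- lapply(1:6, function(i)
    kc(logistic_vals(t, A = 100) + rnorm(length(t), 0, 20), times = t))
  rs <- make_group_rs(curves)
  thresholds <- c(-1, 0, 0.5, 0.9, 1)
  flags <- vapply(thresholds, function(th)
    sum(outlier_analysis(rs, th)$flagged), integer(1))
  expect_true(all(diff(flags) >= 0))  # lowering threshold never flags more

  perm <- sample(6)
  r1 <- outlier_analysis(rs, 0.5)
  r2 <- outlier_analysis(rs[perm], 0.5)
  r2 <- r2[match(r1$well, r2$well), ]
  expect_equal(r1$median_correlation, r2$median_correlation)
  expect_true(all(r1$median_correlation >= -1 &
                    r1$median_correlation <= 1))
})

test_that("a planted anti-correlated outlier among concordant replicates is the only flag", {
  t <- seq(0, 2000, by = 50)
  for (seed in 1:5) {
    set.seed(seed)
    mu <- logistic_vals(t)
    good <- lapply(1:4, function(i) kc(mu + rnorm(length(t), 0, 2),
                                       times = t))
    bad <- kc(rev(mu) + rnorm(length(t), 0, 2), times = t)
    rep <- outlier_analysis(make_group_rs(c(good, list(bad))),
                            threshold = 0.5)
    expect_identical(which(rep$flagged), 5L)
  }
})

test_that("quantile curves match their defining order statistics", {
  t <- seq(0, 60, by = 15)
  consts <- function(vals) lapply(vals, function(v) kc(rep(v, 5), times = t))

  # constants: every quantile curve and threshold equals the constant
  qc <- negative_controls_analysis(make_group_rs(consts(rep(30, 5))))
  expect_true(all(qc$curves == 30))
  expect_true(all(qc$candidate_thresholds == 30))

  # median of {10..50} is 30 at every time point
  qc2 <- negative_controls_analysis(make_group_rs(consts(c(10, 20, 30, 40, 50))),
                                    levels = 0.5)
  expect_equal(as.numeric(qc2$curves["q0.5", ]), rep(30, 5))

  # random controls: exact match to the sort-and-index oracle
  set.seed(23)
  curves <- lapply(1:9, function(i) kc(runif(5, 0, 50), times = t))
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  qc3 <- negative_controls_analysis(make_group_rs(curves), levels = lv)
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  for (j in seq_along(t))
    for (k in seq_along(lv))
      expect_equal(unname(qc3$curves[k, j]),
                   quantile_oracle(vals[, j], lv[k]), tolerance = 1e-12)

  # monotone in level at every time point; odd n median = middle order stat
  expect_true(all(diff(qc3$curves) >= 0) || all(apply(qc3$curves, 2, diff) >= 0))
  expect_equal(as.numeric(qc3$curves["q0.5", ]),
               apply(vals, 2, function(x) sort(x)[5]))

  expect_error(negative_controls_analysis(record_set()), "empty")
  expect_error(negative_controls_analysis(make_group_rs(curves),
                                          levels = c(0, 0.5)), "levels")
  expect_warning(negative_controls_analysis(make_group_rs(curves[1])),
                 "single")

  # non-negative controls get overlay quantiles on the same grid
  qc4 <- negative_controls_analysis(make_group_rs(curves),
                                    non_neg = make_group_rs(curves[1:3],
                                                            strain = "S2"))
  expect_equal(dim(qc4$non_neg), dim(qc4$curves))
})
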