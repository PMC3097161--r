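test_that("correlation matrix equals the direct covariance-formula oracle", {
  t <- seq(0, 90, by = 10)
  up <- kc(seq(0, 100, length.out = 10), times = t)
  down <- kc(seq(100, 0, length.out = 10), times = t)

  cm <- correlation_matrix(make_group_rs(list(up, up)))
  expect_equal(cm$matrix[1, 2], 1)
  cm2 <- correlation_matrix(make_group_rs(list(up, down)))
  expect_equal(cm2$matrix[1, 2], -1)

  set.seed(31)
  curves <- lapply(1:5, function(i) kc(runif(10, 0, 50), times = t))
  cm3 <- correlation_matrix(make_group_rs(curves))
  vals <- lapply(curves, `[[`, "values")
  for (i in 1:5) for (j in 1:5) {
    want <- if (i == j) 1 else pearson_oracle(vals[[i]], vals[[j]])
    expect_equal(cm3$matrix[i, j], want, tolerance = 1e-12)
  }
  expect_equal(cm3$matrix, t(cm3$matrix))

  # order invariance up to simultaneous row/column permutation
  perm <- c(3, 1, 5, 2, 4)
  cm4 <- correlation_matrix(make_group_rs(curves)[perm])
  expect_equal(unname(cm4$matrix), unname(cm3$matrix[perm, perm]),
               tolerance = 1e-12)

  expect_error(correlation_matrix(make_group_rs(curves[1])), "at least 2")
  flatrs <- make_group_rs(list(up, kc(rep(3, 10), times = t)))
  expect_warning(cm5 <- correlation_matrix(flatrs), "zero-variance")
  expect_true(all(is.na(cm5$matrix[2, ])))
  expect_equal(cm5$matrix[1, 1], 1)
})

test_that("pearson_with_p applies the exact t-transform", {
  x <- as.numeric(1:10)
  self <- pearson_with_p(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)

  # orthogonal pair: r = 0 gives p = 1
  xo <- rep(c(1, -1), 6); yo <- rep(c(1, 1, -1, -1), 3)
  orth <- pearson_with_p(xo, yo)
  expect_equal(orth$r, 0)
  expect_equal(orth$p, 1)

  # reference oracle: stats::cor.test
  a <- c(1, 2, 4, 8, 16); b <- c(1, 3, 5, 7, 11)
  got <- pearson_with_p(a, b)
  ct <- cor.test(a, b)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)

  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant")

  # p monotone decreasing in |r| at fixed n
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, function(r) {
    t <- r * sqrt(8 / (1 - r^2))
    2 * pt(-abs(t), 8)
  }, numeric(1))
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    got <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
  expect_true(all(diff(ps) < 0))
})

test_that("profile search ranks records by similarity to the pattern", {
  t <- seq(0, 2000, by = 50)
  pat <- profile_pattern(c(0, 800, 1200, 2000), c(10, 20, 180, 200))
  sig <- kc(logistic_vals(t), times = t)
  set.seed(51)
  flat <- kc(rep(15, length(t)) + runif(length(t)), times = t)
  noise <- kc(runif(length(t), 0, 200), times = t)
  decay <- kc(rev(logistic_vals(t)), times = t)
  rs <- make_group_rs(list(noise, sig, flat, decay))

  pm <- profile_search(rs, pat)
  expect_equal(pm$well[1], "A02")       # the planted sigmoid ranks first
  expect_true(all(diff(pm$r) <= 0))
  expect_equal(pm$rank, 1:4)

  # a record identical to the pattern ranks first with r = 1
  patcurve <- resample(profile_pattern(t, logistic_vals(t)), t)
  rs2 <- make_group_rs(list(noise, kc(patcurve$values, times = t)))
  pm2 <- profile_search(rs2, profile_pattern(t, logistic_vals(t)))
  expect_equal(pm2$r[1], 1)
  expect_equal(pm2$well[1], "A02")

  # decreasing record against increasing pattern: r < 0
  pm3 <- profile_search(make_group_rs(list(decay)), pat)
  expect_lt(pm3$r[1], 0)

  # pattern outside the records' time range
  far <- profile_pattern(c(9000, 9500), c(0, 1))
  expect_error(profile_search(rs, far), "overlap")
})

test_that("k-means recovers planted shape families and the exhaustive optimum", {
  t <- seq(0, 2000, by = 100)
  set.seed(61)
  grow <- lapply(1:4, function(i)
    kc(logistic_vals(t, A = 100 + i) + rnorm(length(t), 0, 0.1), times = t))
  decay <- lapply(1:4, function(i)
    kc(rev(logistic_vals(t, A = 100 + i)) + rnorm(length(t), 0, 0.1),
       times = t))
  rs <- make_group_rs(c(grow, decay))

  cr <- kmeans_cluster(rs, k = 2, seed = 42)
  truth <- rep(1:2, each = 4)
  agree <- max(mean((cr$labels$cluster == truth)),
               mean((3 - cr$labels$cluster) == truth))
  expect_equal(agree, 1)

  # same seed is reproducible; the objective never worsens with restarts
  cr2 <- kmeans_cluster(rs, k = 2, seed = 42)
  expect_identical(cr$labels, cr2$labels)
  expect_identical(cr$objective, cr2$objective)
  cr_more <- kmeans_cluster(rs, k = 2, seed = 42, restarts = 25)
  expect_lte(cr_more$objective, cr$objective + 1e-9)

  # k = 1: single cluster, centroid = mean of all scaled curves
  cr1 <- kmeans_cluster(rs, k = 1, seed = 42)
  expect_true(all(cr1$labels$cluster == 1))
  expect_equal(unname(cr1$centroids[1, ]), unname(colMeans(cr1$scaled)),
               tolerance = 1e-12)

  # centroids equal the mean of their members' scaled vectors
  for (cl in 1:2) {
    idx <- cr$labels$cluster == cl
    expect_equal(unname(cr$centroids[cl, ]),
                 unname(colMeans(cr$scaled[idx, , drop = FALSE])),
                 tolerance = 1e-9)
  }
  # members correlate with their centroid
  expect_true(all(cr$labels$r_to_centroid > 0.9))

  # 6 records, k = 2: objective equals the exhaustive-partition minimum
  set.seed(62)
  small <- lapply(1:6, function(i) kc(runif(8, 0, 50),
                                      times = seq(0, 70, by = 10)))
  rs6 <- make_group_rs(small)
  cr6 <- kmeans_cluster(rs6, k = 2, seed = 42, restarts = 50)
  z <- cr6$scaled
  expect_equal(cr6$objective, brute_force_wss2(z), tolerance = 1e-8)

  expect_error(kmeans_cluster(rs6, k = 7, seed = 1), "exceeds")
  withflat <- make_group_rs(c(small, list(kc(rep(4, 8),
                                             times = seq(0, 70, by = 10)))))
  expect_warning(cr7 <- kmeans_cluster(withflat, k = 2, seed = 1),
                 "zero-variance")
  expect_equal(nrow(cr7$labels), 6L)
})
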