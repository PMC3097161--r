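# Fixture builders and independent oracles used across the suite.

# quick curve over t minutes
kc <- function(values, times = seq(0, by = 15, length.out = length(values))) {
  kinetic_curve(times, values, .validate_nonneg = FALSE)
}

wr <- function(strain = "S1", phenotype = "P1", plate = "PM01", well = "A01",
               replicate = 1L, curve = kc(c(1, 2, 3)), project = "proj",
               species = "org", temperature = 37) {
  well_record(project, species, strain, phenotype, plate, well, replicate,
              temperature, curve)
}

logistic_vals <- function(times, baseline = 15, A = 200, r = 0.01,
                          tm = 1200) {
  baseline + A / (1 + exp(-r * (times - tm)))
}

# Pearson r straight from the covariance formula (independent of stats::cor)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# type-7 quantile by explicit sort-and-index interpolation
quantile_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Welch statistic from first principles
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
brute_force_wss2 <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 1; skip empty
    assign <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    wss <- 0
    for (cl in 1:2) {
      sub <- m[assign == cl, , drop = FALSE]
      ctr <- colMeans(sub)
      wss <- wss + sum(sweep(sub, 2, ctr)^2)
    }
    best <- min(best, wss)
  }
  best
}

# a small record set of replicate groups with known curves
make_group_rs <- function(curves, strain = "S1", phenotype = "P1",
                          plate = "PM01") {
  wells <- plate_wells()
  record_set(lapply(seq_along(curves), function(i)
    wr(strain, phenotype, plate, well = wells[i], curve = curves[[i]])))
}
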