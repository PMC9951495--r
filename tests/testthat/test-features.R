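b25 <- genome_binning("chr1", 500 * 25000, 25000)

test_that("cluster span is bin-range times resolution", {
  expect_identical(cluster_span(make_binned(c(0, 400)), b25), 1e7)
  expect_identical(cluster_span(make_binned(5), b25), 0)
  expect_identical(cluster_span(make_binned(c(10, 11, 500 - 10)), b25),
                   480 * 25000)
})

test_that("pooled quantile thresholds follow the interpolation convention", {
  thr <- pooled_quantile_thresholds(1:100)
  expect_equal(unname(thr), c(20.8, 40.6, 60.4, 80.2))
  expect_identical(unname(pooled_quantile_thresholds(rep(7, 50))),
                   rep(7, 4))
  expect_error(pooled_quantile_thresholds(numeric(0)), "no spans")
})

test_that("chromosome features count many-contact and long-range clusters", {
  cls <- c(lapply(1:7, function(i) make_binned(c(0, i))),        # k = 2
           list(make_binned(c(0, 5, 9)),                          # k = 3
                make_binned(c(0, 2, 4, 6)),                       # k = 4
                make_binned(seq(0, 44, by = 4))))                 # k = 12
  thr <- c(quintile = 1e9, decile = 2e9)   # nothing is "long"
  f <- chromosome_features(cls, thr, b25)
  expect_identical(f$n_clusters, 10L)
  expect_equal(f$pct_many_gt3, 20)
  expect_equal(f$pct_many_gt10, 10)
  expect_equal(f$pct_long, 0)
  f2 <- chromosome_features(cls, c(quintile = 100000, decile = 150000), b25)
  spans <- vapply(cls, cluster_span, 0, binning = b25)
  expect_equal(f2$pct_long, 100 * mean(spans > 100000))
  expect_equal(f2$pct_long_decile, 100 * mean(spans > 150000))
})

test_that("zero-cluster chromosomes report undefined percentages", {
  f <- chromosome_features(list(), c(quintile = 1, decile = 2), b25)
  expect_identical(f$n_clusters, 0L)
  expect_true(is.na(f$pct_many_gt3) && is.na(f$pct_long))
})

test_that("features and the degree-distance table match brute-force recounts", {
  set.seed(33)
  n_bins <- 2000L
  bb <- genome_binning("chrX1", n_bins * 25000, 25000)
  cls <- lapply(1:1000, function(i) {
    k <- sample(c(2, 2, 2, 3, 4, 8, 15, 40, 120), 1)
    make_binned(sample.int(n_bins, min(k, n_bins)) - 1L, "chrX1")
  })
  spans <- vapply(cls, cluster_span, 0, binning = bb)
  thr <- c(quintile = unname(quantile(spans, 0.8)),
           decile = unname(quantile(spans, 0.9)))
  f <- chromosome_features(cls, thr, bb)
  k <- vapply(cls, `[[`, 0L, "k")
  expect_identical(f$n_clusters, 1000L)
  expect_equal(f$pct_many_gt3, 100 * sum(k > 3) / 1000)
  expect_equal(f$pct_many_gt10, 100 * sum(k > 10) / 1000)
  expect_equal(f$pct_long, 100 * sum(spans > thr[["quintile"]]) / 1000)
  expect_equal(f$pct_long_decile, 100 * sum(spans > thr[["decile"]]) / 1000)

  tab <- degree_distance_table(cls, list(chrX1 = bb))
  expect_identical(sum(tab$counts), 1000L)
  # brute-force recount
  breaks <- seq(0, 250, 25)
  recount <- matrix(0L, 10, 5)
  for (i in seq_along(cls)) {
    row <- min(10L, findInterval(spans[i] / 1e6, breaks))
    col <- findInterval(k[i], c(2, 3, 4, 11, 101))
    recount[row, col] <- recount[row, col] + 1L
  }
  expect_identical(unname(tab$counts), recount)
})

test_that("degree-distance table places single clusters correctly", {
  bb <- genome_binning("c", 2000 * 25000, 25000)
  # k = 3, span 30 Mb -> cell (25-50 Mb, 3-mers)
  tab <- degree_distance_table(list(make_binned(c(0, 600, 1200), "c")),
                               list(c = bb))
  expect_identical(tab$counts["25-50", "3-mers"], 1L)
  expect_identical(sum(tab$counts), 1L)
})

test_that("spans beyond the last break land in the final row with a message", {
  bb <- genome_binning("c", 12000 * 25000, 25000)
  expect_message(
    tab <- degree_distance_table(list(make_binned(c(0, 11000), "c")),
                                 list(c = bb)),
    "beyond the last break")
  expect_identical(tab$counts["225-250", "2-mers"], 1L)
})

test_that("OLS regression matches the closed-form oracle", {
  # perfect linear fit
  x <- 1:10
  y <- 2 * x + 1
  r <- suppressWarnings(regress_rmse(y, x))
  expect_equal(unname(r$slopes["x"]), 2)
  expect_lt(r$p_values[["x"]], 1e-12)
  # worked 5-point data set vs textbook formulas
  x5 <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y5 <- c(0.9, 2.1, 1.4, 3.9, 2.6)
  r5 <- regress_rmse(y5, x5)
  o5 <- ols_oracle(y5, cbind(x5))
  expect_equal(unname(r5$slopes["x"]), o5$beta[2], tolerance = 1e-12)
  expect_equal(r5$p_values[["x"]], o5$p[2], tolerance = 1e-12)
  expect_equal(r5$intercept, o5$beta[1], tolerance = 1e-12)
  # length-adjusted model against the two-covariate oracle
  set.seed(44)
  len <- runif(8, 50, 250)   # lengths in Mb keep the oracle well-conditioned
  xf <- runif(8, 0, 30)
  yr <- 0.5 + 0.01 * xf - 1e-3 * len + rnorm(8, 0, 0.05)
  ra <- regress_rmse(yr, xf, length_bp = len, adjust_length = TRUE)
  oa <- ols_oracle(yr, cbind(xf, len))
  expect_equal(unname(ra$slopes), oa$beta[2:3], tolerance = 1e-10)
  expect_equal(unname(ra$p_values), oa$p[2:3], tolerance = 1e-10)
})

test_that("regression guards small samples and constant features", {
  expect_error(regress_rmse(1:2, 1:2), "at least 3")
  expect_error(regress_rmse(1:3, c(1, 1, 1)), "constant")
  expect_error(regress_rmse(1:3, 1:3, length_bp = 1:3, adjust_length = TRUE),
               "at least 4")
})

test_that("planted hot windows dominate their locus", {
  set.seed(55)
  n <- 40
  M <- matrix(runif(n * n, 0, 0.2), n); M <- (M + t(M)) / 2; diag(M) <- 0
  M[11:14, 26:29] <- M[11:14, 26:29] + 5
  M[26:29, 11:14] <- t(M[11:14, 26:29])
  C <- contact_matrix(M, "c", 25000, "N-W")
  res <- region_dominance(C, row_window = c(10, 13), col_window = c(25, 28),
                          locus = c(0, 39), diag_exclusion = 2)
  expect_true(res$strict_max)
  expect_identical(res$rank, 1L)
})

test_that("constant matrices cannot have a strict maximum window", {
  C <- contact_matrix(matrix(1, 20, 20), "c", 25000, "N-W")
  res <- region_dominance(C, c(2, 4), c(12, 14), c(0, 19), diag_exclusion = 1)
  expect_false(res$strict_max)
})

test_that("window ranks agree with exhaustive enumeration", {
  set.seed(56)
  n <- 25
  M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
  C <- contact_matrix(M, "c", 25000, "N-W")
  h <- 3; w <- 4; excl <- 2
  target <- list(r = 4, c = 15)   # 0-based starts
  res <- region_dominance(C, c(target$r, target$r + h - 1),
                          c(target$c, target$c + w - 1), c(0, n - 1),
                          diag_exclusion = excl)
  # oracle: enumerate every window position strictly above the diagonal band
  sums <- c(); tsum <- NA
  for (r0 in 0:(n - h)) for (c0 in 0:(n - w)) {
    cells <- expand.grid(r = r0:(r0 + h - 1), c = c0:(c0 + w - 1))
    if (min(cells$c - cells$r) <= excl) next
    s <- sum(M[cbind(cells$r + 1, cells$c + 1)])
    sums <- c(sums, s)
    if (r0 == target$r && c0 == target$c) tsum <- s
  }
  expect_equal(res$sum, tsum)
  expect_identical(res$n_windows, length(sums))
  expect_identical(res$rank, 1L + sum(sums > tsum))
})

test_that("invalid windows are rejected", {
  C <- contact_matrix(matrix(1, 10, 10), "c", 25000, "N-W")
  expect_error(region_dominance(C, c(0, 5), c(0, 5), c(2, 4)), "within the locus")
  expect_error(region_dominance(C, c(0, 8), c(0, 8), c(0, 7)), "within the locus")
  expect_error(region_dominance(C, c(2, 3), c(3, 4), c(0, 9), diag_exclusion = 3),
               "excluded diagonal")
})
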