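#' Genomic span of a binned cluster
#'
#' The maximum genomic distance straddled by a cluster, measured between bin
#' indices: `(max(bins) - min(bins)) * resolution`. Single-bin clusters span
#' 0. Bin-level spans differ from read-level spans by less than one bin width
#' and are reproducible from the binned representation alone.
#'
#' @param cluster A `binned_cluster`.
#' @param binning The matching [genome_binning()].
#' @return Span in base pairs.
#' @export
cluster_span <- function(cluster, binning) {
  stopifnot(inherits(cluster, "binned_cluster"), inherits(binning, "genome_binning"))
  (max(cluster$bins) - min(cluster$bins)) * binning$resolution
}

#' Pooled span quantile thresholds
#'
#' Empirical quantiles of cluster spans pooled across chromosomes, used to
#' define long-distance clusters genome-wide (so "upper quintile" means the
#' same physical span on every chromosome). Quantiles use linear
#' interpolation between order statistics at position p(n-1)+1
#' (`stats::quantile` type 7).
#'
#' @param spans Numeric vector of spans (base pairs), pooled.
#' @param probs Cut points; default `c(0.2, 0.4, 0.6, 0.8)` (quintiles).
#' @return Named non-decreasing numeric vector of thresholds.
#' @export
pooled_quantile_thresholds <- function(spans, probs = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(spans) == 0L) stop("no spans supplied")
  stats::quantile(spans, probs = probs, type = 7, names = TRUE)
}

#' Per-chromosome cluster features
#'
#' Computes the chromosome-level covariates related to reconstruction
#' disagreement: the percentage of many-contact k-mers (k > 3 and k > 10;
#' single-bin clusters count as k = 2) and the percentage of long-distance
#' clusters (span above the pooled upper-quintile and upper-decile
#' thresholds, strict inequality).
#'
#' @param clusters List of `binned_cluster` objects for one chromosome.
#' @param thresholds Named list or vector with elements/names `quintile` and
#'   `decile`: pooled span thresholds in base pairs (see
#'   [pooled_quantile_thresholds()] at probs 0.8 and 0.9).
#' @param binning The chromosome's [genome_binning()].
#' @return An object of class `chromosome_features`: list with `chromosome`,
#'   `length_bp`, `n_clusters`, `pct_many_gt3`, `pct_many_gt10`, `pct_long`,
#'   `pct_long_decile` (percentages are `NA` when `n_clusters` is 0).
#' @export
chromosome_features <- function(clusters, thresholds, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  thr_q <- as.numeric(thresholds[["quintile"]])
  thr_d <- as.numeric(thresholds[["decile"]])
  n <- length(clusters)
  if (n == 0L) {
    return(structure(list(chromosome = binning$chromosome,
                          length_bp = binning$chrom_length, n_clusters = 0L,
                          pct_many_gt3 = NA_real_, pct_many_gt10 = NA_real_,
                          pct_long = NA_real_, pct_long_decile = NA_real_),
                     class = "chromosome_features"))
  }
  k <- vapply(clusters, `[[`, 0L, "k")
  spans <- vapply(clusters, cluster_span, 0, binning = binning)
  structure(
    list(chromosome = binning$chromosome, length_bp = binning$chrom_length,
         n_clusters = n,
         pct_many_gt3 = 100 * mean(k > 3),
         pct_many_gt10 = 100 * mean(k > 10),
         pct_long = 100 * mean(spans > thr_q),
         pct_long_decile = 100 * mean(spans > thr_d)),
    class = "chromosome_features"
  )
}

#' Regress per-chromosome RMSEs on a cluster feature
#'
#' Ordinary least squares of Procrustes RMSE on one chromosome feature,
#' optionally adjusting for chromosome length, with two-sided t-test
#' p-values per slope. No multiple-testing correction is applied (raw
#' p-values are reported).
#'
#' @param y Numeric vector of per-chromosome RMSEs.
#' @param x Numeric vector of one feature, same order as `y`.
#' @param length_bp Chromosome lengths (base pairs), required when
#'   `adjust_length = TRUE`.
#' @param adjust_length Add chromosome length as a covariate; default
#'   `FALSE`.
#' @return An object of class `regression_result`: list with `slopes`
#'   (named), `intercept`, `p_values` (named, two-sided), `r_squared`, `n`.
#' @export
regress_rmse <- function(y, x, length_bp = NULL, adjust_length = FALSE) {
  ok <- stats::complete.cases(y, x, if (adjust_length) length_bp else rep(0, length(y)))
  y <- y[ok]; x <- x[ok]
  if (adjust_length) length_bp <- length_bp[ok]
  min_n <- if (adjust_length) 4L else 3L
  if (length(y) < min_n)
    stop("need at least ", min_n, " chromosomes for this regression")
  if (stats::sd(x) == 0) stop("feature is constant: slope not identifiable")
  dat <- if (adjust_length) {
    data.frame(y = y, x = x, length_bp = length_bp)
  } else data.frame(y = y, x = x)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  slopes <- co[-1L, "Estimate"]
  pvals <- co[-1L, "Pr(>|t|)"]
  names(slopes) <- names(pvals) <- rownames(co)[-1L]
  structure(
    list(slopes = slopes, intercept = co["(Intercept)", "Estimate"],
         p_values = pvals, r_squared = sm$r.squared, n = length(y)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> n =", x$n, " R^2 =", signif(x$r_squared, 4), "\n")
  for (nm in names(x$slopes))
    cat(sprintf("  %-12s slope %.4g  p %.3g\n", nm, x$slopes[[nm]], x$p_values[[nm]]))
  invisible(x)
}

#' Cross-tabulate clusters by genomic span and interaction degree
#'
#' Counts every cluster once in the cell of its span bin (left-closed,
#' right-open intervals in Mb) and its k stratum. Default strata are
#' 2-mers, 3-mers, 4-10-mers, 11-100-mers and >100-mers; default span bins
#' are 25 Mb wide from 0 to 250 Mb. Spans at or beyond the last break are
#' counted in the final row (with a message).
#'
#' @param clusters List of `binned_cluster` objects (any mix of
#'   chromosomes).
#' @param binnings Named list of [genome_binning()] objects keyed by
#'   chromosome name, covering every cluster's chromosome.
#' @param distance_breaks_mb Span bin edges in Mb; default `seq(0, 250, 25)`.
#' @param k_breaks Right-closed upper edges of the k strata; default
#'   `c(2, 3, 10, 100, Inf)` giving strata {2}, {3}, {4-10}, {11-100},
#'   {>100}.
#' @return An object of class `degree_distance_table`: list with `counts`
#'   (rows = span bins, columns = k strata), `distance_breaks_mb`,
#'   `k_breaks`.
#' @export
degree_distance_table <- function(clusters, binnings,
                                  distance_breaks_mb = seq(0, 250, by = 25),
                                  k_breaks = c(2, 3, 10, 100, Inf)) {
  if (is.null(names(binnings)))
    names(binnings) <- vapply(binnings, `[[`, "", "chromosome")
  nb <- length(distance_breaks_mb) - 1L
  k_lab <- character(length(k_breaks))
  lo <- c(2, utils::head(k_breaks, -1) + 1)
  for (i in seq_along(k_breaks)) {
    k_lab[i] <- if (!is.finite(k_breaks[i])) paste0(">", lo[i] - 1, "-mers")
      else if (lo[i] == k_breaks[i]) paste0(k_breaks[i], "-mers")
      else paste0(lo[i], "-", k_breaks[i], "-mers")
  }
  d_lab <- paste0(utils::head(distance_breaks_mb, -1), "-",
                  utils::tail(distance_breaks_mb, -1))
  counts <- matrix(0L, nb, length(k_breaks), dimnames = list(d_lab, k_lab))
  overflow <- 0L
  for (cl in clusters) {
    b <- binnings[[cl$chromosome]]
    if (is.null(b)) stop("no binning supplied for ", cl$chromosome)
    span_mb <- cluster_span(cl, b) / 1e6
    row <- findInterval(span_mb, distance_breaks_mb, left.open = FALSE)
    if (row > nb) { row <- nb; overflow <- overflow + 1L }
    if (row < 1L) row <- 1L
    col <- which(cl$k <= k_breaks)[1L]
    counts[row, col] <- counts[row, col] + 1L
  }
  if (overflow > 0L)
    message(overflow, " cluster(s) with span beyond the last break counted in the final row")
  structure(list(counts = counts, distance_breaks_mb = distance_breaks_mb,
                 k_breaks = k_breaks),
            class = "degree_distance_table")
}

#' @export
print.degree_distance_table <- function(x, ...) {
  cat("<degree_distance_table> cluster counts by span (Mb) and degree\n")
  print(x$counts)
  invisible(x)
}

#' Sub-region contact dominance check
#'
#' Tests whether the contact counts in a designated rectangular sub-region of
#' a contact matrix exceed the count totals of all equally sized sub-regions
#' within a locus, after excluding windows near the diagonal. An equally
#' sized window is slid over every admissible position in the locus — those
#' whose cells all satisfy col - row > `diag_exclusion`, i.e. windows lying
#' strictly above the excluded diagonal band — and the designated window's
#' sum is ranked among all admissible window sums. Because contact matrices
#' are symmetric, windows below the diagonal mirror those above it and are
#' not enumerated separately (the mirror of any window would always tie it).
#'
#' Bin intervals are given 0-based and inclusive, `c(first, last)`.
#'
#' @param C A [contact_matrix()].
#' @param row_window,col_window Designated window's row/column bin intervals
#'   (the window must lie above the diagonal band: its smallest column minus
#'   its largest row must exceed `diag_exclusion`).
#' @param locus Bin interval delimiting the search region (both axes).
#' @param diag_exclusion Bin offset; windows containing any cell with
#'   col - row <= `diag_exclusion` are excluded. Default 0 (exclude only
#'   the diagonal itself and below).
#' @return List with `sum` (designated window total), `rank` (1 = largest;
#'   1 + number of admissible windows with strictly larger sums),
#'   `strict_max` (is the designated window the unique maximum?), and
#'   `n_windows` (number of admissible windows).
#' @export
region_dominance <- function(C, row_window, col_window, locus,
                             diag_exclusion = 0L) {
  stopifnot(inherits(C, "contact_matrix"))
  M <- C$values
  n <- nrow(M)
  as_iv <- function(x) {
    x <- as.integer(x)
    stopifnot(length(x) == 2L, x[1] <= x[2], x[1] >= 0L, x[2] < n)
    x
  }
  rw <- as_iv(row_window); cw <- as_iv(col_window); lc <- as_iv(locus)
  if (rw[1] < lc[1] || rw[2] > lc[2] || cw[1] < lc[1] || cw[2] > lc[2])
    stop("designated window must lie within the locus (or is larger than it)")
  h <- rw[2] - rw[1] + 1L
  w <- cw[2] - cw[1] + 1L
  window_admissible <- function(r0, c0) {
    # smallest col - row over the window's cells; entire window must sit
    # strictly above the excluded diagonal band
    (c0 - (r0 + h - 1L)) > diag_exclusion
  }
  window_sum <- function(r0, c0)
    sum(M[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w)])
  if (!window_admissible(rw[1], cw[1]))
    stop("designated window overlaps the excluded diagonal band")
  sums <- numeric(0)
  for (r0 in lc[1]:(lc[2] - h + 1L)) {
    for (c0 in lc[1]:(lc[2] - w + 1L)) {
      if (window_admissible(r0, c0)) sums <- c(sums, window_sum(r0, c0))
    }
  }
  target <- window_sum(rw[1], cw[1])
  list(sum = target,
       rank = 1L + sum(sums > target),
       strict_max = sum(sums >= target) == 1L,
       n_windows = length(sums))
}
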