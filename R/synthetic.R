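# All randomness flows from one master seed; each stage derives its own
# stream so adding a stage never perturbs another stage's draws.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 1009) %% 2147483647)
}

#' Configuration for the synthetic SPRITE/Hi-C generator
#'
#' Defines a latent smoothed-random-walk chromosome backbone and the
#' observation models layered on it: SPRITE-like clusters whose members are
#' drawn by spatial (3D) proximity to an anchor, and Hi-C-like Poisson
#' pairwise counts decaying as a power of 3D distance. The defaults emulate
#' the empirical structure of GM12878 SPRITE data: cluster sizes heavily
#' dominated by 2-mers (~75%) with ~12% 3-mers and a power-law tail, and
#' pairwise counts consistent with the inverse-cube contact-distance
#' relation (the inverse of the -1/3 power-law distance transform).
#'
#' @param n_bins Number of genomic bins (>= 10); default 200.
#' @param seed Master seed; default 1.
#' @param smoothing_window Moving-average width (bins) applied to the random
#'   walk; default 5.
#' @param n_clusters Number of SPRITE clusters to draw; default 2000.
#' @param size_distribution Named numeric vector of probabilities over k =
#'   2..k_max; default 0.75 at k = 2, 0.12 at k = 3, and the remaining 0.13
#'   as a k^-3 power-law tail over 4..k_max (the exponent reproduces the
#'   observed share of k > 10 clusters among multi-way clusters in GM12878
#'   SPRITE, ~15%).
#' @param k_max Largest cluster order; default `min(150, n_bins)`.
#' @param proximity_bandwidth Kernel bandwidth (3D length units; backbone
#'   step scale is ~1, RMS radius ~11 at 200 bins) for drawing cluster
#'   members around the anchor; default 3, roughly a quarter of the
#'   configuration radius, emulating a crosslinking complex that is small
#'   relative to the chromosome territory.
#' @param proximity_kernel Radial profile of the member-draw weights:
#'   `"inverse_power"` (default) uses \eqn{(d^2 + bw^2)^{-\gamma/2}} with
#'   \eqn{\gamma} = `contact_decay_exponent`, so pairwise co-occurrence
#'   counts decay as the inverse-power law the -1/3 distance transform
#'   assumes; `"gaussian"` uses \eqn{\exp(-d^2/(2 bw^2))}.
#' @param hic_coverage Expected total pairwise Hi-C count; default 1e6.
#' @param contact_decay_exponent Power of the distance decay of expected
#'   counts; default 3 (matching the -1/3 transform).
#' @param chromosome Chromosome name used when emitting files; default
#'   `"chrS"`.
#' @param resolution Bin width in base pairs; default 25000.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bins = 200L, seed = 1L, smoothing_window = 5L,
                             n_clusters = 2000L, size_distribution = NULL,
                             k_max = max(2L, min(50L, n_bins %/% 4L)),
                             proximity_bandwidth = 3,
                             proximity_kernel = c("inverse_power", "gaussian"),
                             hic_coverage = 1e6,
                             contact_decay_exponent = 3,
                             chromosome = "chrS", resolution = 25000L) {
  proximity_kernel <- match.arg(proximity_kernel)
  n_bins <- as.integer(n_bins)
  if (n_bins < 10L) stop("n_bins must be >= 10")
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be >= 2")
  if (is.null(size_distribution)) {
    ks <- 2:k_max
    p <- numeric(length(ks))
    p[1] <- 0.75
    if (k_max >= 3L) p[2] <- 0.12
    if (k_max >= 4L) {
      tail_ks <- 4:k_max
      tail_p <- tail_ks^(-3)
      p[ks >= 4] <- (1 - sum(p)) * tail_p / sum(tail_p)
    }
    p <- p / sum(p)
    size_distribution <- stats::setNames(p, ks)
  } else {
    if (is.null(names(size_distribution)))
      names(size_distribution) <- seq(2, length.out = length(size_distribution))
    if (abs(sum(size_distribution) - 1) > 1e-8)
      stop("size_distribution probabilities must sum to 1")
    k_max <- max(as.integer(names(size_distribution)))
  }
  stopifnot(smoothing_window >= 1, n_clusters >= 0, proximity_bandwidth > 0,
            hic_coverage > 0, contact_decay_exponent > 0)
  structure(
    list(n_bins = n_bins, seed = as.integer(seed),
         smoothing_window = as.integer(smoothing_window),
         n_clusters = as.integer(n_clusters),
         size_distribution = size_distribution, k_max = k_max,
         proximity_bandwidth = proximity_bandwidth,
         proximity_kernel = proximity_kernel,
         hic_coverage = hic_coverage,
         contact_decay_exponent = contact_decay_exponent,
         chromosome = chromosome, resolution = as.numeric(resolution)),
    class = "synthetic_config"
  )
}

#' Binning implied by a synthetic configuration
#' @param cfg A [synthetic_config()].
#' @return The matching [genome_binning()].
#' @export
synthetic_binning <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genome_binning(cfg$chromosome, cfg$n_bins * cfg$resolution, cfg$resolution)
}

# moving average keeping length, shrinking the window at the ends
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Generate a ground-truth chromosome backbone
#'
#' The backbone is the cumulative sum of independent standard 3D Gaussian
#' steps, smoothed coordinate-wise by a moving average of width
#' `smoothing_window` (shrinking at the ends). Smoothing yields a locally
#' stiff curve that still folds back on itself globally — the feature that
#' lets spatially defined clusters straddle large genomic distances.
#' Deterministic given the seed.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `ground_truth`: list with `backbone`
#'   (n_bins-by-3 coordinates) and `config`.
#' @export
generate_backbone <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  steps <- matrix(stats::rnorm(cfg$n_bins * 3L), cfg$n_bins, 3L)
  walk <- apply(steps, 2L, cumsum)
  smooth <- apply(walk, 2L, moving_average, w = cfg$smoothing_window)
  structure(list(backbone = smooth, config = cfg), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> backbone of %d bins (seed %d, smoothing %d)\n",
              nrow(x$backbone), x$config$seed, x$config$smoothing_window))
  invisible(x)
}

# member-draw kernel matrix over backbone coordinates (diagonal zeroed)
proximity_kernel_matrix <- function(X, cfg) {
  d2 <- as.matrix(stats::dist(X))^2
  K <- switch(cfg$proximity_kernel,
    inverse_power = (d2 + cfg$proximity_bandwidth^2)^
      (-cfg$contact_decay_exponent / 2),
    gaussian = exp(-d2 / (2 * cfg$proximity_bandwidth^2))
  )
  diag(K) <- 0
  K
}

#' Simulate SPRITE clusters from a ground-truth backbone
#'
#' For each cluster, an order k is drawn from the size distribution, an
#' anchor bin with probability proportional to its total contact propensity
#' \eqn{Z_b = \sum_{b'} K(d_{bb'})} (crowded spatial neighbourhoods seed
#' more complexes), and the remaining k - 1 distinct member bins with
#' probability proportional to the proximity kernel \eqn{K(d_{b,anchor})}.
#' Membership is driven by spatial, not genomic, proximity, so multi-way
#' clusters straddle large genomic distances wherever the backbone folds
#' back. Each member bin contributes one read at its genomic midpoint.
#'
#' Under the default inverse-power kernel with propensity-weighted anchors,
#' the expected pairwise (2-mer) count between bins i and j is proportional
#' to \eqn{(d_{ij}^2 + bw^2)^{-\gamma/2}} — the inverse-power contact-decay
#' profile the power-law distance transform inverts. Uniform anchors would
#' instead impose an extra \eqn{1/Z_i + 1/Z_j} coverage bias on every pair.
#'
#' @param truth A [generate_backbone()] result.
#' @param cfg A [synthetic_config()] (defaults to `truth$config`).
#' @return List of `sprite_cluster` objects.
#' @export
simulate_sprite_clusters <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synthetic_config"))
  n <- cfg$n_bins
  if (cfg$k_max > n) stop("k_max (", cfg$k_max, ") exceeds n_bins (", n, ")")
  set.seed(derive_seed(cfg$seed, 2L))
  ks_support <- as.integer(names(cfg$size_distribution))
  mid <- as.integer((seq_len(n) - 1L) * cfg$resolution + cfg$resolution %/% 2)
  K <- proximity_kernel_matrix(truth$backbone, cfg)
  Z <- rowSums(K)
  nc <- cfg$n_clusters
  kdraw <- ks_support[sample.int(length(ks_support), nc, replace = TRUE,
                                 prob = cfg$size_distribution)]
  bins_list <- vector("list", nc)
  # 2-mers: anchor ~ Z then member ~ K[anchor, ] is exactly a pair draw with
  # probability proportional to K_ij; draw all pairs at once
  i2 <- which(kdraw == 2L)
  if (length(i2)) {
    if (sum(K) == 0) {
      # kernel underflow (tiny gaussian bandwidth): anchor + nearest bin
      d2m <- as.matrix(stats::dist(truth$backbone))^2
      diag(d2m) <- Inf
      nn <- apply(d2m, 1L, which.min)
      anchors2 <- sample.int(n, length(i2), replace = TRUE)
      bins_list[i2] <- lapply(anchors2, function(a)
        sort(c(a, nn[a])) - 1L)
    } else {
      ut <- which(upper.tri(K), arr.ind = TRUE)
      picks <- sample.int(nrow(ut), length(i2), replace = TRUE,
                          prob = K[upper.tri(K)])
      bins_list[i2] <- lapply(picks, function(p) unname(ut[p, ]) - 1L)
    }
  }
  # multi-way clusters: per-cluster weighted draws without replacement
  im <- which(kdraw > 2L)
  if (length(im)) {
    anchors <- if (sum(Z) > 0)
      sample.int(n, length(im), replace = TRUE, prob = Z)
    else sample.int(n, length(im), replace = TRUE)
    for (j in seq_along(im)) {
      a <- anchors[j]
      k <- kdraw[im[j]]
      p <- K[a, ]
      if (sum(p > 0) < k - 1L) {
        # kernel underflow (tiny gaussian bandwidth): spatially nearest bins
        others <- setdiff(order(rowSums(sweep(truth$backbone, 2L,
                                              truth$backbone[a, ])^2)),
                          a)[seq_len(k - 1L)]
      } else {
        others <- sample.int(n, k - 1L, prob = p)
      }
      bins_list[im[j]] <- list(sort(c(a, others)) - 1L)
    }
  }
  lapply(seq_len(nc), function(i) {
    b <- sort(bins_list[[i]])
    structure(
      list(cluster_id = sprintf("S%06d", i),
           chromosome = rep(cfg$chromosome, length(b)),
           position = mid[b + 1L],
           mapq = rep(NA_integer_, length(b))),
      class = "sprite_cluster"
    )
  })
}

#' Simulate a Hi-C contact matrix from a ground-truth backbone
#'
#' Pairwise counts are independent Poisson draws with mean
#' \eqn{\lambda_{ij} = c \, d_{ij}^{-\gamma}} where d is 3D backbone
#' distance, \eqn{\gamma} is `contact_decay_exponent` and c is calibrated so
#' the expected total over unordered pairs equals `hic_coverage`. The
#' diagonal is zero.
#'
#' @inheritParams simulate_sprite_clusters
#' @return A [contact_matrix()] with scheme `"hic-raw"`.
#' @export
simulate_hic <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 3L))
  d <- as.matrix(stats::dist(truth$backbone))
  ut <- upper.tri(d)
  if (any(d[ut] == 0))
    stop("coincident backbone points: zero 3D distance has undefined contact rate")
  lam <- d[ut]^(-cfg$contact_decay_exponent)
  lam <- lam * (cfg$hic_coverage / sum(lam))
  counts <- stats::rpois(length(lam), lam)
  M <- matrix(0, cfg$n_bins, cfg$n_bins)
  M[ut] <- counts
  M <- M + t(M)
  contact_matrix(M, cfg$chromosome, cfg$resolution, "hic-raw")
}

#' Write SPRITE clusters in the cluster-file dialect
#'
#' One cluster per line: TAB-separated cluster id then `chrom:position`
#' (`chrom:position:mapq` when a MAPQ is present) read tokens. A `#` header
#' comment records the record count.
#'
#' @param clusters List of `sprite_cluster` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_file <- function(clusters, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste0("# sprite clusters: ", length(clusters), " records"), con)
  for (cl in clusters) {
    tok <- ifelse(is.na(cl$mapq),
                  paste0(cl$chromosome, ":", cl$position),
                  paste0(cl$chromosome, ":", cl$position, ":", cl$mapq))
    writeLines(paste(c(cl$cluster_id, tok), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a contact matrix in the 3-column triplet dialect
#'
#' Upper-triangle (including diagonal) non-zero entries as
#' `coord_i coord_j value` with coordinates = bin start positions; header
#' `#` comments record chromosome, resolution and scheme.
#'
#' @param C A [contact_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_triplet_file <- function(C, path) {
  stopifnot(inherits(C, "contact_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(paste0("# chromosome: ", C$chromosome),
               paste0("# resolution: ", format(C$resolution, scientific = FALSE)),
               paste0("# scheme: ", C$scheme)), con)
  M <- C$values
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    writeLines(paste(format((idx[, 1L] - 1L) * C$resolution, scientific = FALSE, trim = TRUE),
                     format((idx[, 2L] - 1L) * C$resolution, scientific = FALSE, trim = TRUE),
                     format(M[idx], scientific = FALSE, trim = TRUE, digits = 15)), con)
  }
  invisible(path)
}
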