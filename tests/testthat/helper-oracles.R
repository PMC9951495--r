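# Independent oracles and small constructors used across test files.

# Build a sprite_cluster directly (reads assumed pre-filtered when mapq NA).
make_sprite_cluster <- function(id, chrom, pos, mapq = NA_integer_) {
  structure(
    list(cluster_id = id, chromosome = rep_len(chrom, length(pos)),
         position = as.integer(pos),
         mapq = rep_len(as.integer(mapq), length(pos))),
    class = "sprite_cluster"
  )
}

# Build a binned_cluster directly, applying the k conventions.
make_binned <- function(bins, chrom = "chr1") {
  bins <- sort(unique(as.integer(bins)))
  single <- length(bins) == 1L
  structure(
    list(chromosome = chrom, bins = bins,
         k = if (single) 2L else length(bins),
         single_bin_flag = single),
    class = "binned_cluster"
  )
}

# Random binned clusters on [0, n_bins): orders drawn from a small mix.
random_binned_clusters <- function(n_clusters, n_bins, chrom = "chr1",
                                   max_k = 8L) {
  lapply(seq_len(n_clusters), function(i) {
    m <- sample(1:min(max_k, n_bins), 1L)
    make_binned(sample.int(n_bins, m) - 1L, chrom)
  })
}

# Brute-force contact accumulator: triple loop, no shared code with
# build_contact_matrix.
brute_contact_matrix <- function(clusters, scheme, n_bins) {
  w_of <- function(k) switch(scheme,
    "U-W" = 2 / k, "N-W" = 1, "O-W" = k * (k - 1))
  C <- matrix(0, n_bins, n_bins)
  for (cl in clusters) {
    b <- cl$bins + 1L
    if (length(b) == 1L) {
      C[b, b] <- C[b, b] + w_of(2)
    } else {
      w <- w_of(cl$k)
      for (i in seq_along(b)) for (j in seq_along(b)) {
        if (i < j) {
          C[b[i], b[j]] <- C[b[i], b[j]] + w
          C[b[j], b[i]] <- C[b[j], b[i]] + w
        }
      }
    }
  }
  C
}

# Closed-form OLS with two-sided t-test p-values; textbook matrix formulas.
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  XtXi <- solve(t(X1) %*% X1)
  beta <- XtXi %*% t(X1) %*% y
  res <- y - X1 %*% beta
  df <- length(y) - ncol(X1)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  tval <- beta / se
  list(beta = as.numeric(beta),
       p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

# Direct numerical search for the similarity Procrustes minimum: optimises
# rotation (Euler angles), optional reflection, scale, translation.
procrustes_direct_search <- function(X, Y, n_starts = 12L, seed = 99L) {
  set.seed(seed)
  n <- nrow(X)
  rotmat <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])), 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, byrow = TRUE)
    Rx %*% Ry %*% Rz
  }
  best <- Inf
  for (refl in c(1, -1)) {
    F <- diag(c(1, 1, refl))
    obj <- function(par) {
      R <- rotmat(par[1:3]) %*% F
      s <- exp(par[4])
      t <- par[5:7]
      sum((X - (s * Y %*% R + matrix(t, n, 3, byrow = TRUE)))^2)
    }
    for (st in seq_len(n_starts)) {
      p0 <- c(runif(3, -pi, pi), 0, rnorm(3, 0, 0.5))
      o <- optim(p0, obj, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
      if (o$value < best) best <- o$value
    }
  }
  sqrt(best / n)
}

# Weighted raw stress computed independently of the package internals.
weighted_stress_for_test <- function(X, D) {
  d <- as.matrix(dist(X))
  ut <- upper.tri(d) & D$observed
  sum(D$weights[ut] * (D$values[ut] - d[ut])^2)
}
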