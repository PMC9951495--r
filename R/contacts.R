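#' Contact matrix container
#'
#' A symmetric non-negative bin-by-bin matrix of (weighted) contact counts.
#'
#' @param values Numeric n-by-n matrix; must be symmetric, finite and
#'   non-negative.
#' @param chromosome Chromosome name.
#' @param resolution Bin width in base pairs.
#' @param scheme Provenance label: one of the weighting scheme names
#'   (`"U-W"`, `"N-W"`, `"O-W"`), `"hic-raw"`, or `"balanced"`.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, chromosome, resolution, scheme) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (!all(is.finite(values))) stop("contact matrix must be finite")
  if (any(values < 0)) stop("contact matrix must be non-negative")
  if (!isSymmetric(unname(values), tol = 1e-8))
    stop("contact matrix must be symmetric")
  structure(
    list(values = unname(values), chromosome = chromosome,
         resolution = as.numeric(resolution), scheme = scheme),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s, %d x %d bins at %s bp, scheme %s, total mass %.4g\n",
              x$chromosome, nrow(x$values), ncol(x$values),
              format(x$resolution, big.mark = ","), x$scheme, sum(x$values)))
  invisible(x)
}

#' Per-pair increment of a multi-way weighting scheme
#'
#' When a k-way SPRITE cluster is decomposed into its \eqn{\binom{k}{2}}
#' pairwise components, each pair (i, j) increments the contact matrix entry
#' \eqn{C_{ij}} by a scheme-dependent weight:
#' under-weighting (`"U-W"`) adds \eqn{2/k}, neutral-weighting (`"N-W"`) adds
#' 1, and over-weighting (`"O-W"`) adds \eqn{k(k-1)}. At k = 2 the schemes
#' differ only by a factor of two (U-W = N-W = 1, O-W = 2), which is why a
#' preponderance of pairwise clusters makes reconstructions largely
#' scheme-insensitive.
#'
#' @param scheme One of `"U-W"`, `"N-W"`, `"O-W"`.
#' @param k Integer cluster order(s), all >= 2.
#' @return Numeric vector of per-pair increments.
#' @examples
#' increment_weight("U-W", 4)  # 0.5
#' increment_weight("O-W", 5)  # 20
#' @export
increment_weight <- function(scheme, k) {
  scheme <- match.arg(scheme, c("U-W", "N-W", "O-W"))
  if (any(k < 2)) stop("cluster order k must be >= 2")
  k <- as.numeric(k)
  switch(scheme,
    "U-W" = 2 / k,
    "N-W" = rep(1, length(k)),
    "O-W" = k * (k - 1)
  )
}

#' Build a contact matrix from binned SPRITE clusters
#'
#' Each cluster with bins \eqn{b_1 < \dots < b_m} (m >= 2) adds
#' `increment_weight(scheme, k)` to \eqn{C_{b_i b_j}} and \eqn{C_{b_j b_i}}
#' for every unordered bin pair. Single-bin clusters (counted as 2-mers) add
#' `increment_weight(scheme, 2)` once to the diagonal entry of their bin; the
#' diagonal is excluded from reconstruction, so this only keeps the matrix a
#' complete account of the input.
#'
#' @param clusters List of `binned_cluster` objects (see [bin_clusters()]).
#' @param scheme Weighting scheme name; see [increment_weight()].
#' @param binning A [genome_binning()]; all clusters must lie on its
#'   chromosome.
#' @return A [contact_matrix()].
#' @export
build_contact_matrix <- function(clusters, scheme, binning) {
  scheme <- match.arg(scheme, c("U-W", "N-W", "O-W"))
  stopifnot(inherits(binning, "genome_binning"))
  n <- binning$n_bins
  C <- matrix(0, n, n)
  # gather (upper-triangle linear index, weight) pairs across all clusters,
  # then accumulate in one pass; loops over millions of increments in R are
  # otherwise the pipeline's bottleneck at dense coverage
  idx_list <- vector("list", length(clusters))
  w_list <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    stopifnot(inherits(cl, "binned_cluster"))
    if (cl$chromosome != binning$chromosome)
      stop("cluster on ", cl$chromosome, " passed with binning for ",
           binning$chromosome)
    b <- cl$bins
    if (any(b < 0L | b >= n))
      stop("bin index out of range [0, ", n, ") in cluster")
    w <- increment_weight(scheme, 2L)
    if (cl$single_bin_flag) {
      i <- b + 1L
      C[i, i] <- C[i, i] + w
      next
    }
    idx <- b + 1L
    m <- length(idx)
    w <- increment_weight(scheme, cl$k)
    if (m == 2L) {
      idx_list[[ci]] <- (idx[1L] - 1L) * n + idx[2L]
    } else {
      pairs <- utils::combn(idx, 2L)
      idx_list[[ci]] <- (pairs[1L, ] - 1L) * n + pairs[2L, ]
    }
    w_list[[ci]] <- rep(w, length(idx_list[[ci]]))
  }
  lin <- unlist(idx_list)
  if (length(lin)) {
    acc <- rowsum(unlist(w_list), lin)
    li <- as.numeric(rownames(acc))
    i <- (li - 1) %/% n + 1
    j <- li - (i - 1) * n
    C[cbind(i, j)] <- C[cbind(i, j)] + acc[, 1L]
    C[cbind(j, i)] <- C[cbind(j, i)] + acc[, 1L]
  }
  contact_matrix(C, binning$chromosome, binning$resolution, scheme)
}

#' Iterative matrix balancing
#'
#' Generic symmetric iterative proportional fitting that removes coverage
#' bias by equalizing row sums (the role Hi-Corrector plays for raw Hi-C
#' matrices). At each sweep every non-excluded row/column is divided by the
#' square-root of its relative row sum; on convergence all non-excluded row
#' sums are equal, and the matrix is rescaled so their mean is 1. All-zero
#' rows are excluded and stay zero.
#'
#' @param C A [contact_matrix()].
#' @param tol Convergence tolerance on the maximum relative deviation of row
#'   sums from their mean; default 1e-6.
#' @param max_iter Maximum sweeps; default 200.
#' @return A [contact_matrix()] with scheme `"balanced"`.
#' @export
balance_matrix <- function(C, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(C, "contact_matrix"))
  M <- C$values
  nz <- rowSums(M) > 0
  if (!any(nz)) stop("cannot balance an all-zero matrix")
  A <- M[nz, nz, drop = FALSE]
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(A)
    if (any(s == 0))
      stop("row became zero during balancing; matrix structure too sparse")
    rel <- s / mean(s)
    resid <- max(abs(rel - 1))
    if (resid < tol) break
    d <- sqrt(rel)
    A <- A / outer(d, d)
  }
  if (resid >= tol)
    stop("balancing did not converge in ", max_iter,
         " iterations (last residual ", format(resid, digits = 4), ")")
  A <- A / mean(rowSums(A))
  out <- matrix(0, nrow(M), ncol(M))
  out[nz, nz] <- A
  out <- (out + t(out)) / 2   # symmetrize away rounding drift
  contact_matrix(out, C$chromosome, C$resolution, "balanced")
}

#' Distance matrix container for weighted MDS
#'
#' Holds partial pairwise dissimilarities with an observation mask and MDS
#' weights. Unobserved entries (mask `FALSE`) carry weight 0 and do not enter
#' the stress; the diagonal is always unobserved.
#'
#' @param values Numeric n-by-n matrix of dissimilarities (entries outside
#'   the mask are ignored).
#' @param observed Logical symmetric n-by-n mask; if `NULL`, every
#'   off-diagonal finite positive entry is observed.
#' @param weights Numeric n-by-n non-negative weights; if `NULL`, unit weight
#'   on every observed entry.
#' @return An object of class `distance_matrix` with elements `values`,
#'   `observed`, `weights`.
#' @export
distance_matrix <- function(values, observed = NULL, weights = NULL) {
  values <- unname(as.matrix(values))
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (is.null(observed)) {
    observed <- is.finite(values) & values > 0
  }
  observed <- unname(as.matrix(observed))
  diag(observed) <- FALSE
  if (!identical(dim(observed), dim(values)))
    stop("observed mask dimension mismatch")
  if (!isSymmetric(observed)) stop("observed mask must be symmetric")
  if (is.null(weights)) {
    weights <- matrix(0, n, n)
    weights[observed] <- 1
  }
  weights <- unname(as.matrix(weights))
  if (any(weights < 0)) stop("MDS weights must be non-negative")
  if (any(weights[!observed] != 0))
    stop("MDS weights must be zero on unobserved entries")
  v <- values[observed]
  if (any(!is.finite(v)) || any(v < 0))
    stop("observed dissimilarities must be finite and non-negative")
  if (!isSymmetric(unname(ifelse(observed, values, 0)), tol = 1e-10))
    stop("dissimilarities must be symmetric where observed")
  values[!observed] <- NA_real_
  structure(list(values = values, observed = observed, weights = weights),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<distance_matrix> %d points, %d/%d off-diagonal pairs observed\n",
              n, sum(x$observed[upper.tri(x$observed)]), n * (n - 1) / 2))
  invisible(x)
}

#' Power-law conversion of contacts to dissimilarities
#'
#' Maps contact counts to input dissimilarities for MDS via
#' \eqn{D_{ij} = C_{ij}^{\alpha}} with a negative index (default
#' \eqn{\alpha = -1/3}, the biophysically motivated contact-volume scaling;
#' \eqn{-1.08} is a previously used alternative). Zero-contact pairs and the
#' diagonal become unobserved (weight 0) rather than imputed. MDS weights are
#' \eqn{w_{ij} = D_{ij}^{-p}} with `weight_power` p (default 1: weights
#' inversely proportional to distance, so short-range dissimilarities — which
#' are estimated from many contacts — dominate the stress).
#'
#' @param C A [contact_matrix()].
#' @param alpha Negative power-law index; default `-1/3`.
#' @param weight_power Exponent p of the inverse-distance weights; default 1.
#'   Use 0 for unweighted stress.
#' @return A [distance_matrix()].
#' @examples
#' b <- genome_binning("chr1", 75000, 25000)
#' C <- contact_matrix(matrix(c(0, 8, 27, 8, 0, 1, 27, 1, 0), 3), "chr1", 25000, "N-W")
#' D <- power_law_distance(C)
#' D$values[1, 2]   # 8^(-1/3) = 0.5
#' @export
power_law_distance <- function(C, alpha = -1/3, weight_power = 1) {
  stopifnot(inherits(C, "contact_matrix"))
  if (alpha >= 0) stop("power-law index alpha must be negative")
  M <- C$values
  observed <- M > 0
  diag(observed) <- FALSE
  D <- matrix(NA_real_, nrow(M), ncol(M))
  D[observed] <- M[observed]^alpha
  W <- matrix(0, nrow(M), ncol(M))
  W[observed] <- D[observed]^(-weight_power)
  distance_matrix(D, observed, W)
}
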