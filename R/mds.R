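#' Configuration for stress-majorization MDS
#'
#' @param dim Embedding dimension; default 3 (chromatin configurations live
#'   in 3D).
#' @param max_iter Maximum majorization iterations; default 1000.
#' @param rel_tol Relative stress-decrease threshold for convergence;
#'   default 1e-6.
#' @param init Initialization: `"classical"` (classical scaling on the
#'   shortest-path-completed dissimilarity matrix; deterministic) or
#'   `"random"`.
#' @param seed Integer seed governing random initializations; default 1.
#' @param n_restarts Number of runs (first uses `init`, the rest are random
#'   starts); the lowest-stress result is returned. Default 1.
#' @return An object of class `mds_config`.
#' @export
mds_config <- function(dim = 3L, max_iter = 1000L, rel_tol = 1e-6,
                       init = c("classical", "random"), seed = 1L,
                       n_restarts = 1L) {
  init <- match.arg(init)
  stopifnot(dim >= 1, rel_tol > 0, n_restarts >= 1, max_iter >= 1)
  structure(list(dim = as.integer(dim), max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, init = init, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "mds_config")
}

# Connected components of the observation graph; errors if disconnected.
check_connected <- function(observed) {
  g <- igraph::graph_from_adjacency_matrix(observed * 1, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("observation graph is disconnected (", comp$no,
         " components of sizes ", sizes, ")")
  }
  invisible(TRUE)
}

#' Classical-scaling initialization with shortest-path completion
#'
#' Fills unobserved dissimilarities with shortest-path distances over the
#' graph of observed entries (edge length = dissimilarity), then applies
#' classical scaling (double-centering and eigendecomposition) to obtain a
#' starting configuration. On a fully observed exact Euclidean input this
#' already attains the global optimum.
#'
#' @param D A [distance_matrix()].
#' @param dim Embedding dimension; default 3.
#' @return An n-by-dim coordinate matrix.
#' @export
classical_init <- function(D, dim = 3L) {
  stopifnot(inherits(D, "distance_matrix"))
  check_connected(D$observed)
  n <- nrow(D$values)
  A <- matrix(0, n, n)
  A[D$observed] <- D$values[D$observed]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  full <- igraph::distances(g)
  # zero-length observed edges are legal; distances() handles them
  B <- -0.5 * full^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(dim)], 0)
  X <- e$vectors[, seq_len(dim), drop = FALSE] %*% diag(sqrt(ev), dim)
  X
}

# Weighted raw stress sigma(X) = sum_{i<j observed} w_ij (D_ij - d_ij(X))^2
weighted_stress <- function(X, D) {
  d <- as.matrix(stats::dist(X))
  ut <- upper.tri(d) & D$observed
  sum(D$weights[ut] * (D$values[ut] - d[ut])^2)
}

# One Guttman-transform pass given the precomputed Moore-Penrose inverse of
# the weight Laplacian V (Vinv).
guttman_update <- function(X, D, Vinv) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  B <- matrix(0, n, n)
  pos <- D$observed & d > 0
  B[pos] <- -D$weights[pos] * D$values[pos] / d[pos]
  diag(B) <- -rowSums(B)
  Vinv %*% (B %*% X)
}

smacof_run <- function(D, X0, max_iter, rel_tol, Vinv) {
  X <- X0
  sigma <- weighted_stress(X, D)
  trace <- sigma
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- guttman_update(X, D, Vinv)
    s_new <- weighted_stress(X, D)
    trace <- c(trace, s_new)
    if (sigma > 0 && (sigma - s_new) / sigma < rel_tol) {
      converged <- TRUE
      sigma <- s_new
      break
    }
    if (sigma == 0) { converged <- TRUE; break }
    sigma <- s_new
  }
  list(X = X, stress = sigma, trace = trace, converged = converged)
}

#' Weighted MDS by stress majorization (SMACOF)
#'
#' Minimizes the weighted raw stress
#' \eqn{\sigma(X) = \sum_{i<j} w_{ij} (D_{ij} - d_{ij}(X))^2}
#' over n-point configurations X in `dim` dimensions, where the sum runs over
#' observed pairs and \eqn{d_{ij}(X)} is Euclidean distance. Each iteration
#' applies the Guttman transform \eqn{X \leftarrow V^{+} B(X) X}, which
#' never increases the stress; the Moore-Penrose inverse of the weight
#' Laplacian V is computed once and reused. Iteration stops when the relative
#' stress decrease drops below `rel_tol` or `max_iter` is reached. With
#' `n_restarts > 1` the lowest-stress run wins. The returned configuration is
#' translated to zero centroid.
#'
#' @param D A [distance_matrix()]; its observation graph must be connected
#'   and at least one weight positive.
#' @param config An [mds_config()].
#' @return An object of class `reconstruction`: list with `coords`
#'   (n-by-dim, zero centroid), `stress`, `stress_trace` (non-increasing),
#'   `converged`, `seed_used`, `n_iter`.
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' D <- distance_matrix(as.matrix(dist(pts)))
#' r <- smacof_mds(D)
#' r$stress   # ~0: exact Euclidean input is perfectly embeddable
#' @export
smacof_mds <- function(D, config = mds_config()) {
  stopifnot(inherits(D, "distance_matrix"), inherits(config, "mds_config"))
  n <- nrow(D$values)
  if (n < config$dim + 1L)
    stop("need at least dim + 1 = ", config$dim + 1L, " points")
  if (all(D$weights == 0)) stop("all MDS weights are zero")
  check_connected(D$weights > 0)

  W <- D$weights
  V <- -W
  diag(V) <- rowSums(W)
  # Moore-Penrose inverse of the Laplacian of a connected weight graph:
  # pinv(V) = (V + J/n)^{-1} - J/n with J the all-ones matrix.
  J <- matrix(1 / n, n, n)
  Vinv <- solve(V + J) - J

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    use_random <- config$init == "random" || r > 1L
    seed_r <- (config$seed + 7919L * (r - 1L)) %% .Machine$integer.max
    if (use_random) {
      set.seed(seed_r)
      X0 <- matrix(stats::rnorm(n * config$dim), n, config$dim)
      dobs <- D$values[D$observed]
      if (length(dobs)) X0 <- X0 * stats::median(dobs)
    } else {
      X0 <- classical_init(D, config$dim)
    }
    run <- smacof_run(D, X0, config$max_iter, config$rel_tol, Vinv)
    if (is.null(best) || run$stress < best$stress) {
      best <- run
      best$seed_used <- seed_r
    }
  }
  coords <- sweep(best$X, 2L, colMeans(best$X))
  structure(
    list(coords = coords, stress = best$stress, stress_trace = best$trace,
         converged = best$converged, seed_used = best$seed_used,
         n_iter = length(best$trace) - 1L, dim = config$dim),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d points in %dD, stress %.6g after %d iterations%s\n",
              nrow(x$coords), x$dim, x$stress, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Write a reconstruction as a TSV of coordinates
#'
#' Columns: `bin` (0-based), `x`, `y`, `z` (or as many coordinate columns as
#' the embedding dimension).
#'
#' @param recon A `reconstruction` from [smacof_mds()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reconstruction <- function(recon, path) {
  stopifnot(inherits(recon, "reconstruction"))
  df <- data.frame(bin = seq_len(nrow(recon$coords)) - 1L, recon$coords)
  names(df) <- c("bin", c("x", "y", "z", paste0("c", seq_len(10)))[seq_len(ncol(recon$coords))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
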