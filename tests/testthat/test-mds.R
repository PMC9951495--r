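# exact-arithmetic style settings used by the recovery checks
tight <- function(seed = 1L, n_restarts = 1L, init = "classical")
  mds_config(rel_tol = 1e-12, max_iter = 5000, seed = seed,
             n_restarts = n_restarts, init = init)

rms_radius <- function(X) sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))

test_that("perfectly embeddable distances are recovered with near-zero stress", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  D <- distance_matrix(as.matrix(dist(square)))
  r <- smacof_mds(D, tight())
  expect_lt(r$stress, 1e-10)
  d_hat <- as.matrix(dist(r$coords))
  expect_equal(d_hat[upper.tri(d_hat)],
               as.matrix(dist(square))[upper.tri(d_hat)], tolerance = 1e-6)
  expect_equal(colMeans(r$coords), c(0, 0, 0), tolerance = 1e-12)
})

test_that("a random 3D configuration is recovered from its full distance matrix", {
  set.seed(21)
  X <- matrix(rnorm(90), 30, 3)
  D <- distance_matrix(as.matrix(dist(X)))
  r <- smacof_mds(D, tight())
  pr <- procrustes_align(X, r$coords)
  expect_lt(pr$rmse, 1e-4 * rms_radius(X))
})

test_that("recovery survives 40% missing pairs on a connected mask", {
  set.seed(22)
  X <- matrix(rnorm(90), 30, 3)
  dX <- as.matrix(dist(X))
  mask <- matrix(FALSE, 30, 30)
  ut <- which(upper.tri(mask), arr.ind = TRUE)
  drop <- sample(nrow(ut), round(0.4 * nrow(ut)))
  mask[ut] <- TRUE
  mask[ut[drop, , drop = FALSE]] <- FALSE
  # keep the backbone path so the graph stays connected
  for (i in 1:29) mask[i, i + 1] <- TRUE
  mask <- mask | t(mask)
  D <- distance_matrix(dX, observed = mask)
  r <- smacof_mds(D, tight())
  pr <- procrustes_align(X, r$coords)
  expect_lt(pr$rmse, 1e-3 * rms_radius(X))
})

test_that("stress trace is non-increasing on every run", {
  set.seed(23)
  for (i in 1:5) {
    X <- matrix(rnorm(45), 15, 3)
    dX <- as.matrix(dist(X)) * (1 + matrix(runif(225, -0.2, 0.2), 15))
    dX <- (dX + t(dX)) / 2; diag(dX) <- 0
    r <- smacof_mds(distance_matrix(dX),
                    mds_config(seed = i, init = "random", max_iter = 300))
    expect_true(all(diff(r$stress_trace) <= 1e-9 * max(1, r$stress_trace[1])))
  }
})

test_that("classical initialization is exact on fully observed Euclidean input", {
  set.seed(24)
  X <- matrix(rnorm(60), 20, 3)
  D <- distance_matrix(as.matrix(dist(X)))
  X0 <- classical_init(D, 3)
  expect_lt(weighted_stress_for_test(X0, D), 1e-18 * sum(D$values[D$observed]^2))
})

test_that("shortest-path completion fills unobserved legs additively", {
  # collinear points at 0, 1, 3: pair (1,3) unobserved
  vals <- matrix(0, 3, 3)
  vals[1, 2] <- vals[2, 1] <- 1
  vals[2, 3] <- vals[3, 2] <- 2
  obs <- vals > 0
  D <- distance_matrix(vals, observed = obs)
  X0 <- classical_init(D, 3)
  d0 <- as.matrix(dist(X0))
  expect_equal(d0[1, 3], 3, tolerance = 1e-8)   # 1 + 2 via the middle point
})

test_that("classical init at least matches random init in most masked trials", {
  set.seed(25)
  wins <- 0L
  for (i in 1:8) {
    X <- matrix(rnorm(54), 18, 3)
    dX <- as.matrix(dist(X))
    mask <- matrix(FALSE, 18, 18)
    ut <- which(upper.tri(mask), arr.ind = TRUE)
    keep <- sample(nrow(ut), round(0.7 * nrow(ut)))
    mask[ut[keep, , drop = FALSE]] <- TRUE
    for (j in 1:17) mask[j, j + 1] <- TRUE
    mask <- mask | t(mask)
    D <- distance_matrix(dX, observed = mask)
    s_c <- smacof_mds(D, mds_config(seed = i, init = "classical"))$stress
    s_r <- smacof_mds(D, mds_config(seed = i, init = "random"))$stress
    if (s_c <= s_r + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("permuting input points permutes the solution (up to similarity)", {
  set.seed(26)
  X <- matrix(rnorm(48), 16, 3)
  D <- distance_matrix(as.matrix(dist(X)))
  r1 <- smacof_mds(D, tight())
  perm <- sample(16)
  Dp <- distance_matrix(D$values[perm, perm] |> (\(m) {m[is.na(m)] <- 0; m})(),
                        observed = D$observed[perm, perm])
  r2 <- smacof_mds(Dp, tight())
  pr <- procrustes_align(r1$coords[perm, ], r2$coords)
  expect_lt(pr$rmse, 1e-6 * rms_radius(X))
})

test_that("scaling the input rescales the solution (matched seeds)", {
  set.seed(27)
  X <- matrix(rnorm(60), 20, 3)
  dX <- as.matrix(dist(X))
  D1 <- distance_matrix(dX)
  D2 <- distance_matrix(5 * dX)
  r1 <- smacof_mds(D1, tight(seed = 4, init = "random"))
  r2 <- smacof_mds(D2, tight(seed = 4, init = "random"))
  pr <- procrustes_align(r1$coords, r2$coords)
  expect_lt(pr$rmse, 1e-6 * rms_radius(r1$coords))
})

test_that("identical seed and input reproduce the run bitwise", {
  set.seed(28)
  X <- matrix(rnorm(36), 12, 3)
  noise <- matrix(0.1 * sin(1:144), 12, 12)
  noise <- (noise + t(noise)) / 2
  D <- distance_matrix(as.matrix(dist(X)) * (1 + noise))
  cfg <- mds_config(seed = 17, init = "random", n_restarts = 2)
  r1 <- smacof_mds(D, cfg)
  r2 <- smacof_mds(D, cfg)
  expect_identical(r1$coords, r2$coords)
  expect_identical(r1$stress_trace, r2$stress_trace)
  expect_identical(r1$seed_used, r2$seed_used)
})

test_that("disconnected observation graphs and degenerate weights are rejected", {
  vals <- matrix(0, 4, 4)
  vals[1, 2] <- vals[2, 1] <- 1
  vals[3, 4] <- vals[4, 3] <- 1
  D <- distance_matrix(vals, observed = vals > 0)
  expect_error(smacof_mds(D), "disconnected.*2 components")
  W0 <- matrix(0, 4, 4)
  D2 <- distance_matrix(matrix(1, 4, 4), observed = matrix(TRUE, 4, 4) & !diag(4) > 0,
                        weights = W0)
  expect_error(smacof_mds(D2), "weights are zero")
  D3 <- distance_matrix(as.matrix(dist(matrix(rnorm(6), 2, 3))))
  expect_error(smacof_mds(D3), "at least")
})
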