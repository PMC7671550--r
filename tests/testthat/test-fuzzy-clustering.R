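test_that("medoid update minimizes the membership-weighted cost", {
  # 1-D units at 0, 1, 5 all in one cluster: unit 2 has weighted cost
  # 1 + 16 = 17 versus 1 + 25 = 26 and 16 + 25 = 41
  C <- matrix(c(0, 1, 5), ncol = 1)
  U <- cbind(c(1, 1, 1), c(0, 0, 0))
  med <- update_medoids(C, U, f = 1.5)
  expect_equal(med[1L], 2L)
  costs <- vapply(1:3, function(i) brute_medoid_cost(C, U[, 1L], 1.5, i),
                  numeric(1))
  expect_equal(costs, c(26, 17, 41))
  # a cluster with a single fully assigned unit takes that unit as medoid
  U2 <- cbind(c(1, 0, 0), c(0, 1, 1))
  expect_equal(update_medoids(C, U2, f = 1.5)[1L], 1L)
  # brute-force agreement on random instances (k = 2, no collisions forced)
  set.seed(13)
  for (r in 1:10) {
    Cr <- matrix(rnorm(24), 8, 3)
    Ur <- matrix(runif(16), 8, 2); Ur <- Ur / rowSums(Ur)
    med <- update_medoids(Cr, Ur, f = 1.5)
    for (l in 1:2) {
      costs <- vapply(1:8, function(i) brute_medoid_cost(Cr, Ur[, l], 1.5, i),
                      numeric(1))
      costs[med[-l]] <- Inf          # distinctness constraint
      expect_equal(brute_medoid_cost(Cr, Ur[, l], 1.5, med[l]), min(costs))
    }
  }
})

test_that("membership update follows the closed form with one-hot medoids", {
  C <- matrix(c(0, 1, 2), ncol = 1)
  U <- update_memberships(C, medoids = c(1L, 3L), f = 2)
  # middle unit equidistant: (0.5, 0.5); medoids one-hot
  expect_equal(U[2, ], c(0.5, 0.5))
  expect_equal(U[1, ], c(1, 0))
  expect_equal(U[3, ], c(0, 1))
  # f = 2: memberships proportional to 1/d2
  C4 <- rbind(c(0, 0), c(2, 0), c(0, 1))  # d2 of unit 3: 1 and 5
  U4 <- update_memberships(C4, c(1L, 2L), f = 2)
  expect_equal(U4[3, ], c(5, 1) / 6)   # d2^-1 normalized: (1/1, 1/5)
  expect_error(update_memberships(C, c(1L, 1L), f = 2), "distinct")
})

test_that("objective equals the direct double sum", {
  set.seed(14)
  C <- matrix(rnorm(30), 10, 3)
  U <- matrix(runif(20), 10, 2); U <- U / rowSums(U)
  med <- c(2L, 7L)
  D2 <- as.matrix(dist(C))^2
  direct <- sum(sapply(1:10, function(i)
    sum(U[i, ]^1.5 * D2[i, med])))
  expect_equal(fkmed_objective(C, U, med, f = 1.5), direct)
  # all units identical: zero objective
  C0 <- matrix(1, 5, 2)
  expect_equal(fkmed_objective(C0, matrix(0.5, 5, 2), c(1L, 2L), 1.5), 0)
})

test_that("fkmed recovers well-separated clouds exactly", {
  b <- generate_coefficient_blobs(10, rbind(rep(0, 3), rep(10, 3)),
                                  spread = 0.5, seed = 15)
  p <- fkmed(b$C, 2, seed = 16, n_starts = 10)
  expect_equal(adjusted_rand_index(hard_labels(p), b$labels), 1)
  expect_true(p$converged)
  # membership contract
  expect_lt(max(abs(rowSums(p$U) - 1)), 1e-10)
  expect_true(all(p$U >= 0 & p$U <= 1))
  # medoid rows one-hot
  for (l in seq_along(p$medoids))
    expect_equal(p$U[p$medoids[l], l], 1)
})

test_that("duplicate-row groups yield one-hot memberships and zero objective", {
  C <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  p <- fkmed(C, 2, seed = 17, n_starts = 5)
  expect_equal(p$objective, 0)
  expect_true(all(p$U %in% c(0, 1)))
  expect_setequal(hard_labels(p)[1:3], hard_labels(p)[1])
  expect_setequal(hard_labels(p)[4:6], hard_labels(p)[4])
  expect_false(hard_labels(p)[1] == hard_labels(p)[4])
})

test_that("multi-start fkmed attains the enumeration optimum on small instances", {
  hits <- 0L
  for (i in 1:20) {
    b <- small_blob_instance(100 + i)
    p <- fkmed(b$C, 2, n_starts = 30, seed = 300 + i)
    o <- global_oracle_fkmed(b$C, 2)
    expect_lt(max(abs(rowSums(o$U) - 1)), 1e-10)
    if (p$objective <= o$objective + 1e-8) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("objective trace is non-increasing within every run", {
  for (i in 1:5) {
    b <- small_blob_instance(200 + i)
    p <- fkmed(b$C, 2, seed = 400 + i, keep_trace = TRUE, n_starts = 3)
    expect_true(all(diff(p$trace) <= 1e-10))
  }
})

test_that("fuzziness extremes harden or equalize the memberships", {
  b <- generate_coefficient_blobs(6, rbind(rep(0, 3), rep(8, 3)),
                                  spread = 0.7, seed = 18)
  # f -> 1+: memberships approach {0, 1} and match hard k-medoids
  p1 <- fkmed(b$C, 2, f = 1.01, seed = 19, n_starts = 10)
  expect_true(all(pmin(p1$U, 1 - p1$U) < 0.01))
  expect_equal(adjusted_rand_index(hard_labels(p1), b$labels), 1)
  # large f equalizes: near-equidistant configuration (scaled simplex)
  set.seed(20)
  Cs <- 3 * diag(12) + matrix(rnorm(144, 0, 0.05), 12, 12)
  p20 <- fkmed(Cs, 2, f = 20, seed = 21, n_starts = 10)
  nonmed <- setdiff(1:12, p20$medoids)
  expect_lt(max(abs(p20$U[nonmed, ] - 0.5)), 0.02)
  # deviation from 1/k shrinks as f grows on generic data
  devs <- vapply(c(2, 5, 20), function(f) {
    p <- fkmed(b$C, 2, f = f, seed = 22, n_starts = 5)
    max(abs(p$U[setdiff(1:12, p$medoids), ] - 0.5))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("permuting the unit order permutes the solution", {
  b <- generate_coefficient_blobs(8, rbind(rep(0, 3), rep(9, 3)),
                                  spread = 0.6, seed = 23)
  perm <- sample(nrow(b$C))
  p0 <- fkmed(b$C, 2, seed = 24, n_starts = 10)
  p1 <- fkmed(b$C[perm, ], 2, seed = 25, n_starts = 10)
  expect_equal(p1$objective, p0$objective, tolerance = 1e-10)
  expect_equal(adjusted_rand_index(hard_labels(p0)[perm], hard_labels(p1)), 1)
})

test_that("fkm centroids are weighted means and agree with fkmed on separated data", {
  # k-means-style sanity: two tight symmetric pairs, centroids at the pairs
  C <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  pm <- fkm(C, 2, seed = 26, n_starts = 10)
  expect_equal(sort(pm$centroids[, 1]), c(0.05, 10.05), tolerance = 0.05)
  # centroid formula: weighted mean of units under the final memberships
  W <- pm$U^pm$f
  H <- (t(W) %*% C) / colSums(W)
  expect_equal(unname(pm$centroids), unname(H), tolerance = 1e-6)
  b <- generate_coefficient_blobs(10, rbind(rep(0, 3), rep(10, 3)),
                                  spread = 0.5, seed = 27)
  pk <- fkmed(b$C, 2, seed = 28, n_starts = 10)
  pm2 <- fkm(b$C, 2, seed = 28, n_starts = 10)
  expect_equal(adjusted_rand_index(hard_labels(pk), hard_labels(pm2)), 1)
})

test_that("degenerate clustering inputs are rejected", {
  C <- matrix(rnorm(12), 4, 3)
  expect_error(fkmed(C, k = 4), "k must")
  expect_error(fkmed(C, k = 1), "k must")
  expect_error(fkmed(C, k = 2, f = 1), "f must")
  expect_error(fkm(C, k = 4), "k must")
  expect_error(global_oracle_fkmed(matrix(rnorm(48), 16, 3), 2), "n <= 15")
})

test_that("the enumeration oracle matches hand enumeration on colinear points", {
  # units at 0, 1, 10, 11; k = 2, f = 2. Hand enumeration of all six
  # medoid pairs shows {0, 10} (and its mirror {1, 11}) is optimal:
  # unit 1 has d2 = (1, 81), u = (81, 1)/82, cost (81^2 + 81)/82^2;
  # unit 11 has d2 = (121, 1), u = (1, 121)/122, cost (121 + 121^2)/122^2
  C <- matrix(c(0, 1, 10, 11), ncol = 1)
  o <- global_oracle_fkmed(C, 2, f = 2)
  hand <- (81^2 + 81) / 82^2 + (121 + 121^2) / 122^2
  expect_equal(o$objective, hand, tolerance = 1e-12)
  expect_setequal((sort(o$medoids) - 1L) %/% 2L, 0:1)  # one per pair
  # n = k: every unit its own medoid, zero objective
  o2 <- global_oracle_fkmed(C, 4)
  expect_equal(o2$objective, 0)
  # duplicate rows: objective invariant to which duplicate serves as medoid
  Cd <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(global_oracle_fkmed(Cd, 2)$objective, 0)
})

test_that("partitions serialize with memberships, assignments and medoid flags", {
  b <- generate_coefficient_blobs(5, rbind(rep(0, 2), rep(6, 2)),
                                  spread = 0.4, seed = 29)
  p <- fkmed(b$C, 2, seed = 30, n_starts = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_partition(p, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 10L)
  expect_equal(sum(back$is_medoid), 2L)
  expect_equal(back$max_cluster, hard_labels(p))
})
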