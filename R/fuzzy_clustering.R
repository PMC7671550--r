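# Squared Euclidean distance matrix between the rows of C.
sqdist_matrix <- function(C) {
  D <- as.matrix(stats::dist(C))^2
  dimnames(D) <- NULL
  D
}

# Membership update (the Lagrangian stationary point): for each unit,
# u_il = d2_il^{-1/(f-1)} / sum_l' d2_il'^{-1/(f-1)}. A unit at zero
# distance from a prototype (e.g. a medoid itself) gets membership 1 there.
memberships_from_d2 <- function(D2, f) {
  n <- nrow(D2); k <- ncol(D2)
  U <- matrix(0, n, k)
  zero <- D2 <= 0
  hit <- rowSums(zero) > 0L
  if (any(hit)) {
    first0 <- apply(zero[hit, , drop = FALSE], 1L, which.max)
    U[cbind(which(hit), first0)] <- 1
  }
  if (any(!hit)) {
    W <- D2[!hit, , drop = FALSE]^(-1 / (f - 1))
    U[!hit, ] <- W / rowSums(W)
  }
  U
}

#' Update the medoids given a membership matrix
#'
#' For each cluster `l` the medoid is the observed unit `i` minimizing the
#' membership-weighted sum of squared Euclidean distances
#' `sum_i' u_i'l^f * d2(c_i, c_i')` over all candidate units. Ties are
#' broken toward the smallest unit index. If two clusters select the same
#' unit, the cluster with the lower weighted cost keeps it and the other
#' takes its next-best candidate (medoids must be distinct).
#'
#' @param C Units-by-s coefficient matrix (or a precomputed squared
#'   distance matrix via `D2`).
#' @param U n-by-k membership matrix.
#' @param f Fuzziness exponent (> 1).
#' @param D2 Optional precomputed squared-distance matrix.
#' @return Integer vector of `k` distinct medoid unit indices.
#' @export
update_medoids <- function(C, U, f, D2 = NULL) {
  if (is.null(D2)) D2 <- sqdist_matrix(C)
  W <- U^f
  cost <- D2 %*% W                       # cost[i, l]: unit i as medoid of l
  k <- ncol(U)
  med <- integer(k)
  taken <- logical(nrow(D2))
  # assign clusters in order of their best achievable cost so that a
  # collision is resolved in favour of the lower-cost cluster
  ord <- order(apply(cost, 2L, min))
  for (l in ord) {
    cl <- cost[, l]
    cl[taken] <- Inf
    med[l] <- which.min(cl)              # which.min takes the smallest index on ties
    taken[med[l]] <- TRUE
  }
  med
}

#' Update the membership matrix given medoids
#'
#' Applies the closed-form membership update with squared Euclidean
#' distances to the medoid coefficient rows; a unit coinciding with a
#' medoid receives membership 1 to that cluster.
#'
#' @param C Units-by-s coefficient matrix.
#' @param medoids Integer vector of `k` distinct medoid indices.
#' @param f Fuzziness exponent (> 1).
#' @param D2 Optional precomputed squared-distance matrix.
#' @return n-by-k membership matrix with rows summing to 1.
#' @export
update_memberships <- function(C, medoids, f, D2 = NULL) {
  if (anyDuplicated(medoids)) stop("medoids must be distinct", call. = FALSE)
  if (is.null(D2)) D2 <- sqdist_matrix(C)
  memberships_from_d2(D2[, medoids, drop = FALSE], f)
}

#' Fuzzy k-medoids objective value
#'
#' `sum_i sum_l u_il^f d2(c_i, h_l)` with `h_l` the medoid coefficient
#' rows and `d2` squared Euclidean distance.
#'
#' @inheritParams update_memberships
#' @param U n-by-k membership matrix.
#' @return Scalar objective value.
#' @export
fkmed_objective <- function(C, U, medoids, f, D2 = NULL) {
  if (is.null(D2)) D2 <- sqdist_matrix(C)
  sum(U^f * D2[, medoids, drop = FALSE])
}

random_membership <- function(n, k) {
  # each row uniform on the simplex (flat Dirichlet)
  G <- matrix(stats::rexp(n * k), n, k)
  G / rowSums(G)
}

fkmed_single <- function(D2, k, f, tol, max_iter, keep_trace) {
  n <- nrow(D2)
  # random restart: k distinct random units as provisional medoids, with
  # the closed-form memberships they induce. Starting from a flat random
  # U instead tends to begin near the uniform-membership saddle and gets
  # trapped in poor local optima on weakly separated data.
  U <- memberships_from_d2(D2[, sample.int(n, k), drop = FALSE], f)
  med <- update_medoids(NULL, U, f, D2 = D2)
  obj <- fkmed_objective(NULL, U, med, f, D2 = D2)
  trace <- if (keep_trace) obj else NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    U_new <- memberships_from_d2(D2[, med, drop = FALSE], f)
    med_new <- update_medoids(NULL, U_new, f, D2 = D2)
    # guard: collision resolution is heuristic, so never accept a medoid
    # update that increases the objective under the current memberships
    if (fkmed_objective(NULL, U_new, med_new, f, D2 = D2) >
        fkmed_objective(NULL, U_new, med, f, D2 = D2)) med_new <- med
    obj_new <- fkmed_objective(NULL, U_new, med_new, f, D2 = D2)
    if (keep_trace) trace <- c(trace, obj_new)
    delta <- sqrt(sum((U_new - U)^2))
    U <- U_new; med <- med_new; obj <- obj_new
    if (delta <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # medoid rows are exactly one-hot
  U <- memberships_from_d2(D2[, med, drop = FALSE], f)
  list(U = U, medoids = med, objective = fkmed_objective(NULL, U, med, f, D2 = D2),
       n_iter = iter, converged = converged, trace = trace)
}

new_fuzzy_partition <- function(run, f, k, seed, ids, prototype_type,
                                centroids = NULL) {
  structure(list(
    U = run$U, medoids = run$medoids, centroids = centroids,
    objective = run$objective, n_iter = run$n_iter,
    converged = run$converged, trace = run$trace, f = f, k = k,
    seed = seed, unit_ids = ids, prototype = prototype_type
  ), class = "fuzzy_partition")
}

#' Fuzzy k-medoids clustering (on functional coefficients or raw series)
#'
#' Minimizes `sum_i sum_l u_il^f d2(c_i, h_l)` subject to memberships in
#' \[0, 1\] with unit row sums and prototypes constrained to be observed
#' units (medoids), by alternating the medoid and membership updates from
#' a random membership start until the Frobenius change in `U` falls below
#' `tol`. Multiple seeded random starts are run and the solution with the
#' lowest objective returned. Rows of `C` may equally be raw observed
#' series; the algorithm only uses squared Euclidean distances between
#' rows.
#'
#' @param C Units-by-variables numeric matrix (`n >= 3` rows).
#' @param k Number of clusters, `2 <= k < n`.
#' @param f Fuzziness exponent, `> 1`; values up to 1.5 are recommended
#'   for medoid-based algorithms (default 1.5).
#' @param tol Convergence threshold on the Frobenius norm of successive
#'   membership matrices (default 1e-6).
#' @param max_iter Iteration cap per start (default 1000).
#' @param n_starts Number of random starts (default 30).
#' @param seed Optional integer seed for reproducible starts.
#' @param keep_trace Record the objective after every iteration (for
#'   monotonicity checks); default `FALSE`.
#' @return Object of class `fuzzy_partition`: membership matrix `U`,
#'   `medoids` (unit indices), `objective`, `n_iter`, `converged`,
#'   `trace`, `f`, `k`, `seed`, `unit_ids`.
#' @export
fkmed <- function(C, k, f = 1.5, tol = 1e-6, max_iter = 1000L,
                  n_starts = 30L, seed = NULL, keep_trace = FALSE) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  if (f <= 1) stop("fuzziness f must be > 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  D2 <- sqdist_matrix(C)
  best <- NULL
  for (st in seq_len(n_starts)) {
    run <- fkmed_single(D2, k, f, tol, max_iter, keep_trace)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  new_fuzzy_partition(best, f, k, seed, rownames(C), "medoid")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf(
    "Fuzzy %s partition: n = %d, k = %d, f = %g, objective = %.6g (%s in %d iterations)\n",
    x$prototype, nrow(x$U), x$k, x$f, x$objective,
    if (x$converged) "converged" else "not converged", x$n_iter))
  sizes <- table(factor(hard_labels(x), levels = seq_len(x$k)))
  cat("Cluster sizes (max membership):", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Hard cluster labels from a fuzzy partition
#'
#' Assigns every unit to its maximum-membership cluster; ties go to the
#' lowest cluster index.
#'
#' @param partition A `fuzzy_partition` or a membership matrix `U`.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
hard_labels <- function(partition) {
  U <- if (inherits(partition, "fuzzy_partition")) partition$U else partition
  apply(U, 1L, which.max)
}

#' Fuzzy k-means clustering (centroid variant)
#'
#' Drops the medoid constraint: prototypes are the membership-weighted
#' means `h_l = sum_i u_il^f c_i / sum_i u_il^f`, alternated with the same
#' closed-form membership update against the centroids.
#'
#' @inheritParams fkmed
#' @return Object of class `fuzzy_partition` with a `centroids` matrix
#'   (`k x s`) instead of medoid indices.
#' @export
fkm <- function(C, k, f = 1.5, tol = 1e-6, max_iter = 1000L,
                n_starts = 30L, seed = NULL, keep_trace = FALSE) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  if (f <= 1) stop("fuzziness f must be > 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cn2 <- rowSums(C^2)
  d2_to <- function(H) {             # n x k squared distances to centroid rows
    d <- outer(cn2, rowSums(H^2), "+") - 2 * C %*% t(H)
    pmax(d, 0)
  }
  run_one <- function() {
    U <- random_membership(n, k)
    obj <- Inf; trace <- NULL; converged <- FALSE; iter <- 0L
    repeat {
      iter <- iter + 1L
      W <- U^f
      H <- (t(W) %*% C) / colSums(W)
      D2 <- d2_to(H)
      U_new <- memberships_from_d2(D2, f)
      obj <- sum(U_new^f * d2_to(H))
      if (keep_trace) trace <- c(trace, obj)
      delta <- sqrt(sum((U_new - U)^2))
      U <- U_new
      if (delta <= tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    list(U = U, medoids = NULL, centroids = H, objective = obj,
         n_iter = iter, converged = converged, trace = trace)
  }
  best <- NULL
  for (st in seq_len(n_starts)) {
    run <- run_one()
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  p <- new_fuzzy_partition(best, f, k, seed, rownames(C), "centroid",
                           centroids = best$centroids)
  p
}

#' Exhaustive global optimum of the fuzzy k-medoids objective
#'
#' Enumerates every k-subset of units as the medoid set, computes the
#' optimal memberships in closed form, and returns the minimum objective.
#' Intended as a testing oracle; refuses instances with `n > 15`.
#'
#' @inheritParams fkmed
#' @return List `medoids`, `U`, `objective`.
#' @export
global_oracle_fkmed <- function(C, k, f = 1.5) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n > 15L) stop("oracle limited to n <= 15", call. = FALSE)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  D2 <- sqdist_matrix(C)
  subsets <- utils::combn(n, k)
  best <- NULL
  for (j in seq_len(ncol(subsets))) {
    med <- subsets[, j]
    U <- memberships_from_d2(D2[, med, drop = FALSE], f)
    obj <- sum(U^f * D2[, med, drop = FALSE])
    if (is.null(best) || obj < best$objective)
      best <- list(medoids = med, U = U, objective = obj)
  }
  best
}

#' Write a fuzzy partition as a delimited membership table
#'
#' Columns: `patient_id`, `u_1..u_k`, `max_cluster`, `max_membership`,
#' plus an `is_medoid` flag for medoid-based partitions.
#'
#' @param partition A `fuzzy_partition`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the data frame written.
#' @export
write_partition <- function(partition, path, sep = "\t") {
  U <- partition$U
  ids <- partition$unit_ids
  if (is.null(ids)) ids <- as.character(seq_len(nrow(U)))
  df <- data.frame(patient_id = ids, U)
  names(df)[-1L] <- paste0("u_", seq_len(ncol(U)))
  df$max_cluster <- hard_labels(partition)
  df$max_membership <- apply(U, 1L, max)
  if (!is.null(partition$medoids))
    df$is_medoid <- seq_len(nrow(U)) %in% partition$medoids
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
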