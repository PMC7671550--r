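validity_distance <- function(C, distance = c("sqeuclidean", "euclidean")) {
  distance <- match.arg(distance)
  D <- as.matrix(stats::dist(C))
  if (distance == "sqeuclidean") D <- D^2
  dimnames(D) <- NULL
  D
}

#' Per-unit silhouette values
#'
#' For each unit, `a(i)` is its mean distance to the other members of its
#' own cluster and `b(i)` the smallest mean distance to the units of any
#' other cluster; the silhouette is `(b - a) / max(a, b)`, in \[-1, 1\].
#' A unit alone in its cluster gets silhouette 0 (neutral convention).
#'
#' @param C Units-by-variables matrix.
#' @param labels Integer cluster labels (at least two distinct clusters).
#' @param distance `"sqeuclidean"` (default, matching the clustering
#'   objective) or `"euclidean"`.
#' @return Numeric vector of silhouette values.
#' @export
silhouette_values <- function(C, labels,
                              distance = c("sqeuclidean", "euclidean")) {
  D <- validity_distance(C, distance)
  n <- nrow(D)
  if (length(labels) != n) stop("labels do not match C", call. = FALSE)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette needs at least two clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(cl[cl != labels[i]],
                    function(g) mean(D[i, labels == g]), numeric(1L)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Average (crisp) silhouette index
#'
#' @inheritParams silhouette_values
#' @return Mean silhouette `S(k)` in \[-1, 1\].
#' @export
silhouette_index <- function(C, labels,
                             distance = c("sqeuclidean", "euclidean")) {
  mean(silhouette_values(C, labels, distance))
}

#' Fuzzy silhouette index
#'
#' Weighted mean of the per-unit silhouette values with weights
#' `(u_ig - u_ig')^gamma`, where `u_ig >= u_ig'` are the largest and
#' second-largest membership degrees of unit `i`: units close to a
#' prototype count more than units in overlap zones. Hard labels for the
#' silhouette are taken by maximum membership. With a hard `U` (or with
#' `gamma = 0`) the index reduces exactly to the crisp silhouette `S(k)`.
#'
#' @param C Units-by-variables matrix.
#' @param U n-by-k membership matrix (or a `fuzzy_partition`).
#' @param gamma Non-negative weighting exponent (default 1).
#' @inheritParams silhouette_values
#' @return Fuzzy silhouette `FS(k)` in \[-1, 1\].
#' @export
fuzzy_silhouette <- function(C, U, gamma = 1,
                             distance = c("sqeuclidean", "euclidean")) {
  if (inherits(U, "fuzzy_partition")) U <- U$U
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  two <- t(apply(U, 1L, function(u) sort(u, decreasing = TRUE)[1:2]))
  w <- (two[, 1L] - two[, 2L])^gamma
  if (sum(w) <= 0)
    stop("all membership rows are ties: zero total silhouette weight",
         call. = FALSE)
  labels <- apply(U, 1L, which.max)
  s <- silhouette_values(C, labels, distance)
  sum(w * s) / sum(w)
}

#' Select the number of clusters by the fuzzy silhouette
#'
#' Runs [fkmed()] for each candidate `k`, computes `FS(k)`, and reports
#' the maximizer together with every `k` whose index lies within
#' `tolerance` of the maximum — solutions close to the best may carry more
#' interpretable structure and deserve inspection rather than a mechanical
#' argmax.
#'
#' @param C Units-by-variables matrix.
#' @param k_range Candidate numbers of clusters, within `[2, n - 1]`.
#' @param f Fuzziness exponent (default 1.5).
#' @param gamma Fuzzy-silhouette weighting exponent (default 1).
#' @param tolerance FS slack defining the near-maximal set (default 0.05).
#' @param distance Distance for the silhouette (see [silhouette_values()]).
#' @param ... Further arguments passed to [fkmed()] (`n_starts`, `seed`,
#'   `tol`, ...).
#' @return Object of class `k_selection`: `table` (data frame `k`, `FS`,
#'   `S`, `objective`), `best_k`, `near_best` (vector of k), and
#'   `partitions` (list of the fitted `fuzzy_partition`s, named by k).
#' @export
select_k <- function(C, k_range, f = 1.5, gamma = 1, tolerance = 0.05,
                     distance = c("sqeuclidean", "euclidean"), ...) {
  n <- nrow(as.matrix(C))
  if (length(k_range) == 0L) stop("k_range is empty", call. = FALSE)
  if (any(k_range < 2L | k_range >= n))
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  distance <- match.arg(distance)
  parts <- list(); rows <- list()
  for (k in k_range) {
    p <- fkmed(C, k = k, f = f, ...)
    lab <- hard_labels(p)
    fs <- fuzzy_silhouette(C, p$U, gamma = gamma, distance = distance)
    rows[[as.character(k)]] <- data.frame(
      k = k, FS = fs,
      S = if (length(unique(lab)) >= 2L) silhouette_index(C, lab, distance) else NA_real_,
      objective = p$objective)
    parts[[as.character(k)]] <- p
  }
  tab <- do.call(rbind, rows)
  best <- tab$k[which.max(tab$FS)]
  near <- tab$k[tab$FS >= max(tab$FS) - tolerance]
  structure(list(table = tab, best_k = best, near_best = sort(near),
                 partitions = parts),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Best k by FS: %d (near-best: %s)\n", x$best_k,
              paste(x$near_best, collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two hard partitions
#'
#' Chance-corrected agreement under the permutation model; 1 means
#' identical partitions (up to label names), about 0 is expected for
#' independent labelings. Fuzzy partitions must be hardened (maximum
#' membership) before comparison.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI (at most 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Write a per-k validity table as delimited text
#'
#' @param selection A `k_selection` from [select_k()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the table written.
#' @export
write_validity_table <- function(selection, path, sep = "\t") {
  utils::write.table(selection$table, path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(selection$table)
}
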