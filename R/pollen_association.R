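#' One-sided permutation test for positive Spearman correlation
#'
#' Computes the Spearman rank correlation between two coefficient vectors
#' and its one-sided permutation p-value for the alternative `rho > 0`.
#' B-spline coefficients of a fitted curve are serially dependent, so the
#' parametric correlation test is not applicable; the permutation scheme
#' only assumes exchangeability under the null. The p-value uses the
#' add-one estimator `(1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`, which
#' never returns 0.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither
#'   constant.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List `r` (Spearman correlation) and `p` (one-sided p-value).
#' @export
spearman_permutation_test <- function(x, y, n_perm = 10000L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least three observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: ranks are undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  r_obs <- sum(rxc * ryc) / denom
  n <- length(x)
  # permuted correlations, vectorised: columns are permutations of ryc
  P <- vapply(seq_len(n_perm), function(i) ryc[sample.int(n)],
              numeric(n))
  r_perm <- as.vector(crossprod(rxc, P)) / denom
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p = p)
}

#' Allergy-pollen association (ARp) index
#'
#' For each patient and pollen taxon, tests whether the Spearman
#' correlation between the patient's curve coefficients and the pollen
#' curve coefficients is significantly positive (one-sided permutation
#' test). Non-significant pairs score 0; each significant correlation is
#' divided by the sum of that patient's significant correlations, so the
#' significant entries of a patient's row sum to 1 and each entry lies in
#' \[0, 1\]. A patient significantly associated with exactly one pollen
#' scores 1 for it.
#'
#' @param patient_coefs Patients-by-s coefficient matrix.
#' @param pollen_coefs Pollens-by-s coefficient matrix (same basis as the
#'   patients), rownames naming the taxa.
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Optional integer seed (one stream across all tests).
#' @return Object of class `arp_table`: matrices `ARp`, `r`, `p`
#'   (patients x pollens) and the configuration (`alpha`, `n_perm`,
#'   `seed`).
#' @export
arp_index <- function(patient_coefs, pollen_coefs, alpha = 0.05,
                      n_perm = 10000L, seed = NULL) {
  patient_coefs <- as.matrix(patient_coefs)
  pollen_coefs <- as.matrix(pollen_coefs)
  if (nrow(pollen_coefs) < 1L) stop("need at least one pollen", call. = FALSE)
  if (ncol(patient_coefs) != ncol(pollen_coefs))
    stop("patient and pollen coefficients must share the same basis",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(patient_coefs); u <- nrow(pollen_coefs)
  dn <- list(rownames(patient_coefs), rownames(pollen_coefs))
  r <- p <- matrix(NA_real_, n, u, dimnames = dn)
  for (i in seq_len(n)) for (j in seq_len(u)) {
    tst <- spearman_permutation_test(patient_coefs[i, ], pollen_coefs[j, ],
                                     n_perm = n_perm, seed = NULL)
    r[i, j] <- tst$r; p[i, j] <- tst$p
  }
  ARp <- matrix(0, n, u, dimnames = dn)
  for (i in seq_len(n)) {
    sig <- p[i, ] <= alpha
    if (any(sig)) ARp[i, sig] <- r[i, sig] / sum(r[i, sig])
  }
  structure(list(ARp = ARp, r = r, p = p, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "arp_table")
}

#' @export
print.arp_table <- function(x, ...) {
  cat(sprintf("ARp table: %d patients x %d pollens (alpha = %g, %d permutations)\n",
              nrow(x$ARp), ncol(x$ARp), x$alpha, x$n_perm))
  print(round(utils::head(x$ARp), 3))
  if (nrow(x$ARp) > 6L) cat("...\n")
  invisible(x)
}

#' Cluster-level ARp summary
#'
#' For each cluster (patients assigned by maximum membership) and pollen:
#' the membership-weighted mean ARp,
#' `sum_{i in cluster} u_il * ARp_iu / sum_{i in cluster} u_il`, and the
#' percentage of the cluster's patients fully associated with the pollen
#' (`ARp = 1`). A `Total` row summarizes the whole cohort (unweighted
#' mean and overall percentage).
#'
#' @param arp An `arp_table` from [arp_index()].
#' @param U Patients-by-k membership matrix (or `fuzzy_partition`), rows
#'   aligned with the ARp table.
#' @return List of matrices `mean_arp` and `pct_arp1`
#'   ((k + 1) x pollens, last row `Total`).
#' @export
cluster_arp_summary <- function(arp, U) {
  if (inherits(U, "fuzzy_partition")) U <- U$U
  if (nrow(U) != nrow(arp$ARp))
    stop("membership matrix does not align with the ARp table", call. = FALSE)
  k <- ncol(U)
  lab <- apply(U, 1L, which.max)
  pol <- colnames(arp$ARp)
  mean_arp <- pct1 <- matrix(NA_real_, k + 1L, ncol(arp$ARp),
                             dimnames = list(c(paste0("Cluster ", seq_len(k)),
                                               "Total"), pol))
  for (l in seq_len(k)) {
    in_l <- lab == l
    if (!any(in_l)) next
    w <- U[in_l, l]
    mean_arp[l, ] <- colSums(w * arp$ARp[in_l, , drop = FALSE]) / sum(w)
    pct1[l, ] <- 100 * colMeans(arp$ARp[in_l, , drop = FALSE] >= 1 - 1e-12)
  }
  mean_arp[k + 1L, ] <- colMeans(arp$ARp)
  pct1[k + 1L, ] <- 100 * colMeans(arp$ARp >= 1 - 1e-12)
  list(mean_arp = mean_arp, pct_arp1 = pct1)
}

#' Write ARp results as delimited text
#'
#' The patient-level table has one row per patient-pollen pair
#' (`patient_id`, `pollen`, `r`, `p`, `ARp`); the optional cluster summary
#' is written with separate mean and percentage columns.
#'
#' @param arp An `arp_table`.
#' @param path Output file path.
#' @param summary Optional result of [cluster_arp_summary()]; written to
#'   `summary_path`.
#' @param summary_path File path for the cluster summary.
#' @param sep Field separator (default tab).
#' @return Invisibly, the patient-level data frame.
#' @export
write_arp_table <- function(arp, path, summary = NULL, summary_path = NULL,
                            sep = "\t") {
  ids <- rownames(arp$ARp)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(arp$ARp)))
  pol <- colnames(arp$ARp)
  if (is.null(pol)) pol <- paste0("pollen_", seq_len(ncol(arp$ARp)))
  df <- data.frame(
    patient_id = rep(ids, times = length(pol)),
    pollen = rep(pol, each = length(ids)),
    r = as.vector(arp$r), p = as.vector(arp$p), ARp = as.vector(arp$ARp))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(summary)) {
    if (is.null(summary_path))
      stop("summary_path is required when writing the summary", call. = FALSE)
    sm <- data.frame(cluster = rownames(summary$mean_arp))
    for (pn in colnames(summary$mean_arp)) {
      sm[[paste0(pn, "_mean_arp")]] <- summary$mean_arp[, pn]
      sm[[paste0(pn, "_pct_arp1")]] <- summary$pct_arp1[, pn]
    }
    utils::write.table(sm, summary_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(df)
}
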