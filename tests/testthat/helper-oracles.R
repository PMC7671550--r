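# Independent brute-force oracles used to freeze expected values.

# Silhouette by direct definition, no shared code with the package paths.
brute_silhouette <- function(C, labels, squared = TRUE) {
  D <- as.matrix(dist(C))
  if (squared) D <- D^2
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# High-resolution composite Simpson quadrature of the penalty integrand,
# refined within each inter-knot interval (the integrand is piecewise
# polynomial, smooth inside each interval).
brute_penalty_matrix <- function(spec, n_sub = 256L) {
  breaks <- unique(spec$knots)
  R <- matrix(0, spec$s, spec$s)
  for (j in seq_len(length(breaks) - 1L)) {
    a <- breaks[j]; b <- breaks[j + 1L]
    x <- seq(a, b, length.out = 2L * n_sub + 1L)
    h <- (b - a) / (2 * n_sub)
    w <- h / 3 * c(1, rep(c(4, 2), n_sub - 1L), 4, 1)
    B <- basis_matrix(spec, x, deriv = spec$penalty_order)
    R <- R + t(B) %*% (w * B)
  }
  R
}

# Direct evaluation of the weighted medoid cost for one cluster.
brute_medoid_cost <- function(C, u_col, f, candidate) {
  D2 <- as.matrix(dist(C))^2
  sum(u_col^f * D2[candidate, ])
}

# Balanced two-blob instance in coefficient space (n = 12, s = 3).
small_blob_instance <- function(seed) {
  set.seed(seed)
  centers <- matrix(rnorm(6, sd = 3), 2, 3)
  generate_coefficient_blobs(6, centers, spread = 1, seed = seed + 5000)
}
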