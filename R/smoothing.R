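#' B-spline basis specification
#'
#' Describes the shared penalized B-spline system used for every unit in a
#' cohort: the time domain, `q` equally spaced interior knots, the spline
#' order `m` (polynomial degree + 1) and the derivative order of the
#' roughness penalty. The basis dimension is `s = q + m`.
#'
#' @param domain Length-2 numeric, the observation window in day units.
#' @param q Number of equally spaced interior knots (>= 0).
#' @param m Spline order, i.e. polynomial degree + 1 (cubic splines have
#'   `m = 4`).
#' @param penalty_order Derivative order of the roughness penalty
#'   (default 2, penalizing curvature). Must be `< m`.
#' @return Object of class `basis_spec` with elements `domain`, `q`, `m`,
#'   `s`, `penalty_order` and the full `knots` vector (boundary knots
#'   repeated to order `m`).
#' @export
basis_spec <- function(domain, q, m = 4L, penalty_order = 2L) {
  if (length(domain) != 2L || !is.finite(diff(range(domain))) ||
      diff(domain) <= 0)
    stop("domain must be an increasing pair of finite numbers", call. = FALSE)
  if (q < 0L) stop("q must be >= 0", call. = FALSE)
  if (m < 1L) stop("spline order m must be >= 1", call. = FALSE)
  if (penalty_order >= m)
    stop("penalty_order must be smaller than the spline order m", call. = FALSE)
  interior <- if (q > 0L)
    seq(domain[1L], domain[2L], length.out = q + 2L)[-c(1L, q + 2L)]
  else numeric(0)
  structure(list(
    domain = as.numeric(domain), q = as.integer(q), m = as.integer(m),
    s = as.integer(q + m), penalty_order = as.integer(penalty_order),
    knots = c(rep(domain[1L], m), interior, rep(domain[2L], m))
  ), class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf(
    "B-spline basis: order m = %d, q = %d interior knots, s = %d on [%g, %g]\n",
    x$m, x$q, x$s, x$domain[1L], x$domain[2L]))
  invisible(x)
}

#' Evaluate the B-spline basis (or a derivative) at given times
#'
#' @param spec A [basis_spec()].
#' @param times Numeric vector of evaluation times within the domain.
#' @param deriv Derivative order (0 = the basis functions themselves).
#' @return Matrix with `length(times)` rows and `spec$s` columns. For
#'   `deriv = 0` each row sums to 1 (partition of unity).
#' @export
basis_matrix <- function(spec, times, deriv = 0L) {
  if (any(times < spec$domain[1L] - 1e-10 | times > spec$domain[2L] + 1e-10))
    stop("evaluation times outside the basis domain", call. = FALSE)
  times <- pmin(pmax(times, spec$domain[1L]), spec$domain[2L])
  splines::splineDesign(spec$knots, times, ord = spec$m,
                        derivs = rep(deriv, length(times)),
                        outer.ok = FALSE)
}

#' Build a basis evaluator function
#'
#' Convenience closure over [basis_matrix()]: maps any time vector to the
#' basis matrix.
#'
#' @param spec A [basis_spec()].
#' @return Function `(times, deriv = 0)` returning the basis matrix.
#' @export
build_basis <- function(spec) {
  force(spec)
  function(times, deriv = 0L) basis_matrix(spec, times, deriv)
}

#' Roughness penalty matrix
#'
#' The s x s matrix `R` with entries `R[p, p'] = integral of
#' D^d phi_p(t) D^d phi_p'(t) dt` over the domain, where `d` is the
#' penalty order. Since the integrand is piecewise polynomial of degree
#' `2(m - 1 - d)` on each inter-knot interval, Gauss-Legendre quadrature
#' with `m` nodes per interval is exact (up to rounding). `R` is symmetric
#' positive semidefinite with nullspace the polynomials of degree `< d`.
#'
#' @param spec A [basis_spec()].
#' @return Symmetric `s x s` matrix.
#' @export
penalty_matrix <- function(spec) {
  d <- spec$penalty_order
  breaks <- unique(spec$knots)
  gl <- pracma::gaussLegendre(spec$m, -1, 1)
  R <- matrix(0, spec$s, spec$s)
  for (j in seq_len(length(breaks) - 1L)) {
    a <- breaks[j]; b <- breaks[j + 1L]
    x <- (b - a) / 2 * gl$x + (a + b) / 2
    w <- (b - a) / 2 * gl$w
    B <- basis_matrix(spec, x, deriv = d)
    R <- R + crossprod(B * sqrt(w))
  }
  (R + t(R)) / 2
}

# Symmetric factor L with t(L) %*% L = R, via eigendecomposition; rows for
# (numerically) zero eigenvalues are dropped so the augmented system stays
# well scaled at large lambda.
penalty_root <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  keep <- e$values > tol
  if (!any(keep)) return(matrix(0, 0L, ncol(R)))
  sqrt(e$values[keep]) * t(e$vectors[, keep, drop = FALSE])
}

# Core penalized least-squares fit for a cohort sharing times and basis.
# Y: n x v matrix (units in rows). Solved through the QR factorization of
# the augmented design rbind(Phi, sqrt(lambda) L) rather than the normal
# equations: at extreme lambda the normal-equations matrix rounds away the
# penalty nullspace, while the augmented system keeps the large-lambda
# (polynomial) limit accurate.
fit_cohort_once <- function(Y, times, spec, lambda, Phi = NULL, L = NULL) {
  if (is.null(Phi)) Phi <- basis_matrix(spec, times)
  if (is.null(L)) L <- penalty_root(penalty_matrix(spec))
  v <- length(times); s <- spec$s
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  aug <- if (lambda > 0) rbind(Phi, sqrt(lambda) * L) else Phi
  # tiny rank tolerance: at extreme lambda the penalty rows dwarf Phi by
  # ~sqrt(lambda), which the default tolerance would misread as rank loss
  qa <- qr(aug, tol = 1e-14)
  singular <- qa$rank < s
  if (singular) {
    n <- nrow(Y)
    return(list(C = matrix(NA_real_, n, s), SSE = rep(NA_real_, n),
                df = NA_real_, gcv = rep(Inf, n), singular = TRUE,
                lambda = lambda))
  }
  Yaug <- rbind(t(Y), matrix(0, nrow(aug) - v, nrow(Y)))
  C <- qr.coef(qa, Yaug)                      # s x n
  fitted <- Phi %*% C                         # v x n
  SSE <- colSums((t(Y) - fitted)^2)
  Raug <- qr.R(qa)
  G <- backsolve(Raug, t(Phi), transpose = TRUE)  # solves t(Raug) G = t(Phi)
  df <- sum(G^2)                              # trace of the hat matrix
  gcv <- if (df < v) v * SSE / (v - df)^2 else rep(Inf, nrow(Y))
  list(C = t(C), SSE = SSE, df = df, gcv = gcv, fitted = t(fitted),
       singular = FALSE, lambda = lambda)
}

#' Penalized B-spline least-squares fit for one unit
#'
#' Minimizes `SSE + lambda * PEN(x)` where `PEN(x) = c' R c` is the
#' integrated squared `penalty_order`-th derivative of the fitted curve.
#' The effective degrees of freedom `df(lambda)` is the trace of the
#' smoothing (hat) matrix, and `GCV = v * SSE / (v - df)^2` with `v` the
#' number of observations for the unit; a singular system or `df >= v`
#' yields `GCV = Inf` with a `singular` flag.
#'
#' @param y Observed values (length `v`).
#' @param times Observation times within the basis domain (length `v`,
#'   `v >= 2`).
#' @param spec A [basis_spec()].
#' @param lambda Smoothing parameter `>= 0`.
#' @return Object of class `functional_fit`: `coefficients`, `lambda`,
#'   `SSE`, `df`, `gcv`, `fitted`, `residuals`, `singular`, `spec`.
#' @export
fit_penalized <- function(y, times, spec, lambda) {
  if (length(y) != length(times)) stop("y and times differ in length", call. = FALSE)
  if (length(y) < 2L) stop("need at least two observations", call. = FALSE)
  f <- fit_cohort_once(matrix(y, nrow = 1L), times, spec, lambda)
  structure(list(
    coefficients = drop(f$C), lambda = lambda, SSE = f$SSE[1L], df = f$df,
    gcv = f$gcv[1L],
    fitted = if (f$singular) rep(NA_real_, length(y)) else drop(f$fitted),
    residuals = if (f$singular) rep(NA_real_, length(y)) else y - drop(f$fitted),
    singular = f$singular, spec = spec
  ), class = "functional_fit")
}

#' @export
print.functional_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized B-spline fit: s = %d, lambda = %g, SSE = %.4g, df = %.2f, GCV = %.4g\n",
    x$spec$s, x$lambda, x$SSE, x$df, x$gcv))
  invisible(x)
}

#' Select the smoothing parameter by GCV over a log10 grid
#'
#' Evaluates `lambda = 10^g` for every exponent in `grid` and returns the
#' minimizer of the GCV criterion; ties are broken toward the smallest
#' lambda (the smoother fit at equal score).
#'
#' @param y,times,spec As in [fit_penalized()].
#' @param grid Numeric vector of base-10 exponents, default
#'   `seq(-30, 20, by = 0.05)`.
#' @return List `lambda`, `g`, `gcv`, and the full `path` data frame
#'   (`g`, `lambda`, `gcv`).
#' @export
select_lambda <- function(y, times, spec, grid = seq(-30, 20, by = 0.05)) {
  if (length(grid) == 0L) stop("empty lambda grid", call. = FALSE)
  Phi <- basis_matrix(spec, times)
  L <- penalty_root(penalty_matrix(spec))
  Y <- matrix(y, nrow = 1L)
  gcvs <- vapply(grid, function(g)
    fit_cohort_once(Y, times, spec, 10^g, Phi, L)$gcv[1L], numeric(1L))
  if (all(!is.finite(gcvs))) stop("GCV is infinite on the whole grid", call. = FALSE)
  g <- sort(grid)
  gcvs <- gcvs[order(grid)]
  best <- which(gcvs <= min(gcvs[is.finite(gcvs)]) + 0)[1L]  # smallest lambda at ties
  list(lambda = 10^g[best], g = g[best], gcv = gcvs[best],
       path = data.frame(g = g, lambda = 10^g, gcv = gcvs))
}

#' Cohort-level grid search over knots, order and smoothing parameter
#'
#' For every combination of `q` (interior knots) and `m` (order), finds the
#' single shared `lambda = 10^g` minimizing the total GCV,
#' `TGCV(q, m) = sum_i GCV_i`, across all units — all units share the same
#' basis and smoothing parameter so their coefficients are comparable. The
#' selected model is the TGCV argmin unless a parsimony tolerance is given,
#' in which case the simplest model (smallest basis dimension, then lowest
#' order) whose TGCV is within `parsimony_tol` of the minimum is selected
#' and the override recorded.
#'
#' @param Y Units-by-days matrix of (imputed) scores on a common grid.
#' @param times Common observation times (default `1:ncol(Y)`).
#' @param q_options,m_options Candidate interior-knot counts and orders.
#' @param grid Base-10 exponent grid for lambda, default
#'   `seq(-30, 20, by = 0.05)`.
#' @param parsimony_tol Non-negative TGCV slack for preferring a simpler
#'   model; default 0 (pure argmin).
#' @param domain Basis domain, default `range(times)`.
#' @return Object of class `tgcv_search`: `table` (data frame
#'   `model_label`, `m`, `q`, `s`, `lambda`, `TGCV`), `selected` (row of
#'   the chosen model), `spec` (its [basis_spec()]), `coefficients` (the
#'   units-by-s coefficient matrix under the chosen model), `df`, `gcv`
#'   (per-unit breakdown), and `parsimony_override` (logical).
#' @export
tgcv_grid_search <- function(Y, times = seq_len(ncol(Y)),
                             q_options = c(5L, 10L, 15L, 20L),
                             m_options = c(4L, 6L),
                             grid = seq(-30, 20, by = 0.05),
                             parsimony_tol = 0, domain = range(times)) {
  if (anyNA(Y)) stop("Y contains missing values; impute first", call. = FALSE)
  if (length(times) != ncol(Y))
    stop("times must match the columns of Y", call. = FALSE)
  grid <- sort(grid)
  combos <- expand.grid(q = q_options, m = m_options)
  span <- diff(range(domain))
  rows <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    q <- combos$q[i]; m <- combos$m[i]
    spec <- basis_spec(domain, q = q, m = m)
    Phi <- basis_matrix(spec, times)
    L <- penalty_root(penalty_matrix(spec))
    best <- NULL; best_tgcv <- Inf; best_g <- NA_real_
    for (g in grid) {
      f <- fit_cohort_once(Y, times, spec, 10^g, Phi, L)
      tg <- sum(f$gcv)
      if (is.finite(tg) && tg < best_tgcv) {   # ties keep smaller lambda
        best_tgcv <- tg; best <- f; best_g <- g
      }
    }
    if (is.null(best)) stop("GCV infinite over the whole grid for q=", q,
                            ", m=", m, call. = FALSE)
    rows[[i]] <- data.frame(
      model_label = sprintf("B-splines %g-days", span / q),
      m = m, q = q, s = spec$s, lambda = 10^best_g, TGCV = best_tgcv)
    fits[[i]] <- list(fit = best, spec = spec)
  }
  tab <- do.call(rbind, rows)
  min_tgcv <- min(tab$TGCV)
  sel <- which.min(tab$TGCV)
  override <- FALSE
  if (parsimony_tol > 0) {
    near <- which(tab$TGCV <= min_tgcv + parsimony_tol)
    ord <- near[order(tab$s[near], tab$m[near])]
    if (ord[1L] != sel) override <- TRUE
    sel <- ord[1L]
  }
  chosen <- fits[[sel]]
  C <- chosen$fit$C
  rownames(C) <- rownames(Y)
  colnames(C) <- paste0("p", seq_len(ncol(C)))
  structure(list(
    table = tab, selected = tab[sel, ], spec = chosen$spec,
    coefficients = C, lambda = tab$lambda[sel], df = chosen$fit$df,
    gcv = chosen$fit$gcv, parsimony_override = override
  ), class = "tgcv_search")
}

#' @export
print.tgcv_search <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Selected: m = %d, q = %d (TGCV = %.4g%s)\n",
              x$selected$m, x$selected$q, x$selected$TGCV,
              if (x$parsimony_override) ", parsimony override" else ""))
  invisible(x)
}

#' Evaluate a fitted functional curve
#'
#' Computes `x(t) = Phi(t) %*% c` for a coefficient vector (or a
#' units-by-s coefficient matrix, returning one row of values per unit).
#'
#' @param coefficients Coefficient vector of length `s`, a
#'   `functional_fit`, or a matrix with `s` columns.
#' @param spec A [basis_spec()]; taken from the fit if omitted.
#' @param times Evaluation times within the domain.
#' @return Numeric vector (or units-by-times matrix) of curve values.
#' @export
evaluate_curve <- function(coefficients, spec = NULL, times) {
  if (inherits(coefficients, "functional_fit")) {
    if (is.null(spec)) spec <- coefficients$spec
    coefficients <- coefficients$coefficients
  }
  if (is.null(spec)) stop("a basis_spec is required", call. = FALSE)
  Phi <- basis_matrix(spec, times)
  if (is.null(dim(coefficients))) drop(Phi %*% coefficients)
  else coefficients %*% t(Phi)
}

#' Write / read a coefficient matrix as delimited text
#'
#' Columns are labelled `p1..ps`; row names carry the unit (patient or
#' pollen) identifiers.
#'
#' @param C Units-by-s coefficient matrix.
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `write_coefficients()` invisibly returns `C`;
#'   `read_coefficients()` returns the matrix.
#' @export
write_coefficients <- function(C, path, sep = "\t") {
  df <- data.frame(unit_id = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(C)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  C <- as.matrix(df[, -1L, drop = FALSE])
  rownames(C) <- df[[1L]]
  C
}
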