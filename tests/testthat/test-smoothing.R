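test_that("basis dimension is interior knots + order", {
  s1 <- basis_spec(c(0, 1), q = 15, m = 4)
  expect_equal(s1$s, 19L)
  expect_equal(ncol(basis_matrix(s1, seq(0, 1, 0.1))), 19L)
  s2 <- basis_spec(c(0, 1), q = 0, m = 4)   # no interior knots: cubics
  expect_equal(s2$s, 4L)
  expect_error(basis_spec(c(0, 1), q = -1), "q")
  expect_error(basis_spec(c(1, 1), q = 5), "domain")
  expect_error(basis_spec(c(0, 1), q = 5, m = 2, penalty_order = 2), "penalty_order")
})

test_that("B-spline basis rows sum to one at random interior times", {
  set.seed(5)
  spec <- basis_spec(c(1, 40), q = 15, m = 4)
  tt <- runif(1000, 1, 40)
  expect_lt(max(abs(rowSums(basis_matrix(spec, tt)) - 1)), 1e-12)
  spec6 <- basis_spec(c(1, 40), q = 10, m = 6)
  expect_lt(max(abs(rowSums(basis_matrix(spec6, tt)) - 1)), 1e-12)
  expect_error(basis_matrix(spec, 41), "outside")
})

test_that("penalty matrix annihilates straight lines and matches quadrature", {
  for (m in c(4L, 6L)) {
    spec <- basis_spec(c(1, 40), q = 8, m = m)
    R <- penalty_matrix(spec)
    expect_equal(R, t(R))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    # coefficients reproducing 2 + 3t have zero roughness
    cl <- qr.solve(basis_matrix(spec, seq(1, 40, length.out = spec$s)),
                   2 + 3 * seq(1, 40, length.out = spec$s))
    expect_lt(abs(drop(t(cl) %*% R %*% cl)), 1e-10)
    # brute-force Simpson oracle agreement, entrywise
    expect_lt(max(abs(R - brute_penalty_matrix(spec))), 1e-8)
  }
})

test_that("unpenalized saturated fit interpolates and df equals s", {
  set.seed(6)
  spec <- basis_spec(c(1, 10), q = 6, m = 4)      # s = 10 = v
  y <- rnorm(10)
  f <- fit_penalized(y, 1:10, spec, 0)
  expect_lt(f$SSE / sum(y^2), 1e-12)
  spec2 <- basis_spec(c(1, 20), q = 4, m = 4)     # s = 8 < v = 20
  y2 <- rnorm(20)
  f2 <- fit_penalized(y2, 1:20, spec2, 0)
  expect_equal(f2$df, spec2$s, tolerance = 1e-8)
  expect_equal(f2$gcv, 20 * f2$SSE / (20 - spec2$s)^2, tolerance = 1e-8)
})

test_that("extreme smoothing reproduces the least-squares line", {
  set.seed(7)
  y <- sin(seq(0, 3, length.out = 40)) + rnorm(40, 0, 0.1)
  spec <- basis_spec(c(1, 40), q = 10, m = 4)
  f <- fit_penalized(y, 1:40, spec, 1e20)
  ols <- stats::lm(y ~ t, data = data.frame(y = y, t = 1:40))
  expect_lt(max(abs(f$fitted - stats::fitted(ols))), 1e-4)
  expect_equal(f$df, 2, tolerance = 0.01)
})

test_that("singular unpenalized systems are flagged with infinite GCV", {
  spec <- basis_spec(c(1, 10), q = 10, m = 4)     # s = 14 > v = 10
  f <- fit_penalized(rnorm(10), 1:10, spec, 0)
  expect_true(f$singular)
  expect_equal(f$gcv, Inf)
})

test_that("SSE rises and df falls along a lambda ladder", {
  set.seed(8)
  y <- cos(seq(0, 4, length.out = 35)) + rnorm(35, 0, 0.15)
  spec <- basis_spec(c(1, 35), q = 12, m = 4)
  fits <- lapply(10^seq(-6, 8, by = 1), function(l)
    fit_penalized(y, 1:35, spec, l))
  sse <- vapply(fits, `[[`, numeric(1), "SSE")
  df <- vapply(fits, `[[`, numeric(1), "df")
  expect_true(all(diff(sse) >= -1e-10))
  expect_true(all(diff(df) <= 1e-10))
  # penalized solution at lambda = 0 equals the unpenalized LS solution
  c0 <- fit_penalized(y, 1:35, spec, 0)$coefficients
  Phi <- basis_matrix(spec, 1:35)
  expect_equal(c0, drop(qr.solve(Phi, y)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("select_lambda returns the exhaustive grid argmin", {
  set.seed(9)
  y <- sin(seq(0, 2 * pi, length.out = 40)) + rnorm(40, 0, 0.2)
  spec <- basis_spec(c(1, 40), q = 15, m = 4)
  grid <- seq(-4, 4, by = 0.25)
  sel <- select_lambda(y, 1:40, spec, grid = grid)
  # independent re-evaluation through the single-fit path
  gcvs <- vapply(grid, function(g) fit_penalized(y, 1:40, spec, 10^g)$gcv,
                 numeric(1))
  expect_equal(sel$g, grid[which.min(gcvs)])
  expect_equal(sel$gcv, min(gcvs))
  # single-point grid returns that lambda
  one <- select_lambda(y, 1:40, spec, grid = 0.5)
  expect_equal(one$lambda, 10^0.5)
  expect_error(select_lambda(y, 1:40, spec, grid = numeric(0)), "empty")
})

test_that("TGCV search sums per-unit GCV and honours the parsimony override", {
  set.seed(10)
  Y <- t(replicate(6, sin(seq(0, 3, length.out = 30)) + rnorm(30, 0, 0.1)))
  grid <- seq(-3, 3, by = 0.5)
  # one unit, one configuration: TGCV equals that unit's GCV at its lambda*
  gs1 <- tgcv_grid_search(Y[1, , drop = FALSE], q_options = 8L,
                          m_options = 4L, grid = grid)
  sel1 <- select_lambda(Y[1, ], 1:30, basis_spec(c(1, 30), 8L, 4L), grid)
  expect_equal(gs1$selected$TGCV, sel1$gcv, tolerance = 1e-10)
  expect_equal(gs1$selected$lambda, sel1$lambda)
  # argmin picks the lower-TGCV configuration
  gs <- tgcv_grid_search(Y, q_options = c(4L, 10L), m_options = 4L, grid = grid)
  expect_equal(gs$selected$TGCV, min(gs$table$TGCV))
  # a simpler model within tolerance of the minimum is selectable
  gap <- abs(diff(gs$table$TGCV))
  gs_p <- tgcv_grid_search(Y, q_options = c(4L, 10L), m_options = 4L,
                           grid = grid, parsimony_tol = gap + 1e-6)
  expect_equal(gs_p$selected$q, 4L)
  expect_true(gs_p$parsimony_override || gs$selected$q == 4L)
  expect_error(tgcv_grid_search(cbind(Y[, 1:29], NA), grid = grid), "impute")
})

test_that("curve evaluation is consistent with the fit and reproduces polynomials", {
  spec <- basis_spec(c(0, 1), q = 6, m = 4)
  # constant coefficient vector: partition of unity gives a constant curve
  expect_equal(evaluate_curve(rep(2.5, spec$s), spec, seq(0, 1, 0.05)),
               rep(2.5, 21))
  # spline space reproduces linear functions exactly
  tt <- seq(0, 1, length.out = 50)
  cl <- qr.solve(basis_matrix(spec, seq(0, 1, length.out = spec$s)),
                 1 + 2 * seq(0, 1, length.out = spec$s))
  expect_equal(evaluate_curve(cl, spec, tt), 1 + 2 * tt, tolerance = 1e-10)
  # evaluation at observed times equals the fitted values of the fit
  set.seed(11)
  y <- rnorm(25)
  spec2 <- basis_spec(c(1, 25), q = 5, m = 4)
  f <- fit_penalized(y, 1:25, spec2, 1)
  expect_equal(evaluate_curve(f, times = 1:25), f$fitted, tolerance = 1e-10)
  expect_error(evaluate_curve(f, times = 30), "outside")
})

test_that("coefficient matrices round-trip through the text format", {
  set.seed(12)
  C <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("p", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(C, path)
  expect_equal(read_coefficients(path), C)
})
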