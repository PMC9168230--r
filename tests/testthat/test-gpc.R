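# Generalized polynomial chaos: orthonormal families, multi-index sets,
# regression fitting, adaptive growth, moments and Sobol indices.

test_that("beta-orthonormal polynomials have unit Gram matrix", {
  dists <- default_conductivity_uncertainty()
  for (i in c(1, 2, 6)) {   # skin, skull (narrow), WML (wide)
    row <- dists[i, ]
    po <- orthonormal_polys(row, 5)
    q <- gauss_beta_quadrature(20, row)
    V <- po$eval(q$nodes)
    G <- t(V) %*% (q$weights * V)
    expect_equal(G, diag(6), tolerance = 1e-8)
    # psi_0 is the constant 1
    expect_equal(V[, 1], rep(1, 20))
    # degree-d member has exactly degree d: leading differences vanish
    expect_lt(abs(G[2, 3]), 1e-10)           # <psi_1, psi_2> = 0
    expect_equal(G[4, 4], 1, tolerance = 1e-10)  # <psi_3, psi_3> = 1
  }
  expect_error(orthonormal_polys(data.frame(lo = 0, hi = 1, shape1 = -1,
                                            shape2 = 3), 3), "shape")
})

test_that("a two-dimensional joint basis is orthonormal under the joint density", {
  dists <- input_distribution(c("A", "B"), lo = c(0, 2), hi = c(1, 5))
  idx <- total_degree_multiindices(2, 3)
  basis <- gpc_basis(dists, idx)
  qa <- gauss_beta_quadrature(12, dists[1, ])
  qb <- gauss_beta_quadrature(12, dists[2, ])
  grid <- as.matrix(expand.grid(qa$nodes, qb$nodes))
  wts <- as.vector(outer(qa$weights, qb$weights))
  Psi <- eval_gpc_basis(basis, grid)
  G <- t(Psi) %*% (wts * Psi)
  expect_equal(G, diag(nrow(idx)), tolerance = 1e-8)
})

test_that("total-degree multi-index sets enumerate correctly", {
  expect_identical(total_degree_multiindices(1, 0),
                   matrix(0L, 1, 1))
  # brute-force enumeration oracle for n = 6, p = 3
  brute <- as.matrix(expand.grid(rep(list(0:3), 6)))
  expect_identical(nrow(total_degree_multiindices(6, 3)),
                   sum(rowSums(brute) <= 3))
  expect_identical(nrow(total_degree_multiindices(6, 3)), 84L)
  A <- total_degree_multiindices(4, 2)
  expect_true(all(A <= 2))
  expect_true(all(rowSums(A) <= 2))
  expect_identical(nrow(unique(A)), nrow(A))
})

test_that("input sampling respects bounds, symmetry and seeding", {
  dists <- default_conductivity_uncertainty()
  X <- draw_samples(dists, 10000, seed = 4)
  for (i in seq_len(nrow(dists))) {
    expect_true(all(X[, i] >= dists$lo[i] & X[, i] <= dists$hi[i]))
    se <- sqrt((dists$hi[i] - dists$lo[i])^2 / 28 / 10000)
    # 4 standard errors: six simultaneous per-dimension checks
    expect_lt(abs(mean(X[, i]) - (dists$lo[i] + dists$hi[i]) / 2), 4 * se)
  }
  expect_identical(X, draw_samples(dists, 10000, seed = 4))
})

test_that("least squares recovers exact representations", {
  dists <- default_conductivity_uncertainty()
  basis <- gpc_basis(dists, total_degree_multiindices(6, 2))
  X <- draw_samples(dists, 80, seed = 9)
  Psi <- eval_gpc_basis(basis, X)
  # a basis polynomial maps to a unit coefficient vector
  for (k in c(2, 15)) {
    U <- fit_coefficients(X, Psi[, k], basis)
    ek <- numeric(ncol(Psi)); ek[k] <- 1
    expect_equal(as.numeric(U), ek, tolerance = 1e-8)
  }
  # constant response
  U <- fit_coefficients(X, rep(4.2, 80), basis)
  expect_equal(U[1, 1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(U[-1, 1])), 1e-10)
  # 2 + 3 xi1 + xi1 xi2 is reproduced at held-out points
  f <- function(xi) 2 + 3 * xi[1] + xi[1] * xi[2]
  U <- fit_coefficients(X, apply(X, 1, f), basis)
  Xh <- draw_samples(dists, 25, seed = 10)
  pred <- eval_gpc_basis(basis, Xh) %*% U
  expect_equal(as.numeric(pred), apply(Xh, 1, f), tolerance = 1e-8)
  # nonzero coefficients only on indices supported in dims {1, 2} with
  # per-dimension degree <= 1 (the orthonormal expansion of xi1 xi2 also
  # touches the constant and the two linear terms)
  deg <- basis$indices
  live <- which(abs(U) > 1e-8)
  allowed <- which(rowSums(deg[, -(1:2), drop = FALSE]) == 0 &
                     deg[, 1] <= 1 & deg[, 2] <= 1)
  expect_true(all(live %in% allowed))
  # undersampled fits are refused
  expect_error(fit_coefficients(X[1:10, ], rep(1, 10), basis), "samples")
})

test_that("adaptive expansion terminates on easy models and guards bad ones", {
  dists <- default_conductivity_uncertainty()
  lin <- function(xi) c(1 + xi[1] - 2 * xi[3], 0.5 * xi[2])
  mod <- adaptive_expand(lin, dists, residual_tol = 1e-8, seed = 6,
                         n_validation = 10)
  expect_lte(max(rowSums(mod$basis$indices)), 1)  # stayed first order
  expect_lt(mod$validation_error, 1e-8)
  expect_identical(mod$n_model_evals, nrow(mod$samples))
  # non-finite model output is reported with the offending sample
  boom <- function(xi) c(1, NaN)
  expect_error(adaptive_expand(boom, dists, seed = 6), "propagation error")
})

test_that("coefficient-based moments match analytic and Monte-Carlo values", {
  dists <- default_conductivity_uncertainty()
  # q = xi1: variance (hi-lo)^2/28 for beta(3,3), confirmed by simulation
  mod <- adaptive_expand(function(xi) rep(xi[1], 2), dists,
                         residual_tol = 1e-10, seed = 3, n_validation = 0)
  mom <- surrogate_moments(mod)
  span <- dists$hi[1] - dists$lo[1]
  expect_equal(mom$mean, rep((dists$lo[1] + dists$hi[1]) / 2, 2),
               tolerance = 1e-8)
  expect_equal(mom$variance, rep(span^2 / 28, 2), tolerance = 1e-8)
  mc <- with_seed_for_tests(99, stats::rbeta(1e6, 3, 3) * span + dists$lo[1])
  expect_lt(abs(var(mc) - span^2 / 28) / (span^2 / 28), 0.01)
  # constant response: zero variance
  modc <- adaptive_expand(function(xi) 5, dists, residual_tol = 1e-10,
                          seed = 3, n_validation = 0)
  momc <- surrogate_moments(modc)
  expect_equal(momc$mean, 5, tolerance = 1e-10)
  expect_lt(momc$variance, 1e-20)
  # a nonlinear surrogate: coefficient moments equal MC moments of the
  # surrogate itself within 3 standard errors
  f <- function(xi) 1 + xi[1] + 0.3 * xi[1] * xi[2] + 0.1 * xi[4]^2
  modn <- adaptive_expand(function(xi) f(xi), dists, residual_tol = 1e-9,
                          seed = 8, n_validation = 0)
  momn <- surrogate_moments(modn)
  Xmc <- draw_samples(dists, 1e5, seed = 123)
  qs <- as.numeric(evaluate_surrogate(modn, Xmc))
  se_mean <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(momn$mean - mean(qs)), 3 * se_mean)
  se_var <- sd((qs - mean(qs))^2) / sqrt(length(qs))
  expect_lt(abs(momn$variance - var(qs)), 3 * se_var)
})

test_that("Sobol indices decompose the variance correctly", {
  # symmetric additive model on iid inputs: S1 = S2 = 0.5
  d2 <- input_distribution(c("A", "B"), lo = c(0, 0), hi = c(1, 1))
  mod <- adaptive_expand(function(xi) xi[1] + xi[2], d2,
                         residual_tol = 1e-10, seed = 2, n_validation = 0)
  s <- sobol_decomposition(mod)
  expect_equal(unname(s$first_order[, 1]), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(s$interactions, 0, tolerance = 1e-8)
  # random coefficient vectors: indices always sum to one
  dists <- default_conductivity_uncertainty()
  basis <- gpc_basis(dists, total_degree_multiindices(6, 2))
  fake <- structure(list(basis = basis,
                         coefficients = matrix(with_seed_for_tests(5,
                           stats::rnorm(28 * 7)), 28, 7)),
                    class = "gpc_model")
  sf <- sobol_decomposition(fake)
  expect_equal(colSums(sf$first_order) + sf$interactions, rep(1, 7),
               tolerance = 1e-6)
  # q = xi1 + 0.5 xi1 xi2 against a double-loop Monte-Carlo estimator
  f <- function(x1, x2) x1 + 0.5 * x1 * x2
  modi <- adaptive_expand(function(xi) f(xi[1], xi[2]), d2,
                          residual_tol = 1e-10, seed = 4, n_validation = 0)
  si <- sobol_decomposition(modi)
  mc_first <- function(which_dim) with_seed_for_tests(31 + which_dim, {
    outer_n <- 8000; inner_n <- 300
    xf <- stats::rbeta(outer_n, 3, 3)
    inner <- matrix(stats::rbeta(outer_n * inner_n, 3, 3), outer_n)
    fv <- if (which_dim == 1) f(xf, inner) else f(inner, xf)
    cond_means <- rowMeans(fv)
    # debias: Var(cond means) inflates by the mean inner variance / n_inner
    inner_var <- rowSums((fv - cond_means)^2) / (inner_n - 1)
    V <- var(cond_means) - mean(inner_var) / inner_n
    # block the outer loop to estimate the estimator's own sampling error
    blocks <- vapply(split(cond_means, rep(1:10, length.out = outer_n)),
                     var, numeric(1))
    list(S = V, se = stats::sd(blocks) / sqrt(10))
  })
  var_tot <- si$total_variance[1]
  for (d in 1:2) {
    mc <- mc_first(d)
    expect_lt(abs(unname(si$first_order[d, 1]) - mc$S / var_tot),
              3 * mc$se / var_tot + 1e-4)
  }
  # zero-variance points are flagged undefined, not NaN
  modz <- adaptive_expand(function(xi) c(xi[1], 7), d2,
                          residual_tol = 1e-10, seed = 9, n_validation = 0)
  sz <- sobol_decomposition(modz)
  expect_false(sz$undefined[1])
  expect_true(sz$undefined[2])
  expect_true(all(is.na(sz$first_order[, 2])))
})

test_that("constructed variance shares are recovered within 0.02", {
  dists <- default_conductivity_uncertainty()
  a <- c(1, 25, 0.6, 1.5, 3, 0.4)   # per-tissue slopes
  mod <- adaptive_expand(function(xi) sum(a * xi), dists,
                         residual_tol = 1e-9, seed = 12, n_validation = 0)
  s <- sobol_decomposition(mod)
  shares <- a^2 * (dists$hi - dists$lo)^2 / 28
  shares <- shares / sum(shares)
  expect_true(all(abs(s$first_order[, 1] - shares) < 0.02))
})

test_that("validation error reflects surrogate fidelity monotonically", {
  dists <- default_conductivity_uncertainty()
  f <- function(xi) 1 + xi[1] + 0.5 * xi[1]^2 + 0.2 * xi[2]^2
  # full quadratic surrogate: near-exact
  mod2 <- adaptive_expand(function(xi) f(xi), dists, residual_tol = 1e-9,
                          max_order = 2, seed = 3, n_validation = 0)
  e2 <- validation_error(mod2, function(xi) f(xi), n_val = 20, seed = 50)
  expect_lt(e2$mean, 1e-8)
  # order-1 truncation of a quadratic is strictly worse
  mod1 <- adaptive_expand(function(xi) f(xi), dists, residual_tol = 1e-9,
                          max_order = 1, seed = 3, n_validation = 0)
  e1 <- validation_error(mod1, function(xi) f(xi), n_val = 20, seed = 50)
  expect_gt(e1$mean, e2$mean)
})
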