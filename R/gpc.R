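# Generalized polynomial chaos (gPC) surrogate of a scalar field over a
# space of bounded, beta-distributed inputs.
#
# Each uncertain tissue conductivity xi_i ~ beta(alpha, beta) on
# [lo_i, hi_i] gets a family of polynomials orthonormal under its density
# (Jacobi polynomials on the mapped interval).  Joint basis functions are
# tensor products selected by a multi-index set; coefficients are fitted
# by oversampled least squares; the basis is grown adaptively until a
# leave-one-out cross-validation residual is met.  Mean, variance and
# Sobol sensitivity indices follow directly from the coefficients.

#' Uncertain conductivity input space
#'
#' @param tissue Character vector of tissue names (defines the dimension
#'   order of the input vector xi).
#' @param lo,hi Support bounds per tissue, S/m.
#' @param shape1,shape2 Beta shape parameters per tissue (recycled;
#'   default 3, 3 — symmetric and bell-shaped on the bounded range).
#' @return Object of class `input_distribution` (a data frame with one
#'   row per input dimension).
#' @export
input_distribution <- function(tissue, lo, hi, shape1 = 3, shape2 = 3) {
  stopifnot(length(tissue) == length(lo), length(lo) == length(hi))
  if (any(lo >= hi)) stop("each support must satisfy lo < hi")
  if (any(shape1 <= 0) || any(shape2 <= 0)) stop("beta shapes must be positive")
  d <- data.frame(tissue = as.character(tissue), lo = lo, hi = hi,
                  shape1 = rep_len(shape1, length(tissue)),
                  shape2 = rep_len(shape2, length(tissue)),
                  stringsAsFactors = FALSE)
  class(d) <- c("input_distribution", "data.frame")
  d
}

#' Default conductivity uncertainty of the head tissues
#'
#' Beta(3, 3) ranges (S/m) for the six uncertain tissues; air is excluded
#' (fixed insulator).  The lesion range spans the entire spread of brain
#' conductivities, encoding that the conductivity of lesioned white
#' matter is essentially unknown.
#'
#' @param lesioned Include the WML dimension (drop it for lesion-free
#'   phantoms).
#' @return An [input_distribution()].
#' @export
default_conductivity_uncertainty <- function(lesioned = TRUE) {
  d <- input_distribution(
    tissue = c("SKIN", "SKULL", "CSF", "GM", "WM", "WML"),
    lo = c(0.28, 0.0016, 1.2, 0.22, 0.09, 0.09),
    hi = c(0.87, 0.033, 1.8, 0.67, 0.29, 1.8))
  if (!lesioned) d <- d[d$tissue != "WML", ]
  class(d) <- c("input_distribution", "data.frame")
  d
}

# Monic Jacobi recurrence coefficients for weight (1-t)^a (1+t)^b on
# [-1, 1], normalised to unit mass (beta_0 = 1).  Gautschi's formulas.
.jacobi_recurrence <- function(n, a, b) {
  k <- seq_len(n)
  alpha <- c((b - a) / (a + b + 2),
             (b^2 - a^2) / ((2 * k + a + b) * (2 * k + a + b + 2)))
  beta <- numeric(n + 1)
  beta[1] <- 1
  if (n >= 1)
    beta[2] <- 4 * (a + 1) * (b + 1) / ((a + b + 2)^2 * (a + b + 3))
  if (n >= 2) {
    k2 <- 2:n
    beta[k2 + 1] <- 4 * k2 * (k2 + a) * (k2 + b) * (k2 + a + b) /
      ((2 * k2 + a + b)^2 * (2 * k2 + a + b + 1) * (2 * k2 + a + b - 1))
  }
  list(alpha = alpha[seq_len(n + 1)], beta = beta)
}

#' Univariate polynomials orthonormal under a bounded beta density
#'
#' Builds the degree 0..`max_order` family orthonormal with respect to the
#' beta(shape1, shape2) density on `[lo, hi]` (Jacobi polynomials on the
#' mapped interval, normalised to unit norm under the probability
#' measure).
#'
#' @param dist_row One row of an [input_distribution()].
#' @param max_order Highest polynomial degree.
#' @return Object of class `orthonormal_polys` with an `eval(x)` method
#'   returning the N x (max_order + 1) matrix of values.
#' @export
orthonormal_polys <- function(dist_row, max_order) {
  stopifnot(max_order >= 0)
  a <- dist_row$shape2 - 1   # exponent on (1 - t)
  b <- dist_row$shape1 - 1   # exponent on (1 + t)
  if (a <= -1 || b <= -1) stop("invalid beta shape parameters")
  rec <- .jacobi_recurrence(max_order + 1, a, b)
  obj <- list(lo = dist_row$lo, hi = dist_row$hi,
              shape1 = dist_row$shape1, shape2 = dist_row$shape2,
              max_order = max_order, rec = rec)
  obj$eval <- function(x) .eval_orthonormal(obj, x)
  class(obj) <- "orthonormal_polys"
  obj
}

# evaluate the orthonormal family at physical coordinates x in [lo, hi]
.eval_orthonormal <- function(poly, x, max_order = poly$max_order) {
  t <- (2 * x - poly$lo - poly$hi) / (poly$hi - poly$lo)
  out <- matrix(0, length(x), max_order + 1)
  out[, 1] <- 1
  if (max_order >= 1) {
    al <- poly$rec$alpha; be <- poly$rec$beta
    pm1 <- rep(0, length(x)); p0 <- rep(1, length(x))
    for (k in 0:(max_order - 1)) {
      p1 <- ((t - al[k + 1]) * p0 - sqrt(be[k + 1]) * pm1) / sqrt(be[k + 2])
      out[, k + 2] <- p1
      pm1 <- p0; p0 <- p1
    }
  }
  out
}

#' Gauss quadrature for a bounded beta density
#'
#' Golub-Welsch nodes and weights integrating exactly against the
#' beta(shape1, shape2) probability density on `[lo, hi]` up to degree
#' `2 n - 1`.  Used to verify basis orthonormality.
#'
#' @param n Number of nodes.
#' @param dist_row One row of an [input_distribution()].
#' @return List of `nodes` (physical scale) and `weights` (sum to 1).
#' @export
gauss_beta_quadrature <- function(n, dist_row) {
  a <- dist_row$shape2 - 1; b <- dist_row$shape1 - 1
  rec <- .jacobi_recurrence(n, a, b)
  J <- diag(rec$alpha[seq_len(n)])
  if (n > 1) {
    off <- sqrt(rec$beta[2:n])
    J[cbind(1:(n - 1), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1))] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  t_nodes <- rev(e$values)
  w <- rev(e$vectors[1, ]^2)
  list(nodes = (t_nodes * (dist_row$hi - dist_row$lo) +
                  dist_row$lo + dist_row$hi) / 2,
       weights = w / sum(w))
}

#' Total-degree multi-index set
#'
#' All n-dimensional multi-indices `a` with `sum(a) <= p`; the set has
#' `choose(n + p, p)` members.
#'
#' @param n Dimension (>= 1).
#' @param p Maximum total degree (>= 0).
#' @return Integer matrix, one multi-index per row, ordered by total
#'   degree then lexicographically.
#' @export
total_degree_multiindices <- function(n, p) {
  stopifnot(n >= 1, p >= 0)
  grid <- as.matrix(expand.grid(rep(list(0:p), n)))[, n:1, drop = FALSE]
  grid <- grid[rowSums(grid) <= p, , drop = FALSE]
  grid <- grid[order(rowSums(grid), apply(grid, 1, paste, collapse = ",")), ,
               drop = FALSE]
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  grid
}

#' Joint gPC basis
#'
#' @param dists An [input_distribution()].
#' @param indices K x n multi-index matrix (rows = basis terms).
#' @return Object of class `gpc_basis`.
#' @export
gpc_basis <- function(dists, indices) {
  stopifnot(ncol(indices) == nrow(dists))
  max_ord <- max(indices)
  polys <- lapply(seq_len(nrow(dists)), function(i)
    orthonormal_polys(dists[i, ], max_ord))
  structure(list(dists = dists, indices = indices, polys = polys),
            class = "gpc_basis")
}

#' Evaluate the joint basis at sample points
#'
#' @param basis A [gpc_basis()].
#' @param samples N x n matrix on the physical (conductivity) scale.
#' @return N x K design matrix of tensor-product basis values.
#' @export
eval_gpc_basis <- function(basis, samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = nrow(basis$dists))
  n <- ncol(samples); K <- nrow(basis$indices)
  uni <- lapply(seq_len(n), function(i)
    .eval_orthonormal(basis$polys[[i]], samples[, i]))
  Psi <- matrix(1, nrow(samples), K)
  for (i in seq_len(n)) {
    Psi <- Psi * uni[[i]][, basis$indices[, i] + 1, drop = FALSE]
  }
  Psi
}

#' Draw input samples from the joint beta distribution
#'
#' @param dists An [input_distribution()].
#' @param n_samples Number of draws.
#' @param seed Integer seed (reproducible; the caller's RNG state is left
#'   untouched).
#' @return `n_samples` x n matrix on the conductivity scale, columns named
#'   by tissue.
#' @export
draw_samples <- function(dists, n_samples, seed) {
  stopifnot(n_samples >= 1)
  with_seed(seed, {
    X <- vapply(seq_len(nrow(dists)), function(i)
      stats::rbeta(n_samples, dists$shape1[i], dists$shape2[i]) *
        (dists$hi[i] - dists$lo[i]) + dists$lo[i],
      numeric(n_samples))
    X <- matrix(X, nrow = n_samples)
    colnames(X) <- dists$tissue
    X
  })
}

#' Least-squares gPC coefficients
#'
#' Solves the oversampled regression `Psi u = y` for every response
#' column.  A response that lies in the basis span is recovered to
#' machine precision.
#'
#' @param samples N x n input samples.
#' @param responses N x P response matrix (one column per spatial point,
#'   a vector is treated as one point).
#' @param basis A [gpc_basis()].
#' @param oversampling Required ratio N / K (default 2).
#' @return K x P coefficient matrix; attributes `hat_diag` (leverages)
#'   and `loo_rss` support cross-validation.
#' @export
fit_coefficients <- function(samples, responses, basis, oversampling = 2) {
  if (is.null(dim(responses))) responses <- matrix(responses, ncol = 1)
  Psi <- eval_gpc_basis(basis, samples)
  K <- ncol(Psi)
  if (nrow(Psi) < oversampling * K)
    stop(sprintf("need >= %g x %d = %d samples, have %d",
                 oversampling, K, ceiling(oversampling * K), nrow(Psi)))
  qrd <- qr(Psi)
  if (qrd$rank < K) {
    kap <- kappa(Psi)
    stop(sprintf("conditioning error: design matrix rank %d < %d basis terms (condition ~ %.3g)",
                 qrd$rank, K, kap))
  }
  U <- qr.coef(qrd, responses)
  resid <- responses - Psi %*% U
  Q <- qr.Q(qrd)
  h <- rowSums(Q^2)
  U <- as.matrix(U)
  attr(U, "hat_diag") <- h
  attr(U, "residuals") <- as.matrix(resid)
  U
}

# relative leave-one-out cross-validation error of a fit
.loocv_error <- function(U, responses) {
  r <- attr(U, "residuals"); h <- attr(U, "hat_diag")
  loo <- r / pmax(1 - h, 1e-12)
  sqrt(sum(loo^2) / sum(responses^2))
}

#' Adaptive gPC expansion of a forward model
#'
#' Grows an anisotropic multi-index basis for the response of `model_fn`
#' over the input space: starting from the full first-order set, the
#' admissible candidate index (within total degree `max_order`) whose
#' basis function correlates most strongly with the current residual is
#' added, new input samples are drawn to keep the regression oversampled,
#' and the loop stops once the relative leave-one-out cross-validation
#' error falls below `residual_tol` (or the total-degree basis is
#' saturated).
#'
#' @param model_fn Deterministic function: input vector xi (length n, on
#'   the conductivity scale) -> numeric response vector over spatial
#'   points (constant length).
#' @param dists An [input_distribution()] defining the n input dimensions.
#' @param residual_tol Cross-validated relative error target (default
#'   1e-3).
#' @param max_order Maximum total polynomial degree (default 3).
#' @param oversampling Sample-to-coefficient ratio kept during growth
#'   (default 2).
#' @param seed Master seed for the sampling streams.
#' @param n_add Candidate indices added per growth step.
#' @param max_evals Forward-evaluation budget of the expansion (default
#'   96, the upper end of the emulated protocol).  Growth stops before
#'   exceeding it and the best basis seen is kept.
#' @param max_coefficients Cap on the number of retained basis terms
#'   (default 64, the protocol's largest series).
#' @param n_validation Fresh draws used for the recorded hold-out
#'   validation error (0 skips it).
#' @param prune_tol Relative threshold below which a coefficient is
#'   counted as numerically zero when reporting the pruned basis size.
#' @return Object of class `gpc_model`: `basis`, `coefficients` (K x P),
#'   `n_model_evals`, `loocv_error`, `validation_error`/`validation_sd`,
#'   `n_coefficients` (pruned) and `n_coefficients_raw`.
#' @export
adaptive_expand <- function(model_fn, dists, residual_tol = 1e-3,
                            max_order = 3, oversampling = 2, seed = 1,
                            n_add = 2, max_evals = 96, max_coefficients = 64,
                            n_validation = 10, prune_tol = 1e-8) {
  n <- nrow(dists)
  full <- total_degree_multiindices(n, max_order)
  full_keys <- apply(full, 1, paste, collapse = ",")
  indices <- total_degree_multiindices(n, min(1, max_order))
  if (ceiling(oversampling * nrow(indices)) > max_evals)
    stop(sprintf("budget of %d evaluations cannot oversample the %d first-order terms",
                 max_evals, nrow(indices)))
  X <- matrix(numeric(0), 0, n)
  Y <- NULL
  n_evals <- 0L
  batch <- 0L
  path <- list()
  eval_rows <- function(Xnew) {
    out <- lapply(seq_len(nrow(Xnew)), function(i) {
      y <- model_fn(as.numeric(Xnew[i, ]))
      if (any(!is.finite(y)))
        stop(sprintf("propagation error: non-finite model output at sample (%s)",
                     paste(signif(Xnew[i, ], 4), collapse = ", ")))
      y
    })
    do.call(rbind, out)
  }
  repeat {
    K <- nrow(indices)
    need <- ceiling(oversampling * K)
    if (nrow(X) < need) {
      batch <- batch + 1L
      Xnew <- draw_samples(dists, need - nrow(X), derive_seed(seed, batch))
      Y <- rbind(Y, eval_rows(Xnew))
      X <- rbind(X, Xnew)
      n_evals <- nrow(X)
    }
    basis <- gpc_basis(dists, indices)
    U <- fit_coefficients(X, Y, basis, oversampling = oversampling)
    eps <- .loocv_error(U, Y)
    path[[length(path) + 1]] <- indices
    if (eps <= residual_tol) break
    K_next <- K + n_add
    if (ceiling(oversampling * K_next) > max_evals ||
        K_next > max_coefficients) break   # budget reached; keep best basis
    keys <- apply(indices, 1, paste, collapse = ",")
    # admissible candidates: in the total-degree set, not yet active, and
    # with every backward neighbour active (downward-closed growth)
    cand <- full[!(full_keys %in% keys), , drop = FALSE]
    if (nrow(cand) == 0) break
    admissible <- vapply(seq_len(nrow(cand)), function(r) {
      a <- cand[r, ]
      ok <- TRUE
      for (i in which(a > 0)) {
        back <- a; back[i] <- back[i] - 1L
        if (!(paste(back, collapse = ",") %in% keys)) { ok <- FALSE; break }
      }
      ok
    }, logical(1))
    cand <- cand[admissible, , drop = FALSE]
    if (nrow(cand) == 0) break
    cbasis <- gpc_basis(dists, cand)
    Pc <- eval_gpc_basis(cbasis, X)
    R <- attr(U, "residuals")
    score <- as.numeric(rowSums((t(Pc) %*% R)^2)) / pmax(colSums(Pc^2), 1e-300)
    take <- order(score, decreasing = TRUE)[seq_len(min(n_add, nrow(cand)))]
    indices <- rbind(indices, cand[take, , drop = FALSE])
  }
  if (eps > residual_tol && length(path) > 1) {
    # budget or saturation reached: re-score every visited basis on the
    # final sample set and keep the one with the lowest cross-validated
    # error (the growth path is a nested family, so this is a consistent
    # model-selection step, not extra sampling)
    eps_path <- vapply(path, function(idx) {
      Up <- fit_coefficients(X, Y, gpc_basis(dists, idx),
                             oversampling = oversampling)
      .loocv_error(Up, Y)
    }, numeric(1))
    pick <- path[[which.min(eps_path)]]
    if (!identical(dim(pick), dim(indices)) || !all(pick == indices)) {
      indices <- pick
      basis <- gpc_basis(dists, indices)
      U <- fit_coefficients(X, Y, basis, oversampling = oversampling)
    }
    eps <- min(eps_path)
  }
  var_tot <- colSums(U[rowSums(basis$indices) > 0, , drop = FALSE]^2)
  scale2 <- max(var_tot, sum(U[1, ]^2) * 1e-30, .Machine$double.xmin)
  keep <- rowSums(U^2) > prune_tol^2 * scale2
  model <- structure(list(
    basis = basis, coefficients = U,
    samples = X, responses = Y,
    n_model_evals = n_evals, loocv_error = eps,
    n_coefficients_raw = nrow(basis$indices),
    n_coefficients = sum(keep),
    validation_error = NA_real_, validation_sd = NA_real_
  ), class = "gpc_model")
  if (n_validation > 0) {
    ve <- validation_error(model, model_fn, n_val = n_validation,
                           seed = derive_seed(seed, 900001L))
    model$validation_error <- ve$mean
    model$validation_sd <- ve$sd
  }
  model
}

#' @export
print.gpc_model <- function(x, ...) {
  cat(sprintf(paste0("gPC surrogate: %d basis terms (%d above pruning ",
                     "threshold), max degree %d, %d spatial points\n"),
              x$n_coefficients_raw, x$n_coefficients,
              max(rowSums(x$basis$indices)), ncol(x$coefficients)))
  cat(sprintf("  forward evaluations: %d; LOOCV rel. error %.3g", x$n_model_evals,
              x$loocv_error))
  if (is.finite(x$validation_error))
    cat(sprintf("; hold-out rel. error %.3g (sd %.3g)",
                x$validation_error, x$validation_sd))
  cat("\n")
  invisible(x)
}

#' Evaluate a gPC surrogate
#'
#' @param model A `gpc_model`.
#' @param samples N x n input matrix (conductivity scale).
#' @return N x P matrix of surrogate responses.
#' @export
evaluate_surrogate <- function(model, samples) {
  eval_gpc_basis(model$basis, samples) %*% model$coefficients
}

#' Mean and variance from gPC coefficients
#'
#' With an orthonormal basis the mean is the coefficient of the constant
#' term and the variance the sum of squares of all other coefficients.
#'
#' @param model A `gpc_model`.
#' @return List of per-point `mean` and `variance` vectors.
#' @export
surrogate_moments <- function(model) {
  deg <- rowSums(model$basis$indices)
  k0 <- which(deg == 0)
  if (length(k0) != 1) stop("basis must contain exactly one constant term")
  list(mean = as.numeric(model$coefficients[k0, ]),
       variance = colSums(model$coefficients[-k0, , drop = FALSE]^2))
}

#' Variance-based Sobol decomposition from gPC coefficients
#'
#' Groups coefficients by the support of their multi-index: the summed
#' squared coefficients whose support is exactly the subset U, divided by
#' the total variance, is the Sobol index S_U.  First-order indices are
#' reported per input dimension and all higher-order subsets are pooled
#' as `interactions`; per point everything sums to one where the variance
#' is positive.  Points with (numerically) zero variance are flagged
#' `undefined` and carry NA indices rather than a division by zero.
#'
#' @param model A `gpc_model`.
#' @return Object of class `sobol_table`: `first_order` (n x P matrix,
#'   rows named by tissue), `interactions` (P), `total_variance` (P),
#'   `undefined` (logical P), and `by_subset` (named list of all subset
#'   indices).
#' @export
sobol_decomposition <- function(model) {
  idx <- model$basis$indices
  U <- model$coefficients
  deg <- rowSums(idx)
  mom <- surrogate_moments(model)
  var_tot <- mom$variance
  undef <- var_tot <= max(mom$mean^2, 1) * 1e-28
  denom <- ifelse(undef, NA_real_, var_tot)
  support <- apply(idx > 0, 1, function(z) paste(which(z), collapse = ","))
  nz <- which(deg > 0)
  by_subset <- lapply(split(nz, support[nz]), function(rows)
    colSums(U[rows, , drop = FALSE]^2) / denom)
  n <- ncol(idx)
  first <- matrix(NA_real_, n, ncol(U),
                  dimnames = list(model$basis$dists$tissue, NULL))
  inter <- rep(0, ncol(U)); inter[undef] <- NA_real_
  for (s in names(by_subset)) {
    dims <- as.integer(strsplit(s, ",")[[1]])
    if (length(dims) == 1) first[dims, ] <- by_subset[[s]]
    else inter <- inter + by_subset[[s]]
  }
  first[is.na(first) & !rep(undef, each = n)] <- 0  # absent subset => index 0
  structure(list(first_order = first, interactions = inter,
                 total_variance = var_tot, undefined = undef,
                 by_subset = by_subset),
            class = "sobol_table")
}

#' Hold-out validation error of a surrogate
#'
#' Draws `n_val` fresh inputs, runs the original model, and reports the
#' mean (over draws) of the point-averaged relative error
#' `|q_surrogate - q| / |q|`, mirroring how surrogate fidelity is
#' quoted for field magnitudes.
#'
#' @param model A `gpc_model`.
#' @param model_fn The original forward model.
#' @param n_val Number of validation draws (>= 10 recommended).
#' @param seed Seed for the validation draws.
#' @param points Optional indices restricting the spatial points the
#'   error is averaged over (e.g. mid-layer vertices only).
#' @return List with `mean`, `sd` (across draws), `per_draw`, `n_val`.
#' @export
validation_error <- function(model, model_fn, n_val = 25, seed = 1,
                             points = NULL) {
  if (n_val < 1) stop("n_val must be positive")
  if (is.null(points)) points <- seq_len(ncol(model$coefficients))
  Xv <- draw_samples(model$basis$dists, n_val, seed)
  pred <- evaluate_surrogate(model, Xv)
  guard <- 1e-12
  per_draw <- vapply(seq_len(n_val), function(i) {
    q <- model_fn(as.numeric(Xv[i, ]))[points]
    den <- pmax(abs(q), guard * max(abs(q), .Machine$double.xmin))
    mean(abs(pred[i, points] - q) / den)
  }, numeric(1))
  list(mean = mean(per_draw), sd = stats::sd(per_draw),
       per_draw = per_draw, n_val = n_val)
}
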