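# First-order tetrahedral finite-element solver for the quasi-static
# volume-conductor problem: div(sigma grad phi) = 0 with Dirichlet values
# on two tagged electrode patches, piecewise-constant conductivity per
# tissue, piecewise-linear phi and element-constant E = -grad phi.
#
# Geometry is stored in mm; the solver works in SI internally (nodes are
# converted to metres exactly once, in precompute_fem), so potentials are
# volts, fields V/m and patch fluxes amperes.

#' Conductivity assignment for a labeled mesh
#'
#' @param values Named numeric vector, S/m, one entry per tissue label
#'   present in the mesh (AIR is filled in automatically and pinned to
#'   1e-15 S/m, an insulator).
#' @return Named numeric vector of class `conductivity_assignment`.
#' @export
conductivity_assignment <- function(values) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("conductivities must be a named vector (tissue -> S/m)")
  if (!"AIR" %in% names(values)) values <- c(values, AIR = 1e-15)
  values[["AIR"]] <- 1e-15
  bad <- names(values)[values <= 0 & names(values) != "AIR"]
  if (length(bad)) stop("conductivities must be positive: ", paste(bad, collapse = ", "))
  structure(values, class = "conductivity_assignment")
}

#' Precompute the finite-element operators of a mesh
#'
#' Assembles one stiffness matrix per tissue label (so that the system
#' matrix for any conductivity draw is a cheap weighted sum), the
#' element-wise P1 basis gradients, the electrode node sets, and the
#' boundary-triangle-to-element adjacency used for flux integration.  One
#' `fem_system` serves every conductivity draw on the same mesh; the
#' sparse Cholesky factorisation is symbolically analysed once and
#' numerically updated per draw.
#'
#' @param mesh A `tet_mesh` with electrode patches tagged
#'   (see [place_electrodes()]).
#' @return Object of class `fem_system`.
#' @export
precompute_fem <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (!any(mesh$patch == 1) || !any(mesh$patch == 2))
    stop("mesh needs two tagged electrode patches; call place_electrodes() first")
  nodes_m <- mesh$nodes * 1e-3
  elems <- mesh$elems
  m <- nrow(elems)
  p1 <- nodes_m[elems[, 1], ]; a <- nodes_m[elems[, 2], ] - p1
  b <- nodes_m[elems[, 3], ] - p1; cc <- nodes_m[elems[, 4], ] - p1
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, cc); cxa <- cross(cc, a); axb <- cross(a, b)
  det6 <- rowSums(a * bxc)              # 6 * volume (m^3), positive
  g2 <- bxc / det6; g3 <- cxa / det6; g4 <- axb / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)          # gradient of basis fn i, per element
  vol_m3 <- det6 / 6

  # per-tissue stiffness matrices K_t[i,j] = sum_e V_e grad_i . grad_j
  n_nodes <- nrow(mesh$nodes)
  stiff <- list()
  for (t in unique(mesh$label)) {
    sel <- which(mesh$label == t)
    ii <- jj <- xx <- vector("list", 16)
    k <- 0
    for (i in 1:4) for (j in 1:4) {
      k <- k + 1
      ii[[k]] <- elems[sel, i]; jj[[k]] <- elems[sel, j]
      xx[[k]] <- vol_m3[sel] * rowSums(grads[[i]][sel, , drop = FALSE] *
                                         grads[[j]][sel, , drop = FALSE])
    }
    stiff[[t]] <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                       x = unlist(xx), dims = c(n_nodes, n_nodes))
  }

  anode_nodes <- sort(unique(as.vector(mesh$boundary_tri[mesh$patch == 1, ])))
  cathode_nodes <- sort(unique(as.vector(mesh$boundary_tri[mesh$patch == 2, ])))
  fixed <- c(anode_nodes, cathode_nodes)
  free <- setdiff(seq_len(n_nodes), fixed)

  # boundary triangle -> adjacent element (each outer face belongs to one tet)
  enc <- function(tri) {
    s <- t(apply(tri, 1, sort))
    (s[, 1] * (n_nodes + 1) + s[, 2]) * (n_nodes + 1) + s[, 3]
  }
  face_keys <- c(enc(elems[, c(2, 3, 4)]), enc(elems[, c(1, 3, 4)]),
                 enc(elems[, c(1, 2, 4)]), enc(elems[, c(1, 2, 3)]))
  bt_elem <- (match(enc(mesh$boundary_tri), face_keys) - 1) %% m + 1
  if (anyNA(bt_elem)) stop("internal error: unmatched boundary face")

  # outward unit normals and areas of boundary triangles (metres)
  bt <- mesh$boundary_tri
  e1 <- nodes_m[bt[, 2], ] - nodes_m[bt[, 1], ]
  e2 <- nodes_m[bt[, 3], ] - nodes_m[bt[, 1], ]
  nrm <- cross(e1, e2)
  area2 <- sqrt(rowSums(nrm^2))
  env <- new.env(parent = emptyenv())   # caches the Cholesky analysis
  structure(list(
    mesh = mesh, stiff = stiff, grads = grads, vol_m3 = vol_m3,
    anode_nodes = anode_nodes, cathode_nodes = cathode_nodes,
    free = free, fixed = fixed,
    bt_elem = bt_elem, bt_normal = nrm / area2, bt_area_m2 = area2 / 2,
    cache = env
  ), class = "fem_system")
}

#' Solve the electric potential for one conductivity draw
#'
#' Assembles `A(sigma) = sum_t sigma_t K_t`, imposes the Dirichlet values
#' on the two electrode patches, and solves the reduced symmetric system
#' by sparse Cholesky factorisation.  The relative algebraic residual
#' `||A phi - b|| / ||b||` is computed and must not exceed `tol`.
#'
#' @param mesh A `tet_mesh` with tagged patches, or `NULL` when `fem` is
#'   given.
#' @param sigma A [conductivity_assignment()] covering every mesh label.
#' @param anode_value,cathode_value Dirichlet potentials (V) on patch 1/2.
#' @param fem Optional precomputed [precompute_fem()] system (reused
#'   across draws).
#' @param tol Residual acceptance threshold (default 1e-5).
#' @return Object of class `potential_field`: `phi` (V, per node),
#'   `residual`, and the Dirichlet bookkeeping.
#' @export
solve_potential <- function(mesh, sigma, anode_value = 1, cathode_value = -1,
                            fem = NULL, tol = 1e-5) {
  if (is.null(fem)) fem <- precompute_fem(mesh)
  mesh <- fem$mesh
  miss <- setdiff(unique(mesh$label), names(sigma))
  if (length(miss)) stop("missing conductivities for: ", paste(miss, collapse = ", "))
  A <- Reduce(`+`, Map(function(t) sigma[[t]] * fem$stiff[[t]], names(fem$stiff)))
  free <- fem$free; fixed <- fem$fixed
  phi <- numeric(nrow(mesh$nodes))
  phi[fem$anode_nodes] <- anode_value
  phi[fem$cathode_nodes] <- cathode_value
  Aff <- A[free, free]
  b <- -as.numeric(A[free, fixed] %*% phi[fixed])
  if (anode_value == cathode_value) {
    phi[free] <- anode_value
    return(structure(list(phi = phi, residual = 0,
                          anode_value = anode_value, cathode_value = cathode_value),
                     class = "potential_field"))
  }
  ch <- fem$cache$chol
  sol <- tryCatch({
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE, perm = TRUE)
      fem$cache$chol <- ch
    } else {
      ch <- Matrix::update(ch, Matrix::forceSymmetric(Aff))
    }
    as.numeric(Matrix::solve(ch, b))
  }, error = function(e) stop("solver error: ", conditionMessage(e)))
  res <- sqrt(sum((as.numeric(Aff %*% sol) - b)^2)) / sqrt(sum(b^2))
  if (!is.finite(res) || res > tol)
    stop(sprintf("solver did not reach residual %.1e (achieved %.3e)", tol, res))
  phi[free] <- sol
  # consistent nodal reaction fluxes: the discrete current entering the
  # domain through each electrode patch (exactly conservative)
  reac <- as.numeric(A %*% phi)
  structure(list(phi = phi, residual = res,
                 anode_value = anode_value, cathode_value = cathode_value,
                 anode_flux_A = sum(reac[fem$anode_nodes]),
                 cathode_flux_A = sum(reac[fem$cathode_nodes])),
            class = "potential_field")
}

#' Electric field from a solved potential
#'
#' `E = -grad phi`, constant per element (the exact gradient of the
#' piecewise-linear interpolant), evaluated at element centres.
#'
#' @param phi A `potential_field`.
#' @param mesh The mesh it was solved on (ignored when `fem` given).
#' @param fem Optional precomputed system.
#' @return Object of class `field_solution`: `E` (M x 3, V/m), `magnitude`
#'   (V/m), `current_A` (NA until scaled).
#' @export
compute_field <- function(phi, mesh, fem = NULL) {
  stopifnot(inherits(phi, "potential_field"))
  if (is.null(fem)) fem <- precompute_fem(mesh)
  elems <- fem$mesh$elems
  E <- -(fem$grads[[1]] * phi$phi[elems[, 1]] +
           fem$grads[[2]] * phi$phi[elems[, 2]] +
           fem$grads[[3]] * phi$phi[elems[, 3]] +
           fem$grads[[4]] * phi$phi[elems[, 4]])
  structure(list(E = E, magnitude = sqrt(rowSums(E^2)), current_A = NA_real_),
            class = "field_solution")
}

# current (A) leaving the domain through the given boundary triangles,
# integrating sigma E . n per face with the adjacent element's field
.face_flux <- function(solution, fem, sigma, sel) {
  el <- fem$bt_elem[sel]
  sig_el <- unname(sigma[fem$mesh$label[el]])
  Jn <- rowSums(solution$E[el, , drop = FALSE] * fem$bt_normal[sel, , drop = FALSE])
  sum(sig_el * Jn * fem$bt_area_m2[sel])
}

#' Net face-integrated current through the outer boundary
#'
#' Diagnostic: integrates `sigma E . n` over every outer-boundary triangle
#' using the adjacent element's (one-sided) field.  For a conservative
#' solution the net current is zero up to discretisation error; compare
#' against the injected current for scale.
#'
#' @param solution A `field_solution`.
#' @param mesh Mesh (ignored when `fem` given).
#' @param sigma Conductivity assignment of the solve.
#' @param fem Optional precomputed system.
#' @return Net outward current in amperes.
#' @export
boundary_net_flux <- function(solution, mesh, sigma, fem = NULL) {
  if (is.null(fem)) fem <- precompute_fem(mesh)
  .face_flux(solution, fem, sigma, seq_len(nrow(fem$mesh$boundary_tri)))
}

#' Rescale a solution to a target injected current
#'
#' The Dirichlet problem fixes the potential difference, not the current;
#' this reads the discrete current entering the domain through the anode
#' patch (the consistent nodal reaction flux `sum(A phi)` over the patch
#' nodes, which is exactly charge-conserving and far more accurate at
#' coarse resolution than integrating one-sided element gradients over
#' the patch faces) and scales `phi` and `E` linearly so the injected
#' current hits the target (2 mA in the emulated protocol).
#'
#' @param solution A `field_solution`.
#' @param phi The matching `potential_field` (carries the patch fluxes).
#' @param mesh Mesh (ignored when `fem` given).
#' @param sigma The conductivity assignment used for the solve.
#' @param target_current Target injected current (A), e.g. `2e-3`.
#' @param fem Optional precomputed system.
#' @return List with the scaled `solution` and `phi`; the solution carries
#'   `current_A` and both patch fluxes.
#' @export
scale_to_current <- function(solution, phi, mesh, sigma, target_current = 2e-3,
                             fem = NULL) {
  if (is.null(fem)) fem <- precompute_fem(mesh)
  injected <- phi$anode_flux_A
  if (is.null(injected)) stop("potential field carries no patch flux; re-solve")
  if (!is.finite(injected) || abs(injected) < 1e3 * .Machine$double.xmin)
    stop("topology error: zero anode flux (disconnected electrodes?)")
  s <- target_current / injected
  solution$E <- solution$E * s
  solution$magnitude <- solution$magnitude * abs(s)
  phi$phi <- phi$phi * s
  phi$anode_value <- phi$anode_value * s
  phi$cathode_value <- phi$cathode_value * s
  phi$anode_flux_A <- phi$anode_flux_A * s
  phi$cathode_flux_A <- phi$cathode_flux_A * s
  solution$current_A <- target_current
  solution$anode_flux_A <- phi$anode_flux_A
  solution$cathode_flux_A <- phi$cathode_flux_A
  list(solution = solution, phi = phi)
}

#' Precompute surface interpolation weights
#'
#' Inverse-distance weights of the `k` nearest element centroids per
#' surface vertex (exact hits short-circuit to the hitting element).
#' Computing these once lets [interpolate_to_surface()] run in O(V k) per
#' field.
#'
#' @param mesh A `tet_mesh`.
#' @param surface A `tri_surface` lying inside the mesh.
#' @param k Number of contributing element centroids.
#' @return List of index matrix `idx` (V x k) and weight matrix `w`.
#' @export
surface_interp_weights <- function(mesh, surface, k = 8) {
  ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  verts <- surface$vertices
  r_out <- max(sqrt(rowSums(mesh$nodes^2)))
  if (any(sqrt(rowSums(verts^2)) > r_out + 1e-9))
    stop("containment error: surface vertex outside the mesh hull")
  nv <- nrow(verts)
  idx <- matrix(0L, nv, k); w <- matrix(0, nv, k)
  chunk <- 200L
  for (s in seq(1L, nv, by = chunk)) {
    rows <- s:min(s + chunk - 1L, nv)
    d2 <- outer(rowSums(verts[rows, , drop = FALSE]^2), rowSums(ctr^2), `+`) -
      2 * verts[rows, , drop = FALSE] %*% t(ctr)
    for (r in seq_along(rows)) {
      o <- order(d2[r, ])[seq_len(k)]
      d <- sqrt(pmax(d2[r, o], 0))
      idx[rows[r], ] <- o
      if (d[1] < 1e-9) {           # exact hit on a centroid
        w[rows[r], ] <- c(1, rep(0, k - 1))
      } else {
        wi <- 1 / d
        w[rows[r], ] <- wi / sum(wi)
      }
    }
  }
  list(idx = idx, w = w)
}

#' Interpolate an element field onto a surface
#'
#' Per-vertex value = inverse-distance-weighted mean of the `|E|` values
#' of the `k` nearest element centroids; by construction each value is
#' bounded by the contributing element values.
#'
#' @param solution A `field_solution` (its `magnitude` is interpolated).
#' @param mesh The mesh.
#' @param surface Target `tri_surface`.
#' @param k Neighbours (default 8).
#' @param weights Optional precomputed [surface_interp_weights()].
#' @return Numeric vector, one value per surface vertex (V/m).
#' @export
interpolate_to_surface <- function(solution, mesh, surface, k = 8,
                                   weights = NULL) {
  if (is.null(weights)) weights <- surface_interp_weights(mesh, surface, k)
  vals <- matrix(solution$magnitude[weights$idx], nrow(weights$idx))
  rowSums(vals * weights$w)
}
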