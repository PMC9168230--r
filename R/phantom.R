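# Synthetic multi-shell head phantoms.
#
# Concentric spheres stand in for the anatomy: skin, skull, subarachnoid
# CSF, gray matter and a solid white-matter core, with optional spherical
# white-matter-lesion (WML) inclusions and an optional air cavity.  The
# spherical geometry admits a closed-form solution of the volume-conductor
# problem, which serves as the solver oracle.

#' Tissue labels used throughout the package
#' @export
TISSUES <- c("SKIN", "SKULL", "AIR", "CSF", "GM", "WM", "WML")

#' Specify a multi-shell head phantom
#'
#' @param shell_radii Named numeric vector of outer radii in mm for
#'   `skin`, `skull`, `csf`, `gm`, `wm` (strictly decreasing; the WM shell
#'   is the innermost solid ball).  Defaults mimic an adult head:
#'   92/86/80/78/70 mm.
#' @param lesion_target_fraction Target fraction of the WM volume occupied
#'   by lesions, in `[0, 0.5)`.  The group means of the emulated cohort are
#'   0, 0.0072, 0.0211 and 0.0894 for absent/low/medium/high lesion load.
#' @param lesion_radius_range Lesion sphere radii are drawn log-uniformly
#'   from this `[min, max]` range (mm).
#' @param lesion_radial_bias Exponent >= 1 biasing lesion centres towards
#'   the inner white matter (1 = uniform in the WM ball).  Mimics the
#'   periventricular predominance of white-matter hyperintensities.
#' @param include_air_cavity Add a spherical air cavity.
#' @param air_center,air_radius Centre (mm, length 3) and radius (mm) of
#'   the cavity; only used when `include_air_cavity` is `TRUE`.
#' @param seed Integer seed making lesion sampling reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shell_radii = c(skin = 92, skull = 86, csf = 80,
                                         gm = 78, wm = 70),
                         lesion_target_fraction = 0,
                         lesion_radius_range = c(4, 12),
                         lesion_radial_bias = 2,
                         include_air_cavity = FALSE,
                         air_center = c(0, 55, 55), air_radius = 8,
                         seed = 1L) {
  need <- c("skin", "skull", "csf", "gm", "wm")
  if (!all(need %in% names(shell_radii)))
    stop("shell_radii must name skin, skull, csf, gm, wm")
  r <- shell_radii[need]
  if (any(diff(r) >= 0)) stop("shell radii must strictly decrease from skin to wm")
  if (lesion_target_fraction < 0 || lesion_target_fraction >= 0.5)
    stop("lesion_target_fraction must lie in [0, 0.5)")
  if (length(lesion_radius_range) != 2 || lesion_radius_range[1] <= 0 ||
      diff(lesion_radius_range) < 0)
    stop("lesion_radius_range must be increasing and positive")
  if (lesion_radius_range[2] >= r[["wm"]])
    stop("lesion radii must fit inside the WM shell")
  structure(list(
    shell_radii = r,
    lesion_target_fraction = lesion_target_fraction,
    lesion_radius_range = lesion_radius_range,
    lesion_radial_bias = lesion_radial_bias,
    include_air_cavity = isTRUE(include_air_cavity),
    air_center = air_center, air_radius = air_radius,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Multi-shell head phantom\n")
  cat("  outer radii (mm):",
      paste(sprintf("%s=%g", names(x$shell_radii), x$shell_radii), collapse = ", "), "\n")
  cat(sprintf("  lesion target fraction: %.4g of WM volume\n", x$lesion_target_fraction))
  if (x$include_air_cavity) cat("  air cavity at", paste(x$air_center, collapse = ","),
                                "r =", x$air_radius, "mm\n")
  invisible(x)
}

#' Sample non-overlapping lesion spheres inside the white matter
#'
#' Lesions are drawn one at a time (log-uniform radius, radially biased
#' centre) and accepted if they stay inside the WM ball and do not touch a
#' previously accepted lesion.  Accumulation stops once the realized volume
#' fraction is within 10% relative of the target; the final sphere is
#' shrunk to land on the target exactly when possible.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed; defaults to the spec's seed.
#' @return Object of class `lesion_set`: `centers` (L x 3 mm), `radii`
#'   (mm), `realized_fraction` (of WM volume).
#' @export
sample_lesions <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  r_wm <- spec$shell_radii[["wm"]]
  v_wm <- 4 / 3 * pi * r_wm^3
  target <- spec$lesion_target_fraction
  if (target == 0) {
    return(structure(list(centers = matrix(numeric(0), 0, 3), radii = numeric(0),
                          realized_fraction = 0),
                     class = "lesion_set"))
  }
  rmin <- spec$lesion_radius_range[1]; rmax <- spec$lesion_radius_range[2]
  if (4 / 3 * pi * rmin^3 > 1.1 * target * v_wm)
    stop("lesion placement failure: smallest admissible lesion exceeds the target volume")
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 3); radii <- numeric(0)
    vol <- 0; attempts <- 0; max_attempts <- 20000
    while (vol < target * v_wm * 0.999 && attempts < max_attempts) {
      attempts <- attempts + 1
      rad <- exp(stats::runif(1, log(rmin), log(rmax)))
      remaining <- target * v_wm - vol
      if (4 / 3 * pi * rad^3 > remaining) {
        rad <- max(rmin, (3 * remaining / (4 * pi))^(1 / 3))
      }
      avail <- r_wm - rad
      if (avail <= 0) next
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rho <- avail * stats::runif(1)^(spec$lesion_radial_bias / 3)
      ctr <- dir * rho
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
        ok <- all(d > radii + rad)
      }
      if (!ok) next
      centers <- rbind(centers, ctr); radii <- c(radii, rad)
      vol <- vol + 4 / 3 * pi * rad^3
    }
    realized <- vol / v_wm
    if (abs(realized - target) / target > 0.10)
      stop(sprintf(paste0("lesion placement failure after %d attempts: achieved ",
                          "fraction %.4g vs target %.4g"), attempts, realized, target))
    structure(list(centers = centers, radii = radii, realized_fraction = realized),
              class = "lesion_set")
  })
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("Lesion set: %d spheres, realized WM fraction %.4g\n",
              length(x$radii), x$realized_fraction))
  invisible(x)
}

# label of a point set given the spec + lesions (vectorized over rows)
.label_points <- function(pts, spec, lesions) {
  r <- sqrt(rowSums(pts^2))
  sr <- spec$shell_radii
  lab <- rep("SKIN", nrow(pts))
  lab[r <= sr[["skull"]]] <- "SKULL"
  lab[r <= sr[["csf"]]] <- "CSF"
  lab[r <= sr[["gm"]]] <- "GM"
  lab[r <= sr[["wm"]]] <- "WM"
  if (length(lesions$radii) > 0) {
    inwm <- which(lab == "WM")
    for (i in seq_along(lesions$radii)) {
      d2 <- rowSums(sweep(pts[inwm, , drop = FALSE], 2, lesions$centers[i, ])^2)
      lab[inwm[d2 <= lesions$radii[i]^2]] <- "WML"
    }
  }
  if (spec$include_air_cavity) {
    d2 <- rowSums(sweep(pts, 2, spec$air_center)^2)
    lab[d2 <= spec$air_radius^2] <- "AIR"
  }
  lab
}

#' Tetrahedral mesh of a phantom
#'
#' Builds a conforming tetrahedral ball mesh from radially stacked
#' icosphere layers.  Every shell interface coincides with a node layer, so
#' tissue boundaries are exactly resolved; within a shell the number of
#' radial layers is `max(1, round(thickness / target_edge_mm))`.  Prisms
#' between consecutive layers are split into three tetrahedra with
#' index-ordered diagonals, which keeps neighbouring prisms conforming.
#' Elements are labeled by the region membership of their centroid.
#'
#' @param spec A [phantom_spec()].
#' @param lesions A [sample_lesions()] result (empty set allowed).
#' @param target_edge_mm Target radial edge length (mm); controls the
#'   number of radial layers per shell.
#' @param n_subdiv Icosphere subdivision level controlling angular
#'   resolution (default 3: 642 vertices per layer).
#' @param min_dihedral_deg Quality gate: the mesh is rejected if its
#'   minimum dihedral angle falls below this (degrees); stands in for the
#'   sliver removal a general-purpose mesher would perform.
#' @return Object of class `tet_mesh`: `nodes` (N x 3 mm), `elems`
#'   (M x 4), `label` (character, one of [TISSUES]), `boundary_tri`
#'   (outer-surface triangles, outward oriented), `patch` (integer per
#'   boundary triangle; 0 = untagged).
#' @export
mesh_phantom <- function(spec, lesions = sample_lesions(spec),
                         target_edge_mm = 20, n_subdiv = 3,
                         min_dihedral_deg = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  sr <- spec$shell_radii
  bounds <- c(0, rev(unname(sr)))  # 0, wm, gm, csf, skull, skin
  radii <- 0
  for (i in seq_len(length(bounds) - 1)) {
    th <- bounds[i + 1] - bounds[i]
    nl <- max(1L, as.integer(round(th / target_edge_mm)))
    radii <- c(radii, bounds[i] + th * seq_len(nl) / nl)
  }
  radii <- radii[-1]  # strictly positive layer radii, outermost = skin
  ico <- icosphere(n_subdiv)
  nv <- nrow(ico$vertices)
  nlay <- length(radii)
  nodes <- matrix(0, 1 + nlay * nv, 3)
  for (l in seq_len(nlay))
    nodes[1 + (l - 1) * nv + seq_len(nv), ] <- ico$vertices * radii[l]
  idx <- function(l, v) 1 + (l - 1) * nv + v  # node id of vertex v on layer l

  # core: centre node + first layer
  elems <- cbind(1L, idx(1, ico$faces[, 1]), idx(1, ico$faces[, 2]),
                 idx(1, ico$faces[, 3]))
  # prisms between consecutive layers, split into 3 tets each.  The split
  # follows the sorted base-vertex order so that the diagonal on a shared
  # quad face is identical in both adjacent prisms.
  f_sorted <- t(apply(ico$faces, 1, sort))
  for (l in seq_len(nlay - 1)) {
    b <- cbind(idx(l, f_sorted[, 1]), idx(l, f_sorted[, 2]), idx(l, f_sorted[, 3]))
    tp <- cbind(idx(l + 1, f_sorted[, 1]), idx(l + 1, f_sorted[, 2]),
                idx(l + 1, f_sorted[, 3]))
    elems <- rbind(
      elems,
      cbind(b[, 1], b[, 2], b[, 3], tp[, 1]),
      cbind(b[, 2], b[, 3], tp[, 1], tp[, 2]),
      cbind(b[, 3], tp[, 1], tp[, 2], tp[, 3])
    )
  }
  # enforce positive orientation
  vols <- tet_volumes(nodes, elems)
  neg <- vols < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]
  vols <- abs(vols)
  if (any(vols <= 0))
    stop(sprintf("mesh quality error: %d degenerate elements", sum(vols <= 0)))

  centroids <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
                  nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  label <- .label_points(centroids, spec, lesions)

  mind <- min_dihedral_deg(nodes, elems)
  if (mind < min_dihedral_deg)
    stop(sprintf("mesh quality error: min dihedral angle %.3f deg below gate %.3f",
                 mind, min_dihedral_deg))

  boundary_tri <- cbind(idx(nlay, ico$faces[, 1]), idx(nlay, ico$faces[, 2]),
                        idx(nlay, ico$faces[, 3]))
  # orient boundary triangles outward
  c1 <- (nodes[boundary_tri[, 1], ] + nodes[boundary_tri[, 2], ] +
           nodes[boundary_tri[, 3], ]) / 3
  a <- nodes[boundary_tri[, 2], ] - nodes[boundary_tri[, 1], ]
  bb <- nodes[boundary_tri[, 3], ] - nodes[boundary_tri[, 1], ]
  nrm <- cbind(a[, 2] * bb[, 3] - a[, 3] * bb[, 2],
               a[, 3] * bb[, 1] - a[, 1] * bb[, 3],
               a[, 1] * bb[, 2] - a[, 2] * bb[, 1])
  flip <- rowSums(nrm * c1) < 0
  boundary_tri[flip, c(2, 3)] <- boundary_tri[flip, c(3, 2)]

  structure(list(
    nodes = nodes, elems = elems, label = label,
    volumes = vols,
    boundary_tri = boundary_tri,
    patch = integer(nrow(boundary_tri)),
    spec = spec, lesions = lesions,
    n_subdiv = n_subdiv, min_dihedral = mind
  ), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("Tetrahedral phantom mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$elems)))
  tv <- tapply(x$volumes, x$label, sum)
  for (t in names(tv)) cat(sprintf("  %-5s %8d elements, %.3g mm^3\n",
                                   t, sum(x$label == t), tv[[t]]))
  if (any(x$patch > 0))
    cat(sprintf("  electrode patches: %s triangles\n",
                paste(table(x$patch[x$patch > 0]), collapse = " + ")))
  invisible(x)
}

#' Per-tissue labeled volumes of a mesh
#' @param mesh A `tet_mesh`.
#' @return Named numeric vector of summed element volumes (mm^3) per label.
#' @export
tissue_volumes <- function(mesh) {
  vapply(split(mesh$volumes, mesh$label), sum, numeric(1))
}

#' Define a two-electrode montage
#'
#' Electrodes are reduced to their Dirichlet boundary footprint: spherical
#' caps on the outer skin surface with the area of the emulated pad
#' electrodes (25 cm^2 by default).  `bihemispheric_analogue` places the
#' caps laterally (antipodal on the x axis, motor-cortex style);
#' `frontal_occipital_analogue` uses the anterior-posterior axis
#' (maximal-separation style).
#'
#' @param name Montage name.
#' @param cap_area_cm2 Pad contact area (cm^2).
#' @param directions Optional 2 x 3 matrix of unit cap-centre directions
#'   overriding the named defaults (anode first).
#' @return Object of class `electrode_montage`.
#' @export
electrode_montage <- function(name = c("bihemispheric_analogue",
                                       "frontal_occipital_analogue"),
                              cap_area_cm2 = 25, directions = NULL) {
  name <- match.arg(name)
  if (is.null(directions)) {
    directions <- switch(name,
      bihemispheric_analogue = rbind(c(1, 0, 0), c(-1, 0, 0)),
      frontal_occipital_analogue = rbind(c(0, 1, 0), c(0, -1, 0)))
  }
  directions <- directions / sqrt(rowSums(directions^2))
  structure(list(name = name, cap_area_cm2 = cap_area_cm2,
                 directions = directions), class = "electrode_montage")
}

#' Tag electrode patches on the outer boundary
#'
#' Selects boundary triangles for each electrode greedily by angular
#' distance to the cap centre until the accumulated area best matches the
#' requested pad area, i.e. the discrete analogue of a spherical cap of
#' area `2*pi*R^2*(1 - cos(theta))`.
#'
#' @param mesh A `tet_mesh`.
#' @param montage An [electrode_montage()].
#' @param area_tol Maximum tolerated relative mismatch between the tagged
#'   patch area and the requested pad area (default 5%); raise only for
#'   deliberately under-resolved meshes.
#' @return The mesh with `patch` set to 1 (anode) / 2 (cathode) on the
#'   selected boundary triangles, plus `montage` attached.
#' @export
place_electrodes <- function(mesh, montage, area_tol = 0.05) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(montage, "electrode_montage"))
  target_mm2 <- montage$cap_area_cm2 * 100
  tc <- (mesh$nodes[mesh$boundary_tri[, 1], ] +
           mesh$nodes[mesh$boundary_tri[, 2], ] +
           mesh$nodes[mesh$boundary_tri[, 3], ]) / 3
  tcn <- tc / sqrt(rowSums(tc^2))
  areas <- triangle_areas(mesh$nodes, mesh$boundary_tri)
  patch <- integer(nrow(mesh$boundary_tri))
  for (p in 1:2) {
    ang <- acos(pmin(1, pmax(-1, tcn %*% montage$directions[p, ])))
    ord <- order(ang)
    cum <- cumsum(areas[ord])
    k <- which.min(abs(cum - target_mm2))
    sel <- ord[seq_len(k)]
    if (length(sel) == 0)
      stop("resolution error: electrode cap smaller than mesh resolution")
    if (any(patch[sel] != 0))
      stop("electrode patches overlap; montage caps must be disjoint")
    achieved <- cum[k]
    if (abs(achieved - target_mm2) / target_mm2 > area_tol)
      stop(sprintf(paste0("resolution error: achievable patch area %.1f mm^2 ",
                          "misses the %.1f mm^2 cap by more than %.0f%%"),
                   achieved, target_mm2, 100 * area_tol))
    patch[sel] <- p
  }
  mesh$patch <- patch
  mesh$montage <- montage
  mesh
}

#' Mid-layer surface of the gray-matter shell
#'
#' The cortical mid-layer analogue: an icosphere at radius
#' `(r_gm + r_wm) / 2`, the mid-depth of the GM shell, where the field
#' magnitude is evaluated.
#'
#' @param spec A [phantom_spec()].
#' @param n_subdivisions Icosphere subdivision level (>= 4 keeps the
#'   surface area within 1% of the true sphere).
#' @return Object of class `tri_surface` with `vertices`, `faces` and an
#'   empty `channels` list for per-vertex scalars.
#' @export
make_midlayer_surface <- function(spec, n_subdivisions = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  r_gm <- spec$shell_radii[["gm"]]; r_wm <- spec$shell_radii[["wm"]]
  if (r_gm - r_wm <= 0) stop("geometry error: GM shell has zero thickness")
  r_mid <- (r_gm + r_wm) / 2
  ico <- icosphere(n_subdivisions)
  structure(list(vertices = ico$vertices * r_mid, faces = ico$faces,
                 radius = r_mid, channels = list()),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("Triangulated surface: %d vertices, %d faces",
              nrow(x$vertices), nrow(x$faces)))
  if (length(x$channels)) cat("; channels:", paste(names(x$channels), collapse = ", "))
  cat("\n")
  invisible(x)
}
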