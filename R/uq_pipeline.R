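# Per-phantom ("subject") uncertainty analysis, end to end: phantom ->
# mesh -> electrodes -> adaptive gPC of |E| over the uncertain tissue
# conductivities -> per-point mean/variance/Sobol indices on the cortical
# mid-layer, in deep ROIs, and along the electrode-to-electrode sampling
# line -> spatial ROI averages.  The surrogate is built only at the
# mid-layer vertices and ROI/line elements, not over the whole head.

#' Define the regions of interest of a phantom
#'
#' Surface ROIs on the mid-layer: the whole surface and the caps under
#' each electrode (subtending the electrode's angular radius).  Volume
#' ROIs: two 10 mm spheres at lateral offsets deep inside the white
#' matter, geometric stand-ins for subcortical structures.
#'
#' @param spec A [phantom_spec()].
#' @param mesh A `tet_mesh` with electrodes placed.
#' @param montage The [electrode_montage()] used.
#' @param surface The mid-layer `tri_surface`.
#' @param deep_offset_mm,deep_radius_mm Centre offset (along +/- x) and
#'   radius of the deep ROI spheres.
#' @return Object of class `roi_set`: `surface_rois` (named vertex-index
#'   lists) and `volume_rois` (named element-index lists).
#' @export
define_rois <- function(spec, mesh, montage, surface,
                        deep_offset_mm = 35, deep_radius_mm = 10) {
  r_skin <- spec$shell_radii[["skin"]]
  theta <- acos(1 - montage$cap_area_cm2 * 100 / (2 * pi * r_skin^2))
  vdir <- surface$vertices / sqrt(rowSums(surface$vertices^2))
  surface_rois <- list(whole_surface = seq_len(nrow(surface$vertices)))
  for (p in 1:2) {
    ang <- acos(pmin(1, pmax(-1, vdir %*% montage$directions[p, ])))
    surface_rois[[c("under_anode", "under_cathode")[p]]] <- which(ang <= theta)
  }
  ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  volume_rois <- list()
  for (side in c(1, -1)) {
    cc <- c(side * deep_offset_mm, 0, 0)
    sel <- which(sqrt(rowSums(sweep(ctr, 2, cc)^2)) <= deep_radius_mm)
    if (!all(mesh$label[sel] %in% c("WM", "WML")))
      stop("geometry error: deep ROI extends outside the white matter")
    volume_rois[[if (side > 0) "deep_right" else "deep_left"]] <- sel
  }
  if (any(vapply(c(surface_rois, volume_rois), length, integer(1)) == 0))
    stop("empty ROI")
  structure(list(surface_rois = surface_rois, volume_rois = volume_rois,
                 cap_theta_rad = theta),
            class = "roi_set")
}

# locate the tetrahedra containing each query point (NA if outside);
# candidate elements are screened by centroid distance
.locate_elements <- function(mesh, pts, n_candidates = 80, tol = 1e-8) {
  ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  out <- rep(NA_integer_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    d2 <- (ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 + (ctr[, 3] - p[3])^2
    for (e in order(d2)[seq_len(min(n_candidates, length(d2)))]) {
      v <- mesh$elems[e, ]
      M <- t(mesh$nodes[v[2:4], ]) - mesh$nodes[v[1], ]
      bc <- tryCatch(solve(M, p - mesh$nodes[v[1], ]), error = function(err) NULL)
      if (is.null(bc)) next
      l <- c(1 - sum(bc), bc)
      if (all(l >= -tol)) { out[i] <- e; break }
    }
  }
  out
}

#' Sample points along the electrode-to-electrode line
#'
#' Equally spaced samples on the chord between the two electrode patch
#' centres; each sample is attributed to its enclosing element (missing
#' if it falls outside the mesh, e.g. inside an air cavity).
#'
#' @param mesh A `tet_mesh` with electrodes placed.
#' @param n_points Number of samples.
#' @return Data frame: `s_mm` (arclength from the anode), `x`, `y`, `z`,
#'   `element` (NA outside), `label`.
#' @export
sample_line <- function(mesh, n_points = 100) {
  if (!any(mesh$patch == 1)) stop("electrodes not placed")
  areas <- triangle_areas(mesh$nodes, mesh$boundary_tri)
  ends <- lapply(1:2, function(p) {
    sel <- mesh$patch == p
    tc <- (mesh$nodes[mesh$boundary_tri[sel, 1], , drop = FALSE] +
             mesh$nodes[mesh$boundary_tri[sel, 2], , drop = FALSE] +
             mesh$nodes[mesh$boundary_tri[sel, 3], , drop = FALSE]) / 3
    colSums(tc * areas[sel]) / sum(areas[sel])
  })
  tt <- seq(0, 1, length.out = n_points)
  pts <- outer(1 - tt, ends[[1]]) + outer(tt, ends[[2]])
  el <- .locate_elements(mesh, pts)
  data.frame(s_mm = tt * sqrt(sum((ends[[2]] - ends[[1]])^2)),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             element = el,
             label = ifelse(is.na(el), NA_character_, mesh$label[el]),
             stringsAsFactors = FALSE)
}

#' Run the uncertainty analysis of one phantom
#'
#' Builds the phantom, runs the adaptive gPC expansion of the electric
#' field magnitude (scaled to the target injected current) over the
#' uncertain conductivities, and decomposes the per-point variance into
#' Sobol indices.  For a lesion-free phantom the WML input dimension is
#' dropped automatically.
#'
#' @param spec A [phantom_spec()].
#' @param montage An [electrode_montage()].
#' @param dists An [input_distribution()]; rows whose tissue does not
#'   occur in the mesh are dropped (with all-tissue defaults this handles
#'   the lesion-free case).
#' @param target_current_A Injected current (default 2 mA).
#' @param target_edge_mm,n_subdiv,midlayer_subdiv Mesh / mid-layer
#'   resolution (see [mesh_phantom()], [make_midlayer_surface()]).
#' @param n_line_points Samples on the electrode-to-electrode line (0
#'   disables the line profile).
#' @param gpc_opts List of [adaptive_expand()] settings
#'   (`residual_tol`, `max_order`, `oversampling`, `n_add`, `max_evals`,
#'   `n_validation`).
#' @param seed Master seed (lesion placement and every gPC sampling
#'   stream derive from it); defaults to the spec seed.
#' @param area_tol Electrode patch area tolerance (see
#'   [place_electrodes()]).
#' @return Object of class `subject_uq_result`; see the fields
#'   `surface` (mid-layer with `mean`, `var`, `sobol_<tissue>`,
#'   `sobol_interactions` channels), `roi_elements`, `line`, `rois`,
#'   `model`, `provenance`.
#' @export
run_subject <- function(spec, montage = electrode_montage(),
                        dists = default_conductivity_uncertainty(),
                        target_current_A = 2e-3,
                        target_edge_mm = 20, n_subdiv = 3,
                        midlayer_subdiv = 3, n_line_points = 100,
                        gpc_opts = list(), seed = spec$seed,
                        area_tol = 0.05) {
  lesions <- sample_lesions(spec, seed = derive_seed(seed, 11L))
  mesh <- mesh_phantom(spec, lesions, target_edge_mm = target_edge_mm,
                       n_subdiv = n_subdiv)
  mesh <- place_electrodes(mesh, montage, area_tol = area_tol)
  surface <- make_midlayer_surface(spec, midlayer_subdiv)
  rois <- define_rois(spec, mesh, montage, surface)

  present <- unique(mesh$label)
  dists <- dists[dists$tissue %in% present, ]
  class(dists) <- c("input_distribution", "data.frame")
  uncovered <- setdiff(present, c(dists$tissue, "AIR"))
  if (length(uncovered))
    stop("no input distribution for tissues: ", paste(uncovered, collapse = ", "))

  fem <- precompute_fem(mesh)
  iw <- surface_interp_weights(mesh, surface)
  roi_elems <- unique(unlist(rois$volume_rois, use.names = FALSE))
  line <- if (n_line_points > 0) sample_line(mesh, n_line_points) else NULL
  # surrogate values along the line are restricted to the intracranial
  # compartment (the field at skin/skull is outside the expansion domain)
  intracranial <- c("CSF", "GM", "WM", "WML")
  line_elems <- if (is.null(line)) integer(0) else
    unique(line$element[!is.na(line$element) & line$label %in% intracranial])
  extra_elems <- unique(c(roi_elems, line_elems))

  n_surf <- nrow(surface$vertices)
  model_fn <- function(xi) {
    sigma <- conductivity_assignment(stats::setNames(xi, dists$tissue))
    phi <- solve_potential(NULL, sigma, 1, -1, fem = fem)
    fld <- compute_field(phi, NULL, fem = fem)
    sc <- scale_to_current(fld, phi, NULL, sigma, target_current_A, fem = fem)
    c(interpolate_to_surface(sc$solution, NULL, surface, weights = iw),
      sc$solution$magnitude[extra_elems])
  }
  go <- utils::modifyList(list(residual_tol = 1e-3, max_order = 3,
                               oversampling = 2, n_add = 2,
                               max_evals = 96, max_coefficients = 64,
                               n_validation = 10), gpc_opts)
  model <- adaptive_expand(model_fn, dists,
                           residual_tol = go$residual_tol,
                           max_order = go$max_order,
                           oversampling = go$oversampling,
                           n_add = go$n_add, max_evals = go$max_evals,
                           max_coefficients = go$max_coefficients,
                           n_validation = go$n_validation,
                           seed = derive_seed(seed, 22L))
  mom <- surrogate_moments(model)
  sob <- sobol_decomposition(model)

  s_idx <- seq_len(n_surf)
  surface$channels <- c(
    list(mean = mom$mean[s_idx], var = mom$variance[s_idx]),
    stats::setNames(lapply(seq_len(nrow(dists)), function(i)
      sob$first_order[i, s_idx]), paste0("sobol_", dists$tissue)),
    list(sobol_interactions = sob$interactions[s_idx])
  )
  elem_block <- function(ids) {
    pos <- n_surf + match(ids, extra_elems)
    ctr <- (mesh$nodes[mesh$elems[ids, 1], , drop = FALSE] +
              mesh$nodes[mesh$elems[ids, 2], , drop = FALSE] +
              mesh$nodes[mesh$elems[ids, 3], , drop = FALSE] +
              mesh$nodes[mesh$elems[ids, 4], , drop = FALSE]) / 4
    df <- data.frame(element = ids, x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                     label = mesh$label[ids],
                     mean = mom$mean[pos], var = mom$variance[pos],
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(dists)))
      df[[paste0("sobol_", dists$tissue[i])]] <- sob$first_order[i, pos]
    df$sobol_interactions <- sob$interactions[pos]
    df
  }
  roi_df <- NULL
  for (rn in names(rois$volume_rois)) {
    blk <- elem_block(rois$volume_rois[[rn]])
    blk$roi <- rn
    roi_df <- rbind(roi_df, blk)
  }
  line_df <- NULL
  if (!is.null(line)) {
    line_df <- line
    for (cn in c("mean", "var", paste0("sobol_", dists$tissue),
                 "sobol_interactions"))
      line_df[[cn]] <- NA_real_
    found <- !is.na(line$element) & line$label %in% intracranial
    blk <- elem_block(line$element[found])
    for (cn in c("mean", "var", paste0("sobol_", dists$tissue),
                 "sobol_interactions"))
      line_df[[cn]][found] <- blk[[cn]]
    # lesion-free phantoms carry no WML columns at all (kept honest for
    # downstream group statistics)
  }
  structure(list(
    surface = surface, roi_elements = roi_df, line = line_df,
    rois = rois, mesh = mesh, model = model, dists = dists,
    expansion = list(n_surface = n_surf, elements = extra_elems,
                     target_current_A = target_current_A),
    provenance = list(
      spec = spec, montage = montage$name, seed = seed,
      lesion_fraction = lesions$realized_fraction,
      n_model_evals = model$n_model_evals,
      loocv_error = model$loocv_error,
      validation_error = model$validation_error,
      n_elements = nrow(mesh$elems),
      gpc = go, target_current_A = target_current_A)
  ), class = "subject_uq_result")
}

#' @export
print.subject_uq_result <- function(x, ...) {
  cat(sprintf("Subject UQ result (%s montage, lesion fraction %.4g)\n",
              x$provenance$montage, x$provenance$lesion_fraction))
  cat(sprintf("  mesh: %d elements; surrogate: %d forward solves, LOOCV %.3g\n",
              x$provenance$n_elements, x$provenance$n_model_evals,
              x$provenance$loocv_error))
  invisible(x)
}

#' Hold-out validation error of a subject surrogate
#'
#' Draws fresh conductivity samples, re-runs the direct forward solver on
#' the subject's mesh, and reports the surrogate's average relative error
#' (see [validation_error()]), optionally restricted to the mid-layer
#' vertices.
#'
#' @param result A [run_subject()] result.
#' @param n_val Number of fresh validation draws.
#' @param seed Seed for the validation draws (defaults to a fresh stream
#'   derived from the subject's master seed).
#' @param points `"midlayer"` (default) averages over mid-layer vertices
#'   only; `"all"` over every expansion point.
#' @return List with `mean`, `sd`, `per_draw`, `n_val`.
#' @export
holdout_error <- function(result, n_val = 25,
                          seed = derive_seed(result$provenance$seed, 44L),
                          points = c("midlayer", "all")) {
  points <- match.arg(points)
  mesh <- result$mesh
  dists <- result$dists
  fem <- precompute_fem(mesh)
  iw <- surface_interp_weights(mesh, result$surface)
  extra <- result$expansion$elements
  target <- result$expansion$target_current_A
  model_fn <- function(xi) {
    sigma <- conductivity_assignment(stats::setNames(xi, dists$tissue))
    phi <- solve_potential(NULL, sigma, 1, -1, fem = fem)
    fld <- compute_field(phi, NULL, fem = fem)
    sc <- scale_to_current(fld, phi, NULL, sigma, target, fem = fem)
    c(interpolate_to_surface(sc$solution, NULL, result$surface, weights = iw),
      sc$solution$magnitude[extra])
  }
  idx <- if (points == "midlayer") seq_len(result$expansion$n_surface) else NULL
  validation_error(result$model, model_fn, n_val = n_val, seed = seed,
                   points = idx)
}

#' Spatially averaged ROI summaries
#'
#' Area-weighted averages over mid-layer vertex ROIs and volume-weighted
#' averages over element ROIs, for the mean field magnitude, its variance
#' and every Sobol channel.
#'
#' @param result A [run_subject()] result.
#' @param rois A `roi_set` (defaults to the one stored in the result).
#' @return Tidy data frame: `roi`, `metric` (`mean_E`, `var_E`,
#'   `sobol`), `tissue` (NA except for Sobol rows), `value`, `units`.
#' @export
spatial_average <- function(result, rois = result$rois) {
  surf <- result$surface
  tri_a <- triangle_areas(surf$vertices, surf$faces)
  va <- numeric(nrow(surf$vertices))
  for (j in 1:3) {
    agg <- tapply(rep(tri_a / 3, 1), surf$faces[, j], sum)
    va[as.integer(names(agg))] <- va[as.integer(names(agg))] + agg
  }
  tissues <- result$dists$tissue
  rows <- list()
  add <- function(roi, metric, tissue, value, units)
    rows[[length(rows) + 1]] <<- data.frame(roi = roi, metric = metric,
                                            tissue = tissue, value = value,
                                            units = units,
                                            stringsAsFactors = FALSE)
  for (rn in names(rois$surface_rois)) {
    sel <- rois$surface_rois[[rn]]
    if (length(sel) == 0) stop("empty ROI: ", rn)
    w <- va[sel] / sum(va[sel])
    add(rn, "mean_E", NA, sum(w * surf$channels$mean[sel]), "V/m")
    add(rn, "var_E", NA, sum(w * surf$channels$var[sel]), "(V/m)^2")
    for (t in tissues)
      add(rn, "sobol", t, sum(w * surf$channels[[paste0("sobol_", t)]][sel]),
          "dimensionless")
    add(rn, "sobol", "interactions",
        sum(w * surf$channels$sobol_interactions[sel]), "dimensionless")
  }
  for (rn in names(rois$volume_rois)) {
    blk <- result$roi_elements[result$roi_elements$roi == rn, ]
    if (nrow(blk) == 0) stop("empty ROI: ", rn)
    w <- result$mesh$volumes[blk$element]
    w <- w / sum(w)
    add(rn, "mean_E", NA, sum(w * blk$mean), "V/m")
    add(rn, "var_E", NA, sum(w * blk$var), "(V/m)^2")
    for (t in tissues)
      add(rn, "sobol", t, sum(w * blk[[paste0("sobol_", t)]]), "dimensionless")
    add(rn, "sobol", "interactions", sum(w * blk$sobol_interactions),
        "dimensionless")
  }
  do.call(rbind, rows)
}

#' Line profile of a subject result
#'
#' @param result A [run_subject()] result computed with
#'   `n_line_points > 0`.
#' @return The electrode-to-electrode profile data frame (arclength,
#'   position, tissue label, mean/var/Sobol values).
#' @export
line_profile <- function(result) {
  if (is.null(result$line)) stop("result was computed without a line profile")
  result$line
}

#' Run a lesion-load group study
#'
#' Generates `n_per_group` phantoms per lesion-load level (different
#' lesion seeds), runs the subject-level uncertainty analysis on each,
#' and stacks the ROI summaries into one tidy table suitable for the
#' group statistics stage.
#'
#' @param loads Lesion-load fractions per group (defaults to the
#'   absent/low/medium/high group means 0, 0.0072, 0.0211, 0.0894).
#' @param n_per_group Phantoms per load level.
#' @param montage An [electrode_montage()].
#' @param seed Master seed.
#' @param ... Further arguments passed to [run_subject()] (resolution,
#'   `gpc_opts`, ...).
#' @return List: `summaries` (tidy data frame with `subject`, `group`,
#'   `montage` prepended to the [spatial_average()] columns) and
#'   `subjects` (per-subject provenance list).
#' @export
run_group <- function(loads = c(0, 0.0072, 0.0211, 0.0894), n_per_group = 3,
                      montage = electrode_montage(), seed = 1, ...) {
  summaries <- NULL; subjects <- list()
  sid <- 0
  for (g in seq_along(loads)) {
    for (r in seq_len(n_per_group)) {
      sid <- sid + 1
      sseed <- derive_seed(seed, 1000L * g + r)
      spec <- phantom_spec(lesion_target_fraction = loads[g], seed = sseed)
      res <- run_subject(spec, montage = montage, seed = sseed, ...)
      sm <- spatial_average(res)
      sm <- cbind(data.frame(subject = sid, group = sprintf("load_%g", loads[g]),
                             montage = montage$name, stringsAsFactors = FALSE), sm)
      summaries <- rbind(summaries, sm)
      subjects[[sid]] <- res$provenance
    }
  }
  list(summaries = summaries, subjects = subjects)
}
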