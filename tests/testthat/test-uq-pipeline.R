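# Subject-level pipeline: ROI definitions, the end-to-end uncertainty
# run, spatial averaging and the electrode-to-electrode profile.

test_that("ROI definitions follow the montage and stay inside tissue", {
  fx <- fx_coarse()
  surf <- make_midlayer_surface(fx$spec, 2)
  rois <- define_rois(fx$spec, fx$mesh, fx$mesh$montage, surf)
  expect_identical(length(rois$surface_rois$whole_surface),
                   nrow(surf$vertices))
  # the vertex closest to the anode direction lies in the under-anode cap
  vdir <- surf$vertices / sqrt(rowSums(surf$vertices^2))
  closest <- which.max(vdir %*% fx$mesh$montage$directions[1, ])
  expect_true(closest %in% rois$surface_rois$under_anode)
  for (rn in c("deep_left", "deep_right")) {
    sel <- rois$volume_rois[[rn]]
    expect_gt(length(sel), 0)
    expect_true(all(fx$mesh$label[sel] %in% c("WM", "WML")))
  }
  # a deep ROI pushed outside the white matter is rejected
  expect_error(define_rois(fx$spec, fx$mesh, fx$mesh$montage, surf,
                           deep_offset_mm = 75), "geometry error")
})

test_that("the subject run produces coherent uncertainty maps", {
  res <- fx_subject()
  surf <- res$surface
  n <- nrow(surf$vertices)
  expect_length(surf$channels$mean, n)
  expect_true(all(surf$channels$mean > 0))
  expect_true(all(surf$channels$var >= 0))
  # Sobol channels sum to one wherever the variance is positive
  tot <- Reduce(`+`, surf$channels[c(paste0("sobol_", res$dists$tissue),
                                     "sobol_interactions")])
  expect_equal(tot, rep(1, n), tolerance = 1e-6)
  # provenance records the protocol budget
  expect_lte(res$provenance$n_model_evals, 96)
  expect_lte(res$model$n_coefficients_raw, 64)
  # mean(|E|) is close to the field of a single solve at the distribution
  # medians (approximate: mean(q(xi)) != q(median xi) exactly)
  fem <- precompute_fem(res$mesh)
  med <- (res$dists$lo + res$dists$hi) / 2
  sig <- conductivity_assignment(stats::setNames(med, res$dists$tissue))
  phi <- solve_potential(NULL, sig, 1, -1, fem = fem)
  fld <- compute_field(phi, NULL, fem = fem)
  sc <- scale_to_current(fld, phi, NULL, sig, 2e-3, fem = fem)
  iw <- surface_interp_weights(res$mesh, surf)
  direct <- interpolate_to_surface(sc$solution, NULL, surf, weights = iw)
  expect_lt(max(abs(surf$channels$mean - direct) / direct), 0.05)
})

test_that("degenerate (near-point) input distributions yield zero variance", {
  dists <- default_conductivity_uncertainty()
  eps <- 1e-9
  tight <- input_distribution(dists$tissue, lo = (dists$lo + dists$hi) / 2,
                              hi = (dists$lo + dists$hi) / 2 + eps)
  res <- run_subject(fx_spec_f3(), dists = tight, target_edge_mm = 24,
                     n_subdiv = 2, midlayer_subdiv = 2, n_line_points = 0,
                     gpc_opts = list(n_validation = 0), seed = 3)
  expect_lt(max(res$surface$channels$var / res$surface$channels$mean^2),
            1e-12)
})

test_that("lesion-free phantoms drop the WML input dimension", {
  spec <- phantom_spec(lesion_target_fraction = 0, seed = 7)
  res <- run_subject(spec, target_edge_mm = 24, n_subdiv = 2,
                     midlayer_subdiv = 2, n_line_points = 40,
                     gpc_opts = list(n_validation = 0), seed = 7)
  expect_false("WML" %in% res$dists$tissue)
  expect_false("sobol_WML" %in% names(res$surface$channels))
  expect_false("sobol_WML" %in% names(res$line))
})

test_that("spatial averages are correct weighted means", {
  res <- fx_subject()
  sm <- spatial_average(res)
  expect_true(all(c("roi", "metric", "tissue", "value", "units") %in%
                    names(sm)))
  # averages stay inside the range of the member values
  ws <- res$rois$surface_rois$whole_surface
  mrow <- sm[sm$roi == "whole_surface" & sm$metric == "mean_E", "value"]
  expect_gte(mrow, min(res$surface$channels$mean[ws]))
  expect_lte(mrow, max(res$surface$channels$mean[ws]))
  # constant channels average to the constant in every ROI
  cres <- res
  for (ch in names(cres$surface$channels))
    cres$surface$channels[[ch]] <- rep(2, length(cres$surface$channels[[ch]]))
  num <- vapply(cres$roi_elements, is.numeric, logical(1))
  cres$roi_elements[num] <- 2
  cres$roi_elements$element <- res$roi_elements$element
  smc <- spatial_average(cres)
  expect_equal(smc$value, rep(2, nrow(smc)), tolerance = 1e-12)
})

test_that("a hand-built two-triangle surface averages by area weights", {
  # triangle 1: area 0.5 around vertices 1-3; triangle 2: area 1 (scaled)
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 2, 0))
  faces <- rbind(c(1, 2, 3), c(2, 4, 3))
  vals <- c(1, 2, 3, 4)
  a <- triangle_areas(verts, faces)
  # vertex weights: one third of each adjacent triangle's area
  w <- numeric(4)
  for (f in 1:2) for (j in 1:3) w[faces[f, j]] <- w[faces[f, j]] + a[f] / 3
  hand <- sum(w * vals) / sum(w)
  surf <- structure(list(vertices = verts, faces = faces,
                         channels = list(mean = vals, var = vals * 0,
                                         sobol_interactions = vals * 0)),
                    class = "tri_surface")
  fake <- list(surface = surf,
               rois = structure(list(surface_rois = list(whole_surface = 1:4),
                                     volume_rois = list()),
                                class = "roi_set"),
               dists = input_distribution(character(0), numeric(0),
                                          numeric(0)),
               roi_elements = NULL, mesh = NULL)
  sm <- spatial_average(fake, fake$rois)
  expect_equal(sm[sm$metric == "mean_E", "value"], hand, tolerance = 1e-12)
})

test_that("the sampling line runs anode to cathode through the shells", {
  res <- fx_subject()
  lp <- line_profile(res)
  mesh <- res$mesh
  # arclength spans the inter-electrode chord
  spacing <- diff(lp$s_mm[1:2])
  areas <- triangle_areas(mesh$nodes, mesh$boundary_tri)
  ends <- lapply(1:2, function(p) {
    sel <- mesh$patch == p
    tc <- (mesh$nodes[mesh$boundary_tri[sel, 1], , drop = FALSE] +
             mesh$nodes[mesh$boundary_tri[sel, 2], , drop = FALSE] +
             mesh$nodes[mesh$boundary_tri[sel, 3], , drop = FALSE]) / 3
    colSums(tc * areas[sel]) / sum(areas[sel])
  })
  chord <- sqrt(sum((ends[[2]] - ends[[1]])^2))
  expect_lt(abs(lp$s_mm[nrow(lp)] - chord), spacing)
  # tissue order along the line follows the shell structure (the thin CSF
  # shell can fall between samples at this spacing; lesions interleave WM)
  seq_labels <- rle(lp$label[!is.na(lp$label)])$values
  core <- seq_labels[!seq_labels %in% c("WML", "CSF")]
  expect_identical(core[1:4], c("SKIN", "SKULL", "GM", "WM"))
  expect_identical(rev(core)[1:3], c("SKIN", "SKULL", "GM"))
  # intracranial samples carry surrogate values, extracranial do not
  intra <- lp$label %in% c("CSF", "GM", "WM", "WML")
  expect_true(all(is.finite(lp$mean[intra])))
  expect_true(all(is.na(lp$mean[!intra])))
  # Sobol rows along the line sum to one where defined
  sob <- lp[intra, grep("^sobol_", names(lp))]
  expect_equal(unname(rowSums(sob)), rep(1, sum(intra)), tolerance = 1e-6)
})

test_that("WML influence along the line is localized near lesions", {
  res <- fx_subject()
  lp <- line_profile(res)
  les <- res$provenance
  lesions <- sample_lesions(res$provenance$spec,
                            seed = tesuq:::derive_seed(res$provenance$seed, 11L))
  ok <- !is.na(lp$sobol_WML)
  pts <- as.matrix(lp[ok, c("x", "y", "z")])
  dmin <- vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt(rowSums(sweep(lesions$centers, 2, pts[i, ])^2)) - lesions$radii
    min(d)
  }, numeric(1))
  s <- lp$sobol_WML[ok]
  near <- dmin <= 10; far <- dmin > 20
  if (any(near) && any(far))
    expect_gt(mean(s[near]), mean(s[far]))
  # the largest WML contribution occurs close to lesioned tissue
  expect_lte(dmin[which.max(s)], 10)
})

test_that("identical seeds reproduce the subject analysis bit for bit", {
  spec <- phantom_spec(lesion_target_fraction = 0.0211, seed = 21)
  args <- list(spec, target_edge_mm = 24, n_subdiv = 2, midlayer_subdiv = 2,
               n_line_points = 0, gpc_opts = list(n_validation = 0),
               seed = 21)
  r1 <- do.call(run_subject, args)
  r2 <- do.call(run_subject, args)
  expect_identical(spatial_average(r1), spatial_average(r2))
  expect_identical(r1$model$coefficients, r2$model$coefficients)
})

test_that("run_group stacks labelled subject summaries", {
  g <- run_group(loads = c(0, 0.0894), n_per_group = 1, seed = 9,
                 target_edge_mm = 24, n_subdiv = 2, midlayer_subdiv = 2,
                 n_line_points = 0, gpc_opts = list(n_validation = 0))
  expect_setequal(unique(g$summaries$group), c("load_0", "load_0.0894"))
  expect_true(all(c("subject", "group", "montage", "roi", "metric",
                    "tissue", "value", "units") %in% names(g$summaries)))
  expect_length(g$subjects, 2)
  expect_identical(unique(g$summaries$montage), "bihemispheric_analogue")
})

test_that("whole-surface WML contribution grows with lesion load", {
  g <- fx_group()
  wml <- g[g$roi == "whole_surface" & g$metric == "sobol" &
             !is.na(g$tissue) & g$tissue == "WML", ]
  means <- tapply(wml$value, wml$load, mean)
  loads <- as.numeric(names(means))
  expect_true(all(diff(means[order(loads)]) > 0))
  # lesion-free phantoms contribute no WML dimension at all
  expect_false(0 %in% wml$load)
  # on low-load phantoms the WML index is on average the smallest tissue share
  low <- g[g$roi == "whole_surface" & g$metric == "sobol" &
             !is.na(g$tissue) & g$tissue != "interactions" & g$load == 0.0072, ]
  tissue_means <- tapply(low$value, low$tissue, mean)
  expect_identical(names(which.min(tissue_means)), "WML")
})
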