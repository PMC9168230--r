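# Shared, lazily built fixtures.  Everything is generated in code from
# seeded generators; the expensive objects (meshes, FEM systems, full
# subject runs) are cached across test files.

.fx <- new.env(parent = emptyenv())

# run code under a fixed seed without disturbing the suite's RNG state
with_seed_for_tests <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# high-lesion-load spec used throughout
fx_spec_f3 <- function(seed = 3) {
  phantom_spec(lesion_target_fraction = 0.0894, seed = seed)
}

# coarse lesioned mesh + FEM system (level-2 icosphere, ~6k tets)
fx_coarse <- function() {
  if (is.null(.fx$coarse)) {
    spec <- fx_spec_f3()
    les <- sample_lesions(spec, seed = 5)
    mesh <- place_electrodes(mesh_phantom(spec, les, target_edge_mm = 24,
                                          n_subdiv = 2),
                             electrode_montage())
    .fx$coarse <- list(spec = spec, lesions = les, mesh = mesh,
                       fem = precompute_fem(mesh))
  }
  .fx$coarse
}

# default-resolution lesion-free phantom with small (point-like) caps,
# used for the analytic-oracle comparisons
fx_oracle <- function() {
  if (is.null(.fx$oracle)) {
    spec <- phantom_spec()
    mesh <- place_electrodes(
      mesh_phantom(spec, sample_lesions(spec), target_edge_mm = 20,
                   n_subdiv = 3),
      electrode_montage("bihemispheric_analogue", cap_area_cm2 = 4))
    .fx$oracle <- list(spec = spec, mesh = mesh, fem = precompute_fem(mesh))
  }
  .fx$oracle
}

fx_sigma_uniform <- function(value = 0.3) {
  conductivity_assignment(stats::setNames(rep(value, 6),
                                          c("SKIN", "SKULL", "CSF", "GM",
                                            "WM", "WML")))
}

# full coarse subject run (lesioned, with line profile)
fx_subject <- function() {
  if (is.null(.fx$subject)) {
    .fx$subject <- run_subject(fx_spec_f3(), target_edge_mm = 24,
                               n_subdiv = 2, midlayer_subdiv = 2,
                               n_line_points = 80,
                               gpc_opts = list(n_validation = 0), seed = 3)
  }
  .fx$subject
}

# coarse group study: 4 lesion loads x 3 seeds
fx_group <- function() {
  if (is.null(.fx$group)) {
    loads <- c(0, 0.0072, 0.0211, 0.0894)
    rows <- NULL
    for (g in seq_along(loads)) for (r in 1:3) {
      sseed <- 1000L * g + r
      spec <- phantom_spec(lesion_target_fraction = loads[g], seed = sseed)
      res <- run_subject(spec, target_edge_mm = 24, n_subdiv = 2,
                         midlayer_subdiv = 2, n_line_points = 0,
                         gpc_opts = list(n_validation = 0), seed = sseed)
      sm <- spatial_average(res)
      sm$load <- loads[g]; sm$replicate <- r
      rows <- rbind(rows, sm)
    }
    .fx$group <- rows
  }
  .fx$group
}

# the scaled-down protocol reproduction run shared by several acceptance
# checks: high-load phantom, ~28k tets, adaptive surrogate at residual
# 1e-3 / order 3, plus 25 fresh hold-out draws over mid-layer points
fx_protocol_run <- function() {
  if (is.null(.fx$protocol)) {
    spec <- phantom_spec(lesion_target_fraction = 0.0894, seed = 1)
    res <- run_subject(spec, montage = electrode_montage(),
                       target_edge_mm = 20, n_subdiv = 3,
                       midlayer_subdiv = 3, n_line_points = 0,
                       gpc_opts = list(n_validation = 0), seed = 1)
    ve <- holdout_error(res, n_val = 25, points = "midlayer")
    .fx$protocol <- list(result = res, holdout = ve)
  }
  .fx$protocol
}
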