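# Shared fixtures, built once per test run and memoized. The "study"
# fixtures use the package's default recipes and sensor arrays (the
# conditions the Monte Carlo acceptance checks are defined on); the "tiny"
# fixtures are fast small-scale geometries for unit tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_sheet <- function() fixture("tiny_sheet", function() {
  rec <- surface_recipe("cortex-like", folia_amplitude = 0,
                        lobule_wavelength = 20, lobule_amplitude = 5,
                        cap_angular_radius = 20, base_radius = 70,
                        edge_length = 2, seed = 3)
  generate_folded_sheet(rec, max_radius = 80)
})

flat_cap <- function() fixture("flat_cap", function() {
  rec <- surface_recipe("cortex-like", folia_amplitude = 0,
                        lobule_amplitude = 0, cap_angular_radius = 20,
                        base_radius = 70, edge_length = 2, seed = 1)
  generate_folded_sheet(rec)
})

small_arrays <- function() fixture("small_arrays", function() {
  combine_arrays(generate_helmet_array(n_sites = 24),
                 generate_electrode_array(n_electrodes = 24))
})

study_arrays <- function() fixture("study_arrays", function() {
  combine_arrays(generate_helmet_array(), generate_electrode_array())
})

tiny_gain <- function() fixture("tiny_gain", function() {
  src <- source_space(tiny_sheet(), boundary = head_model())
  list(src = src, gain = compute_gain(src, small_arrays()))
})

# full study-condition cortex-like surface and gain (shared by the
# distributed and coherent acceptance checks)
study_cortex <- function() fixture("study_cortex", function() {
  mesh <- generate_folded_sheet(default_recipes(1)[["cortex-like"]],
                                max_radius = 80)
  src <- source_space(mesh, boundary = head_model(), min_dist = 5)
  list(mesh = mesh, src = src, gain = compute_gain(src, study_arrays()))
})

study_cerebellum <- function() fixture("study_cerebellum", function() {
  mesh <- generate_folded_sheet(default_recipes(1)[["cerebellum-like"]],
                                max_radius = 80)
  src <- source_space(mesh, target_count = 10000,
                      boundary = head_model(), min_dist = 5)
  list(mesh = mesh, src = src, gain = compute_gain(src, study_arrays()))
})

study_smoothed <- function() fixture("study_smoothed", function() {
  mesh <- generate_folded_sheet(default_recipes(1)[["smoothed-shell"]],
                                max_radius = 80)
  src <- source_space(mesh, boundary = head_model(), min_dist = 5)
  list(mesh = mesh, src = src, gain = compute_gain(src, study_arrays()))
})

# fine cerebellar mesh for the decimation/grid-density convergence studies
# (edge length = folia_wavelength / 20 over a small cap)
fine_cerebellum_study <- function() fixture("fine_cb", function() {
  rec <- surface_recipe("cerebellum-like", folia_wavelength = 2,
                        folia_amplitude = 1, lobule_wavelength = 20,
                        lobule_amplitude = 3,
                        cap_center_direction = c(0, -1, -0.6),
                        cap_angular_radius = 10, base_radius = 55,
                        edge_length = 0.1, seed = 1)
  mesh <- generate_folded_sheet(rec, max_radius = 80)
  mags <- generate_helmet_array()
  mags <- sensor_array(mags$channels[mags$channels$type == "magnetometer", ])
  mesh_convergence_study(mesh, mags, fraction = 0.55, n_patches = 20,
                         radius_mm = 10, seed = 11,
                         modalities = "mag")
})

# study-condition Monte Carlo runs shared by several acceptance checks
study_distributed <- function() fixture("study_distributed", function() {
  des <- experiment_design("distributed",
                           n_grid = c(1, 2, 3, 5, 9, 10, 30, 100, 300,
                                      1000, 3000, 10000),
                           samples = 200, seed = 1)
  run_distributed(des, list("cortex-like" = study_cortex()$gain))
})

study_coherent_cortex <- function() fixture("study_coherent_cortex", function() {
  des <- experiment_design("coherent",
                           radius_grid = c(5, 7, 10, 15, 20, 30),
                           samples = 200, seed = 1)
  run_coherent(des, list("cortex-like" = study_cortex()$src),
               list("cortex-like" = study_cortex()$gain))
})

study_coherent_folding <- function() fixture("study_coherent_folding", function() {
  des <- experiment_design("coherent",
                           radius_grid = c(5, 7, 10, 15, 20, 30),
                           samples = 200, seed = 1)
  run_coherent(des,
               list("cerebellum-like" = study_cerebellum()$src,
                    "smoothed-shell" = study_smoothed()$src),
               list("cerebellum-like" = study_cerebellum()$gain,
                    "smoothed-shell" = study_smoothed()$gain))
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
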