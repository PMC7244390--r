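#' Default surface recipes of the simulation study
#'
#' The three standard study surfaces inside an 80 mm inner skull:
#' * `cerebellum-like`: posterior-inferior cap at base radius 55 mm with
#'   2 mm folia (amplitude 1 mm) under 20 mm lobular folds (amplitude 3 mm),
#'   meshed at 0.2 mm so the folia are resolved;
#' * `cortex-like`: superior cap at base radius 70 mm with a single 20 mm
#'   fold scale of 5 mm amplitude, meshed at 1.2 mm;
#' * `smoothed-shell`: the cerebellum-like cap with the folia removed and
#'   the lobular relief reduced to a 1 mm undulation (an outer-shell
#'   segmentation shows barely any sulci), meshed at 0.5 mm.
#'
#' @param seed integer seed controlling the folia phase.
#' @return named list of [surface_recipe()]s.
#' @export
default_recipes <- function(seed = 1L) {
  list(
    "cerebellum-like" = surface_recipe(
      kind = "cerebellum-like", folia_wavelength = 2, folia_amplitude = 1,
      lobule_wavelength = 20, lobule_amplitude = 3,
      cap_center_direction = c(0, -1, -0.6), cap_angular_radius = 25,
      base_radius = 55, edge_length = 0.2, seed = seed),
    "cortex-like" = surface_recipe(
      kind = "cortex-like", folia_wavelength = 2, folia_amplitude = 0,
      lobule_wavelength = 20, lobule_amplitude = 5,
      cap_center_direction = c(0, 0, 1), cap_angular_radius = 60,
      base_radius = 70, edge_length = 1.2, seed = seed),
    "smoothed-shell" = surface_recipe(
      kind = "smoothed-shell", folia_wavelength = 2, folia_amplitude = 0,
      lobule_wavelength = 20, lobule_amplitude = 1,
      cap_center_direction = c(0, -1, -0.6), cap_angular_radius = 25,
      base_radius = 55, edge_length = 0.5, seed = seed))
}

config_schema <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    surfaces = list(name = NULL, kind = NULL, folia_wavelength_mm = NULL,
                    folia_amplitude_mm = NULL, lobule_wavelength_mm = NULL,
                    lobule_amplitude_mm = NULL, cap_center_direction = NULL,
                    cap_angular_radius_deg = NULL, base_radius_mm = NULL,
                    edge_length_mm = NULL, source_decimation = NULL),
    head = list(shell_radii_mm = NULL, conductivities_S_per_m = NULL),
    sensors = list(n_meg_sites = NULL, helmet_radius_mm = NULL,
                   meg_coverage_deg = NULL, gradiometer_baseline_mm = NULL,
                   n_electrodes = NULL, eeg_coverage_deg = NULL,
                   layout_csv = NULL),
    forward = list(method = NULL, isolated_skull = NULL,
                   bem_subdivisions = NULL),
    design = list(samples = NULL, n_grid = NULL, radius_grid_mm = NULL,
                  modalities = NULL),
    constants = list(q0_nAm_per_mm2 = NULL, sensitivity_moment_nAm = NULL,
                     min_dist_mm = NULL))
}

check_config_keys <- function(cfg, schema = config_schema(), path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(schema))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(schema[[k]]) && length(schema[[k]]) && is.list(cfg[[k]])) {
      sub <- cfg[[k]]
      if (k == "surfaces") {
        for (s in sub) check_config_keys(s, schema$surfaces,
                                         paste0(path, "surfaces/"))
      } else {
        check_config_keys(sub, schema[[k]], paste0(path, k, "/"))
      }
    }
  }
  invisible(TRUE)
}

#' Default run configuration
#'
#' Desk-scale defaults mirroring the study conditions: three-shell
#' 80/85/92 mm head at 0.3/0.006/0.3 S/m, 102-site MEG helmet (306
#' channels) plus 72 electrodes, analytic sphere forward model, 5 mm
#' exclusion, 200 Monte Carlo samples, patch radii 1-30 mm, q0 = 1
#' nAm/mm^2, and a 100 nAm sensitivity dipole.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L, out_dir = "cerebsim-results") {
  rec <- default_recipes(seed)
  surfaces <- lapply(names(rec), function(nm) {
    r <- rec[[nm]]
    list(name = nm, kind = r$kind,
         folia_wavelength_mm = r$folia_wavelength,
         folia_amplitude_mm = r$folia_amplitude,
         lobule_wavelength_mm = r$lobule_wavelength,
         lobule_amplitude_mm = r$lobule_amplitude,
         cap_center_direction = r$cap_center_direction,
         cap_angular_radius_deg = r$cap_angular_radius,
         base_radius_mm = r$base_radius,
         edge_length_mm = r$edge_length,
         source_decimation = if (nm == "cerebellum-like") 10000L else NA)
  })
  list(seed = as.integer(seed), out_dir = out_dir,
       surfaces = surfaces,
       head = list(shell_radii_mm = c(80, 85, 92),
                   conductivities_S_per_m = c(0.3, 0.006, 0.3)),
       sensors = list(n_meg_sites = 102L, helmet_radius_mm = 102,
                      meg_coverage_deg = 120,
                      gradiometer_baseline_mm = 16.8,
                      n_electrodes = 72L, eeg_coverage_deg = 135,
                      layout_csv = NA),
       forward = list(method = "sphere_analytic", isolated_skull = TRUE,
                      bem_subdivisions = 3L),
       design = list(samples = 200L,
                     n_grid = c(1, 2, 3, 5, 10, 30, 100, 300, 1000, 3000,
                                10000),
                     radius_grid_mm = c(1, 2, 3, 5, 7, 10, 15, 20, 30),
                     modalities = c("mag", "grad", "eeg")),
       constants = list(q0_nAm_per_mm2 = 1, sensitivity_moment_nAm = 100,
                        min_dist_mm = 5))
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()]
#' values.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg)
  def <- default_config(seed = cfg$seed %||% 1L)
  merge_cfg <- function(d, c) {
    for (k in names(c)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(c[[k]]) && k != "surfaces")
        merge_cfg(d[[k]], c[[k]]) else c[[k]]
    }
    d
  }
  merge_cfg(def, cfg)
}

recipe_from_config <- function(s, seed) {
  surface_recipe(kind = s$kind,
                 folia_wavelength = s$folia_wavelength_mm,
                 folia_amplitude = s$folia_amplitude_mm,
                 lobule_wavelength = s$lobule_wavelength_mm,
                 lobule_amplitude = s$lobule_amplitude_mm,
                 cap_center_direction = unlist(s$cap_center_direction),
                 cap_angular_radius = s$cap_angular_radius_deg,
                 base_radius = s$base_radius_mm,
                 edge_length = s$edge_length_mm,
                 seed = seed)
}

#' Run the full simulation pipeline
#'
#' Stages: synthetic anatomy, sensor synthesis, gain computation (cached on
#' disk by content hash), distributed and coherent Monte Carlo, sensitivity
#' maps, and a tabular report. Identical configuration and seed reproduce
#' identical outputs.
#'
#' @param config configuration list (see [default_config()] /
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return A run manifest (list): config hash, seed, per-stage outputs and
#'   wall-clock seconds; also written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  check_config_keys(config)
  t_start <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage_files <- list()
  stage_time <- list()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    res <- expr
    stage_time[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  head <- head_model(shell_radii = unlist(config$head$shell_radii_mm),
                     conductivities = unlist(config$head$conductivities_S_per_m))
  constants <- physiological_constants(
    q0 = config$constants$q0_nAm_per_mm2 * 1e-3,
    sensitivity_moment = config$constants$sensitivity_moment_nAm * 1e-9)

  say("stage 1/6: synthetic anatomy")
  sources <- timed("anatomy", {
    out <- list()
    for (s in config$surfaces) {
      rec <- recipe_from_config(s, child_seed(config$seed, "anatomy"))
      mesh <- generate_folded_sheet(rec, max_radius = head$shell_radii[1L])
      dec <- s$source_decimation
      dec <- if (is.null(dec) || is.na(dec) || dec >= nrow(mesh$vertices))
        NULL else as.integer(dec)
      src <- source_space(mesh, target_count = dec, boundary = head,
                          min_dist = config$constants$min_dist_mm)
      ply <- file.path(out_dir, paste0("surface_", s$name, ".ply"))
      write_ply(mesh, ply)
      stage_files$anatomy <- c(stage_files$anatomy, ply)
      out[[s$name]] <- src
    }
    out
  })

  say("stage 2/6: sensor arrays")
  sensors <- timed("sensors", {
    if (!is.null(config$sensors$layout_csv) &&
        !is.na(config$sensors$layout_csv)) {
      read_sensor_csv(config$sensors$layout_csv)
    } else {
      meg <- generate_helmet_array(
        n_sites = config$sensors$n_meg_sites,
        helmet_radius = config$sensors$helmet_radius_mm,
        coverage = config$sensors$meg_coverage_deg,
        baseline = config$sensors$gradiometer_baseline_mm,
        scalp_radius = head$shell_radii[3L])
      eeg <- generate_electrode_array(
        n_electrodes = config$sensors$n_electrodes,
        scalp_radius = head$shell_radii[3L],
        coverage = config$sensors$eeg_coverage_deg)
      combine_arrays(meg, eeg)
    }
  })
  sens_csv <- file.path(out_dir, "sensors.csv")
  write_sensor_csv(sensors, sens_csv)
  stage_files$sensors <- sens_csv

  say("stage 3/6: gain matrices")
  engine <- if (config$forward$method == "bem_collocation") {
    meshes <- lapply(head$shell_radii, generate_sphere_shell,
                     subdivisions = config$forward$bem_subdivisions)
    forward_engine("bem_collocation",
                   head_model(head$shell_radii, head$conductivities,
                              boundary_meshes = meshes),
                   isolated_skull = config$forward$isolated_skull)
  } else forward_engine("sphere_analytic", head)
  gains <- timed("gain", {
    out <- list()
    cache_dir <- file.path(out_dir, "cache")
    for (nm in names(sources)) {
      key <- rlang::hash(list(config$surfaces, config$head, config$sensors,
                              config$forward, config$seed, nm))
      cdir <- file.path(cache_dir, paste0("gain_", key))
      if (file.exists(file.path(cdir, "gain_values.rds"))) {
        say("  gain cache hit for ", nm)
        out[[nm]] <- read_gain(cdir)
      } else {
        out[[nm]] <- compute_gain(sources[[nm]], sensors, engine)
        write_gain(out[[nm]], cdir)
      }
      stage_files$gain <- c(stage_files$gain, cdir)
    }
    out
  })

  say("stage 4/6: Monte Carlo (distributed + coherent)")
  des_d <- experiment_design("distributed", n_grid = unlist(config$design$n_grid),
                             samples = config$design$samples,
                             seed = config$seed,
                             modalities = unlist(config$design$modalities))
  des_c <- experiment_design("coherent",
                             radius_grid = unlist(config$design$radius_grid_mm),
                             samples = config$design$samples,
                             seed = config$seed,
                             modalities = unlist(config$design$modalities))
  mc <- timed("monte_carlo", {
    dist <- run_distributed(des_d, gains, constants)
    coh <- run_coherent(des_c, sources, gains, constants)
    list(distributed = dist, coherent = coh)
  })
  stage_files$monte_carlo <- c(write_curves(mc$distributed, out_dir),
                               write_curves(mc$coherent, out_dir))
  norm_files <- character()
  if (all(c("cerebellum-like", "cortex-like") %in% names(sources))) {
    for (mod in unlist(config$design$modalities)) {
      sm <- mc$coherent$samples
      nc <- normalize_to_reference(
        sm[sm$surface == "cerebellum-like" & sm$modality == mod, ],
        sm[sm$surface == "cortex-like" & sm$modality == mod, ],
        unlist(config$design$radius_grid_mm))
      f <- file.path(out_dir, paste0("normalized_", mod, ".csv"))
      utils::write.csv(nc, f, row.names = FALSE)
      norm_files <- c(norm_files, f)
    }
  }
  stage_files$monte_carlo <- c(stage_files$monte_carlo, norm_files)

  say("stage 5/6: sensitivity maps")
  stage_files$sensitivity <- timed("sensitivity", {
    files <- character()
    for (nm in names(gains)) {
      for (mod in unlist(config$design$modalities)) {
        map <- sensitivity_map(gains[[nm]], mod,
                               moment = config$constants$sensitivity_moment_nAm,
                               n_vertices = length(sources[[nm]]$kept))
        f <- file.path(out_dir, sprintf("sensitivity_%s_%s.csv", nm, mod))
        write_vertex_scalar_csv(ifelse(is.na(map$values), -1, map$values), f)
        files <- c(files, f)
      }
    }
    summ <- list()
    if (all(c("cerebellum-like", "cortex-like") %in% names(gains))) {
      for (mod in unlist(config$design$modalities)) {
        mt <- sensitivity_map(gains[["cerebellum-like"]], mod,
                              moment = config$constants$sensitivity_moment_nAm)
        mr <- sensitivity_map(gains[["cortex-like"]], mod,
                              moment = config$constants$sensitivity_moment_nAm)
        h <- norm_histogram(mt, mr)
        summ[[mod]] <- list(median_ratio = h$median_test,
                            exceedance_fraction = h$exceedance_fraction,
                            clip_range = as.numeric(percentile_clip(mt)))
      }
    }
    f <- file.path(out_dir, "sensitivity_summary.json")
    jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA)
    c(files, f)
  })

  manifest <- list(config_hash = rlang::hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("cerebsim")),
                   r_version = R.version.string,
                   stages = stage_files, stage_seconds = stage_time,
                   total_seconds = as.numeric(difftime(Sys.time(), t_start,
                                                       units = "secs")),
                   out_dir = out_dir, config = config)
  say("stage 6/6: report")
  manifest$report <- make_report(manifest)
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Render a tabular report from a completed run
#'
#' Assembles a Markdown report (tabular analogs of the conservation-factor
#' and signal-norm figures) strictly from the CSV outputs of the run; no
#' quantity is recomputed.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return path of the written report, invisibly.
#' @export
make_report <- function(manifest) {
  out_dir <- manifest$out_dir
  need <- c("distributed_summary.csv", "coherent_summary.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  lines <- c("# cerebsim run report", "",
             sprintf("- config hash: `%s`", manifest$config_hash),
             sprintf("- seed: %d", manifest$seed),
             sprintf("- package: cerebsim %s", manifest$package_version), "")
  fmt_tab <- function(df, digits = 4) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], signif, digits)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                       " |")))
  }
  ds <- utils::read.csv(file.path(out_dir, "distributed_summary.csv"))
  cs <- utils::read.csv(file.path(out_dir, "coherent_summary.csv"))
  lines <- c(lines, "## Conservation factor vs number of distributed dipoles",
             "", fmt_tab(ds[c("surface", "modality", "n", "C_mean", "C_sd")]),
             "", "## Conservation factor and signal norms vs patch radius",
             "", fmt_tab(cs[c("surface", "modality", "radius_mm", "C_mean",
                              "C_sd", "alpha_mean", "beta_mean")]), "")
  norm_files <- list.files(out_dir, "^normalized_.*\\.csv$",
                           full.names = TRUE)
  for (f in norm_files) {
    nc <- utils::read.csv(f)
    stopifnot(max(abs(nc$alpha_tilde - nc$C_tilde * nc$beta_tilde)) < 1e-9)
    lines <- c(lines,
               sprintf("## Cortex-normalized curves (%s)",
                       sub("normalized_(.*)\\.csv", "\\1", basename(f))),
               "", fmt_tab(nc), "")
  }
  sj <- file.path(out_dir, "sensitivity_summary.json")
  if (file.exists(sj)) {
    s <- jsonlite::read_json(sj)
    if (length(s)) {
      df <- do.call(rbind, lapply(names(s), function(m)
        data.frame(modality = m,
                   median_ratio = s[[m]]$median_ratio,
                   exceedance_fraction = s[[m]]$exceedance_fraction)))
      lines <- c(lines, "## Sensitivity summary (cerebellum vs cortex)", "",
                 fmt_tab(df), "")
    }
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
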