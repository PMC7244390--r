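#' Monte Carlo experiment design
#'
#' Describes one of the two simulation designs: `distributed` (n dipoles
#' drawn uniformly without replacement from the kept source vertices) or
#' `coherent` (patches grown around random seed vertices to the target area
#' pi r^2). Two hundred activations per grid point is the default.
#'
#' @param condition `"distributed"` or `"coherent"`.
#' @param n_grid dipole counts for the distributed design; entries above the
#'   available source count are capped at run time (with a logged message).
#' @param radius_grid patch radii in mm for the coherent design (default
#'   spans 1-30 mm).
#' @param samples Monte Carlo samples per grid point (>= 2).
#' @param seed integer seed (expanded per stage via [child_seed()]).
#' @param modalities channel modalities to evaluate.
#' @return list of class `cereb_design`.
#' @export
experiment_design <- function(condition = c("distributed", "coherent"),
                              n_grid = c(1, 2, 3, 5, 10, 30, 100, 300,
                                         1000, 3000, 10000),
                              radius_grid = c(1, 2, 3, 5, 7, 10, 15, 20, 30),
                              samples = 200, seed = 1L,
                              modalities = c("mag", "grad", "eeg")) {
  condition <- match.arg(condition)
  stopifnot(samples >= 2)
  if (condition == "coherent" && (min(radius_grid) < 0 ||
                                  max(radius_grid) > 100))
    stop("radius_grid must be positive and physiologically plausible (mm)")
  structure(list(condition = condition, n_grid = n_grid,
                 radius_grid = radius_grid, samples = as.integer(samples),
                 seed = as.integer(seed), modalities = modalities),
            class = "cereb_design")
}

#' Draw a distributed dipole sample
#'
#' Uniform sample of `n` kept source vertices without replacement, using the
#' caller's RNG stream.
#'
#' @param src a [source_space()].
#' @param n number of dipoles.
#' @return integer vertex indices.
#' @export
sample_distributed <- function(src, n) {
  kept <- which(src$kept)
  if (n > length(kept))
    stop("n = ", n, " exceeds the ", length(kept), " kept source vertices")
  if (n == length(kept)) return(kept)
  kept[sample.int(length(kept), n)]
}

mc_eval_samples <- function(gain, W, constants, a_n) {
  # W: sources x samples indicator (possibly weighted) sparse matrix
  out <- list()
  for (mod in unique(gain$modality)) {
    gm <- gain_modality(gain, mod)
    S <- as.matrix(gm$values %*% W)
    A <- sqrt(colSums(S^2))
    cn <- sqrt(colSums(gm$values^2))
    B <- as.numeric(cn %*% W)
    C <- conservation_factor(A, B)
    n_act <- as.numeric(Matrix::colSums(W != 0))
    ph <- physiological_norms(A, B, n_act, a_n, constants)
    out[[mod]] <- data.frame(modality = mod, units = modality_units(mod),
                             sample = seq_along(A), n = n_act,
                             a_n_mm2 = a_n * 1e6, A = A, B = B, C = C,
                             alpha = ph$alpha, beta = ph$beta)
  }
  do.call(rbind, out)
}

modality_units <- function(mod) {
  unname(c(mag = "T", grad = "T/m", eeg = "V")[mod])
}

#' Run the distributed-dipole Monte Carlo design
#'
#' For each entry of the n-grid, draws `samples` uniform dipole sets,
#' computes the net and absolute signals per modality, and summarizes the
#' conservation factor and the physiologically scaled norms (mean and
#' sample SD).
#'
#' @param design an [experiment_design()] with condition `"distributed"`.
#' @param gains named list (by surface) of [compute_gain()] results.
#' @param constants a [physiological_constants()] list.
#' @return list of class `cereb_curves` with `samples` (per-sample table)
#'   and `summary` (mean/SD per grid point).
#' @export
run_distributed <- function(design, gains,
                            constants = physiological_constants()) {
  stopifnot(design$condition == "distributed")
  all_samples <- list()
  for (surf in names(gains)) {
    gain <- gains[[surf]]
    N <- ncol(gain$values)
    grid <- sort(unique(pmin(design$n_grid, N)))
    if (any(design$n_grid > N))
      message("n_grid entries above N = ", N, " capped at N (", surf, ")")
    areas <- gain$source_areas
    with_seed(child_seed(design$seed, "mc_distributed"), {
      for (n in grid) {
        idx <- if (n == N) {
          matrix(seq_len(N), N, design$samples)
        } else {
          vapply(seq_len(design$samples),
                 function(s) sample.int(N, n), integer(n))
        }
        idx <- matrix(idx, nrow = n)
        W <- Matrix::sparseMatrix(i = as.vector(idx),
                                  j = rep(seq_len(design$samples), each = n),
                                  x = 1,
                                  dims = c(N, design$samples))
        a_n <- as.numeric(areas %*% W)
        df <- mc_eval_samples(gain, W, constants, a_n)
        df <- df[df$modality %in% design$modalities, ]
        df$surface <- surf
        df$condition <- "distributed"
        all_samples[[length(all_samples) + 1L]] <- df
      }
    })
  }
  samples <- do.call(rbind, all_samples)
  build_curves(samples, "n", design)
}

#' Run the coherent-patch Monte Carlo design
#'
#' For each patch radius r, grows `samples` patches of target area pi r^2
#' around uniformly drawn kept seed vertices (breadth-first accretion on the
#' source-space adjacency), computes per-sample A, B, C and the
#' physiological alpha, beta with the realized patch area, and summarizes
#' per radius. Patches that exhaust the surface are retained with their
#' realized area and counted in attribute `"n_saturated"`.
#'
#' @param design an [experiment_design()] with condition `"coherent"`.
#' @param sources named list (by surface) of [source_space()] objects.
#' @param gains named list of matching [compute_gain()] results.
#' @param constants a [physiological_constants()] list.
#' @return list of class `cereb_curves` (see [run_distributed()]).
#' @export
run_coherent <- function(design, sources, gains,
                         constants = physiological_constants()) {
  stopifnot(design$condition == "coherent")
  all_samples <- list()
  n_sat <- 0L
  for (surf in names(gains)) {
    gain <- gains[[surf]]
    src <- sources[[surf]]
    kept <- which(src$kept)
    col_of <- integer(length(src$kept))
    col_of[gain$source_index] <- seq_along(gain$source_index)
    with_seed(child_seed(design$seed, "mc_coherent"), {
      for (r in design$radius_grid) {
        target <- pi * (r / 1000)^2
        seeds <- kept[sample.int(length(kept), design$samples,
                                 replace = TRUE)]
        useeds <- unique(seeds)
        hd <- igraph::distances(src$graph, v = useeds)
        ti <- tj <- tx <- vector("list", design$samples)
        a_n <- numeric(design$samples)
        for (s in seq_len(design$samples)) {
          patch <- withCallingHandlers(
            grow_patch(src, seeds[s], target,
                       hop_dist = hd[match(seeds[s], useeds), ]),
            warning = function(w) {
              n_sat <<- n_sat + 1L
              invokeRestart("muffleWarning")
            })
          ti[[s]] <- col_of[patch$vertices]
          tj[[s]] <- rep(s, patch$n)
          a_n[s] <- patch$area
        }
        W <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = 1,
                                  dims = c(ncol(gain$values),
                                           design$samples))
        df <- mc_eval_samples(gain, W, constants, a_n)
        df <- df[df$modality %in% design$modalities, ]
        df$surface <- surf
        df$condition <- "coherent"
        df$radius_mm <- r
        all_samples[[length(all_samples) + 1L]] <- df
      }
    })
  }
  samples <- do.call(rbind, all_samples)
  out <- build_curves(samples, "radius_mm", design)
  attr(out, "n_saturated") <- n_sat
  out
}

build_curves <- function(samples, grid_var, design) {
  rownames(samples) <- NULL
  agg <- function(v) {
    s <- stats::aggregate(samples[[v]],
                          by = samples[c("surface", "modality", grid_var)],
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n_samples = length(x)))
    cbind(s[c("surface", "modality", grid_var)],
          stats::setNames(as.data.frame(s$x),
                          c(paste0(v, "_mean"), paste0(v, "_sd"),
                            "n_samples")))
  }
  pieces <- lapply(c("C", "A", "B", "alpha", "beta"), agg)
  summary <- Reduce(function(a, b) merge(a, b[setdiff(names(b), "n_samples")],
                                         by = c("surface", "modality",
                                                grid_var)),
                    pieces)
  summary <- summary[order(summary$surface, summary$modality,
                           summary[[grid_var]]), ]
  rownames(summary) <- NULL
  structure(list(samples = samples, summary = summary, design = design,
                 grid_var = grid_var),
            class = "cereb_curves")
}

#' @export
print.cereb_curves <- function(x, ...) {
  cat(sprintf("Monte Carlo curves (%s design): %d samples over %d grid ",
              x$design$condition, x$design$samples,
              length(unique(x$summary[[x$grid_var]]))))
  cat(sprintf("points,\n  surfaces: %s; modalities: %s\n",
              paste(unique(x$summary$surface), collapse = ", "),
              paste(unique(x$summary$modality), collapse = ", ")))
  invisible(x)
}

#' Write Monte Carlo results to CSV/JSON
#'
#' One per-sample CSV and one summary CSV per (surface, modality), plus a
#' JSON file of per-condition means and SDs.
#'
#' @param curves a `cereb_curves` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisible vector of written paths.
#' @export
write_curves <- function(curves, dir, prefix = curves$design$condition) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_samples.csv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  p3 <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.csv(curves$samples, p1, row.names = FALSE)
  utils::write.csv(curves$summary, p2, row.names = FALSE)
  jsonlite::write_json(curves$summary, p3, dataframe = "rows", digits = NA)
  invisible(c(p1, p2, p3))
}
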