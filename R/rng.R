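#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state, so that deterministic components (mesh phases, Monte Carlo
#' draws) never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive per-stage child seeds from one run seed
#'
#' The pipeline exposes a single user-facing seed; each stage draws from an
#' independent stream whose seed is derived as
#' `(seed * 101 + stage_index) mod (2^31 - 1)`. Documented so that stages can
#' be rerun in isolation with reproducible results.
#'
#' @param seed integer master seed.
#' @param stage integer stage index (>= 1) or stage name known to the
#'   pipeline.
#' @return integer child seed.
#' @export
child_seed <- function(seed, stage) {
  stages <- c(anatomy = 1L, sensors = 2L, gain = 3L, mc_distributed = 4L,
              mc_coherent = 5L, sensitivity = 6L, report = 7L)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) * 101 + stage) %% (2^31 - 1))
}
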