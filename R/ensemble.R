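#' Ensemble specification
#'
#' @param n_models Number of perturbed start models. The production default
#'   of 500 follows the heuristic of ten starts per refinement parameter
#'   (55 parameters for a 18-atom cluster with refined scale); test-scale
#'   runs use 20-50.
#' @param max_disp Maximum perturbation per Cartesian component, Angstrom.
#' @param base_seed Integer seed; model i uses `base_seed + i - 1`.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 500, max_disp = 0.2, base_seed = 1) {
  if (n_models < 1 || max_disp < 0) {
    abort("Need n_models >= 1 and max_disp >= 0.",
          class = "clusterpdf_validation_error")
  }
  structure(list(n_models = as.integer(n_models), max_disp = max_disp,
                 base_seed = as.integer(base_seed)),
            class = "ensemble_spec")
}

#' Randomly perturb a start model
#'
#' Shifts every Cartesian component of every atom by an independent uniform
#' draw from `[-max_disp, +max_disp]`. Deterministic given the seed.
#'
#' @param model A [cluster_model()].
#' @param max_disp Maximum shift per component, Angstrom.
#' @param seed Integer seed.
#' @return A perturbed [cluster_model()].
#' @export
perturb <- function(model, max_disp, seed) {
  if (max_disp < 0) {
    abort("max_disp must be >= 0.", class = "clusterpdf_validation_error")
  }
  xyz <- coords(model)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  shift <- matrix(runif(3 * nrow(xyz), -max_disp, max_disp), ncol = 3)
  set_coords(model, xyz + shift)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run a perturbation-ensemble refinement
#'
#' Generates `n_models` perturbed copies of the start model and runs the
#' two-stage refinement ([refine_positions()] then [refine_wave()]) on each.
#' Models are independent: results are identical under any scheduling given
#' the same seeds. Individual non-convergence is recorded, not fatal; the
#' ensemble errors only if more than 20 % of the refinements fail outright.
#'
#' @param start A [cluster_model()] (typically the crystal structure).
#' @param data Observed [pdf_curve()].
#' @param spec An [ensemble_spec()].
#' @param opts A [refinement_options()].
#' @param refine_wave_stage Run stage 2 on each model.
#' @param cycles Position/wave alternations per model (see
#'   [refine_two_stage()]).
#' @param refit_positions Passed to [refine_wave()].
#' @param progress Print a dot per model.
#' @return A `pdf_ensemble`: list with `results` (list of `pdf_refinement`),
#'   `start_models`, `seeds`, the generating `spec`/`opts`, and an
#'   `rw_summary` (min, max, mean).
#' @export
run_ensemble <- function(start, data, spec = ensemble_spec(),
                         opts = refinement_options(),
                         refine_wave_stage = TRUE, cycles = 2,
                         refit_positions = FALSE, progress = FALSE) {
  seeds <- spec$base_seed + seq_len(spec$n_models) - 1L
  starts <- purrr::map(seeds, ~ perturb(start, spec$max_disp, .x))
  run_one <- function(st) {
    tryCatch({
      if (refine_wave_stage) {
        res <- refine_two_stage(st, data, opts, cycles = cycles)
        if (refit_positions) res <- refine_wave(res, data, opts,
                                                refit_positions = TRUE)
        res
      } else {
        refine_positions(st, data, opts)
      }
    }, error = function(e) e)
  }
  results <- vector("list", spec$n_models)
  for (k in seq_len(spec$n_models)) {
    results[[k]] <- run_one(starts[[k]])
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  failed <- vapply(results, inherits, logical(1), "condition")
  if (mean(failed) > 0.2) {
    abort(sprintf("Ensemble failure rate %.0f%% exceeds 20%%.",
                  100 * mean(failed)),
          class = "clusterpdf_ensemble_error")
  }
  ok <- results[!failed]
  rws <- vapply(ok, function(r) r$rw_value, numeric(1))
  structure(list(results = results, start_models = starts, seeds = seeds,
                 reference = start, spec = spec, opts = opts,
                 failed = failed,
                 rw_summary = c(min = min(rws), max = max(rws),
                                mean = mean(rws))),
            class = "pdf_ensemble")
}

#' @export
print.pdf_ensemble <- function(x, ...) {
  cat(sprintf("<pdf_ensemble> %d models (%d failed), max_disp %.3g A\n",
              x$spec$n_models, sum(x$failed), x$spec$max_disp))
  cat(sprintf("  Rw: min %.4f, mean %.4f, max %.4f\n",
              x$rw_summary["min"], x$rw_summary["mean"], x$rw_summary["max"]))
  invisible(x)
}

.ok_results <- function(ens) ens$results[!ens$failed]

#' Collapse an ensemble into its average structure
#'
#' Per-atom arithmetic mean of the refined positions across models. No
#' re-superposition is performed: the position bounds keep every refinement
#' in the common start-model frame, so all models share one frame already.
#'
#' @param ens A `pdf_ensemble`.
#' @return A [cluster_model()].
#' @export
average_structure <- function(ens) {
  ok <- .ok_results(ens)
  if (length(ok) == 0) {
    abort("Empty ensemble.", class = "clusterpdf_validation_error")
  }
  acc <- Reduce(`+`, purrr::map(ok, ~ coords(.x$model))) / length(ok)
  out <- set_coords(ok[[1]]$model, acc)
  attr(out, "name") <- paste0(model_name(ens$reference), " (ensemble mean)")
  out
}

#' Positional distribution across an ensemble
#'
#' For each atom, the spread statistic is the Euclidean distance of each
#' model's refined position from that atom's ensemble-mean position; the
#' box-plot statistics (min, max, median, IQR) summarise these distances.
#'
#' @param ens A `pdf_ensemble`.
#' @return A `position_distribution`: list with `positions` (long tibble:
#'   model, label, element, x, y, z, distance) and `stats` (per-atom min,
#'   max, median, IQR of distance).
#' @export
position_distribution <- function(ens) {
  ok <- .ok_results(ens)
  mean_xyz <- coords(average_structure(ens))
  positions <- purrr::imap_dfr(ok, function(res, k) {
    m <- res$model
    dx <- coords(m) - mean_xyz
    tibble(model = k, label = m$label, element = m$element,
           x = m$x, y = m$y, z = m$z,
           distance = sqrt(rowSums(dx^2)))
  })
  stats <- positions |>
    dplyr::group_by(.data$label, .data$element) |>
    dplyr::summarise(min = min(.data$distance), max = max(.data$distance),
                     median = median(.data$distance),
                     iqr = stats::IQR(.data$distance), .groups = "drop")
  structure(list(positions = positions, stats = stats),
            class = "position_distribution")
}

#' Mean stage-1 residual of an ensemble
#'
#' Pointwise mean of the stage-1 residual curves (data minus scaled model
#' PDF, before the solvation wave). Averaging over the ensemble suppresses
#' refinement-specific noise roughly as sqrt(n) and exposes any common
#' unmodelled component — for DNA-wrapped clusters, the conformational
#' signature of the DNA around the core.
#'
#' @param ens A `pdf_ensemble`.
#' @return A [pdf_curve()].
#' @export
mean_stage1_residual <- function(ens) {
  ok <- .ok_results(ens)
  if (length(ok) == 0 || is.null(ok[[1]]$residual)) {
    abort("No stage-1 residuals stored.", class = "clusterpdf_validation_error")
  }
  r <- ok[[1]]$residual$r
  g <- Reduce(`+`, purrr::map(ok, ~ .x$residual$g)) / length(ok)
  pdf_curve(r, g, meta = list(source = "mean stage-1 residual",
                              n_models = length(ok)))
}
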