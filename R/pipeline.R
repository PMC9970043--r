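#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end generation workflow. A run is
#' reproducible from `(input, run_config)` alone.
#'
#' @param n_virtual Number of virtual patients to sample.
#' @param format Input format for file inputs (`"auto"`, `"csv"`, `"json"`).
#' @param k_min,k_max Component-scan range (defaults 2 and 20).
#' @param db_rule `"max"` or `"min"`: Davies-Bouldin selection rule (see
#'   [select_components()]).
#' @param patience Early-termination patience of the scan.
#' @param gamma_mode `"exp"` or `"inverse"` weight concentration rule.
#' @param weight_mode Sampling weight mode (see [generate_cohort()]).
#' @param tol,max_iter Variational-inference controls.
#' @param bins Histogram bins for the KL indicator.
#' @param seed Master seed for every stochastic stage.
#' @param curation A [curation_config()]; its seed is overridden by `seed`.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_virtual = 1000L, format = "auto",
                       k_min = 2L, k_max = 20L,
                       db_rule = c("max", "min"), patience = 5L,
                       gamma_mode = c("exp", "inverse"),
                       weight_mode = c("posterior_draw", "expected"),
                       tol = 1e-5, max_iter = 500L, bins = 50L,
                       seed = 1L, curation = curation_config(),
                       out_dir = NULL) {
  structure(
    list(
      n_virtual = check_scalar_int(n_virtual, "n_virtual", min = 0L),
      format = format,
      k_min = check_scalar_int(k_min, "k_min", min = 2L),
      k_max = check_scalar_int(k_max, "k_max", min = 2L),
      db_rule = match.arg(db_rule),
      patience = check_scalar_int(patience, "patience"),
      gamma_mode = match.arg(gamma_mode),
      weight_mode = match.arg(weight_mode),
      tol = tol,
      max_iter = check_scalar_int(max_iter, "max_iter"),
      bins = check_scalar_int(bins, "bins", min = 2L),
      seed = as.integer(seed),
      curation = curation,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  c(
    config[setdiff(names(config), "curation")],
    list(curation = unclass(config$curation))
  )
}

#' Run the full virtual-cohort generation workflow
#'
#' Executes the four-stage workflow end to end: (i) data diagnostics
#' ([curate()]); (ii) component initialization by spectral clustering over
#' the Davies-Bouldin scan ([select_components()]) on the outlier-free
#' curated rows; (iii) variational mixture training with `T = opt`
#' components and weight concentration `exp(-opt)` ([fit_bgmm()]) followed
#' by sampling of `n_virtual` profiles ([generate_cohort()]); (iv)
#' validation of the synthetic cohort against the curated real one
#' ([cohort_fidelity()], skipped with a notice when `n_virtual` is 0).
#' When `config$out_dir` is set, the synthetic cohort (CSV), the model
#' (JSON), the scan, the curation log (JSON lines), the fidelity report and
#' the run log are written there; partial outputs are removed if any stage
#' fails.
#'
#' @param input A file path (CSV/JSON) or an in-memory data frame.
#' @param config A [run_config()].
#' @return Object of class `run_report`: curation summary, the
#'   `component_scan`, the `bgmm` fit, the synthetic tibble, the
#'   `cohort_fidelity` report (or `NULL`), file `paths`, `versions` and
#'   per-stage `timings` (seconds).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_patients = 150, n_features = 8, seed = 5)
#' rep <- run_pipeline(cohort$table,
#'   run_config(n_virtual = 200, k_max = 4, db_rule = "min", seed = 5))
#' glance(rep$fidelity)
#' }
#' @export
run_pipeline <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  written <- character()
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  log_lines <- character()
  log_event <- function(stage, ...) {
    entry <- list(stage = stage, ...)
    log_lines <<- c(log_lines, jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
  }
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("[%s] %s", stage, conditionMessage(e)))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  raw <- timed("load", {
    if (is.character(input)) read_cohort(input, config$format) else {
      stopifnot(is.data.frame(input))
      decode_cells(input, c("", "NA", "NaN", "null"))
    }
  })
  log_event("load", n_rows = nrow(raw), n_features = ncol(raw))

  cur_cfg <- config$curation
  cur_cfg$seed <- config$seed
  curated <- timed("diagnostics", curate(raw, cur_cfg))
  log_event("diagnostics",
            n_eligible = length(curated$eligible_features),
            n_excluded = nrow(curated$excluded_features),
            n_outliers = sum(curated$outlier_flag),
            n_imputed = sum(curated$imputed_mask))

  model_rows <- modeling_rows(curated)
  scan <- timed("components", select_components(
    model_rows, k_range = c(config$k_min, config$k_max),
    rule = config$db_rule, patience = config$patience, seed = config$seed
  ))
  log_event("components", opt = scan$opt, rule = scan$rule,
            n_evaluated = nrow(scan$entries),
            terminated_early = scan$terminated_early)

  fit <- timed("training", fit_bgmm(
    model_rows, opt = scan$opt, gamma_mode = config$gamma_mode,
    tol = config$tol, max_iter = config$max_iter, seed = config$seed
  ))
  log_event("training", gamma = fit$priors$gamma, n_iter = fit$n_iter,
            converged = fit$converged, elbo = tail(fit$elbo_trace, 1))

  synth <- timed("sampling", generate_cohort(
    fit, n = config$n_virtual, seed = config$seed,
    weight_mode = config$weight_mode
  ))
  log_event("sampling", n_virtual = nrow(synth), weight_mode = config$weight_mode)

  fidelity <- NULL
  if (config$n_virtual >= 2L) {
    # score against the outlier-free curated cohort the model mimics:
    # flagged rows are artifacts the generator was told to ignore
    fidelity <- timed("validation",
                      cohort_fidelity(model_rows, synth, bins = config$bins))
    log_event("validation",
              cv_diff = fidelity$cv_diff, inter = fidelity$inter_corr_diff,
              intra = fidelity$intra_corr_diff, gof = fidelity$gof,
              kl = fidelity$kl)
  } else {
    inform("Fewer than 2 virtual patients requested; validation stage skipped.")
    log_event("validation", skipped = TRUE)
  }

  paths <- list()
  if (!is.null(out_dir)) {
    timed("write", {
      paths$synthetic <- emit(file.path(out_dir, "synthetic_cohort.csv"))
      readr::write_csv(synth, paths$synthetic)
      paths$model <- emit(file.path(out_dir, "model.json"))
      write_bgmm(fit, paths$model)
      paths$scan <- emit(file.path(out_dir, "component_scan.json"))
      write_component_scan(scan, paths$scan)
      paths$curation_log <- emit(file.path(out_dir, "curation_log.jsonl"))
      writeLines(
        vapply(seq_len(nrow(curated$log)), function(i) {
          jsonlite::toJSON(as.list(curated$log[i, ]), auto_unbox = TRUE)
        }, character(1)),
        paths$curation_log
      )
      if (!is.null(fidelity)) {
        paths$report <- emit(file.path(out_dir, "quality_report.json"))
        write_fidelity_report(fidelity, paths$report)
      }
      paths$config <- emit(file.path(out_dir, "run_config.json"))
      jsonlite::write_json(config_as_list(config), paths$config,
                           auto_unbox = TRUE, digits = NA, null = "null")
      paths$log <- emit(file.path(out_dir, "run_log.jsonl"))
      writeLines(log_lines, paths$log)
    })
  }

  structure(
    list(
      curation = glance(curated),
      curated = curated,
      scan = scan,
      fit = fit,
      synthetic = synth,
      fidelity = fidelity,
      paths = paths,
      config = config,
      versions = list(
        package = as.character(utils::packageVersion("virtualcohort")),
        r = R.version.string
      ),
      timings = timings
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> opt = %d components, %d virtual patients generated\n",
    x$scan$opt, nrow(x$synthetic)
  ))
  if (!is.null(x$fidelity)) print(x$fidelity)
  invisible(x)
}

#' Fidelity across virtual-population sizes
#'
#' Samples one synthetic cohort per `(size, seed)` pair from an
#' already-trained model and scores each against the real cohort, mirroring
#' the design of scaling experiments where indicator values decay as the
#' virtual population grows. The trained model is reused across sizes by
#' default; `retrain_per_size = TRUE` refits it (same data, same `opt`) for
#' every size.
#'
#' @param fit A `bgmm` model.
#' @param real The curated real cohort the model was trained on.
#' @param sizes Vector of positive virtual-population sizes.
#' @param seeds Vector of seeds; each size is sampled once per seed.
#' @param bins Histogram bins for the KL indicator.
#' @param weight_mode Passed to [generate_cohort()].
#' @param retrain_per_size Refit the mixture for every size.
#' @return Tibble with columns `n_virtual`, `seed`, and the five
#'   indicators.
#' @export
sweep_cohort_sizes <- function(fit, real, sizes, seeds = 1L, bins = 50L,
                               weight_mode = c("posterior_draw", "expected"),
                               retrain_per_size = FALSE) {
  stopifnot(inherits(fit, "bgmm"))
  weight_mode <- match.arg(weight_mode)
  sizes <- vapply(sizes, check_scalar_int, integer(1), name = "sizes")
  purrr::map_dfr(sizes, function(P) {
    model <- if (retrain_per_size) {
      fit_bgmm(real, opt = fit$priors$T, gamma_mode = fit$priors$gamma_mode,
               seed = fit$seed + P)
    } else {
      fit
    }
    purrr::map_dfr(seeds, function(s) {
      synth <- generate_cohort(model, n = P, seed = s, weight_mode = weight_mode)
      rep <- suppressWarnings(cohort_fidelity(real, synth, bins = bins))
      dplyr::bind_cols(tibble(n_virtual = P, seed = as.integer(s)),
                       glance(rep)[1:5])
    })
  })
}
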