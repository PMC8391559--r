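#' Configuration of an end-to-end run
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort, or the
#'   directory of a previously written cohort (with `manifest.csv`).
#' @param validation_centers Center ids held out as the external
#'   validation set (the rest form the exploratory set).
#' @param seed Master seed of the run.
#' @param fbn Fixed bin number for discretization.
#' @param n_repeats CV repeats of the combinatorial search.
#' @param combos Combo whitelist tibble ([enumerate_combos()] subset);
#'   `NULL` enumerates a compact default search space.
#' @param out_dir Output directory; `NULL` for a temporary directory.
#' @param target_spacing Isotropic resampling target, mm.
#' @param n_shuffles Permutation-importance shuffles.
#' @param write_cohort Write the cohort as NIfTI + manifest (default:
#'   in-memory for <= 64 patients).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       validation_centers = c("B", "C"), seed = 1L,
                       fbn = 32L, n_repeats = 20L, combos = NULL,
                       out_dir = NULL, target_spacing = 1,
                       n_shuffles = 50, write_cohort = NULL) {
  structure(list(cohort = cohort, validation_centers = validation_centers,
                 seed = as.integer(seed), fbn = as.integer(fbn),
                 n_repeats = as.integer(n_repeats), combos = combos,
                 out_dir = out_dir, target_spacing = target_spacing,
                 n_shuffles = n_shuffles, write_cohort = write_cohort),
            class = "run_config")
}

#' Subset a cohort by manifest rows
#' @param cohort A `dsc_cohort`.
#' @param idx Logical or integer row index into the manifest.
#' @return A `dsc_cohort` restricted to those patients.
#' @export
subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$manifest <- cohort$manifest[idx, , drop = FALSE]
  if (!is.null(cohort$patients))
    out$patients <- cohort$patients[idx]
  out
}

# compact default search space for desk-scale runs; the full grid of
# enumerate_combos() remains available through the combos argument
default_search_combos <- function() {
  enumerate_combos(
    reducers = c("gini", "f_ratio", "mim"),
    resamplers = c("adasyn", "none"),
    classifiers = c("logreg_l2", "logreg_elasticnet", "random_forest",
                    "knn"),
    k_grid = c(10L, 20L)
  )
}

#' Run the whole analysis end to end
#'
#' Generate (or load) the cohort, select time points, standardize both
#' image versions, extract all features, run the kappa-ranked
#' combinatorial search on the exploratory centers, validate the winning
#' pipeline of each version on the held-out centers, and explain the
#' better version's predictions. Every stage's output is persisted under
#' `out_dir`, stamped with the configuration hash; rerunning the same
#' configuration reproduces identical leaderboards.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return List of class `dscr_run`: `features` (per version),
#'   `search` (per version), `validation` (per version `frozen_model`),
#'   `summary` ([summarize_run()]), `explain` (best version), `config`,
#'   `config_hash`, `out_dir`.
#' @export
run_end_to_end <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  out_dir <- config$out_dir %||% file.path(tempdir(),
                                           paste0("dscr_run_", hash))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[", ..., "]")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("simulate")
  cohort <- stage("simulate", {
    if (is.character(config$cohort)) {
      man <- tibble::as_tibble(utils::read.csv(
        file.path(config$cohort, "manifest.csv")))
      structure(list(manifest = man, patients = NULL, dir = config$cohort),
                class = "dsc_cohort")
    } else {
      n_total <- sum(config$cohort$n_per_center)
      write_it <- config$write_cohort %||% (n_total > 64)
      generate_cohort(config$cohort,
                      dir = if (write_it) file.path(out_dir, "cohort"))
    }
  })
  is_val <- cohort$manifest$center %in% config$validation_centers
  if (!any(is_val) || all(is_val))
    stop("validation centers must hold out a non-empty strict subset")
  expl <- subset_cohort(cohort, !is_val)
  val <- subset_cohort(cohort, is_val)

  combos <- config$combos %||% default_search_combos()
  scheme <- make_folds(expl$manifest$label,
                       pipeline_defaults()$n_folds,
                       config$n_repeats, config$seed)

  features <- list()
  search <- list()
  validation <- list()
  runs <- list()
  for (version in c("np", "p")) {
    say("extract ", version)
    fe <- stage("extract", extract_cohort_features(
      expl, version, fbn = config$fbn,
      target_spacing = config$target_spacing, verbose = verbose))
    fv <- stage("extract", extract_cohort_features(
      val, version, fbn = config$fbn, frozen = frozen_constants(fe),
      target_spacing = config$target_spacing, verbose = verbose))
    features[[version]] <- list(exploratory = fe, validation = fv)
    say("search ", version)
    sr <- stage("search", run_search(fe, combos = combos, scheme = scheme,
                                     seed = config$seed,
                                     verbose = verbose))
    search[[version]] <- sr
    say("validate ", version)
    fm <- stage("validate", external_validate(
      best_combo(sr), fe, val_features = fv, seed = config$seed))
    validation[[version]] <- fm
    runs[[version]] <- list(exploratory = exploratory_metrics(sr),
                            validation = fm$metrics)
    utils::write.csv(
      dplyr::mutate(tibble::as_tibble(sr), config_hash = hash),
      file.path(out_dir, paste0("leaderboard_", version, ".csv")),
      row.names = FALSE)
    utils::write.csv(
      dplyr::mutate(fm$predictions, config_hash = hash),
      file.path(out_dir, paste0("predictions_", version, ".csv")),
      row.names = FALSE)
  }

  say("explain")
  best_version <- if (validation$p$metrics$kappa >=
                        validation$np$metrics$kappa) "p" else "np"
  expl_report <- stage("explain", explain_model(
    validation[[best_version]], features[[best_version]]$validation,
    n_shuffles = config$n_shuffles, seed = config$seed))
  utils::write.csv(
    dplyr::mutate(expl_report$importance, config_hash = hash),
    file.path(out_dir, "importance.csv"), row.names = FALSE)

  summary <- summarize_run(np = runs$np, p = runs$p)
  utils::write.csv(dplyr::mutate(summary$table, config_hash = hash),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, fbn = config$fbn,
         n_repeats = config$n_repeats,
         best_combo = list(np = best_combo(search$np)$combo_id,
                           p = best_combo(search$p)$combo_id),
         validation_kappa = list(np = validation$np$metrics$kappa,
                                 p = validation$p$metrics$kappa)),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)

  structure(list(features = features, search = search,
                 validation = validation, summary = summary,
                 explain = expl_report, best_version = best_version,
                 config = config, config_hash = hash, out_dir = out_dir),
            class = "dscr_run")
}

#' @exportS3Method base::print
print.dscr_run <- function(x, ...) {
  cat("End-to-end DSC radiomics run", x$config_hash, "\n")
  cat("Best version:", x$best_version, "\n")
  print(x$summary)
  invisible(x)
}
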