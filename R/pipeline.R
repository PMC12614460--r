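#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run in one declarative object. All
#' randomness derives from the single `seed`.
#'
#' @param seed Master seed.
#' @param n_total,n_event Cohort size and event count (defaults 774 / 47).
#' @param specs Variable-specification tibble (default [default_cohort_specs()]).
#' @param fractions Train/validation/test fractions (default 0.64/0.16/0.20).
#' @param missingness Inject the specs' MCAR missingness before splitting.
#' @param impute_cycles Chained-imputation sweeps (default 10).
#' @param alpha Univariate screening threshold (default 0.05).
#' @param top_k Optional cap on the number of selected features (smallest
#'   p-values); `NULL` keeps every variable with p below `alpha`.
#' @param families Families to SSA-tune (`"random_forest"`, `"xgboost"`).
#' @param n_salps,n_iter Swarm budget for tuning (defaults 20 / 50).
#' @param cv_k Folds of the tuning fitness (default 5).
#' @param baselines Fit the default-hyperparameter model zoo.
#' @param threshold Operating threshold for point metrics (default 0.5).
#' @param explain Compute Shapley attributions for the tuned models.
#' @param n_explain Test-set rows to explain (default 40).
#' @param n_background Training rows in the attribution background
#'   (default 100).
#' @param n_perm Permutations for the sampling attribution estimator.
#' @param out_dir Output directory for artifacts (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_total = 774, n_event = 47,
                            specs = default_cohort_specs(),
                            fractions = c(0.64, 0.16, 0.20),
                            missingness = TRUE, impute_cycles = 10,
                            alpha = 0.05, top_k = NULL,
                            families = c("random_forest", "xgboost"),
                            n_salps = 20, n_iter = 50, cv_k = 5,
                            baselines = TRUE, threshold = 0.5,
                            explain = TRUE, n_explain = 40,
                            n_background = 100, n_perm = 32,
                            out_dir = tempfile("clinrisk-run-")) {
  structure(list(seed = seed, n_total = n_total, n_event = n_event,
                 specs = specs, fractions = fractions,
                 missingness = missingness, impute_cycles = impute_cycles,
                 alpha = alpha, top_k = top_k, families = families,
                 n_salps = n_salps, n_iter = n_iter, cv_k = cv_k,
                 baselines = baselines, threshold = threshold,
                 explain = explain, n_explain = n_explain,
                 n_background = n_background, n_perm = n_perm,
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, seed, expr) {
  tryCatch(expr, error = function(e) {
    stop("Pipeline stage '", stage, "' failed (seed ", seed, "): ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full rupture-risk pipeline
#'
#' Executes generate -> split -> impute -> screen -> standardize -> SMOTE ->
#' SSA-tune -> baseline zoo -> evaluate -> explain, writes every artifact
#' (cohort CSV, split and screening JSON, convergence traces, tidy metric and
#' curve CSVs, attribution CSV, run manifest JSON) to `config$out_dir`, and
#' enforces the leakage guard: screening, scaling and SMOTE read training
#' rows only; test rows are touched once, at final evaluation.
#'
#' @param config A [pipeline_config()].
#' @return A `clinrisk_run` list: `manifest`, `split`, `screen`, `models`
#'   (tuned + baselines), `metrics`, `curves`, `attributions`, `paths`.
#'   Identical config and seed reproduce byte-identical metric and curve
#'   reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)

  cohort <- run_stage("generate", seed, {
    co <- generate_cohort(config$specs, config$n_total, config$n_event,
                          seed = seed)
    if (config$missingness) co <- inject_missingness(co, config$specs,
                                                     seed = seed + 1L)
    co
  })
  write_cohort(cohort, pth("cohort.csv"))

  split <- run_stage("split", seed,
                     split_cohort(cohort, config$fractions, seed = seed + 2L))
  jsonlite::write_json(unclass(split), pth("split.json"), auto_unbox = FALSE)

  parts <- run_stage("impute", seed, {
    lapply(stats::setNames(nm = c("train", "validation", "test")), function(nm) {
      off <- match(nm, c("train", "validation", "test"))
      impute_chained(cohort[split[[nm]], , drop = FALSE],
                     n_cycles = config$impute_cycles, seed = seed + 2L + off)
    })
  })

  screen <- run_stage("screen", seed,
                      screen_features(parts$train, alpha = config$alpha,
                                      top_k = config$top_k))
  jsonlite::write_json(screen, pth("screen.json"), dataframe = "rows",
                       digits = NA, pretty = TRUE)
  selected <- screen$variable[screen$selected]
  if (length(selected) < 2) {
    stop("Pipeline stage 'screen' failed (seed ", seed,
         "): fewer than 2 variables selected.", call. = FALSE)
  }
  keep <- c(selected, "rupture")
  parts <- lapply(parts, function(p) p[, keep, drop = FALSE])

  std <- run_stage("standardize", seed,
                   standardize(parts$train, parts$validation, parts$test))
  train <- std$partitions[[1]]
  validation <- std$partitions[[2]]
  test <- std$partitions[[3]]

  audit_leakage(split, stage_indices = list(
    screening = split$train, scaler = split$train, smote = split$train))

  train_bal <- run_stage("smote", seed,
                         apply_smote(train, seed = seed + 6L))

  tuned <- run_stage("tune", seed, {
    out <- lapply(stats::setNames(nm = config$families), function(fam) {
      tune_model(train, family = fam, n_salps = config$n_salps,
                 n_iter = config$n_iter, seed = seed + 10L, k = config$cv_k)
    })
    for (fam in names(out)) {
      readr::write_csv(out[[fam]]$trace, pth(paste0("trace_", fam, ".csv")))
    }
    out
  })

  baselines <- list()
  if (isTRUE(config$baselines)) {
    baselines <- run_stage("baselines", seed,
                           baseline_zoo(train_bal, seed = seed + 20L))
  }

  models <- c(stats::setNames(tuned, paste0("ssa_", names(tuned))), baselines)
  metrics <- run_stage("evaluate", seed,
                       evaluate_models(models, test,
                                       threshold = config$threshold))
  readr::write_csv(metrics, pth("metrics.csv"))

  curves <- run_stage("curves", seed, {
    y <- as.integer(test$rupture)
    purrr::imap(models, function(m, nm) {
      if (inherits(m, "tuned_model")) m <- m$model
      p <- predict_prob(m, test)
      dplyr::bind_rows(
        dplyr::mutate(roc_points(p, y), curve = "roc"),
        dplyr::mutate(tibble::as_tibble(decision_curve(p, y)), curve = "dca"),
        dplyr::mutate(tibble::as_tibble(calibration_curve(p, y)),
                      curve = "calibration"),
        dplyr::mutate(threshold_sweep(p, y), curve = "threshold_sweep")
      ) |> dplyr::mutate(model = nm, .before = 1)
    }) |> dplyr::bind_rows()
  })
  readr::write_csv(curves, pth("curves.csv"))

  attributions <- NULL
  if (isTRUE(config$explain) && length(tuned)) {
    attributions <- run_stage("explain", seed, {
      bg_n <- min(config$n_background, nrow(train))
      ex_n <- min(config$n_explain, nrow(test))
      bg <- withr::with_seed(seed + 30L, train[sample(nrow(train), bg_n), ])
      ex <- withr::with_seed(seed + 31L, test[sample(nrow(test), ex_n), ])
      att <- global_attributions(tuned[[1]], ex, background = bg,
                                 n_perm = config$n_perm, seed = seed + 32L)
      readr::write_csv(tidy.attribution_set(att), pth("attributions.csv"))
      att
    })
  }

  manifest <- list(
    seed = seed,
    partition_sizes = lengths(split),
    n_total = config$n_total, n_event = config$n_event,
    fractions = config$fractions,
    alpha = config$alpha, top_k = config$top_k,
    selected_features = selected,
    ssa_budget = list(n_salps = config$n_salps, n_iter = config$n_iter,
                      cv_k = config$cv_k),
    tuned = lapply(tuned, function(tm) tm$assignment),
    families = config$families,
    baselines = names(baselines),
    threshold = config$threshold,
    versions = list(
      r = paste(R.version$major, R.version$minor, sep = "."),
      salpclinrisk = as.character(utils::packageVersion("salpclinrisk")),
      ranger = as.character(utils::packageVersion("ranger")),
      xgboost = as.character(utils::packageVersion("xgboost"))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  structure(list(manifest = manifest, split = split, screen = screen,
                 models = models, metrics = metrics, curves = curves,
                 attributions = attributions,
                 paths = stats::setNames(
                   file.path(config$out_dir,
                             c("cohort.csv", "split.json", "screen.json",
                               "metrics.csv", "curves.csv", "manifest.json")),
                   c("cohort", "split", "screen", "metrics", "curves",
                     "manifest"))),
            class = "clinrisk_run")
}

#' @export
print.clinrisk_run <- function(x, ...) {
  cat("<clinrisk_run> partitions:",
      paste(x$manifest$partition_sizes, collapse = "/"),
      " models:", length(x$models), "\n")
  print(x$metrics[, c("model", "accuracy", "precision", "recall", "f1",
                      "roc_auc", "pr_auc")])
  invisible(x)
}
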