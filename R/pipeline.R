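# One-config orchestration of the full analysis:
# synthesize-or-load -> extract -> select -> compare -> model -> validate,
# with a provenance record and itemized exclusion accounting.

#' Default pipeline configuration
#'
#' All tunable parameters of every stage, with their documented defaults.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = list(mode = "synthetic", manifest = NULL, cohort = NULL),
    synthetic = list(n_patients = 125L, fraction_high_volume = 46 / 125,
                     seed = 1L, with_phantoms = FALSE),
    extraction = list(n_levels = 32L, offsets = "inplane4",
                      aggregation = "mean", min_voxels = 100L),
    selection = list(k = 10L, method = "spearman", prune_r = 0.9),
    comparison = list(threshold_cm3 = sphere_volume_cm3(2),
                      family = "per-modality", alpha = 0.05),
    modelling = list(scenario = "all", B = 1000L, seed = 17L),
    output = list(dir = NULL)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key: '%s'", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key '%s' must be a mapping", full), call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_range <- function(value, name, lower = -Inf, upper = Inf,
                        choices = NULL) {
  if (!is.null(choices)) {
    if (!value %in% choices)
      stop(sprintf("config '%s' must be one of: %s (got '%s')",
                   name, paste(choices, collapse = ", "), value), call. = FALSE)
    return(invisible(value))
  }
  if (!is.numeric(value) || is.na(value) || value < lower || value > upper)
    stop(sprintf("config '%s' out of range [%s, %s]: %s",
                 name, format(lower), format(upper), format(value)), call. = FALSE)
  invisible(value)
}

validate_config <- function(cfg) {
  check_range(cfg$input$mode, "input.mode", choices = c("synthetic", "files"))
  if (cfg$input$mode == "files") {
    for (f in c("manifest", "cohort")) {
      p <- cfg$input[[f]]
      if (is.null(p) || !file.exists(p))
        stop(sprintf("config 'input.%s' must name an existing file in files mode", f),
             call. = FALSE)
    }
  }
  check_range(cfg$synthetic$n_patients, "synthetic.n_patients", 1)
  check_range(cfg$synthetic$fraction_high_volume, "synthetic.fraction_high_volume", 0, 1)
  check_range(cfg$extraction$n_levels, "extraction.n_levels", 2)
  check_range(cfg$extraction$offsets, "extraction.offsets",
              choices = c("inplane4", "full13"))
  check_range(cfg$extraction$aggregation, "extraction.aggregation",
              choices = c("mean", "merged"))
  check_range(cfg$extraction$min_voxels, "extraction.min_voxels", 0)
  check_range(cfg$selection$k, "selection.k", 1)
  check_range(cfg$selection$method, "selection.method",
              choices = c("spearman", "pearson"))
  check_range(cfg$selection$prune_r, "selection.prune_r", 0, 1)
  check_range(cfg$comparison$threshold_cm3, "comparison.threshold_cm3",
              lower = 1e-9)
  check_range(cfg$comparison$family, "comparison.family",
              choices = c("per-modality", "pooled"))
  check_range(cfg$comparison$alpha, "comparison.alpha", 0, 1)
  check_range(cfg$modelling$scenario, "modelling.scenario",
              choices = c("all", "no-adjuvant"))
  check_range(cfg$modelling$B, "modelling.B", 1)
  cfg
}

#' Load and validate a pipeline configuration
#'
#' YAML config; unknown keys are an error (never silently ignored), defaults
#' are applied for everything omitted, and the fully resolved configuration
#' is what [run_pipeline()] echoes into its run directory.
#'
#' @param path YAML file path.
#' @return Validated nested config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file does not exist: '%s'", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' Run the full pipeline
#'
#' Executes synthesize-or-load, feature extraction, de-correlation, the
#' volume-group comparison, scenario modelling and bootstrap validation, and
#' writes every report plus a provenance log into the run directory. The run
#' directory must be new or empty (outputs are immutable); re-running with
#' the same config and seeds reproduces all outputs.
#'
#' @param config validated config list from [load_config()] or
#'   [default_config()].
#' @param output_dir run directory (overrides `config$output$dir`).
#' @return Invisibly, list with the main stage results and output paths.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  cfg <- validate_config(config)
  out_dir <- if (!is.null(output_dir)) output_dir else cfg$output$dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE, no.. = TRUE)))
    stop(sprintf("output directory '%s' exists and is not empty; runs are immutable",
                 out_dir), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  stage <- function(name, expr) {
    log_line("[stage %s] start", name)
    res <- tryCatch(expr, error = function(e) {
      log_line("[stage %s] ERROR: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    log_line("[stage %s] done", name)
    res
  }
  log_line("cervitex %s  run started %s",
           as.character(utils::packageVersion("cervitex")),
           format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  cfg$output$dir <- out_dir
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  # ---- inputs / features -------------------------------------------------
  voi_exclusions <- data.frame(patient_id = character(0), modality = character(0),
                               reason = character(0), stringsAsFactors = FALSE)
  if (cfg$input$mode == "synthetic") {
    gen <- stage("synthesize", {
      spec <- cohort_generator_spec(
        n_patients = cfg$synthetic$n_patients,
        fraction_high_volume = cfg$synthetic$fraction_high_volume,
        threshold_cm3 = cfg$comparison$threshold_cm3,
        seed = cfg$synthetic$seed)
      generate_cohort(spec, with_phantoms = isTRUE(cfg$synthetic$with_phantoms))
    })
    cohort <- gen$cohort
    features <- gen$features
    log_line("synthesized cohort: n=%d (%d high-volume), seed=%d",
             nrow(cohort), sum(cohort$arm == "high"), cfg$synthetic$seed)
  } else {
    loaded <- stage("load", {
      manifest <- utils::read.csv(cfg$input$manifest, stringsAsFactors = FALSE)
      need <- c("patient_id", "modality", "image", "mask")
      if (!all(need %in% names(manifest)))
        stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
      list(manifest = manifest, cohort = read_cohort(cfg$input$cohort))
    })
    cohort <- loaded$cohort
    features <- stage("extract", {
      rows <- list()
      for (i in seq_len(nrow(loaded$manifest))) {
        m <- loaded$manifest[i, ]
        vol <- read_volume(m$image, modality = m$modality)
        msk <- read_mask(m$mask)
        fv <- extract_voi_features(vol, msk,
                                   n_levels = cfg$extraction$n_levels,
                                   offsets = cfg$extraction$offsets,
                                   aggregation = cfg$extraction$aggregation,
                                   min_voxels = cfg$extraction$min_voxels)
        log_line("extract %s/%s: %d voxels, pair counts [%s]%s",
                 m$patient_id, m$modality, fv$voxel_count,
                 paste(fv$pair_counts, collapse = ","),
                 if (fv$eligible) "" else "  INELIGIBLE")
        if (fv$eligible) {
          rows[[length(rows) + 1L]] <- voi_features_row(fv, m$patient_id, m$modality)
        } else {
          voi_exclusions <- rbind(voi_exclusions, data.frame(
            patient_id = m$patient_id, modality = m$modality,
            reason = fv$reason, stringsAsFactors = FALSE))
        }
      }
      if (!length(rows)) stop("no eligible VOI produced any features")
      feature_table(rows)
    })
  }
  # eligibility on sampled features too: below-minimum VOIs are excluded and
  # itemized, mirroring the study's voxel-count rule
  small <- features$voxel_count < cfg$extraction$min_voxels
  if (any(small)) {
    voi_exclusions <- rbind(voi_exclusions, data.frame(
      patient_id = features$patient_id[small], modality = features$modality[small],
      reason = sprintf("VOI has %d voxels, below the eligibility minimum of %d",
                       features$voxel_count[small], cfg$extraction$min_voxels),
      stringsAsFactors = FALSE))
    features <- features[!small, , drop = FALSE]
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_feature_table(features, file.path(out_dir, "features.csv"))

  # ---- de-correlation ----------------------------------------------------
  selection <- stage("select", {
    out <- list()
    for (mod in unique(features$modality)) {
      sub <- features[features$modality == mod, texture_feature_names(), drop = FALSE]
      res <- decorrelate_features(sub, k = cfg$selection$k,
                                  method = cfg$selection$method,
                                  r_threshold = cfg$selection$prune_r)
      log_line("select %s: retained [%s] (dropped [%s])", mod,
               paste(res$retained, collapse = ", "),
               paste(attr(res$retained, "dropped"), collapse = ", "))
      out[[mod]] <- res
    }
    out
  })

  # ---- group comparison --------------------------------------------------
  comparison <- stage("compare", {
    compare_volume_groups(features, cohort,
                          threshold_cm3 = cfg$comparison$threshold_cm3,
                          family = cfg$comparison$family,
                          alpha = cfg$comparison$alpha)
  })
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)

  # ---- modelling ---------------------------------------------------------
  scenario <- stage("model", {
    cand <- default_candidates(cfg$modelling$scenario)
    cand$adc <- character(0)
    cand$t2w <- character(0)
    for (mod in names(selection)) {
      sig <- comparison$feature[comparison$modality == mod & comparison$significant]
      keep <- intersect(as.character(selection[[mod]]$retained), sig)
      slot <- c(ADC = "adc", T2W = "t2w")[[mod]]
      cand[[slot]] <- paste(mod, keep, sep = "_")
      log_line("model candidates (%s): [%s]", mod, paste(keep, collapse = ", "))
    }
    run_scenario(cohort, features, scenario = cfg$modelling$scenario,
                 threshold_cm3 = cfg$comparison$threshold_cm3,
                 candidates = cand, B = cfg$modelling$B,
                 seed = cfg$modelling$seed,
                 categories = c(if (length(cand$adc)) "adc",
                                if (length(cand$t2w)) "t2w", "clinical"))
  })
  utils::write.csv(scenario$report, file.path(out_dir, "models_report.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$univariate, file.path(out_dir, "univariate_roc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = scenario$scenario, n = scenario$n, B = scenario$B,
         seed = scenario$seed, report = scenario$report,
         excluded = as.list(scenario$excluded)),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)

  # ---- exclusion accounting ---------------------------------------------
  utils::write.csv(voi_exclusions, file.path(out_dir, "voi_exclusions.csv"),
                   row.names = FALSE)
  excl <- scenario$excluded
  accounting <- data.frame(reason = c(names(excl), "analyzed"),
                           n = c(as.integer(excl), scenario$n))
  utils::write.csv(accounting, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  log_line("exclusion accounting: cohort %d = analyzed %d + excluded %d",
           nrow(cohort), scenario$n, sum(excl))
  log_line("run completed")

  invisible(list(dir = out_dir, cohort = cohort, features = features,
                 selection = selection, comparison = comparison,
                 scenario = scenario, voi_exclusions = voi_exclusions))
}
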