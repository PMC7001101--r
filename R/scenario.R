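# Scenario orchestration for recurrence prediction in the low-volume arm:
# per-category stepwise models, combined models, nested-model tests, and
# bootstrap optimism correction.

#' Default retained radiomic feature names
#'
#' The de-correlation step on the full texture set typically retains eight
#' features (Contrast and Entropy drop out as near-duplicates of
#' Dissimilarity and Energy).
#'
#' @return Character vector.
#' @export
retained_feature_names <- function() {
  setdiff(texture_feature_names(), c("Contrast", "Entropy"))
}

#' Filter a cohort to a modelling scenario
#'
#' Recurrence is modelled in surgically-treated low-volume patients with
#' known follow-up. Scenario `"all"` keeps all of them (adjuvant therapy
#' becomes a candidate covariate); `"no-adjuvant"` additionally excludes
#' patients who received adjuvant therapy.
#'
#' @param cohort cohort table.
#' @param scenario `"all"` or `"no-adjuvant"`.
#' @param threshold_cm3 low-volume threshold (volume <= threshold).
#' @return The filtered cohort `data.frame` with an `excluded` attribute
#'   itemizing exclusion counts by reason.
#' @export
filter_scenario <- function(cohort, scenario = c("all", "no-adjuvant"),
                            threshold_cm3 = sphere_volume_cm3(2)) {
  scenario <- match.arg(scenario)
  keep <- rep(TRUE, nrow(cohort))
  excl <- c(high_volume = 0L, not_surgical = 0L, no_followup = 0L,
            adjuvant_treated = 0L)
  is_high <- cohort$volume_cm3 > threshold_cm3
  excl["high_volume"] <- sum(keep & is_high); keep <- keep & !is_high
  not_surg <- cohort$treatment != "surgery"
  excl["not_surgical"] <- sum(keep & not_surg); keep <- keep & !not_surg
  no_fu <- cohort$followup == 0L | is.na(cohort$recurrence)
  excl["no_followup"] <- sum(keep & no_fu); keep <- keep & !no_fu
  if (scenario == "no-adjuvant") {
    adj <- cohort$adjuvant == 1L
    excl["adjuvant_treated"] <- sum(keep & adj); keep <- keep & !adj
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded") <- excl
  attr(out, "scenario") <- scenario
  out
}

#' Univariate ROC table for a set of predictors
#'
#' One row per predictor: AUC with DeLong CI, Youden threshold, and
#' sensitivity/specificity (%) at that threshold.
#'
#' @param data modelling data.frame.
#' @param predictors character vector of numeric predictor columns.
#' @param outcome binary outcome column.
#' @return `data.frame`.
#' @export
univariate_roc <- function(data, predictors, outcome = "recurrence") {
  rows <- lapply(predictors, function(p) {
    r <- roc_auc(data[[p]], data[[outcome]])
    data.frame(predictor = p, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2],
               threshold = r$threshold, sensitivity = r$sensitivity,
               specificity = r$specificity, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

default_candidates <- function(scenario) {
  clinical <- c("volume_cm3", "type_adeno", "grade3", "lvsi", "depth_mm", "nodes")
  if (scenario == "all") clinical <- c(clinical, "adjuvant")
  list(adc = paste0("ADC_", retained_feature_names()),
       t2w = paste0("T2W_", retained_feature_names()),
       clinical = clinical)
}

#' Run a recurrence-prediction scenario
#'
#' For each feature category (ADC-radiomic, T2W-radiomic,
#' clinico-pathological): stepwise AIC selection from the category's
#' candidates, ROC of the fitted linear predictor, and bootstrap optimism
#' correction. Combined models add each radiomic category's selected terms
#' to the clinico-pathological terms and are compared with the
#' clinico-pathological model by a likelihood-ratio chi-square test and AIC.
#'
#' @param cohort cohort table (all patients; the scenario filter is applied
#'   internally).
#' @param features long feature table for the cohort.
#' @param scenario `"all"` or `"no-adjuvant"`.
#' @param threshold_cm3 low-volume threshold.
#' @param candidates optional `list(adc =, t2w =, clinical =)` candidate
#'   override.
#' @param B bootstrap resamples (study convention 1000).
#' @param seed mandatory RNG seed for the bootstrap.
#' @param categories subset of `c("adc", "t2w", "clinical")` to run.
#' @return Object of class `scenario_result`: list with `n`, `excluded`,
#'   `models` (per category + combined), `report` (Table-style data.frame)
#'   and `univariate`.
#' @export
run_scenario <- function(cohort, features, scenario = c("all", "no-adjuvant"),
                         threshold_cm3 = sphere_volume_cm3(2),
                         candidates = NULL, B = 1000L, seed,
                         categories = c("adc", "t2w", "clinical")) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  sub <- filter_scenario(cohort, scenario, threshold_cm3)
  if (!nrow(sub)) stop("scenario filter leaves an empty cohort", call. = FALSE)
  wide <- features_wide(features)
  data <- merge(sub, wide, by = "patient_id", sort = TRUE)
  if (is.null(candidates)) candidates <- default_candidates(scenario)
  candidates <- lapply(candidates, function(cs) intersect(cs, names(data)))
  # patients missing any candidate feature (e.g. ineligible VOI) cannot enter
  # the models; they are dropped here and itemized with the exclusions
  cand_cols <- unique(unlist(candidates))
  complete <- if (length(cand_cols))
    stats::complete.cases(data[, cand_cols, drop = FALSE]) else rep(TRUE, nrow(data))
  n_missing <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (!nrow(data)) stop("no patient has complete candidate features", call. = FALSE)
  if (length(unique(data$recurrence)) < 2L)
    stop("filtered cohort lacks both outcome classes; recurrence model undefined",
         call. = FALSE)

  seed_pool <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 10L))
  next_seed <- local({ i <- 0L; function() { i <<- i + 1L; seed_pool[i] } })

  one_category <- function(cand) {
    model <- stepwise_aic(cand, data)
    sc <- model_scores(model)
    roc <- if (length(model$terms)) roc_auc(sc, data$recurrence) else NULL
    val <- bootstrap_validate(model$terms, data, B = B, seed = next_seed())
    list(model = model, roc = roc, validation = val)
  }
  models <- list()
  for (cat in intersect(c("adc", "t2w", "clinical"), categories))
    models[[cat]] <- one_category(candidates[[cat]])

  if ("clinical" %in% names(models)) {
    clin <- models$clinical$model
    for (cat in intersect(c("adc", "t2w"), names(models))) {
      rad_terms <- models[[cat]]$model$terms
      comb_terms <- union(clin$terms, rad_terms)
      comb <- fit_logistic(data, comb_terms)
      lrt <- likelihood_ratio_test(clin, comb)
      sc <- model_scores(comb)
      roc <- if (length(comb_terms)) roc_auc(sc, data$recurrence) else NULL
      val <- bootstrap_validate(comb_terms, data, B = B, seed = next_seed())
      models[[paste0(cat, "_plus_clinical")]] <-
        list(model = comb, roc = roc, validation = val, lrt = lrt)
    }
  }

  label <- c(clinical = "Clinico-pathological", adc = "ADC-Radiomic",
             t2w = "T2W-Radiomic",
             adc_plus_clinical = "ADC-Radiomic + Clinico-pathological",
             t2w_plus_clinical = "T2W-Radiomic + Clinico-pathological")
  report <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(
      model = unname(label[nm]),
      terms = paste(m$model$terms, collapse = " + "),
      auc = if (!is.null(m$roc)) m$roc$auc else NA_real_,
      ci_lo = if (!is.null(m$roc)) m$roc$ci[1] else NA_real_,
      ci_hi = if (!is.null(m$roc)) m$roc$ci[2] else NA_real_,
      corrected_auc = m$validation$corrected_auc,
      aic = m$model$aic,
      resid_df = m$model$n - length(m$model$terms) - 1L,
      resid_deviance = m$model$deviance,
      delta_deviance = if (!is.null(m$lrt)) m$lrt$delta_deviance else NA_real_,
      df = if (!is.null(m$lrt)) m$lrt$df else NA_integer_,
      p_value = if (!is.null(m$lrt)) m$lrt$p else NA_real_,
      stringsAsFactors = FALSE)
  }))

  uni_pred <- intersect(c(paste0("T2W_", retained_feature_names()), "volume_cm3"),
                        names(data))
  structure(list(scenario = scenario, n = nrow(data),
                 excluded = c(attr(sub, "excluded"),
                              missing_features = n_missing),
                 models = models, report = report,
                 univariate = univariate_roc(data, uni_pred),
                 seed = as.integer(seed), B = as.integer(B)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> scenario '%s', n = %d (B = %d)\n",
              x$scenario, x$n, x$B))
  print(x$report[, c("model", "auc", "corrected_auc", "aic", "p_value")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
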