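# Recurrence modelling: logistic fits, stepwise AIC selection, ROC with
# DeLong CI and Youden threshold, nested-model chi-square tests, and
# bootstrap optimism correction through Somers' D.

#' Fit a logistic recurrence model
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`), with
#' explicit convergence and separation flags. Complete separation shows up
#' as fitted probabilities pinned at 0/1 and diverging coefficients; such a
#' fit is flagged rather than silently reported.
#'
#' @param data data.frame containing the outcome and predictors.
#' @param terms character vector of predictor column names (may be empty for
#'   the intercept-only model).
#' @param outcome name of the binary 0/1 outcome column.
#' @return Object of class `recurrence_model`: list with `terms`,
#'   `coefficients`, `deviance`, `aic`, `n`, `converged`, `separation` and
#'   the underlying `fit`.
#' @export
fit_logistic <- function(data, terms = character(0), outcome = "recurrence") {
  y <- data[[outcome]]
  if (is.null(y)) stop(sprintf("outcome column '%s' not found", outcome), call. = FALSE)
  if (anyNA(y)) stop("outcome contains missing values; filter first", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  if (nrow(data) <= length(terms) + 1L)
    stop(sprintf("n = %d too small for %d predictors", nrow(data), length(terms)),
         call. = FALSE)
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  fml <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- sep_warn || any(abs(stats::coef(fit)) > 1e3, na.rm = TRUE)
  structure(list(terms = terms,
                 coefficients = stats::coef(fit),
                 deviance = stats::deviance(fit),
                 aic = stats::AIC(fit),
                 n = nrow(data),
                 converged = fit$converged && !separation,
                 separation = separation,
                 outcome = outcome,
                 fit = fit),
            class = "recurrence_model")
}

#' @export
print.recurrence_model <- function(x, ...) {
  cat(sprintf("<recurrence_model> %s ~ %s\n", x$outcome,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cat(sprintf("  n=%d  deviance=%.3f  AIC=%.3f  converged=%s%s\n",
              x$n, x$deviance, x$aic, x$converged,
              if (x$separation) "  [SEPARATION]" else ""))
  invisible(x)
}

#' Linear predictor of a recurrence model
#'
#' @param model a [fit_logistic()] result.
#' @param newdata optional data.frame; defaults to the fitting data.
#' @return Numeric vector of linear-predictor scores.
#' @export
model_scores <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "recurrence_model"))
  if (is.null(newdata)) unname(model$fit$linear.predictors)
  else unname(stats::predict(model$fit, newdata = newdata, type = "link"))
}

#' Stepwise AIC model selection
#'
#' Forward-backward search starting from the intercept-only model: at each
#' step the single addition or removal that lowers AIC the most is applied;
#' the search stops when no move lowers AIC. Deterministic given the data.
#'
#' @param candidates character vector of candidate predictor columns.
#' @param data data.frame, complete for the candidates.
#' @param outcome binary outcome column name.
#' @param direction passed to `stats::step` (default `"both"`).
#' @return A [fit_logistic()]-style `recurrence_model` for the selected term
#'   set.
#' @export
stepwise_aic <- function(candidates, data, outcome = "recurrence",
                         direction = "both") {
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  if (anyNA(data[, c(outcome, candidates)]))
    stop("data must be complete for outcome and candidates", call. = FALSE)
  null_fml <- stats::as.formula(paste(sprintf("`%s`", outcome), "~ 1"))
  upper_fml <- stats::as.formula(
    paste("~", paste(sprintf("`%s`", candidates), collapse = " + ")))
  null_fit <- stats::glm(null_fml, family = stats::binomial(), data = data,
                         control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  selected <- suppressWarnings(
    stats::step(null_fit, scope = list(lower = ~1, upper = upper_fml),
                direction = direction, trace = 0))
  sel_terms <- attr(stats::terms(selected), "term.labels")
  sel_terms <- gsub("`", "", sel_terms)
  fit_logistic(data, sel_terms, outcome = outcome)
}

auc_concordance <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present for ROC analysis", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)  # midranks: ties get 0.5 credit automatically
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of a score
#'
#' AUC is the concordance probability (ties credited 1/2), its 95% CI by
#' DeLong's method (clipped to \[0, 1\]); the operating threshold maximizes
#' Youden's J = sensitivity + specificity - 1 over the observed scores
#' (classification rule: score >= threshold is positive; J ties break to the
#' lower threshold). Sensitivity and specificity are reported in percent.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 outcome.
#' @param with_threshold also compute the Youden threshold (default TRUE).
#' @return Object of class `roc_result`: list(auc, ci, threshold,
#'   sensitivity, specificity, n_pos, n_neg).
#' @export
roc_auc <- function(scores, labels, with_threshold = TRUE) {
  labels <- as.integer(labels)
  auc <- auc_concordance(scores, labels)
  ci <- tryCatch(suppressWarnings({
    # pROC warns that a degenerate AUC = 1 curve yields the CI [1, 1]; that
    # is exactly the clipped bound we report
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))
  ci <- pmin(pmax(ci, 0), 1)
  threshold <- sens <- spec <- NA_real_
  if (with_threshold) {
    cand <- sort(unique(scores))
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    best_j <- -Inf
    for (t in cand) {
      se <- sum(scores >= t & labels == 1L) / n1
      sp <- sum(scores < t & labels == 0L) / n0
      j <- se + sp - 1
      if (j > best_j + 1e-12) {  # strict improvement => lowest threshold on ties
        best_j <- j; threshold <- t; sens <- se; spec <- sp
      }
    }
    sens <- 100 * sens; spec <- 100 * spec
  }
  structure(list(auc = auc, ci = ci, threshold = threshold,
                 sensitivity = sens, specificity = spec,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f)", x$auc, x$ci[1], x$ci[2]))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold %.3g: sens %.0f%%, spec %.0f%%",
                x$threshold, x$sensitivity, x$specificity))
  cat("\n")
  invisible(x)
}

#' Somers' D rank correlation of a score with a binary outcome
#'
#' D = 2 AUC - 1; equivalently AUC = (1 + D) / 2.
#'
#' @inheritParams roc_auc
#' @return Somers' D in \[-1, 1\].
#' @export
somers_d <- function(scores, labels) {
  2 * auc_concordance(scores, as.integer(labels)) - 1
}

#' Likelihood-ratio (chi-square) test of nested logistic models
#'
#' @param nested,full [fit_logistic()] results on the same rows, with the
#'   nested model's terms a subset of the full model's.
#' @return list(delta_deviance, df, p).
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "recurrence_model"), inherits(full, "recurrence_model"))
  if (!all(nested$terms %in% full$terms))
    stop("models are not nested (nested terms must be a subset of full terms)",
         call. = FALSE)
  if (nested$n != full$n)
    stop("models were fitted on different numbers of rows", call. = FALSE)
  dd <- nested$deviance - full$deviance
  df <- length(full$terms) - length(nested$terms)
  p <- if (df == 0L) 1 else stats::pchisq(dd, df = df, lower.tail = FALSE)
  list(delta_deviance = dd, df = df, p = p)
}

#' Chi-square p-value for a printed deviance difference
#'
#' Convenience for auditing reported nested-model rows from their printed
#' deviance change and degrees of freedom.
#'
#' @param delta_deviance deviance difference.
#' @param df degrees of freedom.
#' @return Upper-tail chi-square p-value.
#' @export
deviance_chisq_p <- function(delta_deviance, df) {
  if (df == 0) return(1)
  stats::pchisq(delta_deviance, df = df, lower.tail = FALSE)
}

#' Bootstrap optimism correction of model discrimination
#'
#' Refits the FIXED term set on `B` bootstrap resamples (with replacement,
#' original n). For each resample, optimism is the Somers' D of the refit on
#' its own resample minus its D on the original data; the corrected D is the
#' apparent D minus the mean optimism, and the corrected AUC is
#' (1 + corrected D)/2 — equivalently apparent AUC minus the mean optimism
#' on the AUC scale, which is what the result reports. Resamples with a
#' single-class outcome or a non-converged fit are redrawn and counted; if
#' more than half of all draws are unusable the procedure aborts.
#'
#' @param terms character vector of model terms (fixed; selection is not
#'   repeated inside the loop unless `reselect` names candidates).
#' @param data model data.frame.
#' @param outcome binary outcome column.
#' @param B number of bootstrap resamples (the study convention is 1000).
#' @param seed mandatory RNG seed, recorded in the result.
#' @param reselect optional candidate set: when given, stepwise selection is
#'   repeated inside every resample (honest-validation variant).
#' @return Object of class `validation_result`: list(apparent_auc,
#'   mean_optimism, corrected_auc, apparent_d, corrected_d, B, seed,
#'   n_redrawn).
#' @export
bootstrap_validate <- function(terms, data, outcome = "recurrence", B = 1000L,
                               seed, reselect = NULL) {
  if (missing(seed)) stop("`seed` is mandatory for bootstrap validation", call. = FALSE)
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  apparent_model <- fit_logistic(data, terms, outcome = outcome)
  y <- data[[outcome]]
  d_app <- somers_d(model_scores(apparent_model), y)
  n <- nrow(data)
  optimism <- numeric(B)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        boot <- data[idx, , drop = FALSE]
        if (length(unique(boot[[outcome]])) < 2L) {
          n_redrawn <- n_redrawn + 1L
        } else {
          fit_b <- tryCatch({
            if (is.null(reselect)) fit_logistic(boot, terms, outcome = outcome)
            else stepwise_aic(reselect, boot, outcome = outcome)
          }, error = function(e) NULL)
          # usability = the IRLS converged; a quasi-separated resample still
          # ranks patients and contributes its (large) optimism honestly
          if (is.null(fit_b) || !fit_b$fit$converged) {
            n_redrawn <- n_redrawn + 1L
          } else {
            d_boot <- somers_d(model_scores(fit_b), boot[[outcome]])
            d_orig <- somers_d(model_scores(fit_b, newdata = data), y)
            optimism[b] <- d_boot - d_orig
            break
          }
        }
        if (n_redrawn > B)
          stop(sprintf("bootstrap validation aborted: %d unusable resamples against %d target draws",
                       n_redrawn, B), call. = FALSE)
      }
    }
  })
  mean_opt_d <- mean(optimism)
  d_corr <- d_app - mean_opt_d
  structure(list(apparent_auc = (1 + d_app) / 2,
                 mean_optimism = mean_opt_d / 2,
                 corrected_auc = (1 + d_corr) / 2,
                 apparent_d = d_app,
                 corrected_d = d_corr,
                 B = B, seed = as.integer(seed), n_redrawn = n_redrawn),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> apparent AUC %.3f, optimism %.3f, corrected AUC %.3f (B=%d, seed=%d)\n",
              x$apparent_auc, x$mean_optimism, x$corrected_auc, x$B, x$seed))
  invisible(x)
}
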