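# Volume-dichotomized group comparison: Shapiro-Wilk gate, Mann-Whitney U
# with Bonferroni correction, one row per feature x modality.

#' Shapiro-Wilk normality test
#'
#' Used only to gate reporting: whatever it says, the comparison pipeline
#' proceeds nonparametrically (the texture features are skewed).
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return list(W, p).
#' @export
shapiro_wilk_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n), call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("Shapiro-Wilk undefined for a constant sample", call. = FALSE)
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

#' Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with a > b, counting ties 1/2. The
#' two-sided p-value is exact (full permutation distribution) when
#' nA + nB <= 12 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param group_a,group_b nonempty numeric samples.
#' @return list(U, p, exact) where `U` is for `group_a`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty", call. = FALSE)
  n_a <- length(group_a); n_b <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- (n_a + n_b) <= 12L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p = unname(res$p.value), exact = use_exact)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a declared family size `m` (which may exceed
#' the number of p-values actually supplied).
#'
#' @param pvals raw p-values in \[0, 1\].
#' @param m family size, `m >= length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(pvals))
    stop("family size `m` must be >= length(pvals)", call. = FALSE)
  pmin(1, m * pvals)
}

#' Compare texture features between volume-dichotomized groups
#'
#' Dichotomizes patients at the volume threshold (low = volume <= threshold,
#' boundary inclusive to low), then for every feature within every modality
#' reports group medians and IQRs, the Mann-Whitney U statistic and raw
#' p-value, and the Bonferroni-adjusted p-value. The family is, by default,
#' the number of features tested within each modality (adjusted separately
#' per modality); `family = "pooled"` adjusts across both modalities at once.
#'
#' @param features long feature table (one row per patient x modality).
#' @param cohort cohort table with `patient_id` and `volume_cm3`.
#' @param threshold_cm3 dichotomization threshold (default the 2-cm-sphere
#'   volume, 4.19 cm^3).
#' @param family `"per-modality"` or `"pooled"` Bonferroni family.
#' @param feature_names features to test (default all ten).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return `data.frame` (one row per feature x modality): medians, IQRs,
#'   group sizes, U, p, p_adj, significant; with attributes `threshold_cm3`
#'   and `family_size`.
#' @export
compare_volume_groups <- function(features, cohort,
                                  threshold_cm3 = sphere_volume_cm3(2),
                                  family = c("per-modality", "pooled"),
                                  feature_names = texture_feature_names(),
                                  alpha = 0.05) {
  family <- match.arg(family)
  if (!(threshold_cm3 > 0)) stop("`threshold_cm3` must be > 0", call. = FALSE)
  vol <- cohort$volume_cm3[match(features$patient_id, cohort$patient_id)]
  if (anyNA(vol))
    stop("every feature table row needs a cohort volume (patient_id mismatch)",
         call. = FALSE)
  grp <- ifelse(vol <= threshold_cm3, "low", "high")
  if (!any(grp == "low") || !any(grp == "high"))
    stop(sprintf("volume threshold %.3g cm^3 leaves an empty group", threshold_cm3),
         call. = FALSE)
  rows <- list()
  for (mod in unique(features$modality)) {
    sel <- features$modality == mod
    for (fn in feature_names) {
      lo <- features[sel & grp == "low", fn]
      hi <- features[sel & grp == "high", fn]
      mw <- mann_whitney_u(lo, hi)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fn, modality = mod,
        n_low = length(lo), n_high = length(hi),
        median_low = stats::median(lo), iqr_low = stats::IQR(lo),
        median_high = stats::median(hi), iqr_high = stats::IQR(hi),
        U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "per-modality") {
    out$p_adj <- NA_real_
    for (mod in unique(out$modality)) {
      idx <- out$modality == mod
      out$p_adj[idx] <- bonferroni_adjust(out$p[idx], m = sum(idx))
    }
    fam_size <- length(feature_names)
  } else {
    out$p_adj <- bonferroni_adjust(out$p, m = nrow(out))
    fam_size <- nrow(out)
  }
  out$significant <- out$p_adj < alpha
  attr(out, "threshold_cm3") <- threshold_cm3
  attr(out, "family_size") <- fam_size
  out
}
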