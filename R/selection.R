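# Feature de-correlation: cluster redundant features, keep one representative
# per cluster (greatest dynamic range), then prune residual high correlations.

feature_matrix <- function(table) {
  if (is.matrix(table)) table <- as.data.frame(table)
  drop_cols <- c("patient_id", "modality", "voxel_count", "volume_cm3")
  x <- table[, setdiff(names(table), drop_cols), drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (!ncol(x)) stop("no numeric feature columns found", call. = FALSE)
  x
}

#' Feature-feature correlation matrix
#'
#' Spearman by default: the texture features are not normally distributed
#' (Shapiro-Wilk), so rank correlation is the safer redundancy measure.
#'
#' @param table data.frame of feature columns (id/bookkeeping columns are
#'   ignored); at least 3 rows, no missing values.
#' @param method `"spearman"` or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- feature_matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 rows to correlate features", call. = FALSE)
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("zero-variance feature(s): %s",
                 paste(names(x)[sds == 0], collapse = ", ")), call. = FALSE)
  stats::cor(x, method = method)
}

#' Cluster features on correlation distance
#'
#' Agglomerative (complete-linkage) clustering on the dissimilarity
#' d = 1 - |r|, cut at `k` clusters. Anticorrelated features are treated as
#' redundant (sign-agnostic distance).
#'
#' @param corr correlation matrix from [feature_correlation()].
#' @param k number of clusters, 1..n_features.
#' @return Object of class `cluster_assignment`: list with `cluster` (named
#'   feature -> id vector, ids contiguous 1..k), `k`, and the `hclust` tree.
#' @export
cluster_features <- function(corr, k) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  n <- nrow(corr)
  if (k < 1L || k > n)
    stop(sprintf("`k` must be between 1 and the number of features (%d)", n),
         call. = FALSE)
  d <- stats::as.dist(1 - abs(corr))
  tree <- stats::hclust(d, method = "complete")
  assignment <- stats::cutree(tree, k = k)
  structure(list(cluster = assignment, k = as.integer(k), tree = tree),
            class = "cluster_assignment")
}

dynamic_range <- function(x, scaling = c("raw", "rank")) {
  scaling <- match.arg(scaling)
  if (scaling == "rank") x <- rank(x) / length(x)
  diff(range(x))
}

#' Select one representative feature per cluster
#'
#' Within each cluster the feature with the greatest dynamic range
#' (max - min, on raw values by default) is kept; ties break to the
#' alphabetically first name.
#'
#' @param assignment a [cluster_features()] result.
#' @param table the feature table the clustering was computed on.
#' @param scaling `"raw"` or `"rank"` dynamic-range scale.
#' @return Character vector of representative names, ordered by cluster id.
#' @export
select_representatives <- function(assignment, table,
                                   scaling = c("raw", "rank")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(assignment, "cluster_assignment"))
  x <- feature_matrix(table)
  feats <- names(assignment$cluster)
  missing_f <- setdiff(feats, names(x))
  if (length(missing_f))
    stop(sprintf("assignment covers feature(s) absent from table: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  vapply(seq_len(assignment$k), function(cl) {
    members <- sort(feats[assignment$cluster == cl])
    rng <- vapply(members, function(f) dynamic_range(x[[f]], scaling), numeric(1))
    members[which.max(rng)]  # which.max takes the first on ties => alphabetical
  }, character(1))
}

#' Prune residual high correlations among representatives
#'
#' Greedy: while any representative pair has |r| above the threshold, take
#' the worst pair and drop its member with the smaller dynamic range (tie:
#' drop the alphabetically later name). Guarantees max pairwise |r| <=
#' threshold on exit.
#'
#' @param selected character vector of representative features.
#' @param table the feature table.
#' @param r_threshold correlation threshold (default 0.9).
#' @param method correlation type, as [feature_correlation()].
#' @param scaling dynamic-range scale.
#' @return The pruned character vector, with a `dropped` attribute naming
#'   removed features.
#' @export
prune_correlated <- function(selected, table, r_threshold = 0.9,
                             method = c("spearman", "pearson"),
                             scaling = c("raw", "rank")) {
  method <- match.arg(method)
  scaling <- match.arg(scaling)
  x <- feature_matrix(table)
  missing_f <- setdiff(selected, names(x))
  if (length(missing_f))
    stop(sprintf("selected feature(s) absent from table: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  keep <- sort(selected)
  dropped <- character(0)
  while (length(keep) >= 2L) {
    r <- abs(stats::cor(x[, keep, drop = FALSE], method = method))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]  # row-major first: deterministic
    pair <- c(keep[worst[1]], keep[worst[2]])
    rng <- vapply(pair, function(f) dynamic_range(x[[f]], scaling), numeric(1))
    victim <- if (rng[1] < rng[2]) pair[1]
              else if (rng[2] < rng[1]) pair[2]
              else sort(pair)[2]
    keep <- setdiff(keep, victim)
    dropped <- c(dropped, victim)
  }
  out <- selected[selected %in% keep]
  attr(out, "dropped") <- dropped
  out
}

#' Full de-correlation step
#'
#' Correlate, cluster at `k`, pick representatives, prune at `r_threshold`.
#'
#' @inheritParams feature_correlation
#' @inheritParams cluster_features
#' @inheritParams prune_correlated
#' @return list(correlation, assignment, representatives, retained).
#' @export
decorrelate_features <- function(table, k = 10L, method = "spearman",
                                 r_threshold = 0.9, scaling = "raw") {
  corr <- feature_correlation(table, method = method)
  assignment <- cluster_features(corr, k = min(k, ncol(corr)))
  reps <- select_representatives(assignment, table, scaling = scaling)
  retained <- prune_correlated(reps, table, r_threshold = r_threshold,
                               method = method, scaling = scaling)
  list(correlation = corr, assignment = assignment,
       representatives = reps, retained = retained)
}
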