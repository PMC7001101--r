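#' Names of the GLCM texture features computed per VOI
#'
#' The ten second-order features retained after redundancy clustering of the
#' full Haralick set: Dissimilarity, Contrast, Energy, Entropy,
#' ClusterProminence, ClusterShade, InverseVariance, Correlation,
#' Autocorrelation and InformationalMeasureCorrelation2.
#'
#' @return Character vector of feature names in canonical column order.
#' @export
texture_feature_names <- function() {
  c("Dissimilarity", "Contrast", "Energy", "Entropy", "ClusterProminence",
    "ClusterShade", "InverseVariance", "Correlation", "Autocorrelation",
    "InformationalMeasureCorrelation2")
}

feature_table_columns <- function() {
  c("patient_id", "modality", texture_feature_names(), "voxel_count", "volume_cm3")
}

#' Assemble a per-(patient, modality) feature table
#'
#' @param rows list of single-row data.frames or named lists with the fixed
#'   feature-table schema: patient id, modality, the ten texture
#'   features, voxel count and VOI volume (cm^3).
#' @return A `data.frame` with fixed column order.
#' @export
feature_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  validate_feature_table(df)
  df[, feature_table_columns()]
}

validate_feature_table <- function(df, require_complete = FALSE) {
  missing_cols <- setdiff(feature_table_columns(), names(df))
  if (length(missing_cols))
    stop(sprintf("feature table is missing columns: %s (expected schema: %s)",
                 paste(missing_cols, collapse = ", "),
                 paste(feature_table_columns(), collapse = ", ")), call. = FALSE)
  key <- paste(df$patient_id, df$modality)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (patient, modality) rows: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Write a feature table to CSV
#'
#' UTF-8, header row, "." decimal, fixed column order. Duplicate
#' (patient, modality) rows are refused.
#'
#' @param table feature table `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  utils::write.csv(table[, feature_table_columns()], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Unknown columns are an error (with the expected schema in the message).
#' Rows with missing feature values are kept but flagged: the returned table
#' carries an `incomplete_rows` attribute with their indices.
#'
#' @param path CSV path written by [write_feature_table()].
#' @return The feature table `data.frame`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("feature table file does not exist: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  unknown <- setdiff(names(df), feature_table_columns())
  if (length(unknown))
    stop(sprintf("unknown feature table column(s): %s (expected schema: %s)",
                 paste(unknown, collapse = ", "),
                 paste(feature_table_columns(), collapse = ", ")), call. = FALSE)
  validate_feature_table(df)
  num_cols <- c(texture_feature_names(), "voxel_count", "volume_cm3")
  incomplete <- which(apply(is.na(df[, num_cols, drop = FALSE]), 1, any))
  if (length(incomplete))
    warning(sprintf("%d feature table row(s) incomplete (missing values): rows %s",
                    length(incomplete), paste(incomplete, collapse = ", ")),
            call. = FALSE)
  attr(df, "incomplete_rows") <- incomplete
  df
}

#' Pivot a long feature table to one row per patient
#'
#' Feature columns are prefixed by modality (`ADC_Dissimilarity`,
#' `T2W_Energy`, ...), the layout the recurrence models consume.
#'
#' @param table long feature table (one row per patient x modality).
#' @return Wide `data.frame`, one row per patient.
#' @export
features_wide <- function(table) {
  validate_feature_table(table)
  pats <- unique(table$patient_id)
  out <- data.frame(patient_id = pats, stringsAsFactors = FALSE)
  for (mod in unique(table$modality)) {
    sub <- table[table$modality == mod, , drop = FALSE]
    block <- sub[match(pats, sub$patient_id), texture_feature_names(), drop = FALSE]
    names(block) <- paste(mod, texture_feature_names(), sep = "_")
    out <- cbind(out, block)
  }
  rownames(out) <- NULL
  out
}
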