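# Clinical-table cleaning, per-patient aggregation of nucleus features,
# and Cox design-matrix assembly.

#' Clean a raw clinical table
#'
#' Maps the categorical immunohistochemistry coding `"neg"`/`"pos"`/
#' `"no data"` to 0/1/`NA` in character columns, passes numeric columns
#' through unchanged, and drops rows lacking `OS` or `FUS` (with a
#' message reporting the count).
#'
#' @param raw data.frame (or CSV path) with at least `patient_id`, `OS`
#'   (years) and `FUS` (event indicator) columns.
#' @return Cleaned `data.frame`; errors on duplicate patient ids.
#' @export
clean_clinical <- function(raw) {
  df <- if (is.character(raw)) utils::read.csv(raw, stringsAsFactors = FALSE,
                                               check.names = FALSE)
        else as.data.frame(raw)
  need <- c("patient_id", "OS", "FUS")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("clinical table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop("duplicate patient_id in clinical table: ",
         paste(unique(dup), collapse = ", "))
  for (col in setdiff(names(df), "patient_id")) {
    if (is.character(df[[col]])) {
      v <- tolower(trimws(df[[col]]))
      mapped <- ifelse(v == "pos", 1,
                ifelse(v == "neg", 0,
                ifelse(v == "no data" | v == "", NA, NA)))
      known <- v %in% c("pos", "neg", "no data", "") | is.na(df[[col]])
      if (all(known)) {
        df[[col]] <- as.numeric(mapped)
      } else {
        num <- suppressWarnings(as.numeric(df[[col]]))
        if (all(is.na(num) == is.na(df[[col]]) | v %in% c("no data", "")))
          df[[col]] <- ifelse(v %in% c("no data", ""), NA, num)
        # otherwise: leave free-text column untouched
      }
    }
  }
  df$OS <- as.numeric(df$OS)
  df$FUS <- as.numeric(df$FUS)
  drop <- is.na(df$OS) | is.na(df$FUS)
  if (any(drop)) {
    message("clean_clinical: dropped ", sum(drop),
            " row(s) lacking OS or FUS")
    df <- df[!drop, , drop = FALSE]
  }
  if (any(df$OS < 0)) stop("negative OS in clinical table")
  if (!all(df$FUS %in% c(0, 1))) stop("FUS must be 0 or 1")
  rownames(df) <- NULL
  df
}

#' Aggregate one patient's nucleus features
#'
#' Arithmetic mean and sample (n-1) standard deviation of each numeric
#' geometric feature across the patient's nuclei. A single-nucleus
#' patient gets `NA` standard deviations.
#'
#' @param features data.frame of per-nucleus feature rows (cell_shapes
#'   dialect), all with the same `patient_id`.
#' @param feature_cols Numeric columns to aggregate (defaults to the 13
#'   scalar geometry columns; angles and tuple columns are excluded).
#' @return One-row data.frame: `patient_id`, then `{feature}_mean` and
#'   `{feature}_std` per feature.
#' @export
aggregate_patient <- function(features,
                              feature_cols = CELL_SHAPE_FEATURES) {
  if (nrow(features) == 0L) stop("empty feature list")
  pid <- unique(features$patient_id)
  if (length(pid) != 1L)
    stop("aggregate_patient expects a single patient, got: ",
         paste(pid, collapse = ", "))
  feature_cols <- intersect(feature_cols, names(features))
  out <- list(patient_id = pid)
  for (f in feature_cols) {
    v <- features[[f]]
    out[[paste0(f, "_mean")]] <- mean(v)
    out[[paste0(f, "_std")]] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aggregate all patients in a feature table
#'
#' @param features cell_shapes-style data.frame covering many patients.
#' @param feature_cols See [aggregate_patient()].
#' @return data.frame with one row per patient, ordered by patient id.
#' @export
aggregate_patients <- function(features,
                               feature_cols = CELL_SHAPE_FEATURES) {
  rows <- lapply(split(features, features$patient_id), aggregate_patient,
                 feature_cols = feature_cols)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a Cox design matrix
#'
#' Inner-joins per-patient feature vectors with the clinical table on
#' `patient_id`, selects the requested feature set, imputes missing
#' covariates, drops zero-variance columns with a warning, and z-scores
#' every column. Never fabricates patients: the output has exactly one
#' row per id present in both tables.
#'
#' @param patient_features data.frame from [aggregate_patients()] (may
#'   be `NULL` for `feature_set = "clinical"`).
#' @param clinical Cleaned clinical table (see [clean_clinical()]).
#' @param feature_set `"clinical"`, `"geometric"`, or `"both"`.
#' @param clinical_covariates Which clinical columns form the clinical
#'   feature set; default: all numeric clinical columns except
#'   `OS`/`FUS`.
#' @param impute `"mean"` (column-mean imputation, default) or
#'   `"complete"` (drop rows with any missing covariate).
#' @return List of class `design_matrix`: `X` (standardized numeric
#'   matrix), `time` (OS), `event` (FUS), `patient_id`, `feature_set`.
#' @export
assemble_design <- function(patient_features, clinical,
                            feature_set = c("both", "clinical", "geometric"),
                            clinical_covariates = NULL,
                            impute = c("mean", "complete")) {
  feature_set <- match.arg(feature_set)
  impute <- match.arg(impute)
  if (is.null(clinical_covariates)) {
    num <- vapply(clinical, is.numeric, logical(1))
    clinical_covariates <- setdiff(names(clinical)[num], c("OS", "FUS"))
  }
  if (feature_set == "clinical") {
    joined <- clinical
    cols <- clinical_covariates
  } else {
    if (is.null(patient_features) || nrow(patient_features) == 0L)
      stop("feature_set '", feature_set, "' needs patient features")
    joined <- merge(patient_features, clinical, by = "patient_id")
    geom_cols <- setdiff(names(patient_features), "patient_id")
    cols <- switch(feature_set,
                   geometric = geom_cols,
                   both = c(clinical_covariates, geom_cols))
  }
  if (nrow(joined) == 0L)
    stop("empty intersection of feature and clinical patient ids")
  X <- as.matrix(joined[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (impute == "complete") {
    keep <- stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]
    joined <- joined[keep, , drop = FALSE]
  } else {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  allna <- apply(X, 2, function(v) all(is.na(v) | is.nan(v)))
  sds <- apply(X, 2, stats::sd)
  bad <- allna | is.na(sds) | sds == 0
  if (any(bad)) {
    warning("dropping zero-variance or all-missing column(s): ",
            paste(colnames(X)[bad], collapse = ", "))
    X <- X[, !bad, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no usable covariate columns remain")
  X <- scale(X)
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  structure(list(X = X, time = joined$OS, event = joined$FUS,
                 patient_id = joined$patient_id,
                 feature_set = feature_set),
            class = "design_matrix")
}
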