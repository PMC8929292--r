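#' @keywords internal
"_PACKAGE"

# Demographic columns every feature table must carry (education optional).
.demo_required <- c("subject_id", "group", "age", "gender")
.demo_optional <- c("education")

#' Feature columns of a table
#'
#' @param table A feature table (data.frame).
#' @return Character vector of the `<modality>:<index>:<region>` feature
#'   column names, in the order they appear.
#' @export
feature_cols <- function(table) {
  grep("^(sMRI|fMRI|DTI):", names(table), value = TRUE)
}

#' Validate a subject-by-feature table
#'
#' Checks the contract every downstream stage relies on: required
#' demographic columns present, no duplicate subject ids, valid group
#' labels (`NC`/`SZ`) and gender codes (`0`/`1`), feature names that
#' follow the `<modality>:<index>:<region>` convention with a valid
#' index-modality pairing, all feature values finite, and (optionally)
#' an exact match against an expected name set.
#'
#' @param table A data.frame.
#' @param expected_names Optional character vector; when given, the
#'   table's feature columns must be exactly this set.
#' @return The validated table, invisibly, with feature columns
#'   reordered into canonical order.
#' @export
validate_feature_table <- function(table, expected_names = NULL) {
  stopifnot(is.data.frame(table))
  missing_demo <- setdiff(.demo_required, names(table))
  if (length(missing_demo))
    stop("missing demographic column(s): ",
         paste(missing_demo, collapse = ", "), call. = FALSE)
  ids <- as.character(table$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(table$group %in% c("NC", "SZ")))
    stop("`group` must be 'NC' or 'SZ'", call. = FALSE)
  if (!all(table$gender %in% c(0, 1)))
    stop("`gender` must be coded 0/1", call. = FALSE)
  if (!is.numeric(table$age) || any(!is.finite(table$age)))
    stop("`age` must be finite numeric", call. = FALSE)

  feats <- feature_cols(table)
  if (length(feats) == 0L)
    stop("table has no feature columns", call. = FALSE)
  extra <- setdiff(names(table), c(.demo_required, .demo_optional, feats))
  if (length(extra))
    stop("column(s) violate the feature naming convention: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  parse_feature_names(feats)   # errors on bad modality/index/region
  if (anyDuplicated(feats))
    stop("duplicate feature column(s)", call. = FALSE)

  for (f in feats) {
    v <- table[[f]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      row <- which(!is.finite(as.numeric(v)))[1L]
      stop(sprintf("non-finite value in feature '%s' at row %d (subject %s)",
                   f, row, ids[row]), call. = FALSE)
    }
  }

  if (!is.null(expected_names)) {
    if (!setequal(feats, expected_names))
      stop("feature columns do not match the expected name set (",
           length(setdiff(expected_names, feats)), " missing, ",
           length(setdiff(feats, expected_names)), " unexpected)",
           call. = FALSE)
  }

  # normalize column order: demographics first, then canonical feature order
  canon <- build_feature_names()
  ord <- feats[order(match(feats, canon))]
  demo <- intersect(c(.demo_required, .demo_optional), names(table))
  invisible(table[, c(demo, ord), drop = FALSE])
}

#' Read a feature table from CSV
#'
#' The exchange format is UTF-8 comma-separated text with a mandatory
#' header row, one row per subject, demographic columns plus feature
#' columns named per [build_feature_names()]. The table is validated on
#' read (see [validate_feature_table()]) and returned with columns in
#' canonical order.
#'
#' @param path Path to the CSV file.
#' @param expected_names Optional expected feature-name set.
#' @return A validated feature table (data.frame).
#' @export
read_feature_table <- function(path, expected_names = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  tab$subject_id <- as.character(tab$subject_id)
  validate_feature_table(tab, expected_names)
}

#' Write a feature table to CSV
#'
#' Floats are written with 17 significant digits so a write/read
#' round-trip reproduces the table exactly.
#'
#' @param table A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a feature table to a modality subset
#'
#' Demographics are preserved; only the feature columns of the requested
#' modalities are retained. Mirrors the modality-ablation analyses in
#' which the identical pipeline is re-run per modality combination.
#'
#' @param table A feature table.
#' @param modalities Non-empty subset of `c("sMRI", "fMRI", "DTI")`.
#' @return A feature table with the reduced feature set.
#' @export
subset_modalities <- function(table, modalities) {
  if (length(modalities) == 0L)
    stop("at least one modality is required", call. = FALSE)
  bad <- setdiff(modalities, .modalities)
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  feats <- feature_cols(table)
  keep <- feats[sub(":.*$", "", feats) %in% modalities]
  if (length(keep) == 0L)
    stop("no feature columns remain for modalities: ",
         paste(modalities, collapse = ", "), call. = FALSE)
  demo <- intersect(c(.demo_required, .demo_optional), names(table))
  table[, c(demo, keep), drop = FALSE]
}

# internal: feature matrix + demographics split
.feature_matrix <- function(table) {
  feats <- feature_cols(table)
  m <- as.matrix(table[, feats, drop = FALSE])
  rownames(m) <- as.character(table$subject_id)
  m
}
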