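#' Subject-by-ROI thickness table
#'
#' Container for region-of-interest (ROI) cortical thickness values: one row
#' per subject, one column per atlas ROI, plus a two-level group factor.
#'
#' @param values numeric matrix, subjects x ROIs, thickness in mm. Row names
#'   are taken as subject ids when `subject_id` is missing.
#' @param group factor or character vector with one entry per subject and
#'   exactly two levels (the first level is treated as group 1).
#' @param subject_id character vector of unique subject identifiers.
#' @param roi_labels character vector of unique ROI names; defaults to the
#'   column names of `values`.
#' @param residualized logical; residualized tables may contain non-positive
#'   values, raw thickness must be strictly positive.
#' @return an object of class `thickness_table`.
#' @export
thickness_table <- function(values, group, subject_id = rownames(values),
                            roi_labels = colnames(values),
                            residualized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(subject_id)) subject_id <- sprintf("sub%03d", seq_len(n))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique")
  if (length(subject_id) != n) stop("subject_id length does not match rows")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI_%03d", seq_len(ncol(values)))
  roi_labels <- as.character(roi_labels)
  if (anyDuplicated(roi_labels)) stop("roi_labels must be unique")
  if (length(roi_labels) != ncol(values)) stop("roi_labels length does not match columns")
  if (anyNA(values)) stop("thickness values contain missing entries")
  if (!residualized && any(values <= 0))
    stop("raw thickness values must be positive (mm)")
  group <- as.factor(group)
  if (length(group) != n) stop("group length does not match number of subjects")
  group <- droplevels(group)
  if (nlevels(group) != 2) stop("exactly two non-empty groups are required")
  dimnames(values) <- list(subject_id, roi_labels)
  structure(list(values = values, group = group,
                 subject_id = subject_id, roi_labels = roi_labels,
                 residualized = isTRUE(residualized)),
            class = "thickness_table")
}

#' @export
print.thickness_table <- function(x, ...) {
  cat(sprintf("thickness_table: %d subjects x %d ROIs (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$residualized) "residualized" else "raw, mm"))
  tab <- table(x$group)
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.thickness_table <- function(x) dim(x$values)

#' Per-subject covariate table
#'
#' @param df data.frame with a `subject_id` column and numeric covariate
#'   columns (typically `age` in years, `gender` coded 0/1, `education` in
#'   years).
#' @return an object of class `covariate_table` (a data.frame).
#' @export
covariate_table <- function(df) {
  df <- as.data.frame(df)
  if (!"subject_id" %in% names(df)) stop("covariate table needs a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in covariate table")
  covs <- setdiff(names(df), "subject_id")
  if (length(covs) == 0) stop("covariate table has no covariate columns")
  for (v in covs) {
    if (!is.numeric(df[[v]])) stop(sprintf("covariate '%s' is not numeric", v))
    if (anyNA(df[[v]])) stop(sprintf("covariate '%s' has missing values", v))
  }
  class(df) <- c("covariate_table", "data.frame")
  df
}

covariate_matrix <- function(covs, subject_id) {
  stopifnot(inherits(covs, "covariate_table") || is.data.frame(covs))
  idx <- match(subject_id, covs$subject_id)
  if (anyNA(idx))
    stop("covariate table is missing subjects: ",
         paste(subject_id[is.na(idx)], collapse = ", "))
  vars <- setdiff(names(covs), "subject_id")
  as.matrix(covs[idx, vars, drop = FALSE])
}

#' Left/right homologue map
#'
#' Pairs each left-hemisphere ROI label with its right-hemisphere homologue;
#' labels without a partner go in `unpaired`. Used for table-level hemisphere
#' swapping of selected subjects (e.g. to orient all lesioned/amputated sides
#' the same way).
#'
#' @param pairs two-column data.frame or matrix (left label, right label).
#' @param unpaired character vector of labels with no homologue.
#' @return an object of class `homologue_map`.
#' @export
homologue_map <- function(pairs, unpaired = character()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("left", "right")
  pairs$left <- as.character(pairs$left)
  pairs$right <- as.character(pairs$right)
  all_labels <- c(pairs$left, pairs$right, unpaired)
  if (anyDuplicated(all_labels))
    stop("each ROI label may appear only once in the homologue map")
  structure(list(pairs = pairs, unpaired = as.character(unpaired)),
            class = "homologue_map")
}

#' Build the default homologue map from L_/R_ prefixed ROI labels
#' @param roi_labels character vector of ROI labels.
#' @export
default_homologue_map <- function(roi_labels) {
  lefts <- grep("^L_", roi_labels, value = TRUE)
  rights <- sub("^L_", "R_", lefts)
  ok <- rights %in% roi_labels
  paired <- data.frame(left = lefts[ok], right = rights[ok],
                       stringsAsFactors = FALSE)
  unpaired <- setdiff(roi_labels, c(paired$left, paired$right))
  homologue_map(paired, unpaired)
}

#' Swap left/right homologue ROI values for selected subjects
#'
#' For each listed subject, the values of every (left, right) ROI pair are
#' exchanged; unpaired ROIs are untouched. Applying the same swap twice
#' restores the original table. This is the table-level analogue of flipping
#' an image before thickness extraction.
#'
#' @param thickness a [thickness_table()].
#' @param subjects character vector of subject ids to flip.
#' @param map a [homologue_map()] covering every ROI label in the table.
#' @return a new `thickness_table`.
#' @export
flip_homologues <- function(thickness, subjects, map) {
  stopifnot(inherits(thickness, "thickness_table"),
            inherits(map, "homologue_map"))
  subjects <- as.character(subjects)
  missing_sub <- setdiff(subjects, thickness$subject_id)
  if (length(missing_sub))
    stop("subjects not in table: ", paste(missing_sub, collapse = ", "))
  covered <- c(map$pairs$left, map$pairs$right, map$unpaired)
  missing_lab <- setdiff(thickness$roi_labels, covered)
  if (length(missing_lab))
    stop("ROI labels missing from homologue map: ",
         paste(missing_lab, collapse = ", "))
  if (length(subjects) == 0) return(thickness)
  v <- thickness$values
  rows <- match(subjects, thickness$subject_id)
  li <- match(map$pairs$left, thickness$roi_labels)
  ri <- match(map$pairs$right, thickness$roi_labels)
  keep <- !is.na(li) & !is.na(ri)
  li <- li[keep]; ri <- ri[keep]
  tmp <- v[rows, li, drop = FALSE]
  v[rows, li] <- v[rows, ri, drop = FALSE]
  v[rows, ri] <- tmp
  out <- thickness
  out$values <- v
  out
}

#' Read / write thickness tables as TSV
#'
#' The on-disk format is UTF-8 tab-separated text with a header row:
#' `subject_id`, `group`, then one column per ROI label.
#'
#' @param path file path.
#' @param residualized passed to [thickness_table()].
#' @return `read_thickness_tsv` returns a `thickness_table`.
#' @export
read_thickness_tsv <- function(path, residualized = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns subject_id and group", path))
  rois <- setdiff(names(df), need)
  thickness_table(as.matrix(df[rois]), df$group, df$subject_id, rois,
                  residualized = residualized)
}

#' @rdname read_thickness_tsv
#' @param thickness a `thickness_table` to write.
#' @export
write_thickness_tsv <- function(thickness, path) {
  df <- data.frame(subject_id = thickness$subject_id,
                   group = as.character(thickness$group),
                   thickness$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write covariate tables as TSV
#' @param path file path.
#' @export
read_covariates_tsv <- function(path) {
  covariate_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_covariates_tsv
#' @param covs a `covariate_table`.
#' @export
write_covariates_tsv <- function(covs, path) {
  write.table(as.data.frame(covs), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a homologue map from a two-column TSV
#'
#' Columns `left` and `right`; rows with an empty or NA `right` entry are
#' treated as unpaired labels.
#' @param path file path.
#' @export
read_homologue_map_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("left", "right") %in% names(df)))
    stop(sprintf("%s: expected columns left and right", path))
  un <- is.na(df$right) | df$right == ""
  homologue_map(df[!un, c("left", "right")], unpaired = df$left[un])
}
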