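#' Construct a feature table
#'
#' An aligned feature-by-sample intensity table, the unit of currency of
#' LC-HRMS peak-picking output, with per-sample roles (sample, blank,
#' pooled QC) and optional per-feature MS2 evidence.
#'
#' @param features Data frame with at least \code{feature_id}, \code{mz}
#'   (Da), \code{rt} (minutes); optional \code{polarity} and \code{adduct}.
#' @param intensities Numeric matrix, one row per feature (rownames =
#'   feature_id), one column per sample.
#' @param roles Data frame with \code{sample_id} and \code{role} in
#'   \code{c("sample", "blank", "qc")}, covering every intensity column.
#' @param ms2 Optional named list (by feature_id) of two-column
#'   (mz, intensity) matrices.
#' @param isotopes Optional named list (by feature_id) of measured isotope
#'   patterns (\code{mz}, \code{abundance} data frames).
#' @return An object of class \code{"feature_table"}.
#' @export
feature_table <- function(features, intensities, roles, ms2 = list(),
                          isotopes = list()) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "rt") %in% names(features)))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features))
    stop("intensity rows must match features", call. = FALSE)
  rownames(intensities) <- features$feature_id
  if (!all(colnames(intensities) %in% roles$sample_id))
    stop("every intensity column needs a role", call. = FALSE)
  if (!all(roles$role %in% c("sample", "blank", "qc")))
    stop("roles must be sample/blank/qc", call. = FALSE)
  if (any(intensities < 0)) stop("negative intensities", call. = FALSE)
  if (is.null(features$polarity))
    features$polarity <- rep(NA_character_, nrow(features))
  if (is.null(features$adduct))
    features$adduct <- rep(NA_character_, nrow(features))
  structure(list(features = features, intensities = intensities,
                 roles = roles, ms2 = ms2, isotopes = isotopes),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$roles$role, c("sample", "blank", "qc")))
  cat("<feature_table> ", nrow(x$features), " features x ",
      ncol(x$intensities), " samples (",
      tab[["sample"]], " sample / ", tab[["blank"]], " blank / ",
      tab[["qc"]], " qc), ", length(x$ms2), " with MS2\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

.role_cols <- function(table, role) {
  ids <- table$roles$sample_id[table$roles$role == role]
  intersect(colnames(table$intensities), ids)
}

.subset_features <- function(table, keep) {
  table$features <- table$features[keep, , drop = FALSE]
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$ms2 <- table$ms2[intersect(names(table$ms2),
                                   table$features$feature_id)]
  table$isotopes <- table$isotopes[intersect(names(table$isotopes),
                                             table$features$feature_id)]
  rownames(table$features) <- NULL
  table
}

#' Minimum peak-height filter
#'
#' Drops features whose maximum height over sample-role columns is below
#' the instrument noise floor.
#'
#' @param table A \code{\link{feature_table}}.
#' @param min_height Minimum peak height in counts (default 3000).
#' @return The filtered table (a subset of the input; idempotent).
#' @export
filter_min_height <- function(table, min_height = 3000) {
  sc <- .role_cols(table, "sample")
  if (!length(sc)) stop("no sample-role columns", call. = FALSE)
  mx <- apply(table$intensities[, sc, drop = FALSE], 1, max)
  .subset_features(table, mx >= min_height)
}

#' Sample-max / blank-max ratio filter
#'
#' Keeps features whose maximum sample intensity exceeds
#' \code{min_ratio} times the maximum blank intensity -- background
#' (procedural contamination) removal.
#'
#' @param table A \code{\link{feature_table}}.
#' @param min_ratio Required sample-max/blank-max ratio (default 5,
#'   strict inequality).
#' @param blank_floor Value substituted for an all-zero blank maximum
#'   (default 1 count).
#' @return The filtered table.
#' @export
filter_sample_blank_ratio <- function(table, min_ratio = 5,
                                      blank_floor = 1) {
  sc <- .role_cols(table, "sample")
  bc <- .role_cols(table, "blank")
  if (!length(bc)) stop("no blank-role columns", call. = FALSE)
  smax <- apply(table$intensities[, sc, drop = FALSE], 1, max)
  bmax <- apply(table$intensities[, bc, drop = FALSE], 1, max)
  bmax[bmax == 0] <- blank_floor
  .subset_features(table, smax / bmax > min_ratio)
}

#' Blank-mean / QC-mean ratio filter
#'
#' Removes features whose procedural-blank signal is a large fraction of
#' the pooled-QC signal.
#'
#' @param table A \code{\link{feature_table}}.
#' @param max_ratio Maximum tolerated blank/QC mean ratio (default 0.5;
#'   removal on strictly greater).
#' @return The filtered table. Features with QC mean 0 are removed (their
#'   ratio is undefined) and counted in a message.
#' @export
filter_blank_qc_ratio <- function(table, max_ratio = 0.5) {
  bc <- .role_cols(table, "blank")
  qc <- .role_cols(table, "qc")
  if (!length(bc) || !length(qc))
    stop("need blank and qc columns", call. = FALSE)
  bmean <- rowMeans(table$intensities[, bc, drop = FALSE])
  qmean <- rowMeans(table$intensities[, qc, drop = FALSE])
  undef <- qmean == 0
  if (any(undef))
    message(sum(undef), " feature(s) removed: QC mean is zero")
  .subset_features(table, !undef & bmean / qmean <= max_ratio)
}

#' QC relative-standard-deviation filter
#'
#' Removes features that are not reproducible across pooled-QC
#' injections.
#'
#' @param table A \code{\link{feature_table}}.
#' @param max_rsd_percent Maximum QC RSD in percent (default 30; removal
#'   on strictly greater).
#' @return The filtered table.
#' @export
filter_qc_rsd <- function(table, max_rsd_percent = 30) {
  qc <- .role_cols(table, "qc")
  if (length(qc) < 2)
    stop("QC RSD needs at least two qc columns", call. = FALSE)
  q <- table$intensities[, qc, drop = FALSE]
  rsd <- 100 * apply(q, 1, stats::sd) / rowMeans(q)
  rsd[is.nan(rsd)] <- Inf  # zero-mean QC: not reproducible
  .subset_features(table, rsd <= max_rsd_percent)
}

#' Spectral-quality filter
#'
#' Removes features without a usable MS2 spectrum: fewer than
#' \code{min_fragments} fragment peaks above \code{min_rel_intensity} of
#' the base peak, or no spectrum at all. Such features cannot support
#' structural elucidation.
#'
#' @param table A \code{\link{feature_table}}.
#' @param min_fragments Minimum number of real fragment peaks (default 3).
#' @param min_rel_intensity Fraction of base-peak intensity below which a
#'   peak counts as grass (default 0.05).
#' @return The filtered table.
#' @export
filter_spectral_quality <- function(table, min_fragments = 3,
                                    min_rel_intensity = 0.05) {
  keep <- vapply(table$features$feature_id, function(id) {
    pk <- table$ms2[[id]]
    if (is.null(pk) || !nrow(pk)) return(FALSE)
    rel <- pk[, 2] / max(pk[, 2])
    sum(rel >= min_rel_intensity) >= min_fragments
  }, logical(1))
  .subset_features(table, keep)
}

#' Read / write feature tables as CSV
#'
#' The CSV carries columns \code{feature_id}, \code{mz}, \code{rt},
#' \code{polarity}, \code{adduct}, then one intensity column per sample;
#' a sidecar roles CSV maps \code{sample_id} to \code{role}. MS-DIAL
#' alignment exports map onto this layout by renaming the Alignment ID,
#' Average Mz and Average Rt(min) columns.
#'
#' @param path Feature CSV path.
#' @param roles_path Sidecar roles CSV path.
#' @return \code{read_feature_csv}: a \code{\link{feature_table}}
#'   (without MS2); \code{write_feature_csv}: invisibly, \code{path}.
#' @export
read_feature_csv <- function(path, roles_path) {
  df <- utils::read.csv(path, check.names = FALSE)
  roles <- utils::read.csv(roles_path)
  meta_cols <- intersect(c("feature_id", "mz", "rt", "polarity",
                           "adduct"), names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  feature_table(df[meta_cols],
                as.matrix(df[sample_cols]),
                roles)
}

#' @rdname read_feature_csv
#' @param table A \code{\link{feature_table}}.
#' @export
write_feature_csv <- function(table, path, roles_path) {
  df <- cbind(table$features[intersect(c("feature_id", "mz", "rt",
                                         "polarity", "adduct"),
                                       names(table$features))],
              as.data.frame(table$intensities))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(table$roles, roles_path, row.names = FALSE)
  invisible(path)
}
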