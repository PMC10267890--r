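## MSP (NIST-style) spectral-library text format: blocks of "Key: value"
## header lines, a "Num Peaks:" count, then one "mz intensity" pair per
## line, records separated by blank lines. Public libraries disagree on
## header spellings; a case-insensitive synonym table maps the common
## dialects onto one record model.

.msp_synonyms <- c(
  "name"            = "name",
  "precursormz"     = "precursor_mz",
  "precursor m/z"   = "precursor_mz",
  "precursor_mz"    = "precursor_mz",
  "precursortype"   = "precursor_type",
  "precursor_type"  = "precursor_type",
  "adduct"          = "precursor_type",
  "ionmode"         = "ion_mode",
  "ion_mode"        = "ion_mode",
  "ionization mode" = "ion_mode",
  "formula"         = "formula",
  "molecular formula" = "formula",
  "inchikey"        = "inchikey",
  "smiles"          = "smiles",
  "cas"             = "cas",
  "casno"           = "cas",
  "cas#"            = "cas",
  "retentiontime"   = "retention_time",
  "retention_time"  = "retention_time",
  "rt"              = "retention_time",
  "collisionenergy" = "collision_energy",
  "collision_energy" = "collision_energy",
  "ce"              = "collision_energy",
  "comment"         = "comment",
  "comments"        = "comment"
)

#' Create a spectrum record
#'
#' @param name Compound label.
#' @param precursor_mz Precursor ion m/z in Da.
#' @param precursor_type Adduct label (e.g. \code{"[M+H]+"}).
#' @param ion_mode \code{"positive"} or \code{"negative"}.
#' @param peaks Two-column matrix or data frame of (mz, intensity).
#' @param formula,inchikey,smiles,cas,retention_time,collision_energy
#'   Optional compound metadata; \code{retention_time} in minutes.
#' @param provenance Source-library label used for deduplication priority.
#' @param extras Named list of unrecognized header fields to preserve.
#' @return A list of class \code{"ms_spectrum"}; peaks are sorted by
#'   ascending m/z.
#' @export
spectrum_record <- function(name, precursor_mz = NA_real_,
                            precursor_type = NA_character_,
                            ion_mode = NA_character_, peaks,
                            formula = NA_character_,
                            inchikey = NA_character_,
                            smiles = NA_character_, cas = NA_character_,
                            retention_time = NA_real_,
                            collision_energy = NA_character_,
                            provenance = NA_character_, extras = list()) {
  peaks <- as.matrix(peaks)
  if (!nrow(peaks) || ncol(peaks) < 2)
    stop("peaks must be a non-empty (mz, intensity) table", call. = FALSE)
  peaks <- peaks[, 1:2, drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0))
    stop("negative peak intensity", call. = FALSE)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(
    name = as.character(name), precursor_mz = as.numeric(precursor_mz),
    precursor_type = as.character(precursor_type),
    ion_mode = as.character(ion_mode), formula = as.character(formula),
    inchikey = as.character(inchikey), smiles = as.character(smiles),
    cas = as.character(cas), retention_time = as.numeric(retention_time),
    collision_energy = as.character(collision_energy),
    provenance = as.character(provenance), peaks = peaks,
    flags = character(), extras = extras
  ), class = "ms_spectrum")
}

#' Create a spectral library
#'
#' @param records List of \code{\link{spectrum_record}} objects.
#' @param dialect Source-format tag.
#' @return A list of class \code{"spectral_library"} with a computed
#'   \code{polarity} (\code{"positive"}, \code{"negative"} or
#'   \code{"mixed"}).
#' @export
spectral_library <- function(records = list(), dialect = "canonical") {
  modes <- unique(stats::na.omit(vapply(records, `[[`, character(1),
                                        "ion_mode")))
  polarity <- if (length(modes) == 1L) modes else
    if (!length(modes)) "unknown" else "mixed"
  structure(list(records = records, dialect = dialect,
                 polarity = polarity),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", length(x$records), " record(s), polarity: ",
      x$polarity, ", dialect: ", x$dialect, "\n", sep = "")
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$records)

#' Read an MSP spectral library
#'
#' @param path Path to an MSP text file.
#' @param dialect \code{"auto"} (default), \code{"nist"} or
#'   \code{"msdial"}; all use the same synonym-tolerant parser, the tag is
#'   recorded on the library.
#' @param peak_mismatch Policy when the declared \code{Num Peaks} count
#'   disagrees with the parsed peak lines: \code{"warn"} (keep parsed
#'   peaks, warn) or \code{"error"}.
#' @return A \code{\link{spectral_library}}.
#' @export
read_msp <- function(path, dialect = c("auto", "nist", "msdial"),
                     peak_mismatch = c("warn", "error")) {
  dialect <- match.arg(dialect)
  peak_mismatch <- match.arg(peak_mismatch)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  blocks <- unname(split(lines[!blank], grp[!blank]))
  records <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    records[[bi]] <- tryCatch(
      .parse_msp_block(blocks[[bi]], peak_mismatch),
      error = function(e) stop("MSP block ", bi, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  spectral_library(records, dialect = dialect)
}

.parse_msp_block <- function(lines, peak_mismatch) {
  fields <- list()
  extras <- list()
  npeaks <- NA_integer_
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop("expected 'Key: value' header, got '", line, "'")
    key <- tolower(trimws(kv[2]))
    val <- trimws(kv[3])
    i <- i + 1L
    if (key %in% c("num peaks", "numpeaks", "num_peaks")) {
      npeaks <- as.integer(val)
      break
    }
    canon <- .msp_synonyms[key]
    if (!is.na(canon)) fields[[canon]] <- val else extras[[kv[2]]] <- val
  }
  if (is.na(npeaks)) stop("missing 'Num Peaks' line")
  peak_lines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  peaks <- do.call(rbind, lapply(peak_lines, function(pl) {
    tok <- strsplit(trimws(pl), "[\t ;]+")[[1]]
    if (length(tok) < 2) stop("bad peak line '", pl, "'")
    as.numeric(tok[1:2])  # trailing annotation tokens ignored
  }))
  if (is.null(peaks)) stop("record has no peaks")
  if (nrow(peaks) != npeaks) {
    msg <- sprintf("declared %d peaks but found %d", npeaks, nrow(peaks))
    if (peak_mismatch == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  mode <- fields$ion_mode
  if (!is.null(mode)) {
    mode <- tolower(mode)
    mode <- c(p = "positive", n = "negative")[substr(mode, 1, 1)]
  }
  spectrum_record(
    name = fields$name %||% "",
    precursor_mz = as.numeric(fields$precursor_mz %||% NA),
    precursor_type = fields$precursor_type %||% NA_character_,
    ion_mode = mode %||% NA_character_,
    formula = fields$formula %||% NA_character_,
    inchikey = fields$inchikey %||% NA_character_,
    smiles = fields$smiles %||% NA_character_,
    cas = fields$cas %||% NA_character_,
    retention_time = as.numeric(fields$retention_time %||% NA),
    collision_energy = fields$collision_energy %||% NA_character_,
    provenance = fields$comment %||% NA_character_,
    peaks = peaks, extras = extras
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectral library to MSP
#'
#' Writes the canonical dialect: uppercase NIST/MS-DIAL-compatible keys in
#' fixed order so that \code{read_msp(write_msp(lib))} round-trips every
#' field.
#'
#' @param lib A \code{\link{spectral_library}}.
#' @param path Output file path; with \code{split_polarity} the polarity
#'   tag is inserted before the extension.
#' @param split_polarity Write positive- and negative-mode records to
#'   separate files.
#' @return Invisibly, the path(s) written.
#' @export
write_msp <- function(lib, path, split_polarity = FALSE) {
  if (split_polarity) {
    modes <- vapply(lib$records, `[[`, character(1), "ion_mode")
    paths <- character()
    for (m in c("positive", "negative")) {
      sub <- spectral_library(lib$records[!is.na(modes) & modes == m],
                              dialect = lib$dialect)
      p <- sub("(\\.[^.]+)$", paste0("_", m, "\\1"), path)
      write_msp(sub, p)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  out <- character()
  for (rec in lib$records) {
    hdr <- c(
      paste0("NAME: ", rec$name),
      if (!is.na(rec$precursor_mz))
        sprintf("PRECURSORMZ: %.6f", rec$precursor_mz),
      if (!is.na(rec$precursor_type))
        paste0("PRECURSORTYPE: ", rec$precursor_type),
      if (!is.na(rec$ion_mode)) paste0("IONMODE: ", rec$ion_mode),
      if (!is.na(rec$formula)) paste0("FORMULA: ", rec$formula),
      if (!is.na(rec$inchikey)) paste0("INCHIKEY: ", rec$inchikey),
      if (!is.na(rec$smiles)) paste0("SMILES: ", rec$smiles),
      if (!is.na(rec$cas)) paste0("CAS: ", rec$cas),
      if (!is.na(rec$retention_time))
        sprintf("RETENTIONTIME: %.4f", rec$retention_time),
      if (!is.na(rec$collision_energy))
        paste0("COLLISIONENERGY: ", rec$collision_energy),
      if (!is.na(rec$provenance)) paste0("COMMENT: ", rec$provenance)
    )
    if (length(rec$extras))
      hdr <- c(hdr, paste0(names(rec$extras), ": ",
                           unlist(rec$extras, use.names = FALSE)))
    pk <- sprintf("%.6f\t%.6f", rec$peaks[, "mz"], rec$peaks[, "intensity"])
    out <- c(out, hdr, paste0("Num Peaks: ", nrow(rec$peaks)), pk, "")
  }
  writeLines(out, path)
  invisible(path)
}
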