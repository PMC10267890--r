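#' Harmonize a spectrum record
#'
#' Cleans one record for compilation: normalizes the adduct label to
#' registry spelling, canonicalizes the formula to Hill notation, rescales
#' intensities to base peak 100, and flags (never rejects) internal
#' inconsistencies -- a precursor m/z more than \code{mz_check_tol} away
#' from the value implied by formula + adduct, fragments above the
#' precursor, or an ion mode contradicting the adduct polarity.
#'
#' @param rec A \code{\link{spectrum_record}}.
#' @param mz_check_tol Tolerance in Da for the formula/adduct/precursor
#'   consistency check (default 0.01).
#' @return The harmonized record; issues are listed in \code{rec$flags}.
#' @export
harmonize_record <- function(rec, mz_check_tol = 0.01) {
  flags <- character()
  if (!is.na(rec$precursor_type)) {
    norm <- normalize_adduct_name(rec$precursor_type)
    if (norm %in% adduct_registry()$name) {
      rec$precursor_type <- norm
      pol <- adduct_lookup(norm)$polarity
      if (is.na(rec$ion_mode)) rec$ion_mode <- pol
      else if (rec$ion_mode != pol) flags <- c(flags, "polarity_conflict")
    } else {
      rec$precursor_type <- norm
      flags <- c(flags, "unknown_adduct")
    }
  }
  if (!is.na(rec$formula)) {
    comp <- tryCatch(parse_formula(rec$formula), error = function(e) NULL)
    if (is.null(comp)) {
      flags <- c(flags, "bad_formula")
    } else {
      rec$formula <- serialize_formula(comp)
      if (!is.na(rec$precursor_mz) && !is.na(rec$precursor_type) &&
          rec$precursor_type %in% adduct_registry()$name) {
        theo <- adduct_mz(monoisotopic_mass(comp), rec$precursor_type)
        if (abs(theo - rec$precursor_mz) > mz_check_tol)
          flags <- c(flags, "precursor_inconsistent")
      }
    }
  }
  if (!is.na(rec$precursor_mz) &&
      max(rec$peaks[, "mz"]) > rec$precursor_mz + 0.5)
    flags <- c(flags, "fragments_above_precursor")
  base <- max(rec$peaks[, "intensity"])
  if (base > 0) rec$peaks[, "intensity"] <- rec$peaks[, "intensity"] / base * 100
  rec$flags <- unique(c(rec$flags, flags))
  rec
}

#' Harmonize every record of a library
#'
#' @param lib A \code{\link{spectral_library}}.
#' @param mz_check_tol See \code{\link{harmonize_record}}.
#' @return The harmonized library.
#' @export
harmonize_library <- function(lib, mz_check_tol = 0.01) {
  lib$records <- lapply(lib$records, harmonize_record,
                        mz_check_tol = mz_check_tol)
  lib
}

## Identity key for deduplication: first block of the InChIKey (2D
## skeleton) when present, else compound name; plus adduct and collision
## energy (exact string).
.record_key <- function(rec) {
  id <- if (!is.na(rec$inchikey) && nzchar(rec$inchikey))
    strsplit(rec$inchikey, "-")[[1]][1] else tolower(rec$name)
  paste(id, rec$precursor_type, rec$collision_energy, sep = "|")
}

#' Deduplicate a spectral library
#'
#' One record survives per (InChIKey first block, adduct, collision
#' energy) key. The survivor is chosen by source priority (earlier in
#' \code{priority} wins), then higher peak count, then lower precursor
#' m/z, then name. Idempotent.
#'
#' @param lib A harmonized \code{\link{spectral_library}}.
#' @param priority Character vector of provenance labels, most trusted
#'   first; unlisted sources rank after listed ones.
#' @return The deduplicated library (stable input order of survivors).
#' @export
deduplicate <- function(lib, priority = character()) {
  if (!length(lib$records)) return(lib)
  keys <- vapply(lib$records, .record_key, character(1))
  prio <- vapply(lib$records, function(r) {
    p <- match(r$provenance, priority)
    if (is.na(p)) length(priority) + 1L else p
  }, numeric(1))
  npk <- vapply(lib$records, function(r) nrow(r$peaks), numeric(1))
  pmz <- vapply(lib$records, function(r) {
    if (is.na(r$precursor_mz)) Inf else r$precursor_mz
  }, numeric(1))
  nm <- vapply(lib$records, `[[`, character(1), "name")
  keep <- logical(length(keys))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    ord <- order(prio[idx], -npk[idx], pmz[idx], nm[idx])
    keep[idx[ord[1]]] <- TRUE
  }
  lib$records <- lib$records[keep]
  lib
}

#' Compile several spectral libraries into one
#'
#' Concatenates, harmonizes, deduplicates by source priority, and checks
#' polarity. The result is independent of the order the libraries are
#' supplied in, given a fixed priority.
#'
#' @param libs List of \code{\link{spectral_library}} objects.
#' @param priority Provenance labels, most trusted first.
#' @param allow_mixed Keep a mixed-polarity result (default TRUE); with
#'   FALSE, mixed polarity is an error and the library should be split
#'   with \code{\link{split_by_polarity}} first.
#' @return A compiled \code{\link{spectral_library}}.
#' @export
compile_libraries <- function(libs, priority = character(),
                              allow_mixed = TRUE) {
  records <- do.call(c, c(lapply(libs, `[[`, "records"), list(list())))
  ## deterministic order regardless of input arrangement
  ord <- order(vapply(records, .record_key, character(1)),
               vapply(records, function(r) {
                 p <- match(r$provenance, priority)
                 if (is.na(p)) length(priority) + 1L else p
               }, numeric(1)))
  lib <- spectral_library(records[ord], dialect = "canonical")
  lib <- harmonize_library(lib)
  lib <- deduplicate(lib, priority = priority)
  lib$polarity <- spectral_library(lib$records)$polarity
  if (!allow_mixed && lib$polarity == "mixed")
    stop("mixed-polarity library; split by polarity first", call. = FALSE)
  lib
}

#' Split a library by ion mode
#'
#' @param lib A \code{\link{spectral_library}}.
#' @return Named list with \code{positive} and \code{negative} libraries;
#'   records with unknown ion mode are dropped with a warning.
#' @export
split_by_polarity <- function(lib) {
  modes <- vapply(lib$records, `[[`, character(1), "ion_mode")
  if (anyNA(modes))
    warning(sum(is.na(modes)), " record(s) without ion mode dropped",
            call. = FALSE)
  list(
    positive = spectral_library(lib$records[!is.na(modes) &
                                              modes == "positive"],
                                dialect = lib$dialect),
    negative = spectral_library(lib$records[!is.na(modes) &
                                              modes == "negative"],
                                dialect = lib$dialect)
  )
}

#' Export a pseudo-MRM transition library
#'
#' For every record, takes the \code{top_n} most intense product ions
#' (ties broken toward lower m/z) with intensities normalized so the
#' largest is 100 -- the transition list used for pseudo-MRM screening of
#' DIA data.
#'
#' @param lib A \code{\link{spectral_library}}.
#' @param top_n Number of product ions per compound (default 5).
#' @return A data frame of class \code{"transition_library"} with columns
#'   \code{compound}, \code{precursor_mz}, \code{product_mz},
#'   \code{rel_intensity} (descending within compound, first is 100) and
#'   \code{reference_rt} (minutes; NA when the record has none, flagged).
#' @export
export_transitions <- function(lib, top_n = 5L) {
  rows <- lapply(lib$records, function(rec) {
    pk <- rec$peaks
    ord <- order(-pk[, "intensity"], pk[, "mz"])
    pk <- pk[ord, , drop = FALSE][seq_len(min(top_n, nrow(pk))), ,
                                  drop = FALSE]
    rel <- pk[, "intensity"] / pk[1, "intensity"] * 100
    data.frame(compound = rec$name,
               precursor_mz = rec$precursor_mz,
               product_mz = pk[, "mz"],
               rel_intensity = rel,
               reference_rt = rec$retention_time,
               rt_missing = is.na(rec$retention_time))
  })
  out <- do.call(rbind, c(rows, list(data.frame())))
  if (is.null(out) || !nrow(out))
    out <- data.frame(compound = character(), precursor_mz = numeric(),
                      product_mz = numeric(), rel_intensity = numeric(),
                      reference_rt = numeric(), rt_missing = logical())
  rownames(out) <- NULL
  class(out) <- c("transition_library", "data.frame")
  out
}

#' Write a transition library as tab-separated text
#'
#' @param tl A \code{"transition_library"} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_transitions <- function(tl, path) {
  utils::write.table(tl[c("compound", "precursor_mz", "product_mz",
                          "rel_intensity", "reference_rt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a transition library written by \code{\link{write_transitions}}
#'
#' @param path Path to the tab-separated transition file.
#' @return A \code{"transition_library"} data frame.
#' @export
read_transitions <- function(path) {
  out <- utils::read.delim(path, na.strings = c("NA", ""))
  out$rt_missing <- is.na(out$reference_rt)
  class(out) <- c("transition_library", "data.frame")
  out
}
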