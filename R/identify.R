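#' Create a structure database
#'
#' A weighted collection of candidate structures for precursor-oriented
#' search. Typical use is three tiers: compounds already identified in
#' the same samples by GC-MS (weight 2), a curated plastic-packaging
#' chemical list (weight 1.5), and a generic food/environment/natural
#' product database (weight 1).
#'
#' @param entries Data frame with columns \code{name} and \code{formula};
#'   optional \code{exact_mass} (Da), \code{inchikey}, \code{smiles},
#'   \code{cas}. Missing exact masses are computed from the formula; a
#'   supplied mass more than 0.001 Da from the formula mass is an error.
#' @param label Database label (e.g. \code{"cppDB"}).
#' @param weight Positive score multiplier (default 1).
#' @return An object of class \code{"structure_db"}.
#' @export
structure_db <- function(entries, label, weight = 1) {
  stopifnot(weight > 0, is.data.frame(entries),
            all(c("name", "formula") %in% names(entries)))
  for (col in c("exact_mass", "inchikey", "smiles", "cas"))
    if (is.null(entries[[col]])) entries[[col]] <- NA
  entries$formula <- vapply(entries$formula, function(f)
    serialize_formula(parse_formula(f)), character(1))
  theo <- vapply(entries$formula, monoisotopic_mass, numeric(1))
  given <- as.numeric(entries$exact_mass)
  bad <- !is.na(given) & abs(given - theo) > 0.001
  if (any(bad))
    stop("exact_mass inconsistent with formula for: ",
         paste(entries$name[bad], collapse = ", "), call. = FALSE)
  entries$exact_mass <- ifelse(is.na(given), theo, given)
  structure(list(label = label, weight = weight, entries = entries),
            class = "structure_db")
}

#' Read a structure database from tab-separated text
#'
#' Expected columns: name, formula, exact_mass, inchikey, smiles, cas
#' (header required; extra columns kept).
#'
#' @param path File path.
#' @param label Database label.
#' @param weight Score multiplier.
#' @return A \code{\link{structure_db}}.
#' @export
read_structure_db <- function(path, label, weight = 1) {
  structure_db(utils::read.delim(path, na.strings = c("NA", "")),
               label = label, weight = weight)
}

#' @export
print.structure_db <- function(x, ...) {
  cat("<structure_db> ", x$label, ": ", nrow(x$entries),
      " entries, weight ", x$weight, "\n", sep = "")
  invisible(x)
}

## ---- spectral matching ----------------------------------------------------

## Pair peaks of two spectra within tol: each peak used at most once,
## closest pairs first.
.pair_peaks <- function(a, b, tol) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) {
    d <- abs(b[, 1] - a[i, 1])
    j <- which(d <= tol)
    if (length(j))
      pairs <- rbind(pairs, cbind(i = i, j = j, d = d[j]))
  }
  if (is.null(pairs)) return(cbind(i = integer(), j = integer()))
  pairs <- pairs[order(pairs[, "d"]), , drop = FALSE]
  used_i <- logical(nrow(a))
  used_j <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  pairs[keep, c("i", "j"), drop = FALSE]
}

#' Composite spectral similarity score
#'
#' Score in [0, 100]: 100 x (0.5 cosine + 0.25 reverse cosine +
#' 0.25 matched-reference-peak fraction), with query/reference peaks
#' paired greedily by mass distance within \code{ms2_tol}. The reverse
#' cosine is computed over reference peaks only, so reference fragments
#' missing from the query are penalized but extra query noise is not.
#'
#' @param query,reference Two-column (mz, intensity) matrices.
#' @param ms2_tol Fragment pairing tolerance in Da (default 0.025).
#' @param weights Component weights (cosine, reverse cosine, matched
#'   fraction); must sum to 1.
#' @return Numeric score in [0, 100].
#' @export
spectral_score <- function(query, reference, ms2_tol = 0.025,
                           weights = c(0.5, 0.25, 0.25)) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  pairs <- .pair_peaks(query, reference, ms2_tol)
  qi <- query[, 2]
  ri <- reference[, 2]
  dot <- sum(qi[pairs[, "i"]] * ri[pairs[, "j"]])
  cosine <- if (sum(qi^2) == 0 || sum(ri^2) == 0) 0 else
    dot / sqrt(sum(qi^2) * sum(ri^2))
  ## reverse: restrict the query vector to peaks matching a reference peak
  rq <- numeric(length(ri))
  rq[pairs[, "j"]] <- qi[pairs[, "i"]]
  rev_cos <- if (sum(rq^2) == 0 || sum(ri^2) == 0) 0 else
    sum(rq * ri) / sqrt(sum(rq^2) * sum(ri^2))
  frac <- nrow(pairs) / nrow(reference)
  100 * sum(weights * c(cosine, rev_cos, frac))
}

#' Match a feature's MS2 against a spectral library
#'
#' Library records within \code{ms1_tol} of the feature precursor are
#' scored with \code{\link{spectral_score}}; only candidates at or above
#' \code{cutoff} are returned.
#'
#' @param mz Feature precursor m/z in Da.
#' @param ms2 Two-column (mz, intensity) fragment spectrum.
#' @param lib A \code{\link{spectral_library}} of matching polarity.
#' @param ms1_tol Precursor tolerance in Da (default 0.01).
#' @param ms2_tol Fragment tolerance in Da (default 0.025).
#' @param cutoff Minimum identification score, percent (default 80).
#' @return Data frame of candidates sorted by descending score: columns
#'   \code{name}, \code{precursor_mz}, \code{adduct}, \code{formula},
#'   \code{inchikey}, \code{score}, \code{source}.
#' @export
spectral_match <- function(mz, ms2, lib, ms1_tol = 0.01, ms2_tol = 0.025,
                           cutoff = 80) {
  if (is.null(ms2) || !nrow(as.matrix(ms2)))
    stop("query feature has no MS2 spectrum", call. = FALSE)
  empty <- data.frame(name = character(), precursor_mz = numeric(),
                      adduct = character(), formula = character(),
                      inchikey = character(), score = numeric(),
                      source = character())
  if (!length(lib$records)) return(empty)
  rows <- lapply(lib$records, function(rec) {
    if (is.na(rec$precursor_mz) ||
        abs(rec$precursor_mz - mz) > ms1_tol) return(NULL)
    s <- spectral_score(ms2, rec$peaks, ms2_tol = ms2_tol)
    data.frame(name = rec$name, precursor_mz = rec$precursor_mz,
               adduct = rec$precursor_type, formula = rec$formula,
               inchikey = rec$inchikey, score = s,
               source = "library_match")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$score >= cutoff, , drop = FALSE]
  out <- out[order(-out$score, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- structure-database scoring -------------------------------------------

#' Isotope-pattern agreement score
#'
#' 1 minus the mean absolute difference of the A+1 and A+2 relative
#' abundances (measured vs theoretical), clamped to [0, 1]. Missing
#' peaks count as abundance 0.
#'
#' @param measured,theoretical Base-normalized isotope patterns
#'   (data frames with \code{mz}, \code{abundance}).
#' @return Score in [0, 1].
#' @export
isotope_score <- function(measured, theoretical) {
  m <- isotope_a1_a2(measured)
  t <- isotope_a1_a2(theoretical)
  max(0, min(1, 1 - mean(abs(m - t))))
}

#' Fragment explanation score by sub-formula matching
#'
#' Fraction of total MS2 intensity carried by peaks whose m/z can be
#' explained as a sub-formula of the candidate plus the adduct's charge
#' carrier, within \code{ms2_tol}. Sub-formulas with RDBE below -0.5 are
#' excluded. The score is invariant to intensity rescaling. This is a
#' formula-level stand-in for bond-disconnection in silico fragmentation:
#' it asks whether fragments are elementally consistent with the
#' candidate, not whether the bonds exist.
#'
#' @param candidate_formula Composition or formula string of the neutral
#'   candidate.
#' @param adduct Adduct name or registry row (its mass delta is the
#'   charge carrier added to each neutral fragment).
#' @param ms2 Two-column (mz, intensity) matrix.
#' @param ms2_tol Fragment tolerance in Da (default 0.025).
#' @return Score in [0, 1].
#' @export
subformula_fragment_score <- function(candidate_formula, adduct, ms2,
                                      ms2_tol = 0.025) {
  ms2 <- as.matrix(ms2)
  if (!nrow(ms2)) stop("empty MS2 spectrum", call. = FALSE)
  comp <- as_composition(candidate_formula)
  a <- if (is.data.frame(adduct)) adduct else adduct_lookup(adduct)
  masses <- .subformula_masses(comp)
  frag_mz <- sort(masses + a$mass_delta / abs(a$charge))
  explained <- vapply(ms2[, 1], function(m) {
    i <- findInterval(m, frag_mz)
    lo <- if (i >= 1) frag_mz[i] else -Inf
    hi <- if (i < length(frag_mz)) frag_mz[i + 1] else Inf
    min(m - lo, hi - m) <= ms2_tol
  }, logical(1))
  sum(ms2[explained, 2]) / sum(ms2[, 2])
}

## All neutral sub-formula masses of comp with RDBE >= -0.5.
.subformula_masses <- function(comp) {
  el <- names(comp)
  mass <- 0
  rdbe_part <- 0
  for (e in el) {
    n <- 0:comp[[e]]
    mass <- outer(mass, n * .ms_monoisotopic[[e]], `+`)
    rdbe_part <- outer(rdbe_part, n * .ms_rdbe_weight[[e]], `+`)
  }
  mass <- as.vector(mass)
  ok <- (1 + as.vector(rdbe_part)) >= -0.5 & mass > 0
  mass[ok]
}

#' Precursor-oriented structure-database search
#'
#' For each adduct hypothesis, database entries whose theoretical adduct
#' m/z lies within \code{ms1_tol} of the feature precursor are scored on
#' the available evidence: mass error (formula score), isotope-pattern
#' agreement, and fragment sub-formula explanation. The base score is the
#' mean of available sub-scores scaled to 10 (the in-silico scoring
#' convention), and the final score multiplies in the database weight.
#' Results are merged across databases and sorted by final score; ties
#' resolve to the higher-weight database, then name.
#'
#' @param mz Feature precursor m/z in Da.
#' @param dbs List of \code{\link{structure_db}} objects (or one).
#' @param adducts Adduct hypotheses: names or registry subset; default
#'   all single/dimer adducts of \code{polarity}.
#' @param polarity Feature polarity, used to pick default adducts.
#' @param ms2 Optional fragment spectrum for the fragment sub-score.
#' @param measured_isotopes Optional measured isotope pattern for the
#'   isotope sub-score.
#' @param ms1_tol Precursor tolerance in Da (default 0.005).
#' @param ms2_tol Fragment tolerance in Da (default 0.025).
#' @return Data frame sorted by descending \code{final_score}: columns
#'   \code{name}, \code{formula}, \code{adduct}, \code{theoretical_mz},
#'   \code{error_da}, \code{formula_score}, \code{isotope_score},
#'   \code{fragment_score}, \code{base_score}, \code{db}, \code{db_weight},
#'   \code{final_score}, \code{rank}, \code{source}.
#' @export
db_search <- function(mz, dbs, adducts = NULL, polarity = NULL, ms2 = NULL,
                      measured_isotopes = NULL, ms1_tol = 0.005,
                      ms2_tol = 0.025) {
  if (inherits(dbs, "structure_db")) dbs <- list(dbs)
  if (!length(dbs)) stop("no structure databases supplied", call. = FALSE)
  reg <- adduct_registry(polarity = polarity)
  if (is.null(adducts)) adducts <- reg$name
  if (is.data.frame(adducts)) adducts <- adducts$name
  rows <- list()
  for (db in dbs) {
    ent <- db$entries
    for (aname in adducts) {
      a <- adduct_lookup(aname)
      theo <- (a$multimer * ent$exact_mass + a$mass_delta) / abs(a$charge)
      hit <- which(abs(theo - mz) <= ms1_tol)
      for (i in hit) {
        fs <- 1 - abs(theo[i] - mz) / ms1_tol
        is_ <- if (!is.null(measured_isotopes))
          isotope_score(measured_isotopes,
                        isotope_pattern(ent$formula[i])) else NA_real_
        fr <- if (!is.null(ms2))
          subformula_fragment_score(ent$formula[i], a, ms2,
                                    ms2_tol = ms2_tol) else NA_real_
        sub <- c(fs, is_, fr)
        base <- mean(sub, na.rm = TRUE) * 10
        rows[[length(rows) + 1L]] <- data.frame(
          name = ent$name[i], formula = ent$formula[i], adduct = a$name,
          theoretical_mz = theo[i], error_da = theo[i] - mz,
          formula_score = fs, isotope_score = is_, fragment_score = fr,
          base_score = base, db = db$label, db_weight = db$weight,
          final_score = base * db$weight, source = "db_search")
      }
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), formula = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      error_da = numeric(), formula_score = numeric(),
                      isotope_score = numeric(),
                      fragment_score = numeric(), base_score = numeric(),
                      db = character(), db_weight = numeric(),
                      final_score = numeric(), rank = integer(),
                      source = character()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$final_score, -out$db_weight, out$name), ,
             drop = FALSE]
  out$rank <- match(-out$final_score, sort(unique(-out$final_score)))
  rownames(out) <- NULL
  out
}

#' Merge library and database annotations for one feature
#'
#' A spectral-library match at or above the cutoff always takes
#' precedence over database candidates; otherwise the top database
#' candidate annotates the feature; otherwise it stays unknown.
#'
#' @param library_hits Result of \code{\link{spectral_match}} (already
#'   cutoff-filtered).
#' @param db_hits Result of \code{\link{db_search}}.
#' @return One-row data frame: \code{status} in \code{"library_match"},
#'   \code{"db_annotated"}, \code{"unknown"}; \code{name},
#'   \code{formula}, \code{score} (library score or db final score),
#'   \code{db}.
#' @export
merge_annotations <- function(library_hits, db_hits) {
  if (!is.null(library_hits) && nrow(library_hits))
    return(data.frame(status = "library_match",
                      name = library_hits$name[1],
                      formula = library_hits$formula[1],
                      score = library_hits$score[1], db = NA_character_))
  if (!is.null(db_hits) && nrow(db_hits))
    return(data.frame(status = "db_annotated", name = db_hits$name[1],
                      formula = db_hits$formula[1],
                      score = db_hits$final_score[1], db = db_hits$db[1]))
  data.frame(status = "unknown", name = NA_character_,
             formula = NA_character_, score = NA_real_,
             db = NA_character_)
}
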