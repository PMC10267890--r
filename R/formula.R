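#' Parse a molecular formula
#'
#' Parses a Hill-notation-like molecular formula (e.g. \code{"C6H11NO"})
#' into an elemental composition. Supported elements are C, H, O, N, P, S,
#' F, Cl, Na and K -- the element set relevant to plastic-migrant screening
#' plus the common adduct cations.
#'
#' @param text A single formula string. Element symbols may carry optional
#'   multi-digit counts; repeated symbols are summed.
#' @return A named integer vector of element counts (class
#'   \code{"ms_composition"}), carrying only elements with count > 0.
#' @examples
#' parse_formula("C6H11NO")
#' serialize_formula(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("empty or invalid formula string", call. = FALSE)
  text <- gsub("[[:space:]_]", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("formula contains unparseable characters: '", text, "'",
         call. = FALSE)
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, .ms_elements)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hill <- c("C", "H", sort(setdiff(.ms_elements, c("C", "H"))))
  counts <- tapply(cnt, factor(sym, levels = hill), sum)
  counts <- counts[!is.na(counts) & counts > 0]
  comp <- as.integer(counts)
  names(comp) <- names(counts)
  if (!length(comp)) stop("formula has no atoms: '", text, "'", call. = FALSE)
  structure(comp, class = "ms_composition")
}

#' Serialize a composition to canonical Hill notation
#'
#' Hill order: C first, then H, then the remaining elements alphabetically.
#' Counts of 1 are omitted. \code{parse_formula(serialize_formula(x))}
#' round-trips exactly.
#'
#' @param comp A named integer vector of element counts.
#' @return A single formula string.
#' @export
serialize_formula <- function(comp) {
  comp <- comp[comp > 0]
  el <- names(comp)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- comp[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @export
print.ms_composition <- function(x, ...) {
  cat("<composition> ", serialize_formula(x), "\n", sep = "")
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "ms_composition")) return(x)
  if (is.numeric(x) && !is.null(names(x)))
    return(structure(as.integer(x[x > 0]), names = names(x)[x > 0],
                     class = "ms_composition"))
  parse_formula(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the exact mass of the lightest isotope.
#'
#' @param comp A composition (named count vector) or a formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H11NO")
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  sum(.ms_monoisotopic[names(comp)] * as.numeric(comp))
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = 1 + C + (N + P)/2 - (H + F + Cl + Na + K)/2, the usual
#' integer-plausibility constraint on neutral even-electron molecules.
#'
#' @param comp A composition or formula string.
#' @return RDBE (may be half-integer or negative for implausible formulas).
#' @export
rdbe <- function(comp) {
  comp <- as_composition(comp)
  1 + sum(.ms_rdbe_weight[names(comp)] * as.numeric(comp))
}
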