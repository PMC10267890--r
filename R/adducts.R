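## Electrospray adduct registry.
##
## m/z = (n * M + mass_delta) / |charge|, with mass_delta carrying the
## electron correction so that computed values are true ion m/z.
## The shipped registry covers the six negative adducts (deprotonated,
## formate "FA" and acetate "Hac" clusters plus their 2M forms), the eight
## positive adducts (H, NH4, Na, K and their 2M forms) routinely produced
## by ESI of food-simulant extracts, and the in-source water-loss ion
## [M+H-H2O]+ seen for hydroxy/carboxy compounds.

.ms_adduct_registry <- local({
  e <- 0.00054857990907
  H <- 1.00782503207
  proton <- H - e
  m <- function(...) sum(.ms_monoisotopic[c(...)])
  nh3 <- .ms_monoisotopic[["N"]] + 3 * H
  h2o <- 2 * H + .ms_monoisotopic[["O"]]
  fa  <- .ms_monoisotopic[["C"]] + 2 * H + 2 * .ms_monoisotopic[["O"]]
  hac <- 2 * .ms_monoisotopic[["C"]] + 4 * H + 2 * .ms_monoisotopic[["O"]]
  na  <- .ms_monoisotopic[["Na"]]
  k   <- .ms_monoisotopic[["K"]]
  df <- rbind(
    data.frame(name = "[M+H]+",       polarity = "positive", multimer = 1L,
               mass_delta = proton,        charge = 1L),
    data.frame(name = "[M+NH4]+",     polarity = "positive", multimer = 1L,
               mass_delta = nh3 + proton,  charge = 1L),
    data.frame(name = "[M+Na]+",      polarity = "positive", multimer = 1L,
               mass_delta = na - e,        charge = 1L),
    data.frame(name = "[M+K]+",       polarity = "positive", multimer = 1L,
               mass_delta = k - e,         charge = 1L),
    data.frame(name = "[2M+H]+",      polarity = "positive", multimer = 2L,
               mass_delta = proton,        charge = 1L),
    data.frame(name = "[2M+NH4]+",    polarity = "positive", multimer = 2L,
               mass_delta = nh3 + proton,  charge = 1L),
    data.frame(name = "[2M+Na]+",     polarity = "positive", multimer = 2L,
               mass_delta = na - e,        charge = 1L),
    data.frame(name = "[2M+K]+",      polarity = "positive", multimer = 2L,
               mass_delta = k - e,         charge = 1L),
    data.frame(name = "[M+H-H2O]+",   polarity = "positive", multimer = 1L,
               mass_delta = proton - h2o,  charge = 1L),
    data.frame(name = "[M-H]-",       polarity = "negative", multimer = 1L,
               mass_delta = -proton,       charge = -1L),
    data.frame(name = "[M+FA-H]-",    polarity = "negative", multimer = 1L,
               mass_delta = fa - proton,   charge = -1L),
    data.frame(name = "[M+Hac-H]-",   polarity = "negative", multimer = 1L,
               mass_delta = hac - proton,  charge = -1L),
    data.frame(name = "[2M-H]-",      polarity = "negative", multimer = 2L,
               mass_delta = -proton,       charge = -1L),
    data.frame(name = "[2M+FA-H]-",   polarity = "negative", multimer = 2L,
               mass_delta = fa - proton,   charge = -1L),
    data.frame(name = "[2M+Hac-H]-",  polarity = "negative", multimer = 2L,
               mass_delta = hac - proton,  charge = -1L)
  )
  rownames(df) <- df$name
  df
})

#' Adduct registry
#'
#' Returns the table of registered electrospray adducts, optionally
#' restricted to one polarity. Each adduct defines the ion transform
#' m/z = (n M + delta) / |z|.
#'
#' @param polarity \code{"positive"}, \code{"negative"} or \code{NULL}
#'   (both).
#' @param extra Optional data frame of user adducts with the same columns
#'   (\code{name, polarity, multimer, mass_delta, charge}) appended to the
#'   shipped registry.
#' @return A data frame with columns \code{name}, \code{polarity},
#'   \code{multimer}, \code{mass_delta} (Da, electron-corrected) and
#'   \code{charge}.
#' @export
adduct_registry <- function(polarity = NULL, extra = NULL) {
  reg <- .ms_adduct_registry
  if (!is.null(extra)) {
    need <- c("name", "polarity", "multimer", "mass_delta", "charge")
    if (!all(need %in% names(extra)))
      stop("extra adducts need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    reg <- rbind(reg, extra[need])
    rownames(reg) <- reg$name
  }
  if (!is.null(polarity)) reg <- reg[reg$polarity == polarity, ]
  reg
}

#' Look up one adduct by name
#'
#' Accepts loose spellings as found in public MSP libraries
#' (\code{"[M+H]"}, \code{"M+H"}, \code{"[2 M + Na]+"}) and normalizes to
#' the registry name.
#'
#' @param name Adduct label.
#' @param registry Registry data frame (default the shipped one).
#' @return A one-row data frame (registry row).
#' @export
adduct_lookup <- function(name, registry = adduct_registry()) {
  key <- normalize_adduct_name(name)
  if (!key %in% registry$name)
    stop("unknown adduct: '", name, "'", call. = FALSE)
  registry[registry$name == key, ]
}

#' Normalize an adduct label to registry spelling
#'
#' @param name Adduct label in any common spelling.
#' @return Canonical name such as \code{"[M+H]+"}; unknown labels are
#'   returned stripped of whitespace rather than rejected.
#' @export
normalize_adduct_name <- function(name) {
  x <- gsub("[[:space:]]", "", name)
  x <- gsub("\\^", "", x)
  ## unicode minus signs to ascii
  x <- gsub("−|–", "-", x)
  no_bracket <- !grepl("^\\[", x)
  if (no_bracket) x <- paste0("[", sub("([+-]?)$", "]\\1", x))
  ## trailing charge missing: infer from inner sign for known cores
  if (grepl("\\]$", x)) {
    core <- sub("^\\[(.*)\\]$", "\\1", x)
    sign <- if (grepl("-H$", core)) "-" else "+"
    x <- paste0(x, sign)
  }
  x
}

#' Theoretical adduct m/z
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da.
#' @param adduct Adduct name (see \code{\link{adduct_registry}}) or a
#'   one-row registry data frame.
#' @return Ion m/z in Da: (n M + delta) / |z|.
#' @examples
#' adduct_mz(monoisotopic_mass("C6H11NO"), "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  a <- if (is.data.frame(adduct)) adduct else adduct_lookup(adduct)
  (a$multimer * neutral_mass + a$mass_delta) / abs(a$charge)
}

#' Invert an adduct transform
#'
#' Recovers the neutral mass from an observed ion m/z, the exact inverse
#' of \code{\link{adduct_mz}}.
#'
#' @param mz Observed ion m/z in Da.
#' @param adduct Adduct name or registry row.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  a <- if (is.data.frame(adduct)) adduct else adduct_lookup(adduct)
  (mz * abs(a$charge) - a$mass_delta) / a$multimer
}
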