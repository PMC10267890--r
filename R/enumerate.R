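#' Enumerate candidate molecular formulas for an accurate mass
#'
#' Exhaustive search over element-count combinations whose theoretical
#' adduct m/z falls within \code{tol} of the target, subject to chemical
#' plausibility constraints (RDBE integral and within range, H/C ratio).
#'
#' @param target_mz Observed ion m/z in Da.
#' @param adducts Character vector of adduct names (or a registry subset)
#'   to consider as hypotheses.
#' @param tol Absolute m/z tolerance in Da (default 0.005, the usual MS1
#'   accurate-mass tolerance).
#' @param elements Character vector of allowed elements (default the
#'   CHONPS + F + Cl screening set).
#' @param bounds Optional named integer vector of per-element maximum
#'   counts; elements not named are capped at
#'   \code{floor(max neutral mass / element mass)}.
#' @param rdbe_range Allowed RDBE interval (default \code{c(0, 40)});
#'   non-integer RDBE is always excluded (even-electron neutral species).
#' @param max_h_per_c Maximum H/C ratio when carbon is present (default 4).
#' @return A data frame sorted by absolute mass error with columns
#'   \code{formula}, \code{adduct}, \code{neutral_mass}, \code{mz},
#'   \code{error_da} and \code{error_ppm}.
#' @examples
#' enumerate_formulas(114.0915, "[M+H]+", elements = c("C", "H", "N", "O"))
#' @export
enumerate_formulas <- function(target_mz, adducts = NULL, tol = 0.005,
                               elements = c("C", "H", "O", "N", "P", "S",
                                            "F", "Cl"),
                               bounds = NULL, rdbe_range = c(0, 40),
                               max_h_per_c = 4) {
  stopifnot(tol > 0)
  if (!length(elements)) stop("empty element set", call. = FALSE)
  bad <- setdiff(elements, .ms_elements)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  reg <- adduct_registry()
  if (is.null(adducts)) adducts <- reg$name
  if (is.data.frame(adducts)) adducts <- adducts$name
  hits <- list()
  for (aname in adducts) {
    a <- adduct_lookup(aname)
    target_m <- neutral_mass_from_mz(target_mz, a)
    mass_tol <- tol * abs(a$charge) / a$multimer
    if (target_m <= 0) next
    comps <- .enumerate_compositions(target_m, mass_tol, elements, bounds,
                                     rdbe_range, max_h_per_c)
    for (comp in comps) {
      m <- monoisotopic_mass(comp)
      mz <- adduct_mz(m, a)
      hits[[length(hits) + 1L]] <- data.frame(
        formula = serialize_formula(comp),
        adduct = a$name,
        neutral_mass = m,
        mz = mz,
        error_da = mz - target_mz,
        error_ppm = (mz - target_mz) / target_mz * 1e6
      )
    }
  }
  if (!length(hits))
    return(data.frame(formula = character(), adduct = character(),
                      neutral_mass = numeric(), mz = numeric(),
                      error_da = numeric(), error_ppm = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(abs(out$error_da), out$formula), ]
  rownames(out) <- NULL
  out
}

## Depth-first enumeration over non-H elements (heaviest first), hydrogen
## resolved last directly from the residual mass window.
.enumerate_compositions <- function(target_m, tol, elements, bounds,
                                    rdbe_range, max_h_per_c) {
  has_h <- "H" %in% elements
  others <- setdiff(elements, "H")
  others <- others[order(-.ms_monoisotopic[others])]
  masses <- .ms_monoisotopic[others]
  hmass <- .ms_monoisotopic[["H"]]
  maxn <- vapply(others, function(e) {
    cap <- floor((target_m + tol) / .ms_monoisotopic[[e]])
    if (!is.null(bounds) && e %in% names(bounds))
      cap <- min(cap, bounds[[e]])
    as.integer(cap)
  }, integer(1))
  hcap <- if (has_h) {
    cap <- floor((target_m + tol) / hmass)
    if (!is.null(bounds) && "H" %in% names(bounds))
      cap <- min(cap, bounds[["H"]])
    as.integer(cap)
  } else 0L
  res <- list()
  counts <- integer(length(others))
  recurse <- function(i, remaining) {
    if (i > length(others)) {
      ## fill hydrogens from the residual mass
      if (has_h && remaining > hmass / 2) {
        nh <- round(remaining / hmass)
        if (nh >= 1 && nh <= hcap &&
            abs(remaining - nh * hmass) <= tol) {
          emit(counts, nh)
        }
      } else if (abs(remaining) <= tol && sum(counts) > 0) {
        emit(counts, 0L)
      }
      return(invisible())
    }
    e_mass <- masses[i]
    nmax <- min(maxn[i], floor((remaining + tol) / e_mass))
    for (n in 0:nmax) {
      counts[i] <<- n
      recurse(i + 1L, remaining - n * e_mass)
    }
    counts[i] <<- 0L
  }
  emit <- function(counts, nh) {
    comp <- c(counts, H = nh)
    names(comp) <- c(others, "H")
    comp <- comp[comp > 0]
    if (!length(comp)) return(invisible())
    r <- rdbe(comp)
    if (abs(r - round(r)) > 1e-9) return(invisible())
    if (r < rdbe_range[1] - 1e-9 || r > rdbe_range[2] + 1e-9)
      return(invisible())
    nc <- if ("C" %in% names(comp)) comp[["C"]] else 0L
    if (nc > 0 && nh > max_h_per_c * nc) return(invisible())
    res[[length(res) + 1L]] <<- structure(as.integer(comp),
                                          names = names(comp),
                                          class = "ms_composition")
  }
  recurse(1L, target_m)
  res
}
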