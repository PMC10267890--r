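#' Simulate the isotope pattern of a composition
#'
#' Iteratively convolves the per-element isotope distributions, aggregating
#' peaks on a fixed mass grid so that unresolvable isotopologues (e.g.
#' 13C2 vs 34S at QTOF resolution) collapse into one peak.
#'
#' @param comp Composition or formula string.
#' @param prune_threshold Isotopologue probabilities below this fraction of
#'   total are dropped during convolution (default 1e-4).
#' @param granularity Aggregation bin width in Da (default 0.001).
#' @return A data frame of class \code{"ms_isotope_pattern"} with columns
#'   \code{mz} (Da, ascending) and \code{abundance} (relative to the base
#'   peak, which is exactly 1).
#' @examples
#' isotope_pattern("C17H26O4")
#' @export
isotope_pattern <- function(comp, prune_threshold = 1e-4,
                            granularity = 0.001) {
  stopifnot(prune_threshold > 0, prune_threshold < 1)
  comp <- as_composition(comp)
  ## convolution keeps everything above a much finer internal floor so the
  ## user-facing prune threshold does not bias retained abundances
  floor_p <- min(prune_threshold, 1e-10)
  mass <- 0
  prob <- 1
  for (el in names(comp)) {
    iso <- .ms_isotopes[[el]]
    for (i in seq_len(comp[[el]])) {
      mass <- outer(mass, iso$mass, `+`)
      prob <- outer(prob, iso$abundance, `*`)
      ## aggregate on the mass grid (probability-weighted centroid per bin)
      bin <- round(as.vector(mass) / granularity)
      agg <- rowsum(as.vector(prob), group = bin)
      wm <- rowsum(as.vector(mass) * as.vector(prob), group = bin)
      mass <- wm[, 1] / agg[, 1]
      prob <- agg[, 1]
      keep <- prob >= floor_p * sum(prob)
      if (!any(keep)) keep <- which.max(prob)
      mass <- mass[keep]
      prob <- prob[keep]
    }
  }
  keep <- prob >= prune_threshold * sum(prob)
  mass <- mass[keep]
  prob <- prob[keep]
  ord <- order(mass)
  mass <- mass[ord]
  prob <- prob[ord]
  out <- data.frame(mz = mass, abundance = prob / max(prob))
  class(out) <- c("ms_isotope_pattern", "data.frame")
  out
}

#' Relative abundances of the A+1 and A+2 isotopologues
#'
#' Convenience accessor used by isotope scoring: abundance (relative to the
#' base peak) summed within the nominal +1 and +2 Da windows of the
#' monoisotopic peak. Missing peaks count as 0.
#'
#' @param pattern An \code{ms_isotope_pattern} (or any data frame with
#'   \code{mz} and \code{abundance}).
#' @return Numeric vector \code{c(a1, a2)}.
#' @export
isotope_a1_a2 <- function(pattern) {
  m0 <- min(pattern$mz)  # monoisotopic peak is the lightest
  d <- pattern$mz - m0
  a1 <- sum(pattern$abundance[d > 0.5 & d <= 1.5])
  a2 <- sum(pattern$abundance[d > 1.5 & d <= 2.5])
  c(a1 = a1, a2 = a2)
}
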