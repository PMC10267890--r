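## Feature clustering: co-eluting features whose cross-sample intensity
## profiles correlate are grouped (adducts, dimers and in-source fragments
## of one compound share its abundance), and intra-cluster mass
## differences are annotated against the adduct registry.

#' Cluster co-eluting, correlated features
#'
#' Builds edges between features within \code{rt_window} minutes of each
#' other whose Pearson correlation across sample-role columns reaches
#' \code{min_r} at p-value \code{max_p} (standard t-transform test), then
#' returns connected components. Each edge's mass difference is annotated
#' as an adduct pair, dimer relation or isotopologue spacing when it
#' matches a registry delta within \code{mz_link_tol}; an edge whose lower
#' m/z appears as a fragment in the higher-m/z feature's MS2 is annotated
#' as an in-source fragment link.
#'
#' @param table A \code{\link{feature_table}}.
#' @param min_r Minimum Pearson r (default 0.8).
#' @param max_p Maximum p-value (default 0.05).
#' @param mz_link_tol Mass-difference annotation tolerance in Da
#'   (default 0.005).
#' @param rt_window Co-elution window in minutes (default 0.025).
#' @param isotopologue Annotate ~1.00336 Da spacings as isotopologue links
#'   (default FALSE).
#' @return A list of clusters; each is a list with \code{member_ids},
#'   \code{edges} (data frame: id1, id2, r, p_value, delta_mz, link_type)
#'   and \code{representatives} (from
#'   \code{\link{select_representatives}}).
#' @export
cluster_features <- function(table, min_r = 0.8, max_p = 0.05,
                             mz_link_tol = 0.005, rt_window = 0.025,
                             isotopologue = FALSE) {
  sc <- .role_cols(table, "sample")
  if (length(sc) < 3)
    stop("need >= 3 sample columns for correlation p-values",
         call. = FALSE)
  ft <- table$features
  n <- nrow(ft)
  ints <- table$intensities[, sc, drop = FALSE]
  edges <- list()
  if (n >= 2) {
    ord <- order(ft$rt)
    for (ii in seq_len(n - 1)) {
      i <- ord[ii]
      for (jj in seq.int(ii + 1L, n)) {
        j <- ord[jj]
        if (ft$rt[j] - ft$rt[i] > rt_window) break
        xi <- ints[i, ]
        xj <- ints[j, ]
        if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
          message("constant intensity vector; no edge for ",
                  ft$feature_id[i], "/", ft$feature_id[j])
          next
        }
        ct <- stats::cor.test(xi, xj, method = "pearson")
        if (is.na(ct$estimate) || ct$estimate < min_r ||
            ct$p.value > max_p) next
        lo <- if (ft$mz[i] <= ft$mz[j]) i else j
        hi <- if (lo == i) j else i
        edges[[length(edges) + 1L]] <- data.frame(
          id1 = ft$feature_id[lo], id2 = ft$feature_id[hi],
          r = unname(ct$estimate), p_value = ct$p.value,
          delta_mz = ft$mz[hi] - ft$mz[lo],
          link_type = .link_type(table, lo, hi, mz_link_tol, isotopologue)
        )
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id1 = character(), id2 = character(), r = numeric(),
               p_value = numeric(), delta_mz = numeric(),
               link_type = character())
  comps <- .connected_components(ft$feature_id, edges)
  lapply(comps, function(ids) {
    ce <- edges[edges$id1 %in% ids & edges$id2 %in% ids, , drop = FALSE]
    cl <- list(member_ids = ids, edges = ce)
    cl$representatives <- select_representatives(cl, table)
    cl
  })
}

## mass-difference annotation between a low- and high-m/z co-eluting pair
.link_type <- function(table, lo, hi, tol, isotopologue) {
  ft <- table$features
  d <- ft$mz[hi] - ft$mz[lo]
  ## in-source fragment: the low m/z appears in the high feature's MS2
  ms2 <- table$ms2[[ft$feature_id[hi]]]
  if (!is.null(ms2) && nrow(ms2) &&
      any(abs(ms2[, 1] - ft$mz[lo]) <= tol))
    return("in_source_fragment")
  reg <- adduct_registry()
  pol <- ft$polarity[lo]
  if (!is.na(pol)) reg <- reg[reg$polarity == pol, ]
  single <- reg[reg$multimer == 1L, ]
  ## adduct pair: difference of two single-M adduct deltas
  dd <- outer(single$mass_delta, single$mass_delta, `-`)
  if (any(abs(abs(dd) - d) <= tol & abs(dd) > tol)) return("adduct")
  ## dimer: m/z(hi) = 2 * neutral(lo) + some delta
  for (ai in seq_len(nrow(single))) {
    for (aj in which(reg$multimer == 2L)) {
      m <- neutral_mass_from_mz(ft$mz[lo], single[ai, ])
      if (abs(adduct_mz(m, reg[aj, ]) - ft$mz[hi]) <= tol)
        return("dimer")
    }
  }
  k <- round(d)
  if (isotopologue && k >= 1 && abs(d - k * 1.0033548378) <= tol)
    return("isotopologue")
  "correlation"
}

.connected_components <- function(ids, edges) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$id1[k], ids))
    b <- find(match(edges$id2[k], ids))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  unname(split(ids, roots))
}

#' Select cluster representatives
#'
#' The most intense member (highest maximum sample intensity) and the
#' most connected member (highest edge degree) are kept for structural
#' elucidation; ties resolve to lower m/z, then name.
#'
#' @param cluster A cluster list with \code{member_ids} and \code{edges}.
#' @param table The \code{\link{feature_table}} the cluster came from.
#' @return List with \code{most_intense} and \code{most_connected}
#'   feature ids.
#' @export
select_representatives <- function(cluster, table) {
  ids <- cluster$member_ids
  idx <- match(ids, table$features$feature_id)
  sc <- .role_cols(table, "sample")
  imax <- apply(table$intensities[idx, sc, drop = FALSE], 1, max)
  mz <- table$features$mz[idx]
  deg <- vapply(ids, function(id) {
    sum(cluster$edges$id1 == id) + sum(cluster$edges$id2 == id)
  }, numeric(1))
  pick <- function(score) ids[order(-score, mz, ids)[1]]
  list(most_intense = pick(imax), most_connected = pick(deg))
}

#' Merge positive- and negative-mode feature tables
#'
#' Features from the two polarities whose inferred neutral masses agree
#' within \code{mz_tol} Da and whose retention times agree within
#' \code{rt_tol} minutes are merged into a single entry that carries both
#' polarities' evidence. The neutral mass of each feature comes from its
#' assigned adduct when present, else from the polarity's default ion
#' ([M+H]+ / [M-H]-). Ambiguous many-to-many matches resolve to the
#' closest mass pairing; the rest pass through unmerged.
#'
#' @param pos_table,neg_table Cleaned \code{\link{feature_table}}s of the
#'   two polarities (same samples).
#' @param mz_tol Neutral-mass tolerance in Da (default 0.005).
#' @param rt_tol Retention-time tolerance in minutes (default 0.025).
#' @return A data frame with one row per merged compound or unmerged
#'   feature: \code{feature_id}, \code{mz}, \code{rt}, \code{polarity},
#'   \code{neutral_mass}, \code{counterpart_id}, \code{merged}.
#' @export
merge_polarities <- function(pos_table, neg_table, mz_tol = 0.005,
                             rt_tol = 0.025) {
  neutral <- function(table, default_adduct) {
    ft <- table$features
    vapply(seq_len(nrow(ft)), function(i) {
      ad <- ft$adduct[i]
      if (is.na(ad) ||
          !normalize_adduct_name(ad) %in% adduct_registry()$name)
        ad <- default_adduct
      neutral_mass_from_mz(ft$mz[i], normalize_adduct_name(ad))
    }, numeric(1))
  }
  pm <- neutral(pos_table, "[M+H]+")
  nm <- neutral(neg_table, "[M-H]-")
  pf <- pos_table$features
  nf <- neg_table$features
  pairs <- list()
  for (i in seq_len(nrow(pf))) {
    j <- which(abs(nm - pm[i]) <= mz_tol & abs(nf$rt - pf$rt[i]) <= rt_tol)
    if (length(j))
      pairs[[length(pairs) + 1L]] <- data.frame(
        i = i, j = j, dmass = abs(nm[j] - pm[i]))
  }
  taken_i <- integer()
  taken_j <- integer()
  merged <- list()
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$dmass), ]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (i %in% taken_i || j %in% taken_j) next
      taken_i <- c(taken_i, i)
      taken_j <- c(taken_j, j)
      merged[[length(merged) + 1L]] <- data.frame(
        feature_id = pf$feature_id[i], mz = pf$mz[i], rt = pf$rt[i],
        polarity = "both", neutral_mass = (pm[i] + nm[j]) / 2,
        counterpart_id = nf$feature_id[j], merged = TRUE)
    }
  }
  passthrough <- function(ft, masses, taken, pol) {
    idx <- setdiff(seq_len(nrow(ft)), taken)
    if (!length(idx)) return(NULL)
    data.frame(feature_id = ft$feature_id[idx], mz = ft$mz[idx],
               rt = ft$rt[idx], polarity = pol,
               neutral_mass = masses[idx],
               counterpart_id = NA_character_, merged = FALSE)
  }
  out <- do.call(rbind, c(merged,
                          list(passthrough(pf, pm, taken_i, "positive"),
                               passthrough(nf, nm, taken_j, "negative"))))
  rownames(out) <- NULL
  out
}
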