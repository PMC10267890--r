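## Pseudo-MRM: precursor-product transition chromatograms are extracted
## from data-independent-acquisition (all-ion / MSE) data and screened
## against a transition library, emulating multiple-reaction monitoring
## without re-acquisition.

#' Construct a DIA run
#'
#' @param sample_id Sample label.
#' @param role \code{"sample"}, \code{"blank"} or \code{"qc"}.
#' @param traces List of traces, each a list with \code{window}
#'   (c(lo, hi) precursor-isolation window in Da), \code{product_mz}
#'   (Da), \code{rt} (minutes, strictly increasing) and \code{intensity}
#'   (>= 0, same length).
#' @param windows Matrix/data frame of precursor windows (columns lo,
#'   hi); default one wide all-ion-fragmentation window, the MSE
#'   acquisition model.
#' @return An object of class \code{"dia_run"}.
#' @export
dia_run <- function(sample_id, role = "sample", traces = list(),
                    windows = cbind(lo = 0, hi = 2000)) {
  for (tr in traces) {
    if (is.unsorted(tr$rt, strictly = TRUE))
      stop("trace rt must be strictly increasing", call. = FALSE)
    if (any(tr$intensity < 0))
      stop("negative trace intensity", call. = FALSE)
  }
  structure(list(sample_id = sample_id, role = role,
                 windows = as.matrix(windows), traces = traces),
            class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  cat("<dia_run> ", x$sample_id, " (", x$role, "), ",
      length(x$traces), " trace(s)\n", sep = "")
  invisible(x)
}

#' Write / read DIA runs as JSON
#'
#' Canonical plain-text fixture format for DIA chromatogram batches.
#'
#' @param runs List of \code{\link{dia_run}} objects.
#' @param path JSON file path.
#' @return \code{write_dia_json}: invisibly, \code{path};
#'   \code{read_dia_json}: a list of \code{\link{dia_run}}s.
#' @export
write_dia_json <- function(runs, path) {
  payload <- lapply(runs, function(r) list(
    sample_id = r$sample_id, role = r$role,
    windows = apply(r$windows, 1, function(w)
      list(lo = w[[1]], hi = w[[2]]), simplify = FALSE),
    traces = lapply(r$traces, function(tr) list(
      window = as.numeric(tr$window), product_mz = tr$product_mz,
      rt = tr$rt, intensity = tr$intensity))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dia_json
#' @export
read_dia_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(r) {
    win <- do.call(rbind, lapply(r$windows, function(w)
      c(lo = w$lo, hi = w$hi)))
    traces <- lapply(r$traces, function(tr)
      list(window = as.numeric(unlist(tr$window)),
           product_mz = tr$product_mz,
           rt = as.numeric(unlist(tr$rt)),
           intensity = as.numeric(unlist(tr$intensity))))
    dia_run(r$sample_id, r$role, traces, win)
  })
}

#' Extract transition chromatograms for a compound library
#'
#' For each library compound, finds the precursor window covering its
#' precursor m/z and collects the traces whose product m/z lies within
#' \code{mz_tol} of a library transition. Compounds whose precursor is
#' outside every window are skipped with a warning.
#'
#' @param run A \code{\link{dia_run}}.
#' @param lib A \code{"transition_library"} data frame.
#' @param mz_tol Product m/z tolerance in Da (default 0.025).
#' @return Named list (by compound) of per-transition trace lists; a
#'   transition with no matching trace gets \code{NULL}.
#' @export
extract_eics <- function(run, lib, mz_tol = 0.025) {
  out <- list()
  for (cmpd in unique(lib$compound)) {
    sub <- lib[lib$compound == cmpd, , drop = FALSE]
    prec <- sub$precursor_mz[1]
    in_win <- any(run$windows[, 1] <= prec & prec <= run$windows[, 2])
    if (!is.na(prec) && !in_win) {
      warning("precursor ", prec, " of '", cmpd,
              "' outside all DIA windows; skipped", call. = FALSE)
      next
    }
    ref_rt <- sub$reference_rt[1]
    traces <- lapply(seq_len(nrow(sub)), function(k) {
      hit <- Filter(function(tr) {
        abs(tr$product_mz - sub$product_mz[k]) <= mz_tol &&
          (is.na(prec) ||
             (tr$window[1] <= prec && prec <= tr$window[2]))
      }, run$traces)
      if (!length(hit)) return(NULL)
      ## closest product m/z wins; ties prefer a trace covering the
      ## compound's reference RT (traces may be RT-local extractions)
      dmz <- vapply(hit, function(tr)
        abs(tr$product_mz - sub$product_mz[k]), numeric(1))
      covers <- vapply(hit, function(tr) {
        !is.na(ref_rt) && ref_rt >= tr$rt[1] &&
          ref_rt <= tr$rt[length(tr$rt)]
      }, logical(1))
      hit[[order(dmz, !covers)[1]]]
    })
    names(traces) <- sprintf("%.4f", sub$product_mz)
    out[[cmpd]] <- traces
  }
  out
}

#' Detect chromatographic peaks in one trace
#'
#' Moving-average smoothing (window 2 x level + 1), local-maximum
#' detection, a minimum contiguous width at half height, a minimum apex
#' height, and trapezoidal area over the peak bounds (descent from the
#' apex to the local baseline).
#'
#' @param trace List with \code{rt} and \code{intensity}.
#' @param smoothing_level Half-width of the moving average (default 1).
#' @param min_width Minimum number of points at or above half height
#'   (default 5).
#' @param min_height Minimum apex height (default 100).
#' @return Data frame of peaks: \code{rt_apex}, \code{height},
#'   \code{area}, \code{width_points}, \code{left}, \code{right}
#'   (point indices). Empty when the trace is shorter than the smoothing
#'   window.
#' @export
detect_peaks <- function(trace, smoothing_level = 1, min_width = 5,
                         min_height = 100) {
  empty <- data.frame(rt_apex = numeric(), height = numeric(),
                      area = numeric(), width_points = integer(),
                      left = integer(), right = integer())
  y0 <- trace$intensity
  n <- length(y0)
  w <- 2 * smoothing_level + 1
  if (n < max(w, min_width)) {
    message("trace shorter than smoothing window; no peaks")
    return(empty)
  }
  y <- if (smoothing_level > 0) {
    sm <- stats::filter(y0, rep(1 / w, w), sides = 2)
    as.numeric(ifelse(is.na(sm), y0, sm))
  } else y0
  rt <- trace$rt
  peaks <- list()
  for (i in seq.int(2L, n - 1L)) {
    if (!(y[i] > y[i - 1] && y[i] >= y[i + 1])) next
    ## descend to local minima on both sides
    l <- i
    while (l > 1 && y[l - 1] <= y[l]) l <- l - 1
    r <- i
    while (r < n && y[r + 1] <= y[r]) r <- r + 1
    apex <- y[i]
    if (apex < min_height) next
    half <- apex / 2
    span <- l:r
    above <- span[y[span] >= half]
    ## contiguous half-height run containing the apex
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    width <- 0L
    for (rn in runs) if (i %in% rn) width <- length(rn)
    if (width < min_width) next
    area <- sum(diff(rt[span]) * (y0[span][-1] + y0[span][-length(span)]) / 2)
    peaks[[length(peaks) + 1L]] <- data.frame(
      rt_apex = rt[i], height = apex, area = area,
      width_points = width, left = l, right = r)
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Score a compound's transition group in one run
#'
#' Composite presence score over four components: retention-time
#' agreement (1 - |drt|/rt_tol, clamped; 1 when the library has no
#' reference RT), precursor-product ion-ratio agreement (1 - mean
#' relative deviation / amp_tol, clamped), peak-shape similarity (mean
#' pairwise correlation of the transition traces over the peak span) and
#' coelution (fraction of transition apexes within rt_tol of the group
#' median). The posterior score is 100 x the mean of available
#' components.
#'
#' @param eics Per-transition trace list for one compound (from
#'   \code{\link{extract_eics}}).
#' @param lib_entry Rows of the transition library for this compound.
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @param amp_tol Amplitude (ion-ratio) tolerance as a fraction
#'   (default 0.15).
#' @param smoothing_level,min_width,min_height Peak-detection settings
#'   (see \code{\link{detect_peaks}}).
#' @return One-row data frame of class \code{"mrm_result"}: compound,
#'   rt_observed, total_area, the four sub-scores, posterior_score,
#'   n_transitions.
#' @export
score_compound <- function(eics, lib_entry, rt_tol = 0.1, amp_tol = 0.15,
                           smoothing_level = 1, min_width = 5,
                           min_height = 100) {
  cmpd <- lib_entry$compound[1]
  found <- list()
  for (k in seq_len(nrow(lib_entry))) {
    tr <- eics[[k]]
    if (is.null(tr)) next
    pk <- detect_peaks(tr, smoothing_level, min_width, min_height)
    if (!nrow(pk)) next
    ref_rt <- lib_entry$reference_rt[k]
    best <- if (!is.na(ref_rt)) which.min(abs(pk$rt_apex - ref_rt)) else
      which.max(pk$height)
    found[[length(found) + 1L]] <- list(
      trace = tr, peak = pk[best, ], ref_int = lib_entry$rel_intensity[k])
  }
  if (!length(found))
    return(structure(data.frame(
      compound = cmpd, rt_observed = NA_real_, total_area = 0,
      rt_score = NA_real_, ratio_score = NA_real_, shape_score = NA_real_,
      coelution_score = NA_real_, posterior_score = 0,
      n_transitions = 0L), class = c("mrm_result", "data.frame")))
  apexes <- vapply(found, function(f) f$peak$rt_apex, numeric(1))
  heights <- vapply(found, function(f) f$peak$height, numeric(1))
  areas <- vapply(found, function(f) f$peak$area, numeric(1))
  rt_obs <- apexes[which.max(heights)]
  ref_rt <- lib_entry$reference_rt[1]
  rt_score <- if (is.na(ref_rt)) 1 else
    1 - min(abs(rt_obs - ref_rt) / rt_tol, 1)
  ## ion ratios relative to the most intense transition
  ratio_score <- if (length(found) >= 2) {
    obs <- heights / max(heights)
    ref <- vapply(found, function(f) f$ref_int, numeric(1))
    ref <- ref / max(ref)
    dev <- mean(abs(obs - ref) / ref)
    1 - min(dev / amp_tol, 1)
  } else NA_real_
  ## shape: mean pairwise correlation over the union peak span
  shape_score <- if (length(found) >= 2) {
    lo <- min(vapply(found, function(f) f$peak$left, numeric(1)))
    hi <- max(vapply(found, function(f) f$peak$right, numeric(1)))
    segs <- lapply(found, function(f) {
      idx <- seq.int(lo, min(hi, length(f$trace$intensity)))
      f$trace$intensity[idx]
    })
    len <- min(lengths(segs))
    segs <- lapply(segs, function(s) s[seq_len(len)])
    cors <- c()
    for (i in seq_len(length(segs) - 1))
      for (j in seq.int(i + 1, length(segs))) {
        if (stats::sd(segs[[i]]) == 0 || stats::sd(segs[[j]]) == 0) next
        cors <- c(cors, stats::cor(segs[[i]], segs[[j]]))
      }
    if (length(cors)) max(0, mean(cors)) else NA_real_
  } else NA_real_
  coelution_score <- mean(abs(apexes - stats::median(apexes)) <= rt_tol)
  subs <- c(rt = rt_score, ratio = ratio_score, shape = shape_score,
            coelution = coelution_score)
  posterior <- 100 * mean(subs, na.rm = TRUE)
  structure(data.frame(
    compound = cmpd, rt_observed = rt_obs, total_area = sum(areas),
    rt_score = rt_score, ratio_score = ratio_score,
    shape_score = shape_score, coelution_score = coelution_score,
    posterior_score = posterior, n_transitions = length(found)),
    class = c("mrm_result", "data.frame"))
}

#' Presence call against blanks
#'
#' A compound is present in a sample when its posterior score reaches
#' the threshold and its total transition area is at least
#' \code{min_blank_ratio} times the largest blank area for the same
#' compound.
#'
#' @param result An \code{"mrm_result"} row for a sample run.
#' @param blank_results List (possibly empty) of \code{"mrm_result"}
#'   rows from blank runs of the same batch.
#' @param min_blank_ratio Required sample/blank area ratio (default 3).
#' @param score_threshold Minimum posterior score, percent (default 60).
#' @param blank_floor Substitute for an all-zero blank area (default 1).
#' @return The result with \code{blank_ratio} and logical \code{present}
#'   added.
#' @export
call_presence <- function(result, blank_results = list(),
                          min_blank_ratio = 3, score_threshold = 60,
                          blank_floor = 1) {
  bmax <- if (length(blank_results))
    max(vapply(blank_results, function(b) b$total_area, numeric(1))) else 0
  bmax <- max(bmax, blank_floor)
  result$blank_ratio <- result$total_area / bmax
  result$present <- result$posterior_score >= score_threshold &
    result$blank_ratio >= min_blank_ratio
  result
}

#' Screen a DIA batch against a transition library
#'
#' Runs extraction, peak detection, scoring and blank-referenced
#' presence calls for every compound in every run of a batch.
#'
#' @param runs List of \code{\link{dia_run}} objects (samples and
#'   blanks).
#' @param lib A \code{"transition_library"}.
#' @param mz_tol Product-ion extraction tolerance in Da (default 0.025).
#' @param rt_tol,amp_tol,score_threshold,min_blank_ratio Screening
#'   thresholds (defaults 0.1 min, 0.15, 60, 3).
#' @param smoothing_level,min_width,min_height Peak-detection settings.
#' @return Data frame: one row per compound x non-blank run with all
#'   score components and the presence flag.
#' @export
screen_batch <- function(runs, lib, mz_tol = 0.025, rt_tol = 0.1,
                         amp_tol = 0.15, score_threshold = 60,
                         min_blank_ratio = 3, smoothing_level = 1,
                         min_width = 5, min_height = 100) {
  score_run <- function(run) {
    eics <- extract_eics(run, lib, mz_tol = mz_tol)
    res <- lapply(names(eics), function(cmpd) {
      le <- lib[lib$compound == cmpd, , drop = FALSE]
      r <- score_compound(eics[[cmpd]], le, rt_tol = rt_tol,
                          amp_tol = amp_tol,
                          smoothing_level = smoothing_level,
                          min_width = min_width, min_height = min_height)
      r$sample_id <- run$sample_id
      r$role <- run$role
      r
    })
    do.call(rbind, res)
  }
  all_res <- lapply(runs, score_run)
  flat <- do.call(rbind, all_res)
  is_blank <- flat$role == "blank"
  out <- lapply(which(!is_blank), function(k) {
    blanks <- which(is_blank & flat$compound == flat$compound[k])
    call_presence(flat[k, ], lapply(blanks, function(b) flat[b, ]),
                  min_blank_ratio = min_blank_ratio,
                  score_threshold = score_threshold)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
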