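## Seeded generators for every input the pipeline consumes. The
## statistical structure mirrors what the cleaning and screening steps
## assume: log-normal compound abundances, multiplicative intensity
## noise (so features of one compound correlate across samples), pooled
## QC as the sample mean, blanks as a configurable contamination
## fraction, Gaussian chromatographic peaks.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## random plausible composition: even-electron RDBE in [0, 15]
.random_composition <- function() {
  repeat {
    nc <- sample(5:30, 1)
    no <- sample(0:5, 1)
    nn <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
    ns <- sample(0:1, 1, prob = c(0.9, 0.1))
    ncl <- sample(0:1, 1, prob = c(0.9, 0.1))
    r <- sample(0:10, 1)  # rings + double bonds
    nh <- 2 * nc + 2 + nn - ncl - 2 * r
    if (nh < 1 || nh > 4 * nc) next
    comp <- c(C = nc, H = nh, N = nn, O = no, S = ns, Cl = ncl)
    return(as_composition(comp))
  }
}

#' Generate a synthetic MS/MS spectral library
#'
#' Deterministic per seed. Formulas are drawn from C/H/N/O/S/Cl with
#' integral non-negative RDBE; fragment peaks are sub-formula masses
#' plus the adduct charge carrier, with optional low-intensity noise
#' peaks.
#'
#' @param n_compounds Number of records (>= 1).
#' @param seed Integer seed.
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @param n_fragments Fragments per spectrum (default 8).
#' @param noise_peaks Number of random noise peaks appended (default 0).
#' @param provenance Source label stamped on the records.
#' @return A \code{\link{spectral_library}}.
#' @export
make_library <- function(n_compounds, seed = 1, polarity = "positive",
                         n_fragments = 8, noise_peaks = 0,
                         provenance = "synthetic") {
  stopifnot(n_compounds >= 1)
  .with_seed(seed, {
    adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
    a <- adduct_lookup(adduct)
    records <- lapply(seq_len(n_compounds), function(i) {
      comp <- .random_composition()
      m <- monoisotopic_mass(comp)
      prec <- adduct_mz(m, a)
      subs <- .subformula_masses(comp)
      subs <- subs[subs > m * 0.15 & subs < m - 0.5]
      k <- min(n_fragments, length(subs))
      frag_mz <- sample(subs, k) + a$mass_delta
      frag_int <- round(stats::runif(k, 5, 100), 1)
      if (noise_peaks > 0) {
        frag_mz <- c(frag_mz, stats::runif(noise_peaks, 50, prec))
        frag_int <- c(frag_int, round(stats::runif(noise_peaks, 1, 5), 1))
      }
      spectrum_record(
        name = sprintf("SYN-%03d", i),
        precursor_mz = round(prec, 4),
        precursor_type = adduct, ion_mode = polarity,
        formula = serialize_formula(comp),
        inchikey = paste0(
          paste(sample(LETTERS, 14, replace = TRUE), collapse = ""),
          "-", paste(sample(LETTERS, 10, replace = TRUE), collapse = ""),
          "-N"),
        retention_time = round(stats::runif(1, 1, 12), 2),
        provenance = provenance,
        peaks = cbind(round(frag_mz, 4), frag_int))
    })
    spectral_library(records, dialect = "canonical")
  })
}

#' Generate a synthetic aligned feature table
#'
#' Each library compound emits one feature per adduct; all features of a
#' compound share its per-sample latent abundance (log-normal across
#' samples) times adduct-specific response, under multiplicative
#' log-normal noise of coefficient of variation \code{noise_cv} -- so
#' adduct pairs correlate across samples. QC columns are the sample mean
#' under small noise; blanks sit at \code{blank_level} of the mean
#' sample signal. Optionally plants co-eluting in-source fragments that
#' share the parent abundance.
#'
#' @param lib A \code{\link{spectral_library}} (e.g. from
#'   \code{\link{make_library}}).
#' @param n_samples,n_blanks,n_qc Column counts (defaults 6, 3, 3).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param blank_level Blank contamination as a fraction of mean sample
#'   signal (default 0.01).
#' @param adducts Adduct names emitted per compound (default
#'   \code{c("[M+H]+", "[M+Na]+")} for positive mode).
#' @param fragment_fraction Fraction of compounds that also emit an
#'   in-source fragment feature (default 0).
#' @param mean_log_abundance,sd_log_abundance Parameters of the latent
#'   log-normal abundance (defaults log(1e5) and 0.8).
#' @param seed Integer seed.
#' @return A \code{\link{feature_table}}; the generating compound and
#'   role of every feature are recorded in
#'   \code{features$truth_compound} and \code{features$truth_role}.
#' @export
make_feature_table <- function(lib, n_samples = 6, n_blanks = 3,
                               n_qc = 3, noise_cv = 0.05,
                               blank_level = 0.01,
                               adducts = c("[M+H]+", "[M+Na]+"),
                               fragment_fraction = 0,
                               mean_log_abundance = log(1e5),
                               sd_log_abundance = 0.8, seed = 1) {
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- function(x) x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
    samples <- sprintf("S%02d", seq_len(n_samples))
    blanks <- sprintf("B%02d", seq_len(n_blanks))
    qcs <- sprintf("QC%02d", seq_len(n_qc))
    roles <- data.frame(
      sample_id = c(samples, blanks, qcs),
      role = c(rep("sample", n_samples), rep("blank", n_blanks),
               rep("qc", n_qc)))
    feats <- list()
    ints <- list()
    ms2 <- list()
    fid <- 0L
    for (rec in lib$records) {
      abundance <- stats::rlnorm(n_samples, mean_log_abundance,
                                 sd_log_abundance)
      neutral <- monoisotopic_mass(rec$formula)
      rt <- rec$retention_time
      emit <- function(mz, response, role, ms2_peaks = NULL) {
        fid <<- fid + 1L
        id <- sprintf("F%04d", fid)
        s <- noisy(abundance * response)
        b <- noisy(rep(mean(abundance) * response * blank_level,
                       n_blanks))
        q <- noisy(rep(mean(s), n_qc) * 1)
        feats[[fid]] <<- data.frame(
          feature_id = id, mz = mz, rt = rt,
          polarity = rec$ion_mode, adduct = NA_character_,
          truth_compound = rec$name, truth_role = role)
        ints[[fid]] <<- c(s, b, q)
        if (!is.null(ms2_peaks)) ms2[[id]] <<- ms2_peaks
        id
      }
      responses <- stats::runif(length(adducts), 0.2, 1)
      responses[1] <- 1
      for (ai in seq_along(adducts)) {
        emit(adduct_mz(neutral, adducts[ai]), responses[ai],
             if (ai == 1) "parent" else "adduct",
             ms2_peaks = if (ai == 1) rec$peaks)
      }
      if (stats::runif(1) < fragment_fraction && nrow(rec$peaks) >= 1) {
        fmz <- rec$peaks[which.max(rec$peaks[, 2]), 1]
        emit(fmz, 0.4, "in_source_fragment")
      }
    }
    feats <- do.call(rbind, feats)
    ints <- do.call(rbind, ints)
    colnames(ints) <- roles$sample_id
    feature_table(feats, ints, roles, ms2 = ms2)
  })
}

#' Generate a synthetic DIA batch
#'
#' Present compounds produce Gaussian peaks at their reference RT (plus
#' optional jitter) on every transition, with heights proportional to
#' the library's relative intensities; the base transition peaks at
#' \code{base_height}. Baseline noise is uniform at
#' \code{base_height / snr}. Blank runs carry \code{blank_fraction} of
#' the sample signal for contaminated compounds.
#'
#' @param lib A \code{"transition_library"}.
#' @param present_map Named list: sample_id -> character vector of
#'   compounds present in it.
#' @param roles Named character vector sample_id -> role; defaults to
#'   \code{"sample"} for every name of \code{present_map}.
#' @param blank_contaminated Compounds carried into blanks (default
#'   none).
#' @param snr Signal-to-noise ratio of the base transition (default 20).
#' @param base_height Apex height of the base transition (default 5000).
#' @param blank_fraction Blank contamination level as a fraction of
#'   \code{base_height} (default 0.1).
#' @param rt_jitter SD of the per-run apex shift in minutes (default
#'   0.01).
#' @param peak_sigma Gaussian peak SD in minutes (default 0.03).
#' @param dt Sampling interval in minutes (default 0.01).
#' @param seed Integer seed.
#' @return List of \code{\link{dia_run}} objects.
#' @export
make_dia_batch <- function(lib, present_map, roles = NULL,
                           blank_contaminated = character(), snr = 20,
                           base_height = 5000, blank_fraction = 0.1,
                           rt_jitter = 0.01, peak_sigma = 0.03,
                           dt = 0.01, seed = 1) {
  if (is.null(roles))
    roles <- stats::setNames(rep("sample", length(present_map)),
                             names(present_map))
  .with_seed(seed, {
    lapply(names(present_map), function(sid) {
      role <- roles[[sid]]
      traces <- list()
      for (cmpd in unique(lib$compound)) {
        sub <- lib[lib$compound == cmpd, , drop = FALSE]
        ref_rt <- sub$reference_rt[1]
        rt <- seq(max(0, ref_rt - 0.5), ref_rt + 0.5, by = dt)
        present <- cmpd %in% present_map[[sid]]
        contaminated <- role == "blank" && cmpd %in% blank_contaminated
        apex_rt <- ref_rt + stats::rnorm(1, 0, rt_jitter)
        for (k in seq_len(nrow(sub))) {
          h <- base_height * sub$rel_intensity[k] / 100
          sig <- if (present && role != "blank") {
            h * exp(-(rt - apex_rt)^2 / (2 * peak_sigma^2))
          } else if (contaminated) {
            h * blank_fraction * exp(-(rt - apex_rt)^2 /
                                       (2 * peak_sigma^2))
          } else 0
          noise <- stats::runif(length(rt), 0, base_height / snr)
          traces[[length(traces) + 1L]] <- list(
            window = c(0, 2000), product_mz = sub$product_mz[k],
            rt = rt, intensity = sig + noise)
        }
      }
      dia_run(sid, role = role, traces = traces)
    })
  })
}
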