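## Independent oracles used across the suite. These deliberately do not
## share code paths with the package implementation.

## published lightest-isotope masses, restated here so mass oracles do not
## read the package's internal table
oracle_masses <- c(C = 12, H = 1.00782503207, O = 15.9949146196,
                   N = 14.0030740048, P = 30.97376163, S = 31.97207100,
                   F = 18.99840322, Cl = 34.96885268,
                   Na = 22.9897692809, K = 38.96370668)

oracle_mass <- function(counts) {
  sum(oracle_masses[names(counts)] * unname(counts))
}

## brute-force isotope distribution: full expansion over every isotopologue
## (feasible for <= 5 atoms), no pruning, no binning
oracle_isotopes <- list(
  C = cbind(m = c(12, 13.0033548378), p = c(0.9893, 0.0107)),
  H = cbind(m = c(1.00782503207, 2.0141017778), p = c(0.999885, 0.000115)),
  O = cbind(m = c(15.9949146196, 16.9991317, 17.9991610),
            p = c(0.99757, 0.00038, 0.00205)),
  Cl = cbind(m = c(34.96885268, 36.96590259), p = c(0.7576, 0.2424))
)

oracle_isotope_pattern <- function(counts) {
  atoms <- rep(names(counts), unname(counts))
  grids <- lapply(atoms, function(a) seq_len(nrow(oracle_isotopes[[a]])))
  combos <- expand.grid(grids)
  mass <- apply(combos, 1, function(idx)
    sum(mapply(function(a, i) oracle_isotopes[[a]][i, "m"], atoms, idx)))
  prob <- apply(combos, 1, function(idx)
    prod(mapply(function(a, i) oracle_isotopes[[a]][i, "p"], atoms, idx)))
  agg <- rowsum(prob, round(mass, 3))
  data.frame(mz = as.numeric(rownames(agg)), p = agg[, 1])
}

## brute-force greedy peak pairing + composite score, written over a
## distance matrix rather than the package's per-peak scan
oracle_spectral_score <- function(q, r, tol = 0.025,
                                  w = c(0.5, 0.25, 0.25)) {
  d <- abs(outer(q[, 1], r[, 1], `-`))
  d[d > tol] <- Inf
  pairs <- NULL
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, k)
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  qi <- q[, 2]; ri <- r[, 2]
  dot <- if (is.null(pairs)) 0 else sum(qi[pairs[, 1]] * ri[pairs[, 2]])
  cosine <- dot / sqrt(sum(qi^2) * sum(ri^2))
  rq <- numeric(length(ri))
  if (!is.null(pairs)) rq[pairs[, 2]] <- qi[pairs[, 1]]
  rev_cos <- if (sum(rq^2) == 0) 0 else
    sum(rq * ri) / sqrt(sum(rq^2) * sum(ri^2))
  frac <- if (is.null(pairs)) 0 else nrow(pairs) / nrow(r)
  100 * sum(w * c(cosine, rev_cos, frac))
}

## Table 1 fixture shipped with the package
table1 <- function() {
  utils::read.delim(system.file("extdata", "table1_migrants.tsv",
                                package = "migrantscreen"),
                    na.strings = c("NA", ""))
}

## random harmonizable spectrum records for round-trip properties
random_records <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(3:10, 1)
    spectrum_record(
      name = paste0("R", i),
      precursor_mz = round(runif(1, 100, 900), 4),
      precursor_type = sample(c("[M+H]+", "[M-H]-", "[M+Na]+"), 1),
      ion_mode = sample(c("positive", "negative"), 1),
      formula = NA_character_,
      inchikey = paste0(paste(sample(LETTERS, 14, TRUE), collapse = ""),
                        "-", paste(sample(LETTERS, 10, TRUE),
                                   collapse = ""), "-N"),
      retention_time = round(runif(1, 0.5, 12), 4),
      collision_energy = sample(c("20", "40", NA), 1),
      provenance = sample(c("libA", "libB"), 1),
      peaks = cbind(round(sort(runif(k, 50, 800)), 4),
                    round(runif(k, 1, 100), 4)))
  })
}
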