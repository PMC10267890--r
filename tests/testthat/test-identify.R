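spec <- function(mz, int) cbind(mz, int)

test_that("spectral score extremes and symmetry behave", {
  s <- spec(c(55.1, 79.2, 107.5), c(100, 40, 10))
  expect_equal(spectral_score(s, s), 100, tolerance = 1e-12)
  disjoint <- spec(c(200.1, 300.2), c(50, 50))
  expect_equal(spectral_score(disjoint, s), 0)
  ## cosine symmetry: weights isolate the cosine component
  a <- spec(c(55.1, 79.2, 107.5), c(100, 40, 10))
  b <- spec(c(55.11, 79.19, 150.0), c(80, 60, 20))
  expect_equal(spectral_score(a, b, weights = c(1, 0, 0)),
               spectral_score(b, a, weights = c(1, 0, 0)),
               tolerance = 1e-12)
})

test_that("spectral score equals the brute-force pairing oracle", {
  set.seed(77)
  for (i in 1:20) {
    ref_mz <- sort(stats::runif(8, 50, 400))
    ref <- spec(ref_mz, stats::runif(8, 5, 100))
    ## query: 80% of reference peaks slightly shifted, plus noise peaks
    keep <- sort(sample(8, 6))
    qry <- spec(c(ref_mz[keep] + stats::runif(6, -0.01, 0.01),
                  stats::runif(3, 50, 400)),
                c(ref[keep, 2] * stats::runif(6, 0.7, 1.3),
                  stats::runif(3, 1, 10)))
    qry <- qry[order(qry[, 1]), ]
    expect_equal(spectral_score(qry, ref),
                 oracle_spectral_score(qry, ref), tolerance = 1e-9)
  }
})

test_that("spectral match applies MS1 gate and the 80% cutoff", {
  ref_peaks <- spec(c(55.05, 79.05, 97.09), c(100, 40, 12))
  mk <- function(name, prec) spectrum_record(
    name, precursor_mz = prec, precursor_type = "[M+H]+",
    ion_mode = "positive", peaks = ref_peaks)
  lib <- spectral_library(list(mk("target", 114.0913),
                               mk("far", 114.5)))
  hits <- spectral_match(114.0915, ref_peaks, lib)
  expect_equal(hits$name, "target")
  expect_equal(hits$score, 100, tolerance = 1e-9)
  ## a degraded query below the cutoff returns nothing
  weak <- spec(c(55.05, 200.0, 300.0), c(10, 100, 80))
  expect_equal(nrow(spectral_match(114.0915, weak, lib)), 0)
  expect_error(spectral_match(114.0915, NULL, lib), "no MS2")
  expect_equal(nrow(spectral_match(114.0915, ref_peaks,
                                   spectral_library())), 0)
})

test_that("isotope score follows the A+1/A+2 arithmetic", {
  p <- isotope_pattern("C17H26O4")
  expect_equal(isotope_score(p, p), 1)
  shifted <- p
  a <- isotope_a1_a2(p)
  ## perturb A+1 by +0.05: score drops by 0.025 (mean of 0.05 and 0)
  i1 <- which(abs(p$mz - min(p$mz) - 1) < 0.5)[1]
  shifted$abundance[i1] <- p$abundance[i1] + 0.05
  expect_equal(isotope_score(shifted, p), 0.975, tolerance = 1e-6)
  ## missing A+2 counts as zero abundance
  trunc <- p[p$mz < min(p$mz) + 1.5, ]
  expect_equal(isotope_score(trunc, p),
               1 - isotope_a1_a2(p)[["a2"]] / 2, tolerance = 1e-6)
})

test_that("sub-formula fragment score separates signal from noise", {
  comp <- "C10H14N2O2"
  proton <- 1.00727646
  subs <- c("C5H7N", "C8H10N2", "C4H6O2")
  frag_mz <- vapply(subs, function(f)
    monoisotopic_mass(f) + proton, numeric(1))
  ## fully explainable spectrum
  expect_equal(subformula_fragment_score(comp, "[M+H]+",
                                         spec(frag_mz, c(100, 50, 20))),
               1)
  ## prime-offset masses are not sub-formulas
  noise <- spec(c(61.3033, 83.7117, 113.9312), c(100, 50, 20))
  expect_equal(subformula_fragment_score(comp, "[M+H]+", noise), 0)
  ## half the intensity explainable
  half <- spec(c(frag_mz[1], 83.7117), c(100, 100))
  expect_equal(subformula_fragment_score(comp, "[M+H]+", half), 0.5)
  ## invariant to intensity rescaling
  sp <- spec(c(frag_mz[1:2], 83.7117), c(10, 60, 30))
  expect_equal(subformula_fragment_score(comp, "[M+H]+", sp),
               subformula_fragment_score(comp, "[M+H]+",
                                         spec(sp[, 1], sp[, 2] * 1e4)))
})

test_that("database entries validate mass/formula consistency", {
  expect_error(structure_db(data.frame(name = "x", formula = "C6H6",
                                       exact_mass = 100), "volDB"),
               "inconsistent")
  db <- structure_db(data.frame(name = "x", formula = "C6H6"), "volDB",
                     weight = 2)
  expect_equal(db$entries$exact_mass, monoisotopic_mass("C6H6"))
  expect_error(structure_db(data.frame(name = "x", formula = "C6H6"),
                            "volDB", weight = 0))
})

test_that("db search ranks by weighted evidence with weight tie-break", {
  db_hi <- structure_db(data.frame(name = "from_volDB",
                                   formula = "C17H26O4"),
                        "volDB", weight = 2)
  db_lo <- structure_db(data.frame(name = "from_genDB",
                                   formula = "C17H26O4"),
                        "genDB", weight = 1)
  mz <- adduct_mz(monoisotopic_mass("C17H26O4"), "[M-H]-")
  hits <- db_search(mz, list(db_lo, db_hi), adducts = "[M-H]-")
  expect_equal(hits$name[1], "from_volDB")
  expect_equal(hits$final_score[1], hits$base_score[1] * 2)
  expect_equal(hits$rank, c(1, 2))
  ## nothing within tolerance: empty
  expect_equal(nrow(db_search(999.9, list(db_hi), adducts = "[M-H]-")), 0)
  expect_error(db_search(mz, list()), "no structure databases")
})

test_that("raising a database weight never lowers its entries' ranks", {
  entries <- data.frame(
    name = c("a", "b"),
    formula = c("C17H26O4", "C16H22N2O3"))  # both near 294.18 neutral
  mz <- adduct_mz(monoisotopic_mass("C17H26O4"), "[M-H]-")
  rank_of <- function(w) {
    dbs <- list(structure_db(entries[1, ], "one", weight = w),
                structure_db(entries[2, ], "two", weight = 1.2))
    h <- db_search(mz, dbs, adducts = "[M-H]-", ms1_tol = 0.01)
    h$rank[h$name == "a"]
  }
  ranks <- vapply(c(0.5, 1, 1.5, 2, 3), rank_of, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("cppDB-style search identifies the oxidation product", {
  ## precursor-oriented search: the peak at 293.1735 in negative mode
  ## against a plastics database containing the candidate
  cpp <- structure_db(data.frame(
    name = c("irganox1010_hydrolysate", "bystander"),
    formula = c("C17H26O4", "C12H22O11")), "cppDB", weight = 1.5)
  hits <- db_search(293.1735, cpp, polarity = "negative")
  expect_equal(hits$name[1], "irganox1010_hydrolysate")
  expect_equal(hits$adduct[1], "[M-H]-")
})

test_that("annotation merge prefers library hits, then db, else unknown", {
  lh <- data.frame(name = "libhit", formula = "C6H6", score = 86,
                   precursor_mz = 100, adduct = "[M+H]+",
                   inchikey = NA, source = "library_match")
  dh <- data.frame(name = "dbhit", formula = "C7H8", final_score = 6.4,
                   db = "cppDB")
  expect_equal(merge_annotations(lh, dh)$status, "library_match")
  expect_equal(merge_annotations(lh, dh)$name, "libhit")
  m <- merge_annotations(lh[0, ], dh)
  expect_equal(m$status, "db_annotated")
  expect_equal(m$score, 6.4)
  expect_equal(merge_annotations(lh[0, ], dh[0, ])$status, "unknown")
})

test_that("printed precursor/adduct pairs rank their compound first", {
  t1 <- table1()
  db <- structure_db(t1[c("name", "formula")], "table1", weight = 1)
  top_ok <- logical(nrow(t1))
  for (i in seq_len(nrow(t1))) {
    hits <- db_search(t1$precursor_mz[i], db, adducts = t1$adduct[i])
    expect_true(t1$name[i] %in% hits$name,
                label = paste("row", t1$no[i], "found"))
    ## rank 1 among candidates that do not share the printed formula
    distinct <- hits[hits$formula != t1$formula[i] |
                       hits$name == t1$name[i], ]
    top_ok[i] <- distinct$name[1] == t1$name[i]
  }
  expect_gte(sum(top_ok), nrow(t1) - 1)
})
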