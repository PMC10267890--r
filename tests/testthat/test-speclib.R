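msp_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("fix-", as.integer(stats::runif(1, 1, 1e8)),
                                ".msp"))
  writeLines(c(
    "NAME: caprolactam",
    "PRECURSORMZ: 114.0915",
    "PRECURSORTYPE: [M+H]+",
    "IONMODE: Positive",
    "FORMULA: C6H11NO",
    "RETENTIONTIME: 3.11",
    "Num Peaks: 3",
    "55.0542 100",
    "79.0542 40.5",
    "97.0886 12",
    "",
    "Name: palmitic acid",
    "PrecursorMZ: 255.2330",
    "Precursor_type: [M-H]-",
    "Ion_mode: N",
    "MYCUSTOM: kept",
    "Num Peaks: 2",
    "237.2224\t10.0",
    "255.2330\t100.0"
  ), path)
  path
}

test_that("MSP parsing handles dialect synonyms and preserves extras", {
  lib <- read_msp(msp_fixture())
  expect_equal(length(lib), 2L)
  r1 <- lib$records[[1]]
  r2 <- lib$records[[2]]
  expect_equal(r1$name, "caprolactam")
  expect_equal(r1$precursor_mz, 114.0915)
  expect_equal(r2$precursor_mz, 255.2330)  # synonym-cased keys
  expect_equal(r1$ion_mode, "positive")
  expect_equal(r2$ion_mode, "negative")
  expect_equal(nrow(r1$peaks), 3)
  expect_equal(r2$extras$MYCUSTOM, "kept")
  expect_equal(lib$polarity, "mixed")
})

test_that("malformed MSP blocks error with the block index", {
  bad <- tempfile(fileext = ".msp")
  writeLines(c("NAME: ok", "Num Peaks: 1", "100 1", "",
               "NAME: broken", "100 1"), bad)
  expect_error(read_msp(bad), "block 2")
  mism <- tempfile(fileext = ".msp")
  writeLines(c("NAME: short", "Num Peaks: 3", "100 1", "101 2"), mism)
  expect_warning(read_msp(mism), "declared 3")
  expect_error(read_msp(mism, peak_mismatch = "error"), "declared 3")
  expect_error(read_msp(tempfile()), "not found")
})

test_that("canonical MSP write/read round-trips every field", {
  lib <- spectral_library(random_records(12, seed = 21))
  f <- tempfile(fileext = ".msp")
  write_msp(lib, f)
  back <- read_msp(f)
  expect_equal(length(back), length(lib))
  for (i in seq_along(lib$records)) {
    a <- lib$records[[i]]
    b <- back$records[[i]]
    for (field in c("name", "precursor_type", "ion_mode", "inchikey",
                    "collision_energy", "provenance"))
      expect_equal(b[[field]], a[[field]], label = field)
    expect_equal(b$precursor_mz, a$precursor_mz, tolerance = 1e-6)
    expect_equal(b$retention_time, a$retention_time, tolerance = 1e-4)
    expect_equal(unname(b$peaks), unname(a$peaks), tolerance = 1e-6)
  }
  ## empty library: a file with zero blocks
  f2 <- tempfile(fileext = ".msp")
  write_msp(spectral_library(), f2)
  expect_equal(length(read_msp(f2)), 0L)
})

test_that("polarity split partitions records and write honours it", {
  lib <- spectral_library(random_records(15, seed = 5))
  halves <- split_by_polarity(lib)
  expect_equal(length(halves$positive) + length(halves$negative),
               length(lib))
  expect_true(all(vapply(halves$negative$records, `[[`, character(1),
                         "ion_mode") == "negative"))
  f <- tempfile(fileext = ".msp")
  paths <- write_msp(lib, f, split_polarity = TRUE)
  expect_equal(length(read_msp(paths[1])), length(halves$positive))
  expect_equal(length(read_msp(paths[2])), length(halves$negative))
})

test_that("harmonization normalizes adducts, rescales and flags", {
  rec <- spectrum_record("caprolactam", precursor_mz = 114.0915,
                         precursor_type = "[M+H]", formula = "C6H11NO",
                         peaks = cbind(c(55.05, 79.05), c(50, 20)))
  h <- harmonize_record(rec)
  expect_equal(h$precursor_type, "[M+H]+")
  expect_equal(h$ion_mode, "positive")
  expect_equal(max(h$peaks[, "intensity"]), 100)
  expect_false("precursor_inconsistent" %in% h$flags)
  ## forced inconsistency: same formula/adduct, wrong precursor
  rec$precursor_mz <- 120.0000
  expect_true("precursor_inconsistent" %in%
                harmonize_record(rec)$flags)
  ## fragment above precursor flagged, not rejected
  rec2 <- spectrum_record("x", precursor_mz = 100,
                          peaks = cbind(c(50, 180), c(10, 100)))
  expect_true("fragments_above_precursor" %in%
                harmonize_record(rec2)$flags)
})

test_that("deduplication keys on inchikey block + adduct + energy", {
  mk <- function(name, ik, adduct, ce, prov, npk) {
    spectrum_record(name, precursor_mz = 200, precursor_type = adduct,
                    ion_mode = "positive", inchikey = ik,
                    collision_energy = ce, provenance = prov,
                    peaks = cbind(100 + seq_len(npk), seq_len(npk)))
  }
  lib <- spectral_library(list(
    mk("a", "AAAAAAAAAAAAAA-BBBBBBBBBB-N", "[M+H]+", "20", "libB", 3),
    mk("a", "AAAAAAAAAAAAAA-CCCCCCCCCC-N", "[M+H]+", "20", "libA", 2),
    mk("b", "DDDDDDDDDDDDDD-EEEEEEEEEE-N", "[M+H]+", "20", "libB", 4)))
  dd <- deduplicate(lib, priority = c("libA", "libB"))
  expect_equal(length(dd), 2L)  # first two share the 2D skeleton key
  expect_equal(vapply(dd$records, `[[`, character(1), "provenance"),
               c("libA", "libB"))
  ## idempotent; identity when keys are disjoint
  expect_equal(deduplicate(dd, priority = c("libA", "libB")), dd)
  solo <- spectral_library(list(mk("c", "FFFFFFFFFFFFFF-GGGGGGGGGG-N",
                                   "[M+Na]+", "20", "libA", 2)))
  expect_equal(length(deduplicate(solo)), 1L)
})

test_that("library compilation is priority-driven and order-stable", {
  recs <- random_records(8, seed = 31)
  libA <- spectral_library(recs[1:5])
  libB <- spectral_library(recs[4:8])  # overlap on 4, 5
  for (r in seq_along(libA$records)) libA$records[[r]]$provenance <- "A"
  for (r in seq_along(libB$records)) libB$records[[r]]$provenance <- "B"
  ab <- compile_libraries(list(libA, libB), priority = c("A", "B"))
  ba <- compile_libraries(list(libB, libA), priority = c("A", "B"))
  expect_equal(length(ab), 8L)
  expect_equal(ab, ba)
  dup_names <- vapply(recs[4:5], `[[`, character(1), "name")
  prov <- vapply(ab$records, `[[`, character(1), "provenance")
  nm <- vapply(ab$records, `[[`, character(1), "name")
  expect_true(all(prov[nm %in% dup_names] == "A"))
  ## idempotence and empty input
  expect_equal(length(compile_libraries(list(ab), priority = "A")), 8L)
  expect_equal(length(compile_libraries(list())), 0L)
})

test_that("transition export takes top-5 ions, normalized, ties to low m/z", {
  rec8 <- spectrum_record("eight", precursor_mz = 400,
                          retention_time = 5,
                          peaks = cbind(101:108,
                                        c(10, 80, 30, 60, 20, 90, 5, 40)))
  tl <- export_transitions(spectral_library(list(rec8)))
  expect_equal(nrow(tl), 5)
  expect_equal(tl$rel_intensity[1], 100)
  expect_true(all(diff(tl$rel_intensity) <= 0))
  expect_equal(tl$product_mz, c(106, 102, 104, 108, 103))
  ## fewer peaks than top_n: export all
  rec3 <- spectrum_record("three", precursor_mz = 300, retention_time = 2,
                          peaks = cbind(c(90, 110, 150), c(5, 50, 10)))
  expect_equal(nrow(export_transitions(spectral_library(list(rec3)))), 3)
  ## tie at the cut rank: lower m/z wins
  rect <- spectrum_record("tie", precursor_mz = 300, retention_time = 2,
                          peaks = cbind(c(100, 110, 120, 130, 140, 150),
                                        c(90, 80, 70, 60, 50, 50)))
  tlt <- export_transitions(spectral_library(list(rect)))
  expect_true(140 %in% tlt$product_mz)
  expect_false(150 %in% tlt$product_mz)
  ## missing reference RT flagged but exported
  recna <- spectrum_record("nort", precursor_mz = 210,
                           peaks = cbind(c(100, 120), c(100, 10)))
  tn <- export_transitions(spectral_library(list(recna)))
  expect_true(all(tn$rt_missing))
  f <- tempfile(fileext = ".tsv")
  write_transitions(rbind(tl, tn), f)
  back <- read_transitions(f)
  expect_equal(back$product_mz, c(tl$product_mz, tn$product_mz))
  expect_equal(back$rt_missing, c(rep(FALSE, 5), TRUE, TRUE))
})

test_that("generated libraries survive the canonical round trip", {
  lib <- make_library(10, seed = 2, noise_peaks = 2)
  f <- tempfile(fileext = ".msp")
  write_msp(lib, f)
  back <- read_msp(f)
  for (i in seq_along(lib$records)) {
    expect_equal(back$records[[i]]$name, lib$records[[i]]$name)
    expect_equal(unname(back$records[[i]]$peaks),
                 unname(lib$records[[i]]$peaks), tolerance = 1e-6)
  }
})
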