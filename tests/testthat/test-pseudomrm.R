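gaussian_trace <- function(apex = 1000, rt0 = 5, sigma = 0.03,
                           dt = 0.005, span = 0.5, baseline = 0) {
  rt <- seq(rt0 - span, rt0 + span, by = dt)
  list(window = c(0, 2000), product_mz = 100,
       rt = rt, intensity = apex * exp(-(rt - rt0)^2 / (2 * sigma^2)) +
         baseline)
}

test_that("peak detection recovers a Gaussian's apex and area", {
  tr <- gaussian_trace(apex = 1000, sigma = 0.03)
  pk <- detect_peaks(tr, smoothing_level = 0)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$rt_apex, 5, tolerance = 1e-6)
  ## closed-form Gaussian integral: A * sigma * sqrt(2*pi)
  expect_equal(pk$area, 1000 * 0.03 * sqrt(2 * pi), tolerance = 0.02)
  expect_gte(pk$width_points, 5)
  ## smoothing level 1 must not lose the peak
  expect_equal(nrow(detect_peaks(tr, smoothing_level = 1)), 1)
})

test_that("peak detection enforces height, width and length gates", {
  expect_equal(nrow(detect_peaks(gaussian_trace(apex = 99))), 0)
  set.seed(4)
  flat <- list(rt = seq(0, 1, 0.01),
               intensity = stats::runif(101, 0, 50))
  expect_equal(nrow(detect_peaks(flat)), 0)
  ## narrow spike fails the width-at-half-height rule
  spike <- gaussian_trace(apex = 5000, sigma = 0.004, dt = 0.01)
  expect_equal(nrow(detect_peaks(spike, min_width = 5)), 0)
  short <- list(rt = c(1, 2), intensity = c(0, 10))
  expect_message(pk <- detect_peaks(short), "shorter")
  expect_equal(nrow(pk), 0)
})

## a clean 3-transition compound: exact ratios, co-apexing
perfect_eics <- function(rt0 = 5, ratios = c(100, 60, 30), jitter = 0,
                         base = 4000) {
  lapply(seq_along(ratios), function(k)
    gaussian_trace(apex = base * ratios[k] / 100, rt0 = rt0 + jitter))
}

lib_entry <- function(rt = 5, ratios = c(100, 60, 30)) {
  data.frame(compound = "cmp", precursor_mz = 300,
             product_mz = c(150.1, 120.1, 90.1),
             rel_intensity = ratios, reference_rt = rt,
             rt_missing = is.na(rt))
}

test_that("a perfect transition group scores 100", {
  r <- score_compound(perfect_eics(), lib_entry())
  expect_equal(r$posterior_score, 100, tolerance = 0.5)
  expect_equal(r$rt_score, 1)
  expect_equal(r$ratio_score, 1, tolerance = 1e-6)
  expect_equal(r$coelution_score, 1)
})

test_that("sub-score arithmetic matches the composite definition", {
  ## apex exactly rt_tol away: rt sub-score 0, posterior ~75
  r <- score_compound(perfect_eics(jitter = 0.1), lib_entry(),
                      rt_tol = 0.1)
  expect_equal(r$rt_score, 0, tolerance = 1e-6)
  expect_equal(r$posterior_score, 75, tolerance = 1)
  ## ratios off by exactly amp_tol mean relative deviation: ratio score 0
  r2 <- score_compound(perfect_eics(ratios = c(100, 60, 30) * 0.85),
                       lib_entry(), amp_tol = 0.15)
  ## observed ratios are self-normalized, so scale all references instead
  skewed <- lib_entry(ratios = c(100, 60 * 1.3, 30 * 0.7))
  r3 <- score_compound(perfect_eics(), skewed, amp_tol = 0.15)
  obs <- c(1, 0.6, 0.3)
  ref <- c(100, 78, 21) / 100
  dev <- mean(abs(obs - ref) / ref)
  expect_equal(r3$ratio_score, 1 - min(dev / 0.15, 1), tolerance = 0.02)
  ## no reference rt: rt sub-score is 1
  r4 <- score_compound(perfect_eics(), lib_entry(rt = NA))
  expect_equal(r4$rt_score, 1)
  ## no detected peaks: zero posterior, absent
  none <- lapply(1:3, function(k) gaussian_trace(apex = 10))
  r5 <- score_compound(none, lib_entry())
  expect_equal(r5$posterior_score, 0)
})

test_that("presence calls honour score and 3x blank-area thresholds", {
  res <- data.frame(compound = "cmp", total_area = 3000,
                    posterior_score = 85)
  blank <- function(a) data.frame(compound = "cmp", total_area = a,
                                  posterior_score = 0)
  expect_true(call_presence(res, list(blank(900)))$present)   # 3.33x
  expect_false(call_presence(res, list(blank(1500)))$present) # 2x
  low <- res
  low$posterior_score <- 59.9
  expect_false(call_presence(low, list(blank(1)))$present)
  ## zero blanks: floor applies, presence possible
  expect_true(call_presence(res, list())$present)
})

test_that("presence is monotone in blank area and posterior score", {
  res <- data.frame(compound = "cmp", total_area = 3000,
                    posterior_score = 70)
  blanks <- seq(0, 4000, by = 250)
  calls <- vapply(blanks, function(b)
    call_presence(res, list(data.frame(compound = "cmp", total_area = b,
                                       posterior_score = 0)))$present,
    logical(1))
  expect_false(any(diff(calls) > 0))  # absent never flips back to present
  scores <- seq(0, 100, by = 5)
  calls2 <- vapply(scores, function(s) {
    r <- res
    r$posterior_score <- s
    call_presence(r, list())$present
  }, logical(1))
  expect_false(any(diff(calls2) < 0))
})

test_that("extraction separates shared product ions by precursor window", {
  lib <- rbind(lib_entry(), lib_entry())
  lib$compound <- rep(c("inA", "inB"), each = 3)
  lib$precursor_mz <- rep(c(300, 700), each = 3)
  mk_tr <- function(win, mz, apex) {
    tr <- gaussian_trace(apex = apex)
    tr$window <- win
    tr$product_mz <- mz
    tr
  }
  traces <- c(lapply(c(150.1, 120.1, 90.1), mk_tr, win = c(50, 500),
                     apex = 1000),
              lapply(c(150.1, 120.1, 90.1), mk_tr, win = c(500, 1000),
                     apex = 9000))
  run <- dia_run("S1", traces = traces,
                 windows = rbind(c(50, 500), c(500, 1000)))
  eics <- extract_eics(run, lib)
  expect_equal(max(eics$inA[[1]]$intensity), 1000, tolerance = 1e-6)
  expect_equal(max(eics$inB[[1]]$intensity), 9000, tolerance = 1e-6)
  ## precursor outside every window: flagged and skipped
  lib_out <- lib_entry()
  lib_out$precursor_mz <- 1500
  run2 <- dia_run("S1", traces = traces, windows = rbind(c(50, 500)))
  expect_warning(e2 <- extract_eics(run2, lib_out), "outside")
  expect_equal(length(e2), 0)
})

test_that("DIA runs survive the JSON round trip", {
  lib <- lib_entry()
  runs <- make_dia_batch(lib, list(S1 = "cmp", B1 = character()),
                         roles = c(S1 = "sample", B1 = "blank"),
                         seed = 8)
  f <- tempfile(fileext = ".json")
  write_dia_json(runs, f)
  back <- read_dia_json(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$sample_id, "S1")
  expect_equal(back[[2]]$role, "blank")
  expect_equal(back[[1]]$traces[[1]]$intensity,
               runs[[1]]$traces[[1]]$intensity, tolerance = 1e-12)
  expect_equal(back[[1]]$traces[[2]]$rt, runs[[1]]$traces[[2]]$rt,
               tolerance = 1e-12)
})

test_that("screening a spiked synthetic batch recovers the truth map", {
  lib <- export_transitions(harmonize_library(make_library(6, seed = 41)))
  samples <- sprintf("S%02d", 1:4)
  cmpds <- unique(lib$compound)
  set.seed(42)
  present <- lapply(samples, function(s)
    sample(cmpds, sample(2:5, 1)))
  names(present) <- samples
  present$B01 <- character()
  roles <- stats::setNames(c(rep("sample", 4), "blank"), names(present))
  runs <- make_dia_batch(lib, present, roles = roles, snr = 20,
                         seed = 43)
  res <- screen_batch(runs, lib)
  truth <- vapply(seq_len(nrow(res)), function(i)
    res$compound[i] %in% present[[res$sample_id[i]]], logical(1))
  expect_equal(res$present, truth)
})
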