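# Suspect screening against the compound database and corrected peak
# areas.

make_peak <- function(code, ppm = 0, snr = 20, phase = "effluent",
                      area = 500, day = 1) {
  db <- compound_db()
  theo <- adduct_mz(monoisotopic_mass(db$formula[db$code == code]))
  data.frame(sample_id = "s1", day = day, phase = phase,
             candidate_compound = code,
             observed_mz = theo * (1 + ppm * 1e-6),
             area = area, snr = snr,
             concentration_factor = if (phase == "solid") NA_real_ else 100,
             dry_weight = if (phase == "solid") 0.5 else NA_real_,
             standard_area_100 = 1000)
}

test_that("the compound database is internally consistent", {
  db <- compound_db()
  expect_true(all(db$parent[db$pathway_position != "parent"] %in% db$code))
  # every formula parses and has a sensible mass
  expect_true(all(vapply(db$formula, monoisotopic_mass, numeric(1)) > 100))
  bad <- db
  bad$parent[2] <- "XYZ"
  expect_error(screen_peaks(make_peak("DCF1"), bad), "parent absent")
})

test_that("screening bounds are strict on ppm and inclusive on S/N", {
  # the rule itself at the exact boundaries
  expect_false(screen_filter(5, 50))    # exactly 5 ppm: strict, fails
  expect_false(screen_filter(-5, 50))
  expect_true(screen_filter(0, 10))     # exactly S/N 10: inclusive, passes
  expect_false(screen_filter(0, 9.999999))
  # through the full m/z round trip, safely off the float boundary
  hit <- screen_peaks(make_peak("DCF1", ppm = 0, snr = 10))
  expect_true(hit$passed)
  over5 <- screen_peaks(make_peak("DCF1", ppm = 5.001, snr = 50))
  expect_false(over5$passed)
  expect_equal(over5$mass_error_ppm, 5.001, tolerance = 1e-6)
  just_under <- screen_peaks(make_peak("ERY2", ppm = -4.99, snr = 10))
  expect_true(just_under$passed)
  low_snr <- screen_peaks(make_peak("GEM1", ppm = 0, snr = 9.99))
  expect_false(low_snr$passed)
  bad <- make_peak("DCF1")
  bad$candidate_compound <- "NOPE"
  expect_error(screen_peaks(bad), "not in database")
})

test_that("the surviving set equals the brute-force row filter on a grid", {
  grid <- expand.grid(ppm = seq(0, 20, by = 0.5) *
                        rep(c(1, -1), length.out = 41),
                      snr = seq(1, 50, by = 1))
  peaks <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    make_peak("GEM3", ppm = grid$ppm[i], snr = grid$snr[i], day = i)
  }))
  hits <- screen_peaks(peaks)
  # brute-force row filter on the recomputed errors (the injected ppm can
  # move by ~1e-10 ppm through the m/z round trip)
  expect_equal(hits$passed, oracle_screen(hits$mass_error_ppm, grid$snr))
  expect_true(all(abs(hits$mass_error_ppm[hits$passed]) < 5))
  expect_true(all(hits$snr[hits$passed] >= 10))
})

test_that("corrected peak areas evaluate the printed formulas", {
  expect_equal(aqueous_corrected_area(1000, 1, 1000), 1.0)
  expect_equal(aqueous_corrected_area(500, 100, 1000), 50)
  expect_equal(aqueous_corrected_area(0, 100, 1000), 0)
  expect_equal(solid_corrected_area(1000, 1000, 1), 1.0)
  expect_equal(solid_corrected_area(300, 1000, 0.5), 0.6)
  expect_equal(solid_corrected_area(300, 1000, 1),
               solid_corrected_area(300, 1000, 0.5) / 2)
  # invariance to common rescaling of area and standard
  expect_equal(aqueous_corrected_area(500 * 7, 100, 1000 * 7),
               aqueous_corrected_area(500, 100, 1000))
  expect_error(aqueous_corrected_area(1, 1, 0), "standard_area_100")
  expect_error(solid_corrected_area(1, 1, 0), "dry_weight")
})

test_that("product time series keeps only passed hits as explicit rows", {
  all_fail <- screen_peaks(rbind(make_peak("DCF1", ppm = 10),
                                 make_peak("DCF1", ppm = 6, day = 2)))
  expect_equal(nrow(product_timeseries(all_fail)), 0)

  days <- 1:5
  peaks <- do.call(rbind, lapply(days, function(d) make_peak("ERY1", day = d)))
  series <- product_timeseries(screen_peaks(peaks))
  expect_equal(nrow(series), length(days))
  expect_equal(series$day, days)
})

test_that("screened series on a noise-free simulation matches the truth table", {
  cfg <- small_cfg(noise_cv = 0)
  sim <- simulate_pharma_series(cfg)
  true_peaks <- sim$peaks[sim$peaks$true_present, ]
  hits <- screen_peaks(sim$peaks)
  # every truly present peak passes; every decoy fails
  expect_true(all(hits$passed[sim$peaks$true_present]))
  expect_true(all(!hits$passed[!sim$peaks$true_present]))
  series <- product_timeseries(hits)
  truth <- sim$truth$product_presence
  truth$phase <- ifelse(truth$phase == "effluent", "effluent", "solid")
  present_truth <- truth[truth$present, ]
  got <- unique(series[c("compound", "phase", "day")])
  expect_equal(nrow(got), nrow(present_truth))
  key <- function(d) paste(d[[1]], d[[2]], d[[3]])
  expect_setequal(key(got),
                  key(present_truth[c("compound", "phase", "day")]))
})
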