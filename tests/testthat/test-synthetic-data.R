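# Synthetic-data generator: determinism, conservation and the stated
# exposure scenario.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(phase_breaks = c(23, 12)), "strictly increasing")
  expect_error(sim_config(phase_breaks = c(12, 100), n_days = 80),
               "phase_breaks")
  expect_error(sim_config(active_fraction = 0.7, phantom_fraction = 0.5),
               "exceed 1")
  expect_error(sim_config(depth_dna = 0), "depth_dna")
  expect_error(sim_config(analyte_influent = c(NH3_N = -1)), "non-negative")
  expect_error(sim_config(analyte_removal_test = c(NH3_N = 1.2)), "\\[0, 1\\]")
})

test_that("identical seeds give identical outputs; different seeds differ", {
  a <- simulate_experiment(small_cfg())
  b <- simulate_experiment(small_cfg())
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- simulate_experiment(small_cfg(seed = 43))
  expect_false(identical(a$pharma$parent_areas, c_$pharma$parent_areas))
  expect_false(identical(a$community$counts_dna, c_$community$counts_dna))
})

test_that("noise-free construction reproduces the exposure phases exactly", {
  cfg <- small_cfg(noise_cv = 0)
  sim <- simulate_pharma_series(cfg)
  areas <- sim$parent_areas

  # quantify + recovery-correct the areas and check phase-wise removal
  for (cmp in c("DCF", "ERY", "GEM")) {
    std <- sim$standards[sim$standards$compound == cmp, ]
    curve <- fit_calibration(std[c("nominal", "area")])
    rset <- sim$recovery_sets[sim$recovery_sets$compound == cmp &
                                sim$recovery_sets$phase == "aqueous", ]
    r <- compute_recovery(rset$prespike_conc, rset$unspiked_conc,
                          rset$postspike_conc)$recovery
    sub <- areas[areas$compound == cmp & areas$reactor == "test", ]
    conc <- correct_for_recovery(quantify(sub$area, curve)$conc, r)
    infl <- conc[sub$phase == "influent"]
    effl <- conc[sub$phase == "effluent"]
    day <- sub$day[sub$phase == "influent"]
    rem <- removal_percent(infl, effl)
    cfg_rem <- cfg$phase1_removal[[cmp]] * 100
    expect_equal(rem[day <= 12], rep(cfg_rem, sum(day <= 12)),
                 tolerance = 1e-8)
    expect_equal(effl[day > 12 & day <= 23], 2 * infl[day > 12 & day <= 23],
                 tolerance = 1e-8)
    expect_equal(rem[day > 23], rep(0, sum(day > 23)), tolerance = 1e-8)
  }
  # no negative concentrations or areas anywhere
  expect_true(all(sim$parent_areas$area >= 0))
  expect_true(all(sim$solids$conc_ug_g >= 0))
  expect_true(all(sim$peaks$area >= 0))
  # every generated product peak maps to a database compound
  expect_true(all(sim$peaks$candidate_compound %in% compound_db()$code))
})

test_that("community libraries sum to depth and phantoms are structural", {
  cfg <- small_cfg(phantom_fraction = 0.1)
  com <- simulate_community(cfg)
  expect_true(all(colSums(com$counts_dna) == cfg$depth_dna))
  expect_true(all(colSums(com$counts_cdna) == cfg$depth_cdna))
  ph <- com$truth$phantom_zotus
  expect_gt(length(ph), 0)
  expect_true(all(rowSums(com$counts_dna[ph, , drop = FALSE]) == 0))
  expect_true(all(rowSums(com$counts_cdna[ph, , drop = FALSE]) > 0))
  # phantom set disjoint from the zero-transcript taxa
  zero_cdna <- rownames(com$counts_cdna)[rowSums(com$counts_cdna) == 0]
  expect_length(intersect(ph, zero_cdna), 0)

  none <- simulate_community(small_cfg(phantom_fraction = 0))
  phantom_pattern <- rowSums(none$counts_dna) == 0 &
    rowSums(none$counts_cdna) > 0
  expect_false(any(phantom_pattern))
})

test_that("unit transcript:gene multipliers give mean ratios near 1", {
  cfg <- sim_config(n_zotus = 30, n_samples_per_reactor = 1,
                    depth_dna = 30000, depth_cdna = 30000,
                    active_multiplier = 1, inactive_multiplier = 1,
                    phantom_fraction = 0, response_effect = 1, seed = 5)
  com <- simulate_community(cfg)
  calls <- call_active(com$counts_dna, com$counts_cdna, n_trials = 20,
                       depth_dna = 15000, depth_cdna = 15000, seed = 9)
  m <- calls$mean_ratio[!is.na(calls$mean_ratio)]
  # abundance-weighted mean ratio approaches 1 at large depth
  w <- calls$dna_reads[!is.na(calls$mean_ratio)]
  expect_equal(sum(m * w) / sum(w), 1, tolerance = 0.05)
  expect_lt(abs(stats::median(m) - 1), 0.15)
})

test_that("analyte series honours configured removal and rejects bad input", {
  cfg <- small_cfg(noise_cv = 0)
  an <- simulate_analytes(cfg)
  rs <- removal_series(an)
  n_test <- rs[rs$reactor == "test" & rs$analyte == "NH3_N", ]
  expect_equal(unique(round(n_test$removal_percent, 8)), 70)
  doc_c <- rs[rs$reactor == "control" & rs$analyte == "DOC", ]
  expect_equal(unique(round(doc_c$removal_percent, 8)), 95)
  # zero effluent gives 100%, influent = effluent gives 0%
  expect_equal(removal_percent(5, 0), 100)
  expect_equal(removal_percent(5, 5), 0)
})
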