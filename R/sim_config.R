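# Simulation configuration: the stated experimental world that the
# synthetic-data generator reproduces (two sequencing batch reactors,
# ~80 days, ~150 ug/L dosing, a 12-day removal phase, a desorption spike
# to ~2x influent through day 23, then negligible removal).

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator.
#' Defaults encode the reference exposure scenario: two reactors (dosed
#' test + undosed control) over 80 days, each pharmaceutical dosed at
#' ~150 ug/L, partial removal through day 12 (sorption + biodegradation),
#' a desorption spike with effluent at about twice influent from day 12
#' to 23, and negligible removal thereafter. Community defaults give a
#' moderately uneven ZOTU pool with a known active subset and structural
#' phantom taxa.
#'
#' @param n_days Experiment length in days.
#' @param dose_day Day pharmaceutical dosing starts.
#' @param influent_level Influent concentration per compound, ug/L.
#' @param phase_breaks Two increasing day boundaries: end of the removal
#'   phase and end of the desorption spike.
#' @param desorption_multiplier Effluent/influent ratio during the
#'   desorption spike (unitless).
#' @param phase1_removal Named fraction removed per compound during the
#'   removal phase.
#' @param aqueous_recovery,solid_recovery Named extraction-recovery
#'   fractions per compound (may exceed 1).
#' @param sampling_interval Integer range of gaps (days) between sampling
#'   events; the irregular schedule is drawn from it.
#' @param n_zotus Number of ZOTUs in the simulated community.
#' @param n_samples_per_reactor Number of community timepoints per reactor.
#' @param active_fraction Fraction of ZOTUs truly active
#'   (transcript:gene concentration ratio `active_multiplier`).
#' @param phantom_fraction Fraction of ZOTUs that are structural phantoms
#'   (zero DNA concentration, positive cDNA concentration).
#' @param active_multiplier,inactive_multiplier Transcript:gene
#'   concentration ratios of truly active (>= 2) and inactive (<= 0.5)
#'   taxa before cDNA renormalisation.
#' @param depth_dna,depth_cdna Library sizes for the DNA and cDNA pools.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise on concentrations and peak areas.
#' @param ppm_sd Standard deviation (ppm) of mass error on true product
#'   peaks; truncated inside the screening band. 0 when `noise_cv` is 0.
#' @param undersampling_phantoms If `TRUE`, structural phantoms are
#'   replaced by low-abundance taxa that can drop out of the DNA library
#'   by undersampling (off by default so the phantom rule is exercised
#'   deterministically).
#' @param response_effect Fold-change from first to last day applied to
#'   designated responder taxa in the test reactor (control unaffected).
#' @param analyte_influent Named influent concentrations (mg/L) of the
#'   conventional analytes.
#' @param analyte_removal_test,analyte_removal_control Named removal
#'   fractions per analyte and reactor.
#' @param seed Integer RNG seed; identical configs give identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_days = 80,
                       dose_day = 0,
                       influent_level = 150,
                       phase_breaks = c(12, 23),
                       desorption_multiplier = 2.0,
                       phase1_removal = c(DCF = 0.50, ERY = 0.18, GEM = 0.40),
                       aqueous_recovery = c(DCF = 0.97, ERY = 1.17, GEM = 0.98),
                       solid_recovery = c(DCF = 0.75, ERY = 0.56, GEM = 0.68),
                       sampling_interval = c(2L, 5L),
                       n_zotus = 150,
                       n_samples_per_reactor = 8,
                       active_fraction = 0.2,
                       phantom_fraction = 0.05,
                       active_multiplier = 3,
                       inactive_multiplier = 0.3,
                       depth_dna = 10000,
                       depth_cdna = 10000,
                       noise_cv = 0.10,
                       ppm_sd = 1.5,
                       undersampling_phantoms = FALSE,
                       response_effect = 2,
                       analyte_influent = c(NH3_N = 50, NO2_N = 0.5,
                                            NO3_N = 0.5, PO4 = 10, DOC = 300),
                       analyte_removal_test = c(NH3_N = 0.70, NO2_N = 0,
                                                NO3_N = 0, PO4 = 0.50,
                                                DOC = 0.90),
                       analyte_removal_control = c(NH3_N = 0.98, NO2_N = 0,
                                                   NO3_N = 0, PO4 = 0.95,
                                                   DOC = 0.95),
                       seed = 1L) {
  check_scalar_number(n_days, "n_days", lower = 1)
  check_scalar_number(influent_level, "influent_level", lower = 0,
                      strict_lower = TRUE)
  if (length(phase_breaks) != 2L || any(diff(phase_breaks) <= 0) ||
      phase_breaks[1] <= 0 || phase_breaks[2] > n_days) {
    stop_config("phase_breaks must be two strictly increasing days in (0, n_days]")
  }
  check_scalar_number(desorption_multiplier, "desorption_multiplier",
                      lower = 1)
  for (f in c(phase1_removal)) check_scalar_number(f, "phase1_removal", 0, 1)
  if (any(aqueous_recovery <= 0) || any(solid_recovery <= 0)) {
    stop_config("recoveries must be positive")
  }
  check_scalar_number(active_fraction, "active_fraction", 0, 1)
  check_scalar_number(phantom_fraction, "phantom_fraction", 0, 1)
  if (active_fraction + phantom_fraction > 1) {
    stop_config("active_fraction + phantom_fraction must not exceed 1")
  }
  check_scalar_number(depth_dna, "depth_dna", 0, strict_lower = TRUE)
  check_scalar_number(depth_cdna, "depth_cdna", 0, strict_lower = TRUE)
  check_scalar_number(noise_cv, "noise_cv", 0)
  check_scalar_number(n_zotus, "n_zotus", 2)
  check_scalar_number(n_samples_per_reactor, "n_samples_per_reactor", 1)
  if (any(analyte_influent < 0)) {
    stop_config("analyte influent concentrations must be non-negative")
  }
  if (any(analyte_removal_test < 0) || any(analyte_removal_test > 1) ||
      any(analyte_removal_control < 0) || any(analyte_removal_control > 1)) {
    stop_config("analyte removal fractions must lie in [0, 1]")
  }
  structure(
    list(n_days = n_days, dose_day = dose_day,
         influent_level = influent_level,
         phase_breaks = phase_breaks,
         desorption_multiplier = desorption_multiplier,
         phase1_removal = phase1_removal,
         aqueous_recovery = aqueous_recovery,
         solid_recovery = solid_recovery,
         sampling_interval = as.integer(sampling_interval),
         n_zotus = as.integer(n_zotus),
         n_samples_per_reactor = as.integer(n_samples_per_reactor),
         active_fraction = active_fraction,
         phantom_fraction = phantom_fraction,
         active_multiplier = active_multiplier,
         inactive_multiplier = inactive_multiplier,
         depth_dna = as.integer(depth_dna),
         depth_cdna = as.integer(depth_cdna),
         noise_cv = noise_cv,
         ppm_sd = if (noise_cv == 0) 0 else ppm_sd,
         undersampling_phantoms = isTRUE(undersampling_phantoms),
         response_effect = response_effect,
         analyte_influent = analyte_influent,
         analyte_removal_test = analyte_removal_test,
         analyte_removal_control = analyte_removal_control,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Irregular sampling days: cumulative gaps drawn from sampling_interval,
# starting at day 0, capped at n_days. Deterministic under the config seed.
sampling_days <- function(config) {
  with_seed(derive_seed(config$seed, 11L), {
    gaps <- sample(seq(config$sampling_interval[1], config$sampling_interval[2]),
                   size = ceiling(config$n_days / config$sampling_interval[1]),
                   replace = TRUE)
    days <- c(0, cumsum(gaps))
    days[days <= config$n_days]
  })
}

# Phase label for a day under the configured breaks.
phase_of_day <- function(day, config) {
  ifelse(day <= config$phase_breaks[1], "removal",
         ifelse(day <= config$phase_breaks[2], "desorption", "steady"))
}

# True removal fraction of a compound on a day (signed; negative during
# the desorption spike).
true_removal_fraction <- function(day, compound, config) {
  ph <- phase_of_day(day, config)
  ifelse(ph == "removal", config$phase1_removal[[compound]],
         ifelse(ph == "desorption", -(config$desorption_multiplier - 1), 0))
}

# Multiplicative lognormal noise factors with the configured CV
# (mean 1 by construction).
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
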