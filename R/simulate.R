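# Synthetic-data generators: pharmaceutical series with peak observations,
# paired DNA/cDNA community matrices, and conventional-analyte series.
# Every generated table is accompanied by ground truth so downstream
# stages can be tested without external data.

# Per-compound peak-area calibration slopes (area units per ug/L) used to
# synthesize standards and parent peak areas. Arbitrary but fixed scale.
.sim_cal_slope <- c(DCF = 1200, ERY = 800, GEM = 1500)

#' Simulate pharmaceutical concentration series and peak observations
#'
#' Generates, for the dosed test reactor and the undosed control reactor:
#' calibration standards, spike-recovery triplets, parent peak areas for
#' influent and effluent samples, solid-phase concentrations, and
#' degradation-product peak observations, along with the ground truth
#' (true removal fraction per compound per day; true product presence per
#' product, day and phase).
#'
#' The exposure scenario: influent at `influent_level` with multiplicative
#' lognormal noise; effluent = influent x (1 - true removal), where true
#' removal is the configured phase-1 fraction through the first phase
#' break, -(desorption_multiplier - 1) during the desorption spike, and 0
#' afterwards. Solid-phase concentrations rise during the removal phase and
#' decay during desorption. Degradation-product peaks are present in the
#' effluent through the desorption phase and in the solid phase throughout,
#' with areas proportional to biodegraded mass; decoy peaks with mass
#' errors well outside the screening band are added so the screen is
#' exercised.
#'
#' @param config A [sim_config()].
#' @return List with data.frames `standards`, `recovery_sets`,
#'   `parent_areas`, `solids`, `peaks`, and a `truth` list
#'   (`true_removal`, `product_presence`).
#' @export
simulate_pharma_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  db <- compound_db()
  compounds <- db$code[db$pathway_position == "parent"]
  products <- db[db$pathway_position != "parent", ]
  days <- sampling_days(config)
  cf <- 100          # 100 mL loaded -> 1 mL extract
  dry_weight <- 0.5  # g dry granules per solid sample
  std_levels <- c(0, 10, 50, 100, 200)

  with_seed(derive_seed(config$seed, 21L), {
    # calibration standards (methanol and water pooled; solvent retained)
    standards <- do.call(rbind, lapply(compounds, function(cmp) {
      do.call(rbind, lapply(c("methanol", "water"), function(sv) {
        data.frame(compound = cmp, solvent = sv, nominal = std_levels,
                   area = .sim_cal_slope[[cmp]] * std_levels *
                     lnoise(length(std_levels), config$noise_cv / 2))
      }))
    }))

    # spike-recovery triplets at the configured recoveries, nominal 100 ug/L
    recovery_sets <- do.call(rbind, lapply(compounds, function(cmp) {
      do.call(rbind, lapply(c("aqueous", "solid"), function(ph) {
        r <- if (ph == "aqueous") config$aqueous_recovery[[cmp]]
             else config$solid_recovery[[cmp]]
        un <- config$influent_level * r  # unspiked sample, post-extraction
        data.frame(compound = cmp, phase = ph, nominal_spike = 100,
                   prespike_conc = un + 100 * r,
                   unspiked_conc = un,
                   postspike_conc = un + 100)
      }))
    }))

    grid <- expand.grid(reactor = c("test", "control"), day = days,
                        compound = compounds, stringsAsFactors = FALSE)
    grid$dosed <- grid$reactor == "test" & grid$day >= config$dose_day
    grid$removal <- ifelse(grid$dosed,
                           mapply(true_removal_fraction, grid$day,
                                  grid$compound,
                                  MoreArgs = list(config = config)),
                           0)
    grid$infl_true <- ifelse(grid$dosed, config$influent_level, 0)
    grid$effl_true <- grid$infl_true * (1 - grid$removal)

    n <- nrow(grid)
    infl_meas <- grid$infl_true * lnoise(n, config$noise_cv)
    effl_meas <- grid$effl_true * lnoise(n, config$noise_cv)

    # measured parent areas embed the extraction recovery; quantification
    # plus recovery correction downstream recovers the true value
    rec <- config$aqueous_recovery[grid$compound]
    slope <- .sim_cal_slope[grid$compound]
    parent_areas <- rbind(
      data.frame(grid[c("reactor", "day", "compound")], phase = "influent",
                 area = slope * infl_meas * rec),
      data.frame(grid[c("reactor", "day", "compound")], phase = "effluent",
                 area = slope * effl_meas * rec)
    )
    parent_areas$sample_id <- paste(parent_areas$reactor, "d",
                                    parent_areas$day, parent_areas$phase,
                                    sep = "_")

    # solid phase: linear rise over the removal phase, exponential decay
    # during and after desorption; only where dosed
    pb <- config$phase_breaks
    s_max <- config$influent_level * config$phase1_removal[grid$compound] * 0.05
    s_true <- ifelse(!grid$dosed, 0,
                     ifelse(grid$day <= pb[1], s_max * grid$day / pb[1],
                            s_max * exp(-0.25 * (grid$day - pb[1]))))
    solids <- data.frame(grid[c("reactor", "day", "compound")],
                         conc_ug_g = s_true * lnoise(n, config$noise_cv))

    # degradation-product peaks: present in effluent through the
    # desorption phase and in the solid phase whenever solid-phase parent
    # remains; area tracks biodegraded (phase 1) or washed-out (phase 2) mass
    prod_grid <- expand.grid(day = days, code = products$code,
                             stringsAsFactors = FALSE)
    prod_grid <- merge(prod_grid, products[c("code", "parent", "formula")],
                       by = "code")
    prod_grid <- prod_grid[order(prod_grid$code, prod_grid$day), ]
    peaks <- do.call(rbind, lapply(seq_len(nrow(prod_grid)), function(i) {
      row <- prod_grid[i, ]
      ph_label <- phase_of_day(row$day, config)
      present_aq <- row$day >= config$dose_day & row$day <= pb[2]
      present_solid <- row$day >= config$dose_day
      rel <- switch(ph_label, removal = 0.5 + 0.5 * row$day / pb[1],
                    desorption = 2, steady = 0.4)
      base_area <- .sim_cal_slope[[row$parent]] * 100 *
        config$phase1_removal[[row$parent]] * 0.2 * rel
      std_area <- .sim_cal_slope[[row$parent]] * 100
      theo <- adduct_mz(monoisotopic_mass(row$formula))
      out <- NULL
      if (present_aq) {
        ppm <- if (config$ppm_sd == 0) 0 else
          max(min(rnorm(1, 0, config$ppm_sd), 4.5), -4.5)
        out <- rbind(out, data.frame(
          reactor = "test", day = row$day, phase = "effluent",
          candidate_compound = row$code,
          observed_mz = theo * (1 + ppm * 1e-6),
          area = base_area * lnoise(1, config$noise_cv),
          snr = 10 + rgamma(1, shape = 4, scale = 10),
          concentration_factor = cf, dry_weight = NA_real_,
          standard_area_100 = std_area, true_present = TRUE))
      }
      if (present_solid) {
        ppm <- if (config$ppm_sd == 0) 0 else
          max(min(rnorm(1, 0, config$ppm_sd), 4.5), -4.5)
        out <- rbind(out, data.frame(
          reactor = "test", day = row$day, phase = "solid",
          candidate_compound = row$code,
          observed_mz = theo * (1 + ppm * 1e-6),
          area = base_area * 0.3 * lnoise(1, config$noise_cv),
          snr = 10 + rgamma(1, shape = 4, scale = 10),
          concentration_factor = NA_real_, dry_weight = dry_weight,
          standard_area_100 = std_area, true_present = TRUE))
      }
      # decoy peak: same nominal candidate, mass error far outside the band
      if (row$day > pb[2] && row$code %in% c("DCF1", "ERY2", "GEM1")) {
        ppm <- sample(c(-1, 1), 1) * runif(1, 8, 18)
        out <- rbind(out, data.frame(
          reactor = "test", day = row$day, phase = "effluent",
          candidate_compound = row$code,
          observed_mz = theo * (1 + ppm * 1e-6),
          area = base_area * 0.2, snr = runif(1, 1, 40),
          concentration_factor = cf, dry_weight = NA_real_,
          standard_area_100 = std_area, true_present = FALSE))
      }
      out
    }))
    peaks$sample_id <- paste(peaks$reactor, "d", peaks$day, peaks$phase,
                             sep = "_")

    presence <- expand.grid(compound = products$code, day = days,
                            phase = c("effluent", "solid"),
                            stringsAsFactors = FALSE)
    presence$present <- ifelse(
      presence$phase == "effluent",
      presence$day >= config$dose_day & presence$day <= pb[2],
      presence$day >= config$dose_day)

    list(
      standards = standards,
      recovery_sets = recovery_sets,
      parent_areas = parent_areas,
      solids = solids,
      peaks = peaks,
      truth = list(
        true_removal = data.frame(grid[c("reactor", "day", "compound")],
                                  removal_fraction = grid$removal),
        product_presence = presence
      )
    )
  })
}

# Internal lineage table: realistic aerobic-granular-sludge families with
# consistent higher ranks, recycled over ZOTUs.
.ags_lineages <- data.frame(
  domain = "Bacteria",
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Nitrospirota", "Bacteroidota",
             "Bacteroidota", "Bacteroidota", "Proteobacteria",
             "Actinobacteriota"),
  class = c("Gammaproteobacteria", "Gammaproteobacteria",
            "Gammaproteobacteria", "Gammaproteobacteria", "Nitrospiria",
            "Bacteroidia", "Bacteroidia", "Bacteroidia",
            "Alphaproteobacteria", "Actinomycetia"),
  order = c("Burkholderiales", "Burkholderiales", "Methylophilales",
            "Nitrosomonadales", "Nitrospirales", "Flavobacteriales",
            "Chitinophagales", "Chitinophagales", "Rhizobiales",
            "Micrococcales"),
  family = c("Rhodocyclaceae", "Competibacteraceae", "Methylophilaceae",
             "Nitrosomonadaceae", "Nitrospiraceae", "Flavobacteriaceae",
             "Chitinophagaceae", "Saprospiraceae", "Xanthobacteraceae",
             "Microbacteriaceae"),
  stringsAsFactors = FALSE
)

#' Simulate paired DNA/cDNA community count matrices
#'
#' For each reactor and timepoint a latent DNA composition is drawn
#' (lognormal base profile with Dirichlet sample-to-sample wobble), DNA
#' counts are multinomial at `depth_dna`, and cDNA counts are multinomial
#' at `depth_cdna` from a composition in which truly active taxa carry
#' `active_multiplier` times their DNA concentration and inactive taxa
#' `inactive_multiplier` times (renormalised). Structural phantom taxa
#' have zero DNA concentration and a positive cDNA concentration, so they
#' can never appear in a DNA library. In the test reactor a designated
#' responder subset of the active taxa trends up or down over time by
#' `response_effect`-fold; the control community is stationary.
#'
#' @param config A [sim_config()].
#' @return List with `counts_dna` and `counts_cdna` (ZOTU x sample integer
#'   matrices spanning both reactors), `samples` (sample metadata:
#'   `sample_id`, `reactor`, `day`), `taxonomy` (7-rank data.frame), and
#'   `truth` (`active_zotus`, `phantom_zotus`, `responders`,
#'   `dna_composition` matrix of latent DNA concentrations).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$active_fraction + config$phantom_fraction > 1) {
    stop_config("active_fraction + phantom_fraction must not exceed 1")
  }
  n <- config$n_zotus
  zotus <- sprintf("Zotu%03d", seq_len(n))
  n_phantom <- round(config$phantom_fraction * n)
  n_active <- round(config$active_fraction * n)

  with_seed(derive_seed(config$seed, 31L), {
    phantom <- if (n_phantom > 0) sample(zotus, n_phantom) else character(0)
    non_phantom <- setdiff(zotus, phantom)
    active <- if (n_active > 0) sample(non_phantom, n_active) else character(0)
    # responders: half of the active set, split into up / down movers
    responders <- data.frame(zotu_id = character(0), sign = integer(0))
    if (length(active) >= 4) {
      resp <- sample(active, floor(length(active) / 2))
      responders <- data.frame(
        zotu_id = resp,
        sign = rep_len(c(1L, -1L), length(resp)))
    }

    # base composition: lognormal profile, bounded skew so non-phantom taxa
    # stay deep enough that undersampling-induced DNA dropout is negligible
    base <- setNames(rlnorm(n, 0, 0.6), zotus)
    base[phantom] <- 0
    if (config$undersampling_phantoms && length(phantom)) {
      # rare-but-present phantoms instead of structural zeros
      base[phantom] <- stats::quantile(base[non_phantom], 0.02) / 20
    }
    base <- base / sum(base)
    cdna_extra <- setNames(rlnorm(n, 0, 0.6), zotus)  # phantom cDNA mass

    mult <- setNames(rep(config$inactive_multiplier, n), zotus)
    mult[active] <- config$active_multiplier

    days <- round(seq(0, config$n_days,
                      length.out = config$n_samples_per_reactor))
    samples <- expand.grid(day = days, reactor = c("test", "control"),
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste0(samples$reactor, "_d", samples$day)

    theta <- 200  # Dirichlet concentration for sample-to-sample wobble
    counts_dna <- matrix(0L, n, nrow(samples),
                         dimnames = list(zotus, samples$sample_id))
    counts_cdna <- counts_dna
    dna_comp <- matrix(0, n, nrow(samples),
                       dimnames = list(zotus, samples$sample_id))

    for (j in seq_len(nrow(samples))) {
      p <- base
      if (samples$reactor[j] == "test" && nrow(responders) > 0 &&
          config$response_effect != 1) {
        frac <- samples$day[j] / config$n_days
        fold <- config$response_effect ^ (responders$sign * frac)
        p[responders$zotu_id] <- p[responders$zotu_id] * fold
        p <- p / sum(p)
      }
      nz <- p > 0
      wob <- p
      wob[nz] <- rgamma(sum(nz), shape = p[nz] * theta, rate = 1)
      wob <- wob / sum(wob)
      dna_comp[, j] <- wob
      counts_dna[, j] <- rmultinom(1, config$depth_dna, wob)

      cp <- wob * mult
      cp[phantom] <- cdna_extra[phantom] / sum(cdna_extra[phantom] + 1) *
        config$phantom_fraction  # small positive phantom cDNA mass
      if (!length(phantom)) cp[phantom] <- numeric(0)
      cp <- cp / sum(cp)
      counts_cdna[, j] <- rmultinom(1, config$depth_cdna, cp)
    }

    lin <- .ags_lineages[rep_len(seq_len(nrow(.ags_lineages)), n), ]
    taxonomy <- data.frame(zotu_id = zotus, lin,
                           genus = paste0("g_", zotus),
                           row.names = NULL, stringsAsFactors = FALSE)

    list(counts_dna = counts_dna, counts_cdna = counts_cdna,
         samples = samples, taxonomy = taxonomy,
         truth = list(active_zotus = sort(active),
                      phantom_zotus = sort(phantom),
                      responders = responders,
                      dna_composition = dna_comp))
  })
}

#' Simulate conventional-analyte time series
#'
#' Influent/effluent series for NH3-N, NO2-N, NO3-N, PO4 and DOC in both
#' reactors, with configurable removal per analyte and reactor and
#' multiplicative lognormal noise.
#'
#' @param config A [sim_config()].
#' @return Tidy data.frame: `sample_id`, `reactor`, `day`, `phase`,
#'   `analyte`, `value`, `units`.
#' @export
simulate_analytes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- sampling_days(config)
  analytes <- names(config$analyte_influent)
  with_seed(derive_seed(config$seed, 41L), {
    grid <- expand.grid(reactor = c("test", "control"), day = days,
                        analyte = analytes, stringsAsFactors = FALSE)
    infl_true <- config$analyte_influent[grid$analyte]
    removal <- ifelse(grid$reactor == "test",
                      config$analyte_removal_test[grid$analyte],
                      config$analyte_removal_control[grid$analyte])
    n <- nrow(grid)
    out <- rbind(
      data.frame(grid, phase = "influent",
                 value = infl_true * lnoise(n, config$noise_cv)),
      data.frame(grid, phase = "effluent",
                 value = infl_true * (1 - removal) * lnoise(n, config$noise_cv))
    )
    out$units <- "mg/L"
    out$sample_id <- paste(out$reactor, "d", out$day, out$phase, sep = "_")
    out[c("sample_id", "reactor", "day", "phase", "analyte", "value", "units")]
  })
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running all three generators from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `pharma` ([simulate_pharma_series()] output),
#'   `community` ([simulate_community()] output), and `analytes`
#'   ([simulate_analytes()] output).
#' @export
simulate_experiment <- function(config = sim_config()) {
  list(pharma = simulate_pharma_series(config),
       community = simulate_community(config),
       analytes = simulate_analytes(config))
}

#' Write a simulated experiment to delimited files
#'
#' Serialises every generated table (and the ground-truth tables) as CSV
#' under `dir`. Count matrices are written as ZOTU-by-sample tables with a
#' `zotu_id` first column.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(sim$pharma$standards, "standards")
  wr(sim$pharma$recovery_sets, "recovery_sets")
  wr(sim$pharma$parent_areas, "parent_areas")
  wr(sim$pharma$solids, "solids")
  wr(sim$pharma$peaks, "peaks")
  wr(sim$pharma$truth$true_removal, "truth_removal")
  wr(sim$pharma$truth$product_presence, "truth_product_presence")
  wr(data.frame(zotu_id = rownames(sim$community$counts_dna),
                sim$community$counts_dna, check.names = FALSE),
     "counts_dna")
  wr(data.frame(zotu_id = rownames(sim$community$counts_cdna),
                sim$community$counts_cdna, check.names = FALSE),
     "counts_cdna")
  wr(sim$community$samples, "samples")
  wr(sim$community$taxonomy, "taxonomy")
  wr(data.frame(zotu_id = sim$community$truth$active_zotus), "truth_active")
  wr(data.frame(zotu_id = sim$community$truth$phantom_zotus), "truth_phantom")
  wr(sim$analytes, "analytes")
  invisible(paths)
}
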