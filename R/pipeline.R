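# End-to-end orchestration: simulate (or load) -> quantify -> screen ->
# active -> respond -> report, with a manifest of parameters, seeds and
# content hashes so a rerun with the same configuration is verifiably
# identical.

#' Pipeline configuration
#'
#' Either `simulation` (a list of [sim_config()] arguments, possibly
#' empty for the defaults) or `input_dir` (a directory of tables as
#' written by [write_simulation()]) must be supplied.
#'
#' @param simulation List of [sim_config()] arguments, or `NULL`.
#' @param input_dir Directory of input tables, or `NULL`.
#' @param outdir Output directory for stage tables and the manifest.
#' @param seed Master seed; overrides the simulation block's seed.
#' @param loq Limit of quantification, ug/L; corrected concentrations
#'   below it are flagged.
#' @param max_ppm,min_snr Screening filter bounds.
#' @param n_trials,active_threshold,depth Active-caller parameters
#'   (`depth = NULL` uses the minimum library total).
#' @param response_band,min_abundance Response-ratio parameters.
#' @param n_perm Permutations for vector fitting.
#' @param t1,t2 Sample ids for the response-ratio comparison; defaults to
#'   the second and third test-reactor timepoints.
#' @param ordination Optional path to a samples x axes coordinate table
#'   (CSV, first column sample ids). When absent, classical metric MDS of
#'   the active composition is used as stand-in coordinates.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(), input_dir = NULL,
                            outdir = tempfile("granulefate_run_"),
                            seed = 1, loq = 10, max_ppm = 5, min_snr = 10,
                            n_trials = 100, active_threshold = 1,
                            depth = NULL, response_band = 0.5,
                            min_abundance = 0.001, n_perm = 999,
                            t1 = NULL, t2 = NULL, ordination = NULL) {
  if (is.null(simulation) && is.null(input_dir)) {
    stop_config("config needs a simulation block or an input_dir")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_config("input_dir does not exist: ", input_dir)
  }
  check_scalar_number(seed, "seed")
  check_scalar_number(max_ppm, "max_ppm", 0, strict_lower = TRUE)
  check_scalar_number(min_snr, "min_snr", 0)
  check_scalar_number(n_trials, "n_trials", 1)
  check_scalar_number(min_abundance, "min_abundance", 0)
  check_scalar_number(response_band, "response_band", 0, 1)
  structure(
    list(simulation = simulation, input_dir = input_dir, outdir = outdir,
         seed = as.integer(seed), loq = loq, max_ppm = max_ppm,
         min_snr = min_snr, n_trials = n_trials,
         active_threshold = active_threshold, depth = depth,
         response_band = response_band, min_abundance = min_abundance,
         n_perm = n_perm, t1 = t1, t2 = t2, ordination = ordination),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path Path to a flat JSON object whose keys are
#'   [pipeline_config()] arguments (`simulation` may itself be an object
#'   of [sim_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Read a simulated experiment back from delimited files
#'
#' Inverse of [write_simulation()]; reconstructs the table bundle the
#' pipeline stages consume.
#'
#' @param dir Directory written by [write_simulation()].
#' @return List with the same shape as [simulate_experiment()] output.
#' @export
read_simulation <- function(dir) {
  rd <- function(name) read.csv(file.path(dir, paste0(name, ".csv")),
                                stringsAsFactors = FALSE)
  mat <- function(name) {
    d <- rd(name)
    m <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- d[[1]]
    m
  }
  list(
    pharma = list(
      standards = rd("standards"),
      recovery_sets = rd("recovery_sets"),
      parent_areas = rd("parent_areas"),
      solids = rd("solids"),
      peaks = rd("peaks"),
      truth = list(true_removal = rd("truth_removal"),
                   product_presence = rd("truth_product_presence"))
    ),
    community = list(
      counts_dna = mat("counts_dna"),
      counts_cdna = mat("counts_cdna"),
      samples = rd("samples"),
      taxonomy = rd("taxonomy"),
      truth = list(active_zotus = rd("truth_active")$zotu_id,
                   phantom_zotus = rd("truth_phantom")$zotu_id)
    ),
    analytes = rd("analytes")
  )
}

# Quantification stage: calibration + recovery correction of parent peak
# areas, then mass-balance removal for pharmaceuticals and analytes.
stage_quantify <- function(sim, cfg) {
  compounds <- unique(sim$pharma$standards$compound)
  curves <- lapply(setNames(compounds, compounds), function(cmp) {
    s <- sim$pharma$standards[sim$pharma$standards$compound == cmp, ]
    fit_calibration(s[c("nominal", "area")], compound = cmp)
  })
  rec_tab <- sim$pharma$recovery_sets[sim$pharma$recovery_sets$phase == "aqueous", ]
  recov <- vapply(setNames(compounds, compounds), function(cmp) {
    r <- rec_tab[rec_tab$compound == cmp, ]
    compute_recovery(r$prespike_conc, r$unspiked_conc, r$postspike_conc)$recovery
  }, numeric(1))

  pa <- sim$pharma$parent_areas
  q <- do.call(rbind, lapply(seq_len(nrow(pa)), function(i) {
    quantify(pa$area[i], curves[[pa$compound[i]]])
  }))
  conc <- data.frame(pa[c("sample_id", "reactor", "day", "phase")],
                     analyte = pa$compound,
                     raw_conc = q$conc,
                     recovery = unname(recov[pa$compound]))
  conc$value <- correct_for_recovery(conc$raw_conc, conc$recovery)
  conc$below_loq <- conc$value < cfg$loq
  conc$units <- "ug/L"

  pharma_removal <- removal_series(conc)
  analyte_removal <- removal_series(sim$analytes)

  # total nitrogen: sum the as-N species per reactor/day/phase
  nspec <- sim$analytes[sim$analytes$analyte %in% c("NH3_N", "NO2_N", "NO3_N"), ]
  tn <- aggregate(list(value = nspec$value),
                  nspec[c("reactor", "day", "phase")], sum)
  tn$analyte <- "TN"
  tn_removal <- removal_series(tn)

  list(calibration = data.frame(
         compound = compounds,
         slope = vapply(curves, `[[`, numeric(1), "slope"),
         intercept = vapply(curves, `[[`, numeric(1), "intercept"),
         r_squared = vapply(curves, `[[`, numeric(1), "r_squared"),
         recovery = unname(recov[compounds]), row.names = NULL),
       concentrations = conc,
       removal = rbind(pharma_removal, analyte_removal, tn_removal))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate/load, quantify,
#' screen, active, respond, report), writes every stage table as CSV
#' under the configured output directory, and writes `manifest.json`
#' recording package version, parameters, seed and the MD5 hash of every
#' output file. Rerunning with an identical configuration reproduces
#' identical hashes.
#'
#' @param config A [pipeline_config()] or a path to a JSON config file.
#' @return Invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outdir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  stage <- function(name, expr) {
    logf("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(config$outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_simulation(config$input_dir)
    } else {
      args <- config$simulation
      args$seed <- config$seed
      s <- simulate_experiment(do.call(sim_config, args))
      write_simulation(s, file.path(config$outdir, "inputs"))
      s
    }
  })
  written <- c(written, sort(list.files(file.path(config$outdir, "inputs"),
                                        full.names = TRUE)))

  quant <- stage("quantify", stage_quantify(sim, config))
  emit(quant$calibration, "calibration")
  emit(quant$concentrations, "concentrations")
  emit(quant$removal, "removal")

  screen <- stage("screen", {
    hits <- screen_peaks(sim$pharma$peaks, max_ppm = config$max_ppm,
                         min_snr = config$min_snr)
    list(hits = hits, series = product_timeseries(hits))
  })
  emit(screen$hits, "screen_hits")
  emit(screen$series, "product_timeseries")

  active <- stage("active", {
    calls <- call_active(sim$community$counts_dna, sim$community$counts_cdna,
                         n_trials = config$n_trials,
                         threshold = config$active_threshold,
                         depth_dna = config$depth, depth_cdna = config$depth,
                         seed = derive_seed(config$seed, 51L))
    comp <- active_relative_abundance(calls, sim$community$counts_dna)
    fam <- aggregate_family(comp, sim$community$taxonomy)
    div <- diversity_indices(sim$community$counts_dna)
    list(calls = calls, composition = comp, families = fam, diversity = div)
  })
  emit(active$calls, "active_calls")
  emit(active$composition, "active_composition")
  emit(active$families$full, "active_families_full")
  emit(active$families$reported, "active_families_reported")
  emit(active$diversity, "diversity")

  respond <- stage("respond", {
    meta <- sim$community$samples
    test_ids <- meta$sample_id[meta$reactor == "test"]
    t1 <- if (is.null(config$t1)) test_ids[min(2, length(test_ids))] else config$t1
    t2 <- if (is.null(config$t2)) test_ids[min(3, length(test_ids))] else config$t2
    rt <- response_table(active$composition, t1, t2,
                         min_abundance = config$min_abundance,
                         band = config$response_band)

    # ordination coordinates: user-supplied, or stand-in metric MDS of the
    # active composition (NMDS itself is outside this package)
    comp_w <- active$composition
    wide <- tapply(comp_w$abundance,
                   list(comp_w$sample_id, comp_w$zotu_id),
                   sum, default = 0)
    if (!is.null(config$ordination)) {
      ord_df <- read.csv(config$ordination, stringsAsFactors = FALSE)
      scores <- as.matrix(ord_df[, -1, drop = FALSE])
      rownames(scores) <- ord_df[[1]]
    } else {
      scores <- stats::cmdscale(stats::dist(wide), k = 2)
      colnames(scores) <- c("axis1", "axis2")
    }
    list(response = rt, scores = scores, t1 = t1, t2 = t2)
  })

  # vector fitting of effluent pharmaceutical concentrations onto the
  # ordination coordinates, matched by nearest sampled day per reactor
  vec <- stage("vectors", {
    scores <- respond$scores
    meta <- sim$community$samples
    meta <- meta[match(rownames(scores), meta$sample_id), ]
    conc <- quant$concentrations
    effl <- conc[conc$phase == "effluent", ]
    compounds <- unique(effl$analyte)
    fits <- lapply(setNames(compounds, compounds), function(cmp) {
      e <- effl[effl$analyte == cmp, ]
      v <- vapply(seq_len(nrow(meta)), function(i) {
        er <- e[e$reactor == meta$reactor[i], ]
        er$value[which.min(abs(er$day - meta$day[i]))]
      }, numeric(1))
      if (sd(v) == 0) return(NULL)
      vector_fit(scores, v, n_perm = config$n_perm,
                 seed = derive_seed(config$seed, 61L, match(cmp, compounds)))
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    data.frame(
      variable = names(fits),
      r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
      p_value = vapply(fits, `[[`, numeric(1), "p_value"),
      do.call(rbind, lapply(fits, function(f) {
        setNames(as.data.frame(t(f$direction)),
                 paste0("axis", seq_along(f$direction)))
      })),
      row.names = NULL)
  })
  emit(respond$response, "response_ratios")
  emit(data.frame(sample_id = rownames(respond$scores), respond$scores,
                  row.names = NULL), "ordination_scores")
  emit(vec, "vector_fits")

  report <- stage("report", {
    counts <- table(factor(respond$response$category,
                           levels = c("negative", "neutral", "positive")))
    list(
      removal = quant$removal,
      products = screen$series,
      families = active$families$reported,
      response_summary = data.frame(category = names(counts),
                                    n_zotus = as.integer(counts)),
      empty_active_samples = attr(active$composition, "empty_samples")
    )
  })
  emit(report$response_summary, "response_summary")

  manifest <- list(
    package = "granulefate",
    version = as.character(utils::packageVersion("granulefate")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("outdir", "input_dir", "ordination"))],
    t1 = respond$t1, t2 = respond$t2,
    files = as.list(tools::md5sum(sort(unique(written))))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done: ", length(written), " tables written")

  invisible(list(simulation = sim, quantification = quant, screening = screen,
                 active = active, response = respond$response,
                 vector_fits = vec, report = report, manifest = manifest,
                 outdir = config$outdir))
}
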