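# Pharmaceutical quantification: calibration, spike-recovery correction,
# concentration factors, solid-phase concentrations, and mass-balance
# percent removal.

#' Fit a peak-area calibration curve
#'
#' Ordinary least-squares line relating peak area to nominal standard
#' concentration. Standards prepared in different solvents may be pooled
#' into one fit; keep a solvent column upstream if stratified fits are
#' wanted.
#'
#' @param standards data.frame (or 2-column matrix) with nominal
#'   concentrations (ug/L) in the first column and peak areas in the second.
#' @param compound Optional compound label carried on the result.
#' @return An object of class `calibration_curve` with elements `compound`,
#'   `slope` (area per ug/L), `intercept` (area), `r_squared`, `standards`.
#' @export
fit_calibration <- function(standards, compound = NA_character_) {
  standards <- as.data.frame(standards)
  names(standards)[1:2] <- c("nominal", "area")
  if (nrow(standards) < 2 || length(unique(standards$nominal)) < 2) {
    stop("calibration requires at least 2 distinct nominal levels")
  }
  if (any(standards$area < 0)) stop("peak areas must be >= 0")
  fit <- lm(area ~ nominal, data = standards)
  slope <- unname(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$area - mean(standards$area))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  if (slope <= 0) {
    stop("calibration slope is not positive; curve invalid")
  }
  structure(
    list(compound = compound, slope = slope,
         intercept = unname(coef(fit)[1]),
         r_squared = r2, standards = standards),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve%s: area = %.4g * conc + %.4g (r^2 = %.4f)\n",
              if (is.na(x$compound)) "" else paste0(" [", x$compound, "]"),
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify a concentration from a peak area
#'
#' Inverts the calibration line; values below the calibration intercept are
#' clipped to 0 and flagged below range, mirroring a limit-of-quantification
#' regime.
#'
#' @param area Peak area(s).
#' @param curve A `calibration_curve`.
#' @return data.frame with `conc` (ug/L) and logical `below_range`.
#' @export
quantify <- function(area, curve) {
  if (!inherits(curve, "calibration_curve")) stop("curve must be a calibration_curve")
  conc <- (area - curve$intercept) / curve$slope
  # tolerate least-squares rounding at the intercept itself
  tol <- 1e-9 * (abs(curve$intercept) + 1) / curve$slope
  below <- conc < -tol
  conc[conc < 0] <- 0
  data.frame(conc = conc, below_range = below)
}

#' Solid-phase-extraction concentration factor
#'
#' Loaded sample volume divided by final extract volume; e.g. 100 mL
#' concentrated to 1 mL gives a factor of 100.
#'
#' @param loaded_volume Loaded sample volume, mL (> 0).
#' @param extract_volume Final extract volume, mL (> 0).
#' @return Unitless concentration factor.
#' @export
concentration_factor <- function(loaded_volume, extract_volume) {
  if (any(loaded_volume <= 0) || any(extract_volume <= 0)) {
    stop("volumes must be positive")
  }
  loaded_volume / extract_volume
}

#' Spike-recovery fraction from a prespike/unspiked/postspike triplet
#'
#' One duplicate is spiked before extraction (prespike), the other is
#' extracted unspiked and then half of it is spiked after extraction
#' (postspike). Recovery is
#' \deqn{(C_{pre} - C_{un}) / (C_{post} - C_{un})}
#' Recovery may exceed 1 (matrix enhancement; erythromycin commonly shows
#' ~117\%) and is not clipped. Prespike equal to unspiked gives recovery 0
#' with a total-loss flag.
#'
#' @param prespike_conc Measured concentration of the pre-spiked sample, ug/L.
#' @param unspiked_conc Measured concentration of the unspiked sample, ug/L.
#' @param postspike_conc Measured concentration of the post-spiked sample,
#'   ug/L; must exceed `unspiked_conc`.
#' @return List with `recovery` (fraction) and logical `total_loss`.
#' @export
compute_recovery <- function(prespike_conc, unspiked_conc, postspike_conc) {
  if (any(c(prespike_conc, unspiked_conc, postspike_conc) < 0)) {
    stop("concentrations must be >= 0")
  }
  denom <- postspike_conc - unspiked_conc
  if (any(denom <= 0)) {
    stop("recovery undefined: postspike concentration must exceed unspiked")
  }
  r <- (prespike_conc - unspiked_conc) / denom
  list(recovery = r, total_loss = r == 0)
}

#' Correct a measured concentration for extraction recovery
#'
#' @param raw_conc Measured concentration (ug/L aqueous or ug/g solid).
#' @param recovery Recovery fraction in (0, 2].
#' @return Corrected concentration, `raw_conc / recovery`.
#' @export
correct_for_recovery <- function(raw_conc, recovery) {
  if (any(recovery <= 0) || any(recovery > 2)) {
    stop("recovery must be in (0, 2]")
  }
  raw_conc / recovery
}

#' Mass-balance percent removal at one timepoint
#'
#' Removal computed from influent and effluent concentrations, treating
#' per-cycle influent and effluent volumes as equal:
#' \deqn{100 (C_{in} - C_{eff}) / C_{in}}
#' Negative removal indicates effluent above influent (e.g. desorption:
#' effluent at twice influent gives -100\%). Influent <= 0 yields `NA`
#' (removal undefined).
#'
#' @param influent Influent concentration(s).
#' @param effluent Effluent concentration(s), same units.
#' @return Percent removal; `NA` where influent is not positive.
#' @export
removal_percent <- function(influent, effluent) {
  out <- 100 * (influent - effluent) / influent
  out[!is.finite(influent) | influent <= 0] <- NA_real_
  out
}

#' Total-nitrogen percent removal
#'
#' Sums the nitrogen species (all in consistent as-N units) per phase and
#' applies the mass-balance removal to the totals.
#'
#' @param nh3_in,nh3_eff Ammonia-N influent/effluent concentrations.
#' @param no2_in,no2_eff Nitrite-N influent/effluent concentrations.
#' @param no3_in,no3_eff Nitrate-N influent/effluent concentrations.
#' @return Percent removal of total nitrogen.
#' @export
total_nitrogen_removal <- function(nh3_in, nh3_eff,
                                   no2_in = 0, no2_eff = 0,
                                   no3_in = 0, no3_eff = 0) {
  removal_percent(nh3_in + no2_in + no3_in, nh3_eff + no2_eff + no3_eff)
}

#' Solid-phase concentration per gram dry biomass
#'
#' @param extract_conc Concentration in the extract, ug/L.
#' @param extract_volume Extract volume, mL.
#' @param dry_weight Sample dry weight, g (> 0).
#' @return Concentration in ug/g dry weight.
#' @export
solid_phase_concentration <- function(extract_conc, extract_volume,
                                      dry_weight) {
  if (any(dry_weight <= 0)) stop("dry_weight must be > 0")
  if (any(extract_volume <= 0)) stop("extract_volume must be > 0")
  extract_conc * (extract_volume / 1000) / dry_weight
}

#' Per-timepoint removal series from a tidy concentration table
#'
#' @param concentrations data.frame with columns `analyte`, `day`, `phase`
#'   (`"influent"` / `"effluent"`) and `value`; extra columns (e.g.
#'   `reactor`) are used as additional grouping keys if named in `by`.
#' @param by Extra grouping columns (default `"reactor"` when present).
#' @return data.frame with one row per group x analyte x day:
#'   `influent_conc`, `effluent_conc`, `removal_percent`.
#' @export
removal_series <- function(concentrations,
                           by = intersect("reactor", names(concentrations))) {
  keys <- c(by, "analyte", "day")
  infl <- concentrations[concentrations$phase == "influent", ]
  effl <- concentrations[concentrations$phase == "effluent", ]
  infl_m <- aggregate(infl["value"], infl[keys], mean)
  names(infl_m)[names(infl_m) == "value"] <- "influent_conc"
  effl_m <- aggregate(effl["value"], effl[keys], mean)
  names(effl_m)[names(effl_m) == "value"] <- "effluent_conc"
  out <- merge(infl_m, effl_m, by = keys)
  out$removal_percent <- removal_percent(out$influent_conc, out$effluent_conc)
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
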