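# Suspect screening of mass-spectral peaks against a compound database,
# and corrected-peak-area statistics for relative tracking of degradation
# products over time.

#' Screen peak observations against a compound database
#'
#' Each peak row names a candidate compound; the peak passes when its
#' absolute mass error against the candidate's theoretical adduct m/z is
#' strictly below `max_ppm` \emph{and} its signal-to-noise ratio is at
#' least `min_snr`. The ppm bound is strict (a peak at exactly 5 ppm
#' fails); the S/N bound is inclusive (S/N = 10 passes).
#'
#' Corrected areas are attached where normalisation inputs are present:
#' aqueous peaks need `concentration_factor` and `standard_area_100`
#' (the same-run 100 ug/L parent standard's peak area), solid peaks need
#' `dry_weight` and `standard_area_100`. Peaks lacking a usable standard
#' area are flagged `unnormalizable` rather than dropped.
#'
#' @param peaks data.frame with columns `sample_id`, `day`, `phase`
#'   (one of `"influent"`, `"effluent"`, `"solid"`), `candidate_compound`,
#'   `observed_mz`, `area`, `snr`, and, per phase, `concentration_factor`
#'   or `dry_weight`, plus `standard_area_100`.
#' @param db Compound database (see [compound_db()]).
#' @param max_ppm Strict upper bound on absolute ppm mass error (default 5).
#' @param min_snr Inclusive lower bound on signal-to-noise (default 10).
#' @param adduct Adduct assumed for theoretical m/z (default `"[M+H]+"`).
#' @return The input peaks with added columns `theoretical_mz`,
#'   `mass_error_ppm`, `passed`, `corrected_area`, `unnormalizable`.
#' @export
screen_peaks <- function(peaks, db = compound_db(), max_ppm = 5,
                         min_snr = 10, adduct = "[M+H]+") {
  db <- validate_compound_db(db)
  unknown <- setdiff(unique(peaks$candidate_compound), db$code)
  if (length(unknown)) {
    stop("candidate compound(s) not in database: ",
         paste(unknown, collapse = ", "))
  }
  theo <- vapply(db$formula,
                 function(f) adduct_mz(monoisotopic_mass(f), adduct),
                 numeric(1))
  names(theo) <- db$code

  hits <- peaks
  hits$theoretical_mz <- unname(theo[hits$candidate_compound])
  hits$mass_error_ppm <- mass_error_ppm(hits$observed_mz, hits$theoretical_mz)
  hits$passed <- screen_filter(hits$mass_error_ppm, hits$snr, max_ppm, min_snr)

  std <- hits$standard_area_100
  hits$unnormalizable <- !is.finite(std) | std <= 0
  hits$corrected_area <- NA_real_
  aq <- hits$phase %in% c("influent", "effluent") & !hits$unnormalizable
  if (any(aq)) {
    hits$corrected_area[aq] <- aqueous_corrected_area(
      hits$area[aq], hits$concentration_factor[aq], std[aq])
  }
  so <- hits$phase == "solid" & !hits$unnormalizable
  if (any(so)) {
    hits$corrected_area[so] <- solid_corrected_area(
      hits$area[so], std[so], hits$dry_weight[so])
  }
  hits
}

#' Degradation-product reporting rule
#'
#' The two-part filter applied by [screen_peaks()]: the absolute mass
#' error must be strictly less than `max_ppm` and the signal-to-noise
#' ratio at least `min_snr` (inclusive). A peak at exactly 5 ppm fails;
#' one at exactly S/N 10 passes.
#'
#' @param mass_error_ppm Signed ppm mass error(s).
#' @param snr Signal-to-noise ratio(s).
#' @param max_ppm Strict ppm bound (default 5).
#' @param min_snr Inclusive S/N bound (default 10).
#' @return Logical vector.
#' @export
screen_filter <- function(mass_error_ppm, snr, max_ppm = 5, min_snr = 10) {
  abs(mass_error_ppm) < max_ppm & snr >= min_snr
}

#' Aqueous corrected peak area
#'
#' Normalises a degradation product's peak area to the same-run 100 ug/L
#' parent standard and scales by the solid-phase-extraction concentration
#' factor:
#' \deqn{\mathrm{area} \times \mathrm{CF} / \mathrm{area}_{100}}
#' A relative concentration proxy, not an absolute quantification.
#'
#' @param area Degradation product peak area.
#' @param concentration_factor Loaded volume / extract volume (unitless).
#' @param standard_area_100 Peak area of the relevant 100 ug/L parent
#'   standard (> 0).
#' @return Unitless corrected area.
#' @export
aqueous_corrected_area <- function(area, concentration_factor,
                                   standard_area_100) {
  if (any(standard_area_100 <= 0)) stop("standard_area_100 must be > 0")
  area * concentration_factor / standard_area_100
}

#' Solid-phase corrected peak area
#'
#' \deqn{\mathrm{area} / (\mathrm{area}_{100} \times \mathrm{dry\ weight})}
#'
#' @param area Degradation product peak area.
#' @param standard_area_100 Peak area of the relevant 100 ug/L parent
#'   standard (> 0).
#' @param dry_weight Sample dry weight in g (> 0).
#' @return Corrected area per g dry biomass.
#' @export
solid_corrected_area <- function(area, standard_area_100, dry_weight) {
  if (any(standard_area_100 <= 0)) stop("standard_area_100 must be > 0")
  if (any(dry_weight <= 0)) stop("dry_weight must be > 0")
  area / (standard_area_100 * dry_weight)
}

#' Corrected-area time series of screened degradation products
#'
#' Restricts screened hits to those passing the filter and returns a
#' long-format series of corrected areas per compound, phase and day.
#' Non-detections are explicit gaps (absent rows), not zeros: a failed or
#' absent peak carries no abundance information.
#'
#' @param hits Output of [screen_peaks()].
#' @return data.frame with columns `compound`, `phase`, `day`,
#'   `corrected_area` (one row per passed hit), ordered by compound,
#'   phase, day.
#' @export
product_timeseries <- function(hits) {
  keep <- hits[hits$passed & !hits$unnormalizable,
               c("candidate_compound", "phase", "day", "corrected_area")]
  names(keep)[1] <- "compound"
  keep <- keep[order(keep$compound, keep$phase, keep$day), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
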