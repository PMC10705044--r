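# Independent oracles used across the suite. The mass table below was
# typed separately from NIST isotope listings (not shared with the
# package's internal table) so the monoisotopic-mass checks are a genuine
# dual route.

oracle_mono <- c(H = 1.007825032, C = 12, N = 14.003074, O = 15.994915,
                 Cl = 34.968853, Na = 22.989769, S = 31.972071)
oracle_proton <- 1.00727646

# Hand summation of a parsed formula over the oracle table.
oracle_mono_mass <- function(counts) {
  sum(oracle_mono[names(counts)] * counts)
}

# Brute-force row-wise screening filter: the two printed rules, applied
# literally per row.
oracle_screen <- function(ppm, snr, max_ppm = 5, min_snr = 10) {
  keep <- logical(length(ppm))
  for (i in seq_along(ppm)) {
    keep[i] <- (abs(ppm[i]) < max_ppm) && (snr[i] >= min_snr)
  }
  keep
}

# Shannon entropy by the closed form, written independently of the
# package implementation.
oracle_shannon <- function(x) {
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Small community config shared by several tests (fast but non-trivial).
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_zotus = 40, n_samples_per_reactor = 3,
         depth_dna = 2000, depth_cdna = 2000, seed = 42),
    list(...))
  do.call(sim_config, args)
}
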