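# Active-microbiome caller: paired rarefaction of DNA (rRNA gene) and
# cDNA (rRNA transcript) libraries over repeated trials, transcript:gene
# ratios with the phantom-taxon rule, active-taxon classification,
# active-community composition, family aggregation, and diversity.

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement so the rarefied library sums to
#' `depth` exactly. Reproducible under `seed`.
#'
#' @param counts Named (or plain) non-negative integer count vector.
#' @param depth Target depth; must not exceed `sum(counts)`.
#' @param seed Optional integer seed; if `NULL`, uses the current RNG
#'   stream.
#' @return Integer vector of the same length and names, summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  nm <- names(counts)
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (depth > total) {
    stop("rarefaction depth (", depth, ") exceeds library total (", total, ")")
  }
  draw <- function() {
    if (depth == total) return(counts)
    picked <- sample.int(total, depth)
    # map read indices back to taxa via the cumulative count boundaries
    tabulate(findInterval(picked, cumsum(counts), left.open = TRUE) + 1L,
             nbins = length(counts))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  names(out) <- nm
  out
}

#' Transcript:gene ratios for one paired rarefaction trial
#'
#' Rarefies the DNA and cDNA libraries of one sample to their respective
#' depths and returns, per taxon, the ratio of rarefied cDNA relative
#' abundance to rarefied DNA relative abundance. Taxa present in the
#' rarefied cDNA library but absent from the rarefied DNA library
#' (phantom in this trial) are assigned the fixed value 100. Taxa absent
#' from both rarefied libraries get `NA` (no value; they contribute
#' nothing to across-trial means).
#'
#' @param dna_counts,cdna_counts Count vectors over the same taxon index.
#' @param depth_dna,depth_cdna Rarefaction depths for each pool.
#' @param seed Optional integer seed for the trial.
#' @param phantom_value Ratio assigned to trial-level phantoms (default
#'   100).
#' @return Numeric vector of per-taxon ratios (`NA` = absent from trial).
#' @export
ratio_one_trial <- function(dna_counts, cdna_counts, depth_dna, depth_cdna,
                            seed = NULL, phantom_value = 100) {
  if (length(dna_counts) != length(cdna_counts)) {
    stop("DNA and cDNA vectors must share one taxon index")
  }
  run <- function() {
    d <- rarefy(dna_counts, depth_dna)
    c_ <- rarefy(cdna_counts, depth_cdna)
    dr <- d / sum(d)
    cr <- c_ / sum(c_)
    ratio <- cr / dr                      # both > 0
    ratio[cr > 0 & dr == 0] <- phantom_value  # phantom in this trial
    ratio[cr == 0 & dr > 0] <- 0
    ratio[cr == 0 & dr == 0] <- NA_real_  # absent: no value this trial
    ratio
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  names(out) <- names(dna_counts)
  out
}

#' Call the active microbial community
#'
#' For every sample shared by the DNA and cDNA count matrices, runs
#' `n_trials` paired rarefaction trials, averages each taxon's
#' transcript:gene ratio over the trials in which it had a value, and
#' calls a taxon active in that sample when the mean ratio meets
#' `threshold` (default >= 1). Structural phantom taxa (zero DNA reads
#' overall but positive cDNA reads) receive the phantom value in every
#' trial where they are drawn and are active by construction.
#'
#' @param dna,cdna ZOTU x sample integer count matrices with identical
#'   row (taxon) names; their common samples are analysed.
#' @param n_trials Number of rarefaction trials (default 100).
#' @param threshold Mean-ratio threshold for the active call (default 1).
#' @param depth_dna,depth_cdna Rarefaction depths; default is the minimum
#'   library total across all samples of both pools.
#' @param seed Master seed; one child seed is derived per (sample, trial)
#'   so per-sample results are order-independent.
#' @param phantom_value Ratio substituted for trial-level phantoms.
#' @param absent_as_zero If `TRUE`, trials where a taxon is absent from
#'   both rarefied libraries count as ratio 0 instead of being excluded
#'   from the mean.
#' @return data.frame (`active_calls`) with one row per taxon x sample:
#'   `zotu_id`, `sample_id`, `mean_ratio`, `phantom_frequency` (fraction
#'   of contributing trials the taxon was a trial-level phantom),
#'   `n_trials_present`, `dna_reads` (unrarefied), `cdna_reads`, `active`.
#' @export
call_active <- function(dna, cdna, n_trials = 100, threshold = 1,
                        depth_dna = NULL, depth_cdna = NULL,
                        seed = 1, phantom_value = 100,
                        absent_as_zero = FALSE) {
  if (is.null(rownames(dna)) || is.null(rownames(cdna)) ||
      !identical(rownames(dna), rownames(cdna))) {
    stop("DNA and cDNA matrices must share identical taxon (row) names")
  }
  shared <- intersect(colnames(dna), colnames(cdna))
  if (!length(shared)) stop("no samples shared between DNA and cDNA matrices")
  default_depth <- min(c(colSums(dna[, shared, drop = FALSE]),
                         colSums(cdna[, shared, drop = FALSE])))
  if (is.null(depth_dna)) depth_dna <- default_depth
  if (is.null(depth_cdna)) depth_cdna <- default_depth

  res <- lapply(seq_along(shared), function(si) {
    s <- shared[si]
    dvec <- dna[, s]
    cvec <- cdna[, s]
    sums <- matrix(0, nrow(dna), 2)  # ratio sum, n present
    ph <- numeric(nrow(dna))
    for (tr in seq_len(n_trials)) {
      r <- ratio_one_trial(dvec, cvec, depth_dna, depth_cdna,
                           seed = derive_seed(seed, si, tr),
                           phantom_value = phantom_value)
      if (absent_as_zero) r[is.na(r)] <- 0
      has <- !is.na(r)
      sums[has, 1] <- sums[has, 1] + r[has]
      sums[has, 2] <- sums[has, 2] + 1
      ph <- ph + (has & r == phantom_value)
    }
    mean_ratio <- ifelse(sums[, 2] > 0, sums[, 1] / sums[, 2], NA_real_)
    data.frame(zotu_id = rownames(dna), sample_id = s,
               mean_ratio = mean_ratio,
               phantom_frequency = ifelse(sums[, 2] > 0, ph / sums[, 2], 0),
               n_trials_present = sums[, 2],
               dna_reads = as.integer(dvec),
               cdna_reads = as.integer(cvec),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, res)
  calls$active <- !is.na(calls$mean_ratio) & calls$mean_ratio >= threshold
  rownames(calls) <- NULL
  attr(calls, "depth_dna") <- depth_dna
  attr(calls, "depth_cdna") <- depth_cdna
  attr(calls, "threshold") <- threshold
  calls
}

#' Relative abundance within the active community
#'
#' Restricts each sample to its active taxa and renormalises their
#' unrarefied DNA read counts. Phantom taxa contribute their DNA reads
#' as-is (zero for structural phantoms), following the convention that
#' DNA read numbers — not cDNA — carry abundance information.
#'
#' @param calls Output of [call_active()].
#' @param dna ZOTU x sample DNA count matrix (unrarefied).
#' @return data.frame `zotu_id`, `sample_id`, `abundance` over active
#'   taxa only; samples whose active set has zero DNA reads are returned
#'   with `abundance = NA` and flagged via the `empty_samples` attribute.
#' @export
active_relative_abundance <- function(calls, dna) {
  act <- calls[calls$active, c("zotu_id", "sample_id", "dna_reads")]
  empty <- character(0)
  out <- do.call(rbind, lapply(split(act, act$sample_id), function(d) {
    tot <- sum(d$dna_reads)
    if (tot == 0) {
      empty <<- c(empty, d$sample_id[1])
      d$abundance <- NA_real_
    } else {
      d$abundance <- d$dna_reads / tot
    }
    d
  }))
  rownames(out) <- NULL
  out <- out[, c("zotu_id", "sample_id", "abundance")]
  attr(out, "empty_samples") <- empty
  out
}

#' Aggregate a composition to family level
#'
#' Sums ZOTU relative abundances by family per sample. The full table
#' preserves the per-sample totals exactly; the reporting view drops
#' families that never reach `min_plot_abundance` in any sample.
#'
#' @param composition data.frame `zotu_id`, `sample_id`, `abundance`.
#' @param taxonomy data.frame with `zotu_id` and `family` columns; ZOTUs
#'   without a family are grouped as `"unclassified"`.
#' @param min_plot_abundance Reporting threshold (default 0.01 = 1\%).
#' @return List with `full` (family x sample long table) and `reported`
#'   (filtered view).
#' @export
aggregate_family <- function(composition, taxonomy,
                             min_plot_abundance = 0.01) {
  fam <- setNames(taxonomy$family, taxonomy$zotu_id)
  f <- fam[composition$zotu_id]
  f[is.na(f) | !nzchar(f)] <- "unclassified"
  agg <- aggregate(list(abundance = composition$abundance),
                   list(family = f, sample_id = composition$sample_id),
                   sum)
  keep <- unique(agg$family[!is.na(agg$abundance) &
                              agg$abundance >= min_plot_abundance])
  list(full = agg,
       reported = agg[agg$family %in% keep, , drop = FALSE])
}

#' Per-sample diversity indices from DNA reads
#'
#' Observed-ZOTU richness and Shannon entropy (natural log), computed
#' from the DNA pool (cDNA read numbers can be biased by reverse
#' transcription and are not used for diversity).
#'
#' @param dna ZOTU x sample DNA count matrix.
#' @return data.frame `sample_id`, `richness`, `shannon`; empty samples
#'   are flagged with `NA` indices.
#' @export
diversity_indices <- function(dna) {
  out <- data.frame(
    sample_id = colnames(dna),
    richness = colSums(dna > 0),
    shannon = apply(dna, 2, function(x) {
      tot <- sum(x)
      if (tot == 0) return(NA_real_)
      p <- x[x > 0] / tot
      -sum(p * log(p))
    }),
    row.names = NULL
  )
  out
}
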