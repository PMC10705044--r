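# Between-timepoint response ratios of active taxa, neutral-band
# classification, the minimum-abundance filter, and permutation-tested
# vector fitting of environmental variables onto ordination coordinates.

#' Bounded response ratio between two timepoints
#'
#' Symmetric difference-over-sum statistic
#' \deqn{(b - a) / (b + a)}
#' bounded in \[-1, 1\]: +1 when a taxon appears (absent at t1, present
#' at t2), -1 when it disappears, 0 when unchanged. Both abundances zero
#' gives `NA` (undefined).
#'
#' @param a Relative abundance at the first timepoint (>= 0).
#' @param b Relative abundance at the second timepoint (>= 0).
#' @return Response ratio(s) in \[-1, 1\], `NA` where `a + b == 0`.
#' @export
response_ratio <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  out <- (b - a) / (b + a)
  out[(a + b) == 0] <- NA_real_
  out
}

#' Classify a response ratio against the neutral band
#'
#' Values with absolute value at most `band` (inclusive) are neutral;
#' beyond the band the sign decides positive/negative. The three
#' categories partition \[-1, 1\] exactly.
#'
#' @param rr Response ratio(s) in \[-1, 1\].
#' @param band Half-width of the neutral band (default 0.5).
#' @return Character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
classify_response <- function(rr, band = 0.5) {
  if (any(abs(rr) > 1 + 1e-12, na.rm = TRUE)) {
    stop("response ratios must lie in [-1, 1]")
  }
  ifelse(is.na(rr), NA_character_,
         ifelse(abs(rr) <= band, "neutral",
                ifelse(rr > 0, "positive", "negative")))
}

#' Minimum-abundance filter across two timepoints
#'
#' Keeps taxa whose relative abundance strictly exceeds `min_abundance`
#' at either timepoint, so taxa that appear or vanish between the
#' timepoints are retained.
#'
#' @param abundance_t1,abundance_t2 Named abundance vectors over the same
#'   taxon index.
#' @param min_abundance Strict threshold (default 0.001 = 0.1\%).
#' @return Character vector of surviving taxon ids.
#' @export
filter_min_abundance <- function(abundance_t1, abundance_t2,
                                 min_abundance = 0.001) {
  if (!identical(names(abundance_t1), names(abundance_t2))) {
    stop("abundance vectors must share one taxon index")
  }
  names(abundance_t1)[abundance_t1 > min_abundance |
                        abundance_t2 > min_abundance]
}

#' Response-ratio table between two samples of an active composition
#'
#' Applies the minimum-abundance filter, computes response ratios, and
#' classifies them against the neutral band.
#'
#' @param composition Output of [active_relative_abundance()].
#' @param t1,t2 Sample ids of the two timepoints.
#' @param min_abundance Strict abundance threshold (default 0.001).
#' @param band Neutral band half-width (default 0.5).
#' @return data.frame `zotu_id`, `abundance_t1`, `abundance_t2`,
#'   `response_ratio`, `category`.
#' @export
response_table <- function(composition, t1, t2, min_abundance = 0.001,
                           band = 0.5) {
  get_comp <- function(s) {
    d <- composition[composition$sample_id == s, ]
    if (!nrow(d)) stop("sample not found in composition: ", s)
    setNames(d$abundance, d$zotu_id)
  }
  a <- get_comp(t1)
  b <- get_comp(t2)
  ids <- union(names(a), names(b))
  av <- setNames(rep(0, length(ids)), ids)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  keep <- filter_min_abundance(av, bv, min_abundance)
  rr <- response_ratio(av[keep], bv[keep])
  data.frame(zotu_id = keep,
             abundance_t1 = unname(av[keep]),
             abundance_t2 = unname(bv[keep]),
             response_ratio = unname(rr),
             category = classify_response(unname(rr), band),
             stringsAsFactors = FALSE)
}

#' Fit an environmental vector onto ordination coordinates
#'
#' Regresses a centred per-sample variable on the centred ordination
#' scores; the fitted direction (unit vector) maximises the correlation
#' of the variable with a linear combination of axes, the squared
#' multiple correlation is the vector's r-squared, and significance is
#' assessed by permuting the variable:
#' \deqn{p = (1 + \#\{r^2_{perm} \ge r^2_{obs}\}) / (1 + n_{perm})}
#'
#' @param scores Samples x axes numeric matrix of ordination coordinates.
#' @param values Per-sample environmental variable (length `nrow(scores)`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `vector_fit`: `direction` (unit vector over
#'   axes), `r_squared`, `p_value`, `n_perm`.
#' @export
vector_fit <- function(scores, values, n_perm = 999, seed = 1) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3) stop("vector fitting needs at least 3 samples")
  if (ncol(scores) < 2) stop("vector fitting needs at least 2 axes")
  if (length(values) != nrow(scores) || any(!is.finite(values))) {
    stop("values must be finite, one per sample")
  }
  if (sd(values) == 0) stop("constant values: vector fit undefined")

  xc <- scale(scores, center = TRUE, scale = FALSE)
  r2_of <- function(v) {
    vc <- v - mean(v)
    beta <- qr.coef(qr(xc), vc)
    beta[is.na(beta)] <- 0
    fit <- xc %*% beta
    list(beta = beta, r2 = sum(fit^2) / sum(vc^2))
  }
  obs <- r2_of(values)
  dir <- obs$beta / sqrt(sum(obs$beta^2))
  perm_r2 <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) r2_of(sample(values))$r2, numeric(1))
  })
  structure(
    list(direction = as.numeric(dir), r_squared = obs$r2,
         p_value = (1 + sum(perm_r2 >= obs$r2)) / (1 + n_perm),
         n_perm = n_perm),
    class = "vector_fit"
  )
}

#' @export
print.vector_fit <- function(x, ...) {
  cat(sprintf("Vector fit: r^2 = %.4f, p = %.4g (%d permutations)\n",
              x$r_squared, x$p_value, x$n_perm))
  cat("direction:", paste(sprintf("%.3f", x$direction), collapse = ", "), "\n")
  invisible(x)
}
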