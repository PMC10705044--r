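# Rarefaction, transcript:gene ratios, the phantom rule, active calling,
# composition, family aggregation and diversity.

test_that("rarefaction conserves depth and is seed-deterministic", {
  x <- c(a = 50L, b = 30L, c = 0L, d = 20L)
  expect_identical(rarefy(x, 100), x)       # full depth: identity
  one <- rarefy(x, 1, seed = 7)
  expect_equal(sum(one), 1)
  expect_equal(sum(one > 0), 1)
  expect_identical(rarefy(x, 40, seed = 11), rarefy(x, 40, seed = 11))
  expect_equal(sum(rarefy(x, 40, seed = 11)), 40)
  expect_true(all(rarefy(x, 40, seed = 11) <= x))
  expect_error(rarefy(x, 101), "exceeds")
})

test_that("rarefied counts match the hypergeometric expectation", {
  x <- c(a = 120L, b = 60L, c = 15L, d = 5L)
  depth <- 100L
  n_rep <- 4000
  set.seed(1)
  draws <- matrix(0, n_rep, length(x))
  for (i in seq_len(n_rep)) draws[i, ] <- rarefy(x, depth)
  exp_mean <- depth * x / sum(x)
  # hypergeometric variance for each taxon's rarefied count
  N <- sum(x)
  v <- depth * (x / N) * (1 - x / N) * (N - depth) / (N - 1)
  mc_se <- sqrt(v / n_rep)
  expect_true(all(abs(colMeans(draws) - exp_mean) <= 3 * mc_se + 1e-9))
})

test_that("rarefy agrees with vegan's rrarefy marginally", {
  skip_if_not_installed("vegan")
  x <- matrix(c(300L, 150L, 50L), 1, dimnames = list("s", c("a", "b", "c")))
  set.seed(2)
  mine <- replicate(1500, rarefy(x[1, ], 100))
  vg <- suppressWarnings(t(replicate(1500, vegan::rrarefy(x, 100)[1, ])))
  expect_equal(rowMeans(mine), colMeans(vg), tolerance = 0.05)
})

test_that("trial ratios implement the phantom and absence contracts", {
  # identical composition at full depth: all ratios 1
  x <- c(a = 10L, b = 20L, c = 70L)
  r <- ratio_one_trial(x, x, 100, 100, seed = 1)
  expect_equal(unname(r), rep(1, 3))

  dna <- c(a = 100L, b = 0L, c = 0L)
  cdna <- c(a = 50L, b = 50L, c = 0L)
  r <- ratio_one_trial(dna, cdna, 100, 100, seed = 1)
  expect_equal(unname(r[["b"]]), 100)   # phantom in this trial
  expect_true(is.na(r[["c"]]))          # absent from both: no value
  expect_error(ratio_one_trial(dna, cdna[1:2], 10, 10), "taxon index")
})

test_that("structural phantoms are always active; infinite threshold empties the call", {
  dna <- matrix(c(500L, 500L, 0L), 3, 2,
                dimnames = list(c("z1", "z2", "ph"), c("s1", "s2")))
  cdna <- matrix(c(450L, 450L, 100L), 3, 2,
                 dimnames = list(c("z1", "z2", "ph"), c("s1", "s2")))
  calls <- call_active(dna, cdna, n_trials = 10, seed = 3)
  phc <- calls[calls$zotu_id == "ph", ]
  expect_true(all(phc$mean_ratio == 100))
  expect_true(all(phc$active))
  expect_true(all(phc$phantom_frequency == 1))

  none <- call_active(dna, cdna, n_trials = 10, threshold = Inf, seed = 3)
  expect_false(any(none$active))
})

test_that("the caller recovers a strong composition ratio at depth", {
  # one taxon with cDNA:DNA composition ratio 3 among an even background
  set.seed(8)
  n <- 20
  p_dna <- rep(1 / n, n)
  p_cdna <- p_dna
  p_cdna[1] <- 3 * p_dna[1]
  p_cdna <- p_cdna / sum(p_cdna)
  active_hits <- 0
  for (rep in 1:20) {
    dna <- matrix(as.integer(rmultinom(1, 5000, p_dna)), n, 1,
                  dimnames = list(sprintf("z%02d", 1:n), "s1"))
    cdna <- matrix(as.integer(rmultinom(1, 5000, p_cdna)), n, 1,
                   dimnames = list(sprintf("z%02d", 1:n), "s1"))
    calls <- call_active(dna, cdna, n_trials = 20,
                         depth_dna = 2500, depth_cdna = 2500, seed = rep)
    if (calls$active[calls$zotu_id == "z01"]) active_hits <- active_hits + 1
  }
  expect_gte(active_hits, 19)
})

test_that("active composition normalises DNA reads over the active set", {
  dna <- matrix(c(80L, 20L, 0L), 3, 1,
                dimnames = list(c("z1", "z2", "ph"), "s1"))
  cdna <- matrix(c(90L, 5L, 5L), 3, 1,
                 dimnames = list(c("z1", "z2", "ph"), "s1"))
  calls <- call_active(dna, cdna, n_trials = 5, seed = 1)
  comp <- active_relative_abundance(calls, dna)
  expect_equal(sum(comp$abundance), 1)
  # phantom contributes its (zero) DNA reads; z1 dominates
  expect_equal(comp$abundance[comp$zotu_id == "z1"], 1)
  expect_equal(comp$abundance[comp$zotu_id == "ph"], 0)

  # single active taxon -> abundance exactly 1
  calls2 <- calls[calls$zotu_id == "z1", ]
  comp2 <- active_relative_abundance(calls2, dna)
  expect_equal(comp2$abundance, 1)
})

test_that("active abundances rank like the true composition on synthetic truth", {
  cfg <- small_cfg(phantom_fraction = 0, depth_dna = 8000, depth_cdna = 8000)
  com <- simulate_community(cfg)
  calls <- call_active(com$counts_dna, com$counts_cdna, n_trials = 20,
                       seed = 2)
  comp <- active_relative_abundance(calls, com$counts_dna)
  s <- com$samples$sample_id[1]
  got <- comp[comp$sample_id == s, ]
  truth <- com$truth$dna_composition[got$zotu_id, s]
  expect_gt(stats::cor(got$abundance, truth, method = "spearman"), 0.9)
})

test_that("family aggregation partitions abundance and filters the view", {
  comp <- data.frame(zotu_id = c("z1", "z2", "z3"),
                     sample_id = "s1",
                     abundance = c(0.6, 0.395, 0.005))
  tax <- data.frame(zotu_id = c("z1", "z2", "z3"),
                    family = c("A", "A", "B"))
  fam <- aggregate_family(comp, tax)
  expect_equal(sum(fam$full$abundance), 1)
  expect_equal(fam$full$abundance[fam$full$family == "A"], 0.995)
  expect_false("B" %in% fam$reported$family)   # never reaches 1%
  expect_true("B" %in% fam$full$family)

  # single family at 1.0
  fam1 <- aggregate_family(comp, data.frame(zotu_id = comp$zotu_id,
                                            family = "A"))
  expect_equal(fam1$full$abundance, 1)
})

test_that("diversity indices follow their closed forms", {
  m <- matrix(c(10L, 0L, 0L,
                5L, 5L, 5L), 3, 2,
              dimnames = list(c("z1", "z2", "z3"), c("one", "even")))
  d <- diversity_indices(m)
  expect_equal(d$richness, c(1, 3))
  expect_equal(d$shannon, c(0, log(3)))
  set.seed(6)
  x <- matrix(as.integer(rmultinom(1, 1000, runif(8))), 8, 1,
              dimnames = list(letters[1:8], "s"))
  expect_equal(diversity_indices(x)$shannon, oracle_shannon(x[, 1]))
  skip_if_not_installed("vegan")
  expect_equal(diversity_indices(x)$shannon,
               unname(vegan::diversity(t(x), index = "shannon")))
})
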