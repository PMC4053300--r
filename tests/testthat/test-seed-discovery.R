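# CS50/CS95 percentiles, pooled tallies, binomial caller, Bonferroni.

test_that("percentiles interpolate between closest order statistics", {
  s <- speciesPercentiles(c(0.2, 0.4, 0.6, 0.8), "a")
  expect_equal(s$cs50, 0.5)
  expect_equal(speciesPercentiles(c(0.1, 0.5, 0.9), "b")$cs50, 0.5)
  cst <- speciesPercentiles(rep(0.3, 10), "c")
  expect_equal(cst$cs50, 0.3)
  expect_equal(cst$cs95, 0.3)
  expect_true(s$cs50 <= s$cs95)
  expect_equal(s$n_windows, 4L)
  expect_error(speciesPercentiles(numeric(0), "empty"), "excluded")
})

test_that("tallies classify against each species' own CS50 and pool counts", {
  wl <- list(
    s1 = mkWindows(rep("AAACCCG", 2), c(0.9, 0.9), "s1"),
    s2 = mkWindows("AAACCCG", 0.1, "s2"),
    s3 = mkWindows("AAACCCG", 0.5, "s3"))   # exactly at CS50: a tie
  sm <- rbind(mkSummaries("s1", 0.5, 0.9), mkSummaries("s2", 0.5, 0.9),
              mkSummaries("s3", 0.5, 0.9))
  t <- tallySeeds(wl, sm)
  expect_equal(nrow(t), 1L)
  expect_equal(t$site_7mer, "AAACCCG")
  expect_equal(t$seed_7mer, "CGGGTTT")
  expect_equal(t$count_high, 2L)
  expect_equal(t$count_low, 1L)
  expect_equal(t$ties_excluded, 1L)
  # unknown species rejected
  expect_error(tallySeeds(list(sX = wl$s1), sm), "without a percentile summary")
  # only observed 7-mers appear
  expect_equal(nrow(tallySeeds(list(s1 = wl$s1[0]), sm)), 0L)
})

test_that("per-species CS50 is what splits windows, not a global one", {
  wl <- list(
    s1 = mkWindows("AAACCCG", 0.4, "s1"),    # 0.4 > s1's cs50 of 0.2 -> high
    s2 = mkWindows("AAACCCG", 0.4, "s2"))    # 0.4 < s2's cs50 of 0.6 -> low
  sm <- rbind(mkSummaries("s1", 0.2, 0.9), mkSummaries("s2", 0.6, 0.9))
  t <- tallySeeds(wl, sm)
  expect_equal(t$count_high, 1L)
  expect_equal(t$count_low, 1L)
})

test_that("binomial caller is exact and matches closed forms", {
  expect_equal(binomialSeedTest(10L, 0L), 0.5^10)
  expect_equal(binomialSeedTest(5L, 5L), 638 / 1024)   # pmf sum k = 5..10
  expect_equal(binomialSeedTest(0L, 10L), 1.0)
  expect_true(is.na(binomialSeedTest(0L, 0L)))
  # genome-scale n: exact survival function, log-space for extreme tails
  expect_equal(binomialSeedTest(5.005e6, 4.995e6),
               stats::pbinom(5.005e6 - 1, 1e7, 0.5, lower.tail = FALSE))
  lp <- binomialSeedTest(5.1e6, 4.9e6, log = TRUE)
  expect_true(is.finite(lp) && lp < -1000)
})

test_that("binomial caller agrees with brute-force pmf summation (n <= 25)", {
  for (n in 1:25)
    for (h in 0:n)
      expect_equal(binomialSeedTest(h, n - h), bruteBinomTail(h, n - h),
                   tolerance = 1e-12)
})

test_that("binomial symmetry and monotonicity hold", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    h <- sample(0:n, 1)
    # swapping high and low: p -> 1 - p + P(X = h)
    expect_equal(binomialSeedTest(n - h, h),
                 1 - binomialSeedTest(h, n - h) + choose(n, h) / 2^n,
                 tolerance = 1e-12)
  }
  for (n in c(5L, 12L, 25L)) {
    p <- binomialSeedTest(0:n, n:0)
    expect_true(all(diff(p) <= 1e-15))       # non-increasing in count_high
  }
})

test_that("Bonferroni caps at 1 and requires excess high counts", {
  tally <- data.frame(seed_7mer = c("A", "B", "C", "D"),
                      site_7mer = c("A", "B", "C", "D"),
                      count_high = c(30L, 10L, 1L, 2L),
                      count_low = c(0L, 5L, 30L, 2L),
                      ties_excluded = 0L,
                      p_raw = c(1e-6, 0.001, 1 - 1e-12, 0))
  calls <- bonferroniCall(tally, mTests = "all_kmers")
  expect_equal(calls$p_bonferroni, c(0.016384, 1, 1, 0))
  expect_equal(calls$is_candidate, c(TRUE, FALSE, FALSE, FALSE))
  # "D" fails the direction rule even though p = 0 would pass alpha
  callsD <- bonferroniCall(tally[4, ], mTests = "observed")
  expect_false(callsD$is_candidate)          # high == low: not above background
  expect_error(bonferroniCall(tally, mTests = 0L), "positive integer")
  # observed mode multiplies by the number of tallied 7-mers
  calls2 <- bonferroniCall(tally, mTests = "observed")
  expect_equal(calls2$p_bonferroni[1], 4e-6)
})

test_that("tally counts partition all retained windows of each 7-mer", {
  cfg <- simConfig(seed = 21L, nSpecies = 2L, nGenes = 30L)
  sim <- simulateBundle(cfg)
  res <- runSeedDiscovery(sim$bundles)
  calls <- as.data.frame(seedCalls(res))
  total <- sum(calls$count_high + calls$count_low + calls$ties_excluded)
  expect_equal(total, sum(speciesSummaries(res)$n_windows))
  perSite <- table(unlist(lapply(scanWindows(res),
                                 function(w) mcols(w)$site_7mer)))
  expect_equal(calls$count_high + calls$count_low + calls$ties_excluded,
               as.integer(perSite[calls$site_7mer]))
})

test_that("degenerate input with all scores equal yields zero candidates", {
  b <- toyBundle(scores = rep(0.3, 400))
  res <- runSeedDiscovery(list(b))
  calls <- seedCalls(res)
  expect_true(all(calls$ties_excluded > 0))
  expect_true(all(is.na(calls$p_raw)))
  expect_length(candidateSeeds(res), 0L)
  expect_equal(speciesSummaries(res)$cs50, 0.3)
})

test_that("the scan is deterministic: identical inputs, identical tables", {
  cfg <- simConfig(seed = 31L, nSpecies = 2L, nGenes = 25L)
  sim <- simulateBundle(cfg)
  r1 <- runSeedDiscovery(sim$bundles)
  r2 <- runSeedDiscovery(sim$bundles)
  expect_identical(as.data.frame(seedCalls(r1)), as.data.frame(seedCalls(r2)))
  expect_identical(as.data.frame(speciesSummaries(r1)),
                   as.data.frame(speciesSummaries(r2)))
})

test_that("species without scored windows are excluded, all-empty errors", {
  good <- toyBundle()
  empty <- SpeciesBundle("noinfo", genomeSeq(good), geneRanges(good),
                         list(chr1 = rep(NA_real_, 400)))
  expect_warning(res <- runSeedDiscovery(list(good, empty)),
                 "retained no scored windows")
  expect_equal(speciesSummaries(res)$species_id, "toy")
  expect_error(suppressWarnings(runSeedDiscovery(list(empty))),
               "no species retained")
})
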