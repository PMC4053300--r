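suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
  library(Biostrings)
})

# Deterministic toy species built in code: one 400-nt chromosome, two genes
# (one per strand) placed so both 80-nt UTRs are fully inside the chromosome.
toyBundle <- function(scores = NULL, repeatMask = GRanges(),
                      codingMask = GRanges(), seed = 42L) {
  set.seed(seed)
  seqv <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  genome <- DNAStringSet(stats::setNames(paste(seqv, collapse = ""), "chr1"))
  genes <- GRanges("chr1", IRanges(c(101, 301), c(180, 380)),
                   strand = c("+", "-"), gene_id = c("gPlus", "gMinus"))
  if (is.null(scores)) scores <- round(stats::runif(400), 3)
  SpeciesBundle("toy", genome, genes, list(chr1 = scores),
                repeatMask, codingMask)
}

# Hand-built window GRanges for tally/target tests.
mkWindows <- function(sites, wcs, speciesId = "sp", geneId = "g1",
                      start = NULL, strand = "+", chrom = "chr1") {
  n <- length(sites)
  if (is.null(start)) start <- seq(1L, by = 10L, length.out = n)
  gr <- GRanges(chrom, IRanges(start, width = 7L),
                strand = rep(strand, length.out = n))
  mcols(gr) <- DataFrame(gene_id = rep(geneId, length.out = n),
                         species_id = speciesId,
                         site_7mer = sites, wcs = wcs)
  gr
}

mkSummaries <- function(speciesId, cs50, cs95, nWindows = 100L) {
  data.frame(species_id = speciesId, n_windows = nWindows,
             cs50 = cs50, cs95 = cs95, stringsAsFactors = FALSE)
}

mkResult <- function(windowsList, summaries, calls = NULL,
                     params = list(utrLength = 80L, k = 7L,
                                   seedOrientation = "revcomp",
                                   mTests = "all_kmers", alpha = 0.05)) {
  if (is.null(calls))
    calls <- bonferroniCall(tallySeeds(windowsList, summaries))
  new("SeedScanResult", calls = calls, summaries = DataFrame(summaries),
      windows = windowsList, params = params)
}

# Independent oracle: exact upper binomial tail at p = 1/2 by direct
# pmf summation, P(X >= h) = sum_{j=h..n} C(n, j) / 2^n.
bruteBinomTail <- function(h, l) {
  n <- h + l
  if (n == 0) return(NA_real_)
  sum(choose(n, seq.int(h, n))) / 2^n
}

# Independent oracle: exhaustive hypergeometric tail.  Elements 1..M form
# set one; enumerate every possible draw of n elements from 1..N and count
# draws sharing >= k elements with set one.
enumHyperTail <- function(N, M, n, k) {
  draws <- utils::combn(N, n)
  sum(colSums(draws <= M) >= k) / ncol(draws)
}

# All 4^k k-mers, C-locale sorted.
mkAllKmers <- function(k = 7L) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)
  sort(do.call(paste0, g), method = "radix")
}

randomSevenMers <- function(n, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = ""),
    character(1))
}
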