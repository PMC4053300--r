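# Reading the standard formats into a bundle, and writing the outputs.

writeToyFiles <- function(dir, conservationLines = NULL) {
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", "ACGTACGTACGTACGTACGT"), fa)              # 20 nt
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "sim", "gene", "1", "8", ".", "+", ".",
                     "ID=g1", sep = "\t")), gff)
  bg <- file.path(dir, "cons.bedGraph")
  if (is.null(conservationLines))
    conservationLines <- c("chr1\t0\t8\t0.5", "chr1\t10\t12\t0.25")
  writeLines(conservationLines, bg)
  list(fa = fa, gff = gff, bg = bg)
}

test_that("FASTA, GFF3 and bedGraph parse with correct coordinate conversion", {
  d <- withr::local_tempdir()
  p <- writeToyFiles(d)
  b <- readSpeciesBundle("sp1", p$fa, p$gff, p$bg)
  expect_s4_class(b, "SpeciesBundle")
  expect_equal(names(genomeSeq(b)), "chr1")
  expect_equal(unname(width(genomeSeq(b))), 20L)
  # GFF3 is 1-based closed: gene 1..8 spans 8 nt
  g <- geneRanges(b)
  expect_equal(start(g), 1L)
  expect_equal(end(g), 8L)
  expect_equal(width(g), 8L)
  expect_equal(g$gene_id, "g1")
  # bedGraph "chr1 0 8 0.5" covers the first 8 bases; the rest is missing
  cons <- conservationTrack(b)$chr1
  expect_equal(cons[1:8], rep(0.5, 8))
  expect_true(all(is.na(cons[9:10])))
  expect_equal(cons[11:12], rep(0.25, 2))
  expect_true(all(is.na(cons[13:20])))
})

test_that("lowercase FASTA is uppercased, not treated as repeat", {
  d <- withr::local_tempdir()
  p <- writeToyFiles(d)
  writeLines(c(">chr1", "acgtACGTacgtACGTacgt"), p$fa)
  b <- readSpeciesBundle("sp1", p$fa, p$gff, p$bg)
  expect_equal(as.character(genomeSeq(b)$chr1),
               "ACGTACGTACGTACGTACGT")
  expect_length(repeatMask(b), 0L)
})

test_that("invalid inputs are rejected with the offender identified", {
  d <- withr::local_tempdir()
  p <- writeToyFiles(d)
  # score outside [0, 1]
  bad <- file.path(d, "bad.bedGraph")
  writeLines("chr1\t0\t4\t1.5", bad)
  expect_error(readSpeciesBundle("sp1", p$fa, p$gff, bad), "outside \\[0, 1\\]")
  # unknown chromosome in annotation
  gff2 <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               paste("chrX", "sim", "gene", "1", "8", ".", "+", ".",
                     "ID=g1", sep = "\t")), gff2)
  expect_error(readSpeciesBundle("sp1", p$fa, gff2, p$bg),
               "unknown chromosome 'chrX'")
  # missing file
  expect_error(readSpeciesBundle("sp1", file.path(d, "nope.fa"), p$gff, p$bg),
               "does not exist")
})

test_that("seed table is sorted by corrected P with lexicographic ties", {
  calls <- S4Vectors::DataFrame(
    seed_7mer = c("TTTTTTT", "AAAAAAA", "CCCCCCC"),
    site_7mer = c("AAAAAAA", "TTTTTTT", "GGGGGGG"),
    count_high = c(5L, 9L, 2L), count_low = c(5L, 1L, 8L),
    ties_excluded = 0L,
    p_raw = c(0.01, 0.01, 0.5), p_bonferroni = c(0.2, 0.2, 1),
    is_candidate = c(FALSE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSeedTable(calls, path)
  got <- read.delim(path)
  expect_equal(names(got),
               c("seed_7mer", "site_7mer", "count_high", "count_low",
                 "p_raw", "p_bonferroni", "is_candidate"))
  # equal corrected P: AAAAAAA before TTTTTTT; CCCCCCC (p=1) last
  expect_equal(got$seed_7mer, c("AAAAAAA", "TTTTTTT", "CCCCCCC"))

  writeSeedTable(calls[0, ], path)
  expect_equal(readLines(path),
               "seed_7mer\tsite_7mer\tcount_high\tcount_low\tp_raw\tp_bonferroni\tis_candidate")
})

test_that("target sites export as BED6+2 with the 1000x WCS score rule", {
  sites <- GRanges("chr1", IRanges(c(501, 601), width = 7), strand = "+")
  mcols(sites) <- DataFrame(species_id = "sp", gene_id = c("g1", "g2"),
                            seed_7mer = c("AAAAAAA", "CCCCCCC"),
                            site_7mer = c("TTTTTTT", "GGGGGGG"),
                            wcs = c(1.0, 0.0))
  path <- withr::local_tempfile(fileext = ".bed")
  writeTargetSites(sites, path)
  got <- read.delim(path, header = FALSE)
  expect_equal(got$V2, c(500L, 600L))        # 0-based half-open on disk
  expect_equal(got$V3, c(507L, 607L))
  expect_equal(got$V5, c(1000L, 0L))
  expect_equal(got$V4, c("g1|AAAAAAA", "g2|CCCCCCC"))

  writeTargetSites(sites[0], path)
  expect_identical(readLines(path), character(0))
})

test_that("BED output round-trips to identical intervals", {
  sites <- GRanges("chr1", IRanges(c(11, 51, 101), width = 7),
                   strand = c("+", "-", "+"))
  mcols(sites) <- DataFrame(species_id = "sp",
                            gene_id = c("g1", "g2", "g3"),
                            seed_7mer = "AAAAAAA", site_7mer = "TTTTTTT",
                            wcs = c(0.25, 0.5, 0.75))
  path <- withr::local_tempfile(fileext = ".bed")
  writeTargetSites(sites, path)
  back <- rtracklayer::import(path, format = "bed",
    extraCols = c(site_7mer = "character", wcs = "numeric"))
  expect_equal(start(back), start(sites))
  expect_equal(end(back), end(sites))
  expect_equal(as.character(strand(back)), as.character(strand(sites)))
  expect_equal(back$wcs, sites$wcs)
})

test_that("simulated on-disk bundles read back equal to the in-memory truth", {
  d <- withr::local_tempdir()
  cfg <- simConfig(seed = 5L, nSpecies = 1L, nGenes = 10L)
  sim <- simulateBundle(cfg, outDir = d)
  sp <- names(sim$bundles)[1]
  b2 <- readSpeciesBundle(sp,
                          file.path(d, paste0(sp, "_genome.fa")),
                          file.path(d, paste0(sp, "_genes.gff3")),
                          file.path(d, paste0(sp, "_conservation.bedGraph")),
                          file.path(d, paste0(sp, "_repeats.bed")),
                          file.path(d, paste0(sp, "_cds.bed")))
  b1 <- sim$bundles[[sp]]
  expect_equal(as.character(genomeSeq(b2)), as.character(genomeSeq(b1)))
  expect_equal(start(geneRanges(b2)), start(geneRanges(b1)))
  expect_equal(end(geneRanges(b2)), end(geneRanges(b1)))
  expect_equal(geneRanges(b2)$gene_id, geneRanges(b1)$gene_id)
  c1 <- conservationTrack(b1)$chr1
  c2 <- conservationTrack(b2)$chr1
  expect_equal(is.na(c1), is.na(c2))
  expect_equal(c1[!is.na(c1)], c2[!is.na(c2)], tolerance = 1e-6)
  expect_equal(ranges(repeatMask(b2)), ranges(repeatMask(b1)))
  expect_equal(ranges(codingMask(b2)), ranges(codingMask(b1)))
})
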