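#' Configuration for the multi-species conservation simulator
#'
#' Bundles, validates and defaults every knob of
#' \code{\link{simulateBundle}}. The defaults are the study conditions the
#' package's recovery experiments run under: 10 species of 200 genes each,
#' 80-nt 3'UTRs, 5 true seeds planted into 20\% of UTRs per seed,
#' Beta-distributed per-base background scores with mean 0.30 and planted
#' scores with mean 0.95 (both with concentration 10, i.e.
#' \code{Beta(mean * 10, (1 - mean) * 10)}).
#'
#' Genes are laid out non-overlapping on one chromosome per species, each in
#' a slot of width \code{utrLength + geneLength + utrLength + interGeneGap},
#' so a gene's 80-nt UTR never reaches a neighbouring gene body regardless
#' of strand. \code{chromLength} is derived from that layout when not given.
#'
#' \code{isolateFlank} controls the simulator's site-isolation buffer: the
#' conservation track is left uncovered (missing) for that many nt on each
#' side of every planted site, so that the planted window is the only scored
#' window touching the site and ground truth is unambiguous at window
#' resolution (see the methods vignette; 0 disables the buffer).
#' \code{plantInRepeats = TRUE} is a diagnostic scenario that covers each
#' planted site with a repeat interval instead of avoiding repeats, to
#' verify that repeat exclusion blocks recovery.
#'
#' @param seed RNG seed (integer).
#' @param nSpecies,nGenes,geneLength,utrLength,interGeneGap layout, in nt.
#' @param chromLength chromosome length; default derived from the layout.
#' @param trueSeeds character vector of true 7-mer seeds to plant.
#' @param plantProb probability a UTR receives a planted site, per seed.
#' @param backgroundMean,backgroundConc,plantedMean,plantedConc Beta
#'   parameters (mean in (0,1), concentration > 0) of the background and
#'   planted per-base score distributions.
#' @param repeatFrac fraction of each genome covered by repeat intervals.
#' @param repeatLength length of each repeat interval, nt.
#' @param isolateFlank site-isolation buffer width, nt (default 6).
#' @param plantInRepeats plant sites inside repeats (diagnostic; default
#'   \code{FALSE}).
#' @param seedOrientation \code{"revcomp"} (default): the planted UTR site
#'   is the reverse complement of the seed; \code{"identity"}: the seed
#'   itself.
#' @return a validated \code{SimConfig} (classed list).
#' @export
simConfig <- function(seed = 1L, nSpecies = 10L, nGenes = 200L,
                      geneLength = 120L, utrLength = 80L, interGeneGap = 20L,
                      chromLength = NULL,
                      trueSeeds = c("ACGTCTA", "CCATGAG", "GATCGTA",
                                    "TGCAACT", "AGGCTTC"),
                      plantProb = 0.2,
                      backgroundMean = 0.3, backgroundConc = 10,
                      plantedMean = 0.95, plantedConc = 10,
                      repeatFrac = 0.05, repeatLength = 50L,
                      isolateFlank = 6L, plantInRepeats = FALSE,
                      seedOrientation = c("revcomp", "identity")) {
  seedOrientation <- match.arg(seedOrientation)
  k <- 7L
  slot <- utrLength + geneLength + utrLength + interGeneGap
  if (is.null(chromLength)) chromLength <- nGenes * slot + utrLength
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              nGenes = as.integer(nGenes), geneLength = as.integer(geneLength),
              utrLength = as.integer(utrLength),
              interGeneGap = as.integer(interGeneGap),
              chromLength = as.integer(chromLength), slot = as.integer(slot),
              trueSeeds = toupper(trueSeeds), plantProb = plantProb,
              backgroundMean = backgroundMean, backgroundConc = backgroundConc,
              plantedMean = plantedMean, plantedConc = plantedConc,
              repeatFrac = repeatFrac, repeatLength = as.integer(repeatLength),
              isolateFlank = as.integer(isolateFlank),
              plantInRepeats = isTRUE(plantInRepeats),
              seedOrientation = seedOrientation, k = k)
  if (any(nchar(cfg$trueSeeds) != k) || any(grepl("[^ACGT]", cfg$trueSeeds)))
    stop("trueSeeds must be 7-mers over {A,C,G,T}")
  if (anyDuplicated(cfg$trueSeeds)) stop("trueSeeds must be distinct")
  if (cfg$plantProb < 0 || cfg$plantProb > 1) stop("plantProb must be in [0, 1]")
  for (m in c(cfg$backgroundMean, cfg$plantedMean))
    if (m <= 0 || m >= 1) stop("score-distribution means must lie in (0, 1)")
  if (cfg$nGenes * cfg$slot + cfg$utrLength > cfg$chromLength)
    stop("infeasible packing: ", cfg$nGenes, " genes of slot width ",
         cfg$slot, " do not fit in chromLength ", cfg$chromLength)
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$nSpecies, "species x", x$nGenes, "genes,",
      "chromLength", x$chromLength, "\n")
  cat("  true seeds:", paste(x$trueSeeds, collapse = " "),
      sprintf("(plantProb %.2f, orientation %s)\n", x$plantProb,
              x$seedOrientation))
  cat(sprintf("  scores: background Beta(mean %.2f, conc %g), planted Beta(mean %.2f, conc %g)\n",
              x$backgroundMean, x$backgroundConc, x$plantedMean, x$plantedConc))
  cat(sprintf("  repeats: %.1f%% of genome in %d-nt intervals; isolateFlank %d nt\n",
              100 * x$repeatFrac, x$repeatLength, x$isolateFlank))
  invisible(x)
}

.rbetaMean <- function(n, mean, conc) stats::rbeta(n, mean * conc, (1 - mean) * conc)

#' Simulate a multi-species genome bundle with planted conserved seed sites
#'
#' Generates, for every species, an i.i.d. uniform-composition genome,
#' non-overlapping genes on random strands, a per-base background
#' conservation track, and then — for each (UTR, true seed) pair with
#' probability \code{plantProb} — writes the seed's target site (its reverse
#' complement under the default orientation) into the UTR sense strand at a
#' uniformly chosen offset and redraws the site's 7 per-base scores from the
#' planted distribution. Sites within one UTR are kept at least
#' \code{7 + isolateFlank} nt apart (a plant that cannot be placed after 25
#' tries is skipped and does not enter the ground truth). Repeat intervals
#' cover \code{repeatFrac} of the genome and avoid planted sites unless
#' \code{plantInRepeats}. Coding intervals are the gene bodies. Everything
#' is reproducible from \code{config$seed}.
#'
#' With \code{outDir} set, each species' bundle is also written in the
#' standard text formats \code{\link{readSpeciesBundle}} reads
#' (\code{<sp>_genome.fa}, \code{<sp>_genes.gff3},
#' \code{<sp>_conservation.bedGraph}, \code{<sp>_repeats.bed},
#' \code{<sp>_cds.bed}) plus a \code{ground_truth.tsv}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outDir optional directory for the on-disk bundle.
#' @return list with \code{$bundles} (named list of
#'   \code{\linkS4class{SpeciesBundle}}), \code{$truth} (data frame of
#'   planted sites: \code{species_id}, \code{gene_id}, \code{seed_7mer},
#'   \code{site_7mer}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{utr_offset}), and \code{$config}.
#' @export
simulateBundle <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  cfg <- config
  bundles <- list()
  truth <- list()
  siteSeqs <- if (cfg$seedOrientation == "revcomp")
    as.character(reverseComplement(DNAStringSet(cfg$trueSeeds)))
  else cfg$trueSeeds

  for (si in seq_len(cfg$nSpecies)) {
    sp <- sprintf("sp%02d", si)
    L <- cfg$chromLength
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    scores <- .rbetaMean(L, cfg$backgroundMean, cfg$backgroundConc)

    slotStart <- (seq_len(cfg$nGenes) - 1L) * cfg$slot + 1L
    gStart <- slotStart + cfg$utrLength
    gEnd <- gStart + cfg$geneLength - 1L
    std <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
    geneIds <- sprintf("%s_g%04d", sp, seq_len(cfg$nGenes))
    genes <- GRanges("chr1", IRanges(gStart, gEnd), strand = std,
                     gene_id = geneIds,
                     seqinfo = Seqinfo("chr1", L))

    # 3'UTR genomic span per gene under the layout (never clipped)
    utrS <- ifelse(std == "+", gEnd + 1L, gStart - cfg$utrLength)
    utrE <- utrS + cfg$utrLength - 1L

    planted <- matrix(integer(0), ncol = 2)   # genomic start, seed index
    spTruth <- list()
    maxOff <- cfg$utrLength - cfg$k           # 0-based offsets 0..73
    minSep <- cfg$k + cfg$isolateFlank
    for (gi in seq_len(cfg$nGenes)) {
      doPlant <- which(stats::runif(length(cfg$trueSeeds)) < cfg$plantProb)
      if (!length(doPlant)) next
      usedStarts <- integer(0)
      for (ti in doPlant) {
        placed <- FALSE
        for (try in seq_len(25L)) {
          off <- sample.int(maxOff + 1L, 1L) - 1L
          gs <- if (std[gi] == "+") utrS[gi] + off
                else utrE[gi] - off - (cfg$k - 1L)
          if (!length(usedStarts) || all(abs(gs - usedStarts) >= minSep)) {
            placed <- TRUE; break
          }
        }
        if (!placed) next
        usedStarts <- c(usedStarts, gs)
        site <- siteSeqs[ti]
        genomic <- if (std[gi] == "+") site
                   else as.character(reverseComplement(DNAStringSet(site)))
        seqv[gs:(gs + cfg$k - 1L)] <- strsplit(genomic, "")[[1L]]
        scores[gs:(gs + cfg$k - 1L)] <-
          .rbetaMean(cfg$k, cfg$plantedMean, cfg$plantedConc)
        planted <- rbind(planted, c(gs, ti))
        spTruth[[length(spTruth) + 1L]] <-
          data.frame(species_id = sp, gene_id = geneIds[gi],
                     seed_7mer = cfg$trueSeeds[ti], site_7mer = site,
                     chrom = "chr1", start = gs, end = gs + cfg$k - 1L,
                     strand = std[gi], utr_offset = off,
                     stringsAsFactors = FALSE)
      }
    }

    # isolation buffer: leave the track uncovered beside every planted site
    if (nrow(planted) && cfg$isolateFlank > 0L) {
      sitePos <- unlist(lapply(planted[, 1L],
                               function(s) s:(s + cfg$k - 1L)))
      flankPos <- unlist(lapply(planted[, 1L], function(s)
        c(seq(s - cfg$isolateFlank, s - 1L),
          seq(s + cfg$k, s + cfg$k + cfg$isolateFlank - 1L))))
      flankPos <- setdiff(flankPos[flankPos >= 1L & flankPos <= L], sitePos)
      scores[flankPos] <- NA_real_
    }

    nRep <- floor(cfg$repeatFrac * L / cfg$repeatLength)
    if (cfg$plantInRepeats && nrow(planted)) {
      repGR <- GRanges("chr1", IRanges(planted[, 1L], width = cfg$k),
                       seqinfo = Seqinfo("chr1", L))
    } else if (nRep > 0L) {
      avoid <- if (nrow(planted))
        IRanges(planted[, 1L] - cfg$isolateFlank,
                planted[, 1L] + cfg$k - 1L + cfg$isolateFlank)
      else IRanges()
      starts <- integer(0); tries <- 0L
      while (length(starts) < nRep && tries < 50L * nRep) {
        tries <- tries + 1L
        cand <- sample.int(L - cfg$repeatLength + 1L, 1L)
        ir <- IRanges(cand, width = cfg$repeatLength)
        if ((!length(avoid) ||
             !length(IRanges::findOverlaps(ir, avoid))) &&
            (!length(starts) ||
             !length(IRanges::findOverlaps(
               ir, IRanges(starts, width = cfg$repeatLength)))))
          starts <- c(starts, cand)
      }
      repGR <- GRanges("chr1", IRanges(sort(starts), width = cfg$repeatLength),
                       seqinfo = Seqinfo("chr1", L))
    } else {
      repGR <- GRanges(seqinfo = Seqinfo("chr1", L))
    }

    cdsGR <- genes
    mcols(cdsGR) <- DataFrame(gene_id = geneIds)
    genome <- DNAStringSet(stats::setNames(paste(seqv, collapse = ""), "chr1"))
    bundles[[sp]] <- SpeciesBundle(sp, genome, genes,
                                   list(chr1 = scores), repGR, cdsGR)
    if (length(spTruth)) truth[[sp]] <- do.call(rbind, spTruth)
  }

  truthDf <- if (length(truth)) do.call(rbind, unname(truth)) else
    data.frame(species_id = character(), gene_id = character(),
               seed_7mer = character(), site_7mer = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), utr_offset = integer(),
               stringsAsFactors = FALSE)
  rownames(truthDf) <- NULL
  out <- list(bundles = bundles, truth = truthDf, config = cfg)
  if (!is.null(outDir)) writeSimulatedBundle(out, outDir)
  out
}

#' Write a simulated bundle to disk in standard text formats
#'
#' @param sim result of \code{\link{simulateBundle}}.
#' @param outDir output directory (created if needed).
#' @return named list of per-species file paths, invisibly.
#' @export
writeSimulatedBundle <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in names(sim$bundles)) {
    b <- sim$bundles[[sp]]
    p <- list(fasta = file.path(outDir, paste0(sp, "_genome.fa")),
              genes = file.path(outDir, paste0(sp, "_genes.gff3")),
              cons = file.path(outDir, paste0(sp, "_conservation.bedGraph")),
              repeats = file.path(outDir, paste0(sp, "_repeats.bed")),
              cds = file.path(outDir, paste0(sp, "_cds.bed")))
    writeXStringSet(genomeSeq(b), p$fasta)
    g <- geneRanges(b)
    mcols(g) <- DataFrame(type = "gene", ID = g$gene_id, Name = g$gene_id)
    rtracklayer::export(g, p$genes, format = "gff3")
    cons <- conservationTrack(b)[["chr1"]]
    runs <- S4Vectors::Rle(cons)
    rs <- cumsum(c(0L, S4Vectors::runLength(runs)))
    val <- S4Vectors::runValue(runs)
    keep <- !is.na(val)                       # uncovered positions stay absent
    covGR <- GRanges("chr1",
                     IRanges(rs[which(keep)] + 1L,
                             width = S4Vectors::runLength(runs)[keep]),
                     score = val[keep],
                     seqinfo = seqinfo(geneRanges(b)))
    rtracklayer::export(covGR, p$cons, format = "bedGraph")
    rtracklayer::export(repeatMask(b), p$repeats, format = "bed")
    cds <- codingMask(b)
    mcols(cds) <- DataFrame(name = cds$gene_id)
    rtracklayer::export(cds, p$cds, format = "bed")
    paths[[sp]] <- p
  }
  utils::write.table(sim$truth, file.path(outDir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Score seed-discovery calls against simulation ground truth
#'
#' @param result a \code{\linkS4class{SeedScanResult}} (or a character
#'   vector of called seeds).
#' @param truth ground-truth data frame (or \code{SimConfig}, or a
#'   character vector of true seeds).
#' @return list: \code{sensitivity} (fraction of true seeds called),
#'   \code{nFalsePositives}, \code{falsePositives}, \code{missed}.
#' @export
evaluateRecovery <- function(result, truth) {
  called <- if (is(result, "SeedScanResult")) candidateSeeds(result)
            else as.character(result)
  trueSeeds <- if (inherits(truth, "SimConfig")) truth$trueSeeds
               else if (is.data.frame(truth)) unique(truth$seed_7mer)
               else as.character(truth)
  trueSeeds <- unique(trueSeeds)
  if (length(trueSeeds) == 0L)
    return(list(sensitivity = NA_real_,
                nFalsePositives = length(called),
                falsePositives = called, missed = character(0)))
  list(sensitivity = length(intersect(called, trueSeeds)) / length(trueSeeds),
       nFalsePositives = length(setdiff(called, trueSeeds)),
       falsePositives = sort(setdiff(called, trueSeeds), method = "radix"),
       missed = sort(setdiff(trueSeeds, called), method = "radix"))
}
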