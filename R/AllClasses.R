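#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#'   countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet reverseComplement alphabetFrequency
#'   readDNAStringSet writeXStringSet extractAt
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
NULL

#' SpeciesBundle: one species' genome, annotation and conservation track
#'
#' Container for everything the seed scan needs from one species: the genome
#' sequence, gene annotation, a per-base conservation track on \code{[0, 1]}
#' (with \code{NA} marking positions without conservation information), and
#' optional repeat and coding-region interval masks.
#'
#' All intervals are held as \code{GRanges} (1-based, closed); BED and wiggle
#' inputs are converted at the file boundary by \code{\link{readSpeciesBundle}}.
#' Missing conservation values stay \code{NA}: absence of information is not
#' a score of zero, and windows touching an \code{NA} position are never
#' scored.
#'
#' @slot speciesId single character label.
#' @slot genome named \code{DNAStringSet}, alphabet restricted to
#'   \code{A,C,G,T,N} (soft-masked lowercase is folded to uppercase on read).
#' @slot genes \code{GRanges} with a \code{gene_id} metadata column; strands
#'   \code{+}/\code{-} only; unique ids.
#' @slot conservation named list, one numeric vector per chromosome, length
#'   equal to the chromosome length, values in \code{[0, 1]} or \code{NA}.
#' @slot repeatMask \code{GRanges} of repeat intervals (may be empty).
#' @slot codingMask \code{GRanges} of coding (CDS) intervals (may be empty).
#'
#' @seealso \code{\link{readSpeciesBundle}}, \code{\link{simulateBundle}}
#' @export
setClass("SpeciesBundle",
  representation(
    speciesId    = "character",
    genome       = "DNAStringSet",
    genes        = "GRanges",
    conservation = "list",
    repeatMask   = "GRanges",
    codingMask   = "GRanges"
  )
)

setValidity("SpeciesBundle", function(object) {
  msg <- character()
  if (length(object@speciesId) != 1L || is.na(object@speciesId) ||
      !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty string")
  chroms <- names(object@genome)
  if (is.null(chroms) || anyDuplicated(chroms))
    msg <- c(msg, "genome chromosomes must be uniquely named")
  if (length(object@genome) && any(width(object@genome) < 1L))
    msg <- c(msg, "chromosome lengths must be >= 1")
  if (length(object@genome)) {
    af <- alphabetFrequency(object@genome)
    bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
    if (any(bad > 0))
      msg <- c(msg, sprintf("genome sequence of %s contains letters outside {A,C,G,T,N}",
                            paste(chroms[bad > 0], collapse = ", ")))
  }
  g <- object@genes
  if (length(g)) {
    if (is.null(g$gene_id) || anyDuplicated(g$gene_id) || anyNA(g$gene_id))
      msg <- c(msg, "genes must carry unique non-NA gene_id metadata")
    if (!all(as.character(seqnames(g)) %in% chroms))
      msg <- c(msg, sprintf("gene(s) %s reference unknown chromosome(s)",
        paste(utils::head(g$gene_id[!as.character(seqnames(g)) %in% chroms], 3L),
              collapse = ", ")))
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    cl <- stats::setNames(width(object@genome), chroms)
    onKnown <- as.character(seqnames(g)) %in% chroms
    if (any(onKnown) &&
        (any(start(g)[onKnown] < 1L) ||
         any(end(g)[onKnown] > cl[as.character(seqnames(g))[onKnown]])))
      msg <- c(msg, "gene coordinates fall outside chromosome bounds")
  }
  cons <- object@conservation
  if (!all(names(cons) %in% chroms))
    msg <- c(msg, "conservation track references unknown chromosome(s)")
  for (nm in intersect(names(cons), chroms)) {
    v <- cons[[nm]]
    if (!is.numeric(v) || length(v) != width(object@genome)[match(nm, chroms)])
      msg <- c(msg, sprintf("conservation vector for %s must match chromosome length", nm))
    else if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, sprintf("conservation scores for %s outside [0, 1]", nm))
  }
  for (mask in list(object@repeatMask, object@codingMask)) {
    if (length(mask) && !all(as.character(seqnames(mask)) %in% chroms))
      msg <- c(msg, "mask interval references unknown chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesBundle
#'
#' @param speciesId single character species label.
#' @param genome named \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences; lowercase is folded to uppercase.
#' @param genes \code{GRanges} with a \code{gene_id} column.
#' @param conservation named list of per-base numeric score vectors on
#'   \code{[0, 1]}; \code{NA} marks positions without conservation
#'   information.
#' @param repeatMask,codingMask optional \code{GRanges} masks.
#' @return a validated \code{SpeciesBundle}.
#' @examples
#' gn <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT"))
#' genes <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(1, 4), strand = "+", gene_id = "g1")
#' SpeciesBundle("sp1", gn, genes, list(chr1 = rep(0.5, 12)))
#' @export
SpeciesBundle <- function(speciesId, genome, genes,
                          conservation = list(),
                          repeatMask = GRanges(), codingMask = GRanges()) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  genome <- DNAStringSet(toupper(as.character(genome)))
  new("SpeciesBundle", speciesId = as.character(speciesId), genome = genome,
      genes = genes, conservation = conservation,
      repeatMask = repeatMask, codingMask = codingMask)
}

setMethod("show", "SpeciesBundle", function(object) {
  cat("SpeciesBundle:", object@speciesId, "\n")
  cat("  chromosomes:", length(object@genome),
      sprintf("(%s bp)", format(sum(width(object@genome)), big.mark = ",")), "\n")
  cat("  genes:      ", length(object@genes), "\n")
  covered <- sum(vapply(object@conservation, function(v) sum(!is.na(v)), 0))
  cat("  conservation:", format(covered, big.mark = ","), "positions scored\n")
  cat("  repeat mask: ", length(object@repeatMask), "intervals;",
      "coding mask:", length(object@codingMask), "intervals\n")
})

#' SeedScanResult: output of the genome-wide seed scan
#'
#' Holds the per-7-mer candidate-seed calls, the per-species CS50/CS95
#' percentile summaries, the retained windows (needed downstream for
#' CS95-gated target-site extraction), and the scan parameters.
#'
#' @slot calls \code{DataFrame}: one row per observed 7-mer with columns
#'   \code{seed_7mer}, \code{site_7mer}, \code{count_high}, \code{count_low},
#'   \code{ties_excluded}, \code{p_raw}, \code{p_bonferroni},
#'   \code{is_candidate}.
#' @slot summaries \code{DataFrame}: \code{species_id}, \code{n_windows},
#'   \code{cs50}, \code{cs95}.
#' @slot windows named list of per-species window \code{GRanges}.
#' @slot params list of scan parameters (UTR length, k, seed orientation,
#'   Bonferroni multiplier mode, alpha).
#' @export
setClass("SeedScanResult",
  representation(
    calls     = "DataFrame",
    summaries = "DataFrame",
    windows   = "list",
    params    = "list"
  )
)

setMethod("show", "SeedScanResult", function(object) {
  cat("SeedScanResult\n")
  cat("  species:         ", nrow(object@summaries), "\n")
  cat("  windows retained:",
      format(sum(object@summaries$n_windows), big.mark = ","), "\n")
  cat("  7-mers observed: ", nrow(object@calls), "\n")
  cat("  candidate seeds: ", sum(object@calls$is_candidate), "\n")
  p <- object@params
  cat(sprintf("  params: utrLength=%d k=%d orientation=%s mTests=%s alpha=%g\n",
              p$utrLength, p$k, p$seedOrientation, as.character(p$mTests),
              p$alpha))
})

#' OverlapTest: hypergeometric seed-set overlap test
#'
#' Result of testing whether the overlap \code{k} between two seed sets of
#' sizes \code{M} and \code{n}, drawn from a universe of \code{N} possible
#' k-mers, is larger than expected by chance. \code{pPoint} is the exact
#' point probability of observing exactly \code{k} shared seeds;
#' \code{pValue} is the inclusive upper tail \eqn{P(X \ge k)}.
#'
#' @slot N,M,n,k integer hypergeometric parameters.
#' @slot pPoint,pValue numeric probabilities.
#' @seealso \code{\link{overlapTest}}, \code{\link{hypergeomTest}}
#' @export
setClass("OverlapTest",
  representation(N = "integer", M = "integer", n = "integer", k = "integer",
                 pPoint = "numeric", pValue = "numeric")
)

setValidity("OverlapTest", function(object) {
  msg <- character()
  if (object@M > object@N || object@n > object@N)
    msg <- c(msg, "set sizes M and n must not exceed universe size N")
  if (object@k < 0L || object@k > min(object@M, object@n))
    msg <- c(msg, "overlap k must satisfy 0 <= k <= min(M, n)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapTest", function(object) {
  cat("Hypergeometric seed-set overlap test\n")
  cat(sprintf("  universe N = %d, set sizes M = %d and n = %d, overlap k = %d\n",
              object@N, object@M, object@n, object@k))
  cat(sprintf("  P(X = k) = %.6g\n", object@pPoint))
  cat(sprintf("  P(X >= k) = %.6g\n", object@pValue))
})
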