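#' Define fixed-length 3'UTR regions downstream of genes
#'
#' Archaeal and bacterial gene annotations carry no UTR coordinates, so the
#' 3'UTR is defined operationally as the \code{utrLength} nucleotides
#' immediately 3' of each gene's annotated end: genomic-right of the gene on
#' the \code{+} strand, genomic-left on the \code{-} strand. Regions are
#' clipped at chromosome ends; a gene abutting a chromosome edge yields a
#' zero-length region that is flagged (\code{utr_flagged}) and skipped by
#' \code{\link{enumerateWindows}}.
#'
#' @param genes \code{GRanges} with a \code{gene_id} column, strands
#'   \code{+}/\code{-}.
#' @param genome named \code{DNAStringSet} with the chromosomes the genes
#'   live on.
#' @param utrLength UTR length in nucleotides (default 80).
#' @return \code{GRanges} of UTR regions, one per gene, with metadata columns
#'   \code{gene_id}, \code{utr_seq} (the 5'-to-3' sense-strand sequence,
#'   reverse-complemented for \code{-} genes) and \code{utr_flagged}.
#' @examples
#' gn <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 250), collapse = "")))
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500),
#'   strand = "+", gene_id = "g1")
#' defineUTR(genes, gn)   # UTR spans 501..580
#' @export
defineUTR <- function(genes, genome, utrLength = 80L) {
  stopifnot(is(genes, "GRanges"), is(genome, "DNAStringSet"),
            utrLength >= 1L)
  if (length(genes) == 0L)
    return(GRanges(gene_id = character(), utr_seq = character(),
                   utr_flagged = logical()))
  if (is.null(genes$gene_id)) stop("genes must carry a 'gene_id' column")
  chrom <- as.character(seqnames(genes))
  if (!all(chrom %in% names(genome)))
    stop("gene(s) on chromosome(s) absent from the genome: ",
         paste(unique(chrom[!chrom %in% names(genome)]), collapse = ", "))
  clen <- stats::setNames(width(genome), names(genome))[chrom]
  std <- as.character(strand(genes))
  if (!all(std %in% c("+", "-"))) stop("gene strand must be '+' or '-'")

  plus <- std == "+"
  us <- ue <- integer(length(genes))
  us[plus] <- end(genes)[plus] + 1L
  ue[plus] <- pmin(end(genes)[plus] + utrLength, clen[plus])
  ue[!plus] <- start(genes)[!plus] - 1L
  us[!plus] <- pmax(start(genes)[!plus] - utrLength, 1L)
  w <- ue - us + 1L                       # may be 0 at chromosome edges
  flagged <- w <= 0L
  us[flagged] <- 1L; ue[flagged] <- 0L    # canonical empty range
  utr <- GRanges(chrom, IRanges(us, ue), strand = std)

  seqs <- character(length(utr))
  for (nm in unique(chrom)) {
    sel <- which(chrom == nm & !flagged)
    if (length(sel))
      seqs[sel] <- as.character(extractAt(genome[[nm]],
                                          IRanges(us[sel], ue[sel])))
  }
  rc <- !plus & !flagged
  if (any(rc))
    seqs[rc] <- as.character(reverseComplement(DNAStringSet(seqs[rc])))
  mcols(utr)$gene_id <- genes$gene_id
  mcols(utr)$utr_seq <- seqs
  mcols(utr)$utr_flagged <- flagged
  if (any(flagged))
    message(sum(flagged), " gene(s) with empty 3'UTR at a chromosome edge, ",
            "excluded downstream")
  utr
}

#' Enumerate strand-aware sliding windows over 3'UTRs and score them
#'
#' Slides a k-nt window (default 7) at 1-nt steps from the 5' end of every
#' UTR along its sense strand and computes each window's Window Conservation
#' Score (WCS): the arithmetic mean of the 7 genomic per-base conservation
#' scores, which is strand-invariant. A full 80-nt UTR yields 74 windows.
#'
#' Windows are dropped, never partially scored, when (i) the window sequence
#' contains \code{N}, (ii) any of the k positions lacks a conservation score,
#' or (iii) the window overlaps a repeat interval by at least
#' \code{repeatOverlapMinBases} bases. Drop counts are kept in
#' \code{metadata()} of the returned ranges.
#'
#' @param utrs UTR \code{GRanges} from \code{\link{defineUTR}}.
#' @param conservation named list of per-base score vectors (one per
#'   chromosome, \code{NA} = missing).
#' @param repeatMask optional \code{GRanges} of repeat intervals.
#' @param k window width (default 7).
#' @param speciesId species label stamped on every window.
#' @param repeatOverlapMinBases minimum repeat overlap, in bases, that
#'   disqualifies a window (default 1, the strictest reading).
#' @return \code{GRanges} of retained windows, enumerated 5' to 3' within
#'   each UTR, with columns \code{gene_id}, \code{species_id},
#'   \code{site_7mer} (sense strand) and \code{wcs}.
#' @export
enumerateWindows <- function(utrs, conservation, repeatMask = NULL,
                             k = 7L, speciesId = "species",
                             repeatOverlapMinBases = 1L) {
  stopifnot(is(utrs, "GRanges"), k >= 1L)
  drops <- c(n_base = 0L, missing_score = 0L, repeat_overlap = 0L)
  flg <- mcols(utrs)$utr_flagged
  if (is.null(flg)) flg <- rep(FALSE, length(utrs))
  keep <- !flg & width(utrs) >= k
  utrs <- utrs[keep]
  empty <- GRanges(seqinfo = seqinfo(utrs))
  mcols(empty) <- DataFrame(gene_id = character(), species_id = character(),
                            site_7mer = character(), wcs = numeric())
  if (length(utrs) == 0L) { metadata(empty)$dropped <- drops; return(empty) }

  nw  <- width(utrs) - k + 1L
  idx <- rep(seq_along(utrs), nw)
  off <- sequence(nw) - 1L                       # 0-based offset from UTR 5' end
  chrom <- as.character(seqnames(utrs))[idx]
  plus  <- as.character(strand(utrs))[idx] == "+"
  ws <- integer(length(idx))
  ws[plus]  <- start(utrs)[idx][plus] + off[plus]
  ws[!plus] <- end(utrs)[idx][!plus] - off[!plus] - (k - 1L)
  win <- GRanges(chrom, IRanges(ws, width = k),
                 strand = strand(utrs)[idx])
  site <- substring(mcols(utrs)$utr_seq[idx], off + 1L, off + k)

  # direct k-term summation: windows with identical score patterns get
  # bit-identical WCS, so exact ties at CS50 are detected reliably
  wcs <- numeric(length(win))
  nNA <- integer(length(win))
  for (nm in unique(chrom)) {
    v <- conservation[[nm]]
    sel <- which(chrom == nm)
    if (is.null(v)) stop("conservation track does not cover chromosome ", nm)
    a <- ws[sel]
    acc <- numeric(length(a)); miss <- integer(length(a))
    for (i in 0:(k - 1L)) {
      vi <- v[a + i]
      na <- is.na(vi)
      miss <- miss + na
      acc <- acc + ifelse(na, 0, vi)
    }
    wcs[sel] <- acc / k
    nNA[sel] <- miss
  }

  hasN <- grepl("N", site, fixed = TRUE)
  noScore <- nNA > 0L
  inRepeat <- if (!is.null(repeatMask) && length(repeatMask))
    countOverlaps(win, repeatMask, minoverlap = repeatOverlapMinBases) > 0L
  else rep(FALSE, length(win))
  drops["n_base"] <- sum(hasN)
  drops["missing_score"] <- sum(!hasN & noScore)
  drops["repeat_overlap"] <- sum(!hasN & !noScore & inRepeat)
  ok <- !hasN & !noScore & !inRepeat

  win <- win[ok]
  mcols(win) <- DataFrame(gene_id = mcols(utrs)$gene_id[idx][ok],
                          species_id = rep(speciesId, sum(ok)),
                          site_7mer = site[ok],
                          wcs = wcs[ok])
  metadata(win)$dropped <- drops
  win
}

#' Map a target-site 7-mer to its implied miRNA seed
#'
#' A miRNA seed (nucleotides 2-8 of the mature miRNA) pairs with its UTR
#' target site by Watson-Crick complementarity, so the seed implied by a
#' detected site is the site's reverse complement (the default). The
#' \code{"identity"} orientation reports the site 7-mer itself, for
#' comparisons against seed lists whose orientation convention is unknown.
#'
#' @param site character vector of k-mers over \code{A,C,G,T}.
#' @param orientation \code{"revcomp"} (default) or \code{"identity"}.
#' @return character vector of implied seeds.
#' @examples
#' windowSeed("AAAAAAA")              # "TTTTTTT"
#' windowSeed("ACGTACG")              # "CGTACGT"
#' windowSeed("ACGTACG", "identity")  # unchanged
#' @export
windowSeed <- function(site, orientation = c("revcomp", "identity")) {
  orientation <- match.arg(orientation)
  if (length(site) == 0L) return(character())
  if (orientation == "identity") return(site)
  as.character(reverseComplement(DNAStringSet(site)))
}
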