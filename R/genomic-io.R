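#' Read one species' input files into a validated SpeciesBundle
#'
#' Reads the four (plus two optional) standard-format inputs for one species
#' and assembles them into a \code{\linkS4class{SpeciesBundle}}, converting
#' every format's coordinate convention at the boundary: FASTA genome
#' (lowercase soft-masking folded to uppercase, never treated as repeat),
#' gene annotation as BED (0-based half-open) or GFF3 (1-based closed,
#' feature type \code{gene}), a conservation track as fixed/variable-step
#' wiggle or bedGraph with scores in \code{[0, 1]} (positions the track does
#' not cover stay missing, not zero), and optional repeat and CDS interval
#' masks (BED, or GFF3 \code{CDS} features).
#'
#' @param speciesId species label.
#' @param fastaPath genome FASTA (optionally gzipped).
#' @param annotationPath gene annotation, \code{.bed} or \code{.gff/.gff3}.
#' @param conservationPath conservation track, \code{.wig}/\code{.bedGraph}.
#' @param repeatPath,cdsPath optional interval files.
#' @param chromFilter optional character vector: keep only these
#'   chromosomes (e.g. to drop plasmids/unplaced scaffolds). Default keeps
#'   every sequence in the FASTA.
#' @return a validated \code{\linkS4class{SpeciesBundle}}.
#' @export
readSpeciesBundle <- function(speciesId, fastaPath, annotationPath,
                              conservationPath, repeatPath = NULL,
                              cdsPath = NULL, chromFilter = NULL) {
  for (p in c(fastaPath, annotationPath, conservationPath, repeatPath, cdsPath))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))   # FASTA id = first token
  genome <- DNAStringSet(toupper(as.character(genome)))
  if (!is.null(chromFilter)) genome <- genome[names(genome) %in% chromFilter]
  if (length(genome) == 0L) stop("no chromosomes retained from ", fastaPath)

  genes <- .readFeatures(annotationPath, type = "gene")
  if (is.null(genes$gene_id) || anyNA(genes$gene_id))
    stop("annotation records without a usable gene identifier in ",
         annotationPath)
  .checkChroms(genes, genome, annotationPath, ids = genes$gene_id)

  conservation <- .readConservation(conservationPath, genome)

  repeatMask <- if (!is.null(repeatPath)) {
    m <- .readFeatures(repeatPath, type = "any")
    .checkChroms(m, genome, repeatPath); m
  } else GRanges()
  codingMask <- if (!is.null(cdsPath)) {
    m <- .readFeatures(cdsPath, type = "CDS")
    .checkChroms(m, genome, cdsPath); m
  } else GRanges()

  SpeciesBundle(speciesId, genome, genes, conservation,
                repeatMask, codingMask)
}

# BED or GFF3 feature reading; rtracklayer converts BED's 0-based half-open
# and GFF3's 1-based closed coordinates into GRanges at the boundary.
.readFeatures <- function(path, type = "gene") {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (type != "any" && !is.null(gr$type))
      gr <- gr[as.character(gr$type) == type]
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else NULL
    if ((is.null(id) || anyNA(id)) && !is.null(gr$Name))
      id <- ifelse(is.na(id), as.character(gr$Name), id)
    mcols(gr) <- NULL
    gr$gene_id <- id
    gr
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    id <- if (!is.null(gr$name)) as.character(gr$name) else NULL
    mcols(gr) <- NULL
    gr$gene_id <- id
    gr
  } else stop("unsupported annotation format '", ext, "' for ", path)
}

.checkChroms <- function(gr, genome, path, ids = NULL) {
  chrom <- as.character(seqnames(gr))
  bad <- !chrom %in% names(genome)
  if (any(bad)) {
    what <- if (!is.null(ids)) paste0(" (record ", ids[bad][1L], ")") else ""
    stop("record in ", path, " references unknown chromosome '",
         chrom[bad][1L], "'", what)
  }
  clen <- stats::setNames(width(genome), names(genome))
  out <- start(gr) < 1L | end(gr) > clen[chrom]
  if (any(out))
    stop("record in ", path, " extends outside chromosome bounds: ",
         chrom[out][1L], ":", start(gr)[out][1L], "-", end(gr)[out][1L])
  invisible(TRUE)
}

# Expand a wiggle/bedGraph track into per-base vectors; uncovered = NA.
.readConservation <- function(path, genome) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  fmt <- switch(ext, wig = "wig", bedgraph = "bedGraph", bg = "bedGraph",
                stop("unsupported conservation format '", ext, "' for ", path))
  gr <- rtracklayer::import(path, format = fmt)
  .checkChroms(gr, genome, path)
  sc <- as.numeric(gr$score)
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    stop("conservation score outside [0, 1] in ", path, ": ",
         sc[which(sc < 0 | sc > 1)[1L]])
  cons <- lapply(stats::setNames(width(genome), names(genome)),
                 function(L) rep(NA_real_, L))
  chrom <- as.character(seqnames(gr))
  for (nm in unique(chrom)) {
    sel <- which(chrom == nm)
    pos <- sequence(width(gr)[sel], from = start(gr)[sel])
    cons[[nm]][pos] <- rep(sc[sel], width(gr)[sel])
  }
  cons
}

#' Write the candidate-seed table as TSV
#'
#' One row per tested 7-mer with the pooled counts and raw/corrected
#' binomial P values, sorted by \code{p_bonferroni} ascending with ties
#' broken lexicographically by seed, so identical inputs always produce
#' byte-identical files.
#'
#' @param calls a \code{\linkS4class{SeedScanResult}} or its
#'   \code{seedCalls} table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSeedTable <- function(calls, path) {
  if (is(calls, "SeedScanResult")) calls <- seedCalls(calls)
  df <- as.data.frame(calls)[, c("seed_7mer", "site_7mer", "count_high",
                                 "count_low", "p_raw", "p_bonferroni",
                                 "is_candidate")]
  ord <- order(df$p_bonferroni, df$seed_7mer, method = "radix")
  utils::write.table(df[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-species CS50/CS95 summary as TSV
#'
#' @param summaries a \code{\linkS4class{SeedScanResult}} or its
#'   \code{speciesSummaries} table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSpeciesSummary <- function(summaries, path) {
  if (is(summaries, "SeedScanResult")) summaries <- speciesSummaries(summaries)
  df <- as.data.frame(summaries)[, c("species_id", "n_windows", "cs50", "cs95")]
  df <- df[order(df$species_id, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target sites as BED6+2
#'
#' Standard 6-column BED (0-based half-open, written at the boundary from
#' the internal 1-based ranges) with \code{name = gene_id|seed},
#' \code{score = round(1000 * WCS)}, plus two extra columns: the sense-strand
#' site 7-mer and the unrounded WCS.
#'
#' @param sites target-site \code{GRanges} from
#'   \code{\link{callTargetSites}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTargetSites <- function(sites, path) {
  if (length(sites) == 0L) { file.create(path); return(invisible(path)) }
  sl <- seqlengths(sites)
  if (!all(is.na(sl))) {
    chrom <- as.character(seqnames(sites))
    out <- start(sites) < 1L | end(sites) > sl[chrom]
    if (any(out, na.rm = TRUE))
      stop("target site outside chromosome bounds: ",
           chrom[which(out)[1L]], ":", start(sites)[which(out)[1L]])
  }
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites) - 1L,      # BED is 0-based half-open
                   end = end(sites),
                   name = paste(mcols(sites)$gene_id,
                                mcols(sites)$seed_7mer, sep = "|"),
                   score = as.integer(round(1000 * mcols(sites)$wcs)),
                   strand = as.character(strand(sites)),
                   site_7mer = mcols(sites)$site_7mer,
                   wcs = mcols(sites)$wcs,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
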