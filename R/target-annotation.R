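#' Extract candidate miRNA target sites (CS95-gated, coding-excluded)
#'
#' A retained window becomes a target site when all three filters pass:
#' (i) its implied seed is one of the candidate seeds, (ii) its WCS is
#' strictly greater than its own species' CS95 (ties at the threshold are
#' dropped), and (iii) it overlaps no coding (CDS) interval by one base or
#' more — coding overlap inflates conservation for reasons unrelated to
#' targeting, so those sites are ruled out at this stage even though they
#' were allowed during seed calling. Per-filter drop counts are stored in
#' \code{metadata()} of the result.
#'
#' @param result a \code{\linkS4class{SeedScanResult}} (windows and
#'   CS95 thresholds are taken from it).
#' @param codingMasks named list of coding-interval \code{GRanges}, one per
#'   species (e.g. \code{codingMask(bundle)}); species absent from the list
#'   are treated as having no coding annotation.
#' @param candidates candidate seeds to match; defaults to
#'   \code{candidateSeeds(result)}.
#' @return \code{GRanges} of surviving sites sorted by (species,
#'   chromosome, start), with columns \code{species_id}, \code{gene_id},
#'   \code{seed_7mer}, \code{site_7mer}, \code{wcs}.
#' @export
callTargetSites <- function(result, codingMasks = list(),
                            candidates = candidateSeeds(result)) {
  stopifnot(is(result, "SeedScanResult"))
  orientation <- scanParams(result)$seedOrientation
  summaries <- speciesSummaries(result)
  cs95 <- stats::setNames(summaries$cs95, summaries$species_id)
  out <- list()
  drops <- c(not_candidate = 0L, below_cs95 = 0L, coding_overlap = 0L)
  for (sp in names(scanWindows(result))) {
    w <- scanWindows(result)[[sp]]
    if (length(w) == 0L) next
    seed <- windowSeed(mcols(w)$site_7mer, orientation)
    isCand <- seed %in% candidates
    above <- mcols(w)$wcs > cs95[[sp]]            # strict: ties dropped
    cds <- codingMasks[[sp]]
    inCds <- if (!is.null(cds) && length(cds))
      countOverlaps(w, cds, minoverlap = 1L) > 0L
    else rep(FALSE, length(w))
    drops["not_candidate"] <- drops["not_candidate"] + sum(!isCand)
    drops["below_cs95"] <- drops["below_cs95"] + sum(isCand & !above)
    drops["coding_overlap"] <- drops["coding_overlap"] +
      sum(isCand & above & inCds)
    keep <- isCand & above & !inCds
    if (!any(keep)) next
    s <- w[keep]
    mcols(s) <- DataFrame(species_id = sp,
                          gene_id = mcols(w)$gene_id[keep],
                          seed_7mer = seed[keep],
                          site_7mer = mcols(w)$site_7mer[keep],
                          wcs = mcols(w)$wcs[keep])
    out[[sp]] <- s
  }
  if (length(out) == 0L) {
    sites <- GRanges()
    mcols(sites) <- DataFrame(species_id = character(), gene_id = character(),
                              seed_7mer = character(), site_7mer = character(),
                              wcs = numeric())
  } else {
    sites <- unlist(GenomicRanges::GRangesList(unname(out)), use.names = FALSE)
    ord <- order(mcols(sites)$species_id, as.character(seqnames(sites)),
                 start(sites), method = "radix")
    sites <- sites[ord]
  }
  metadata(sites)$dropped <- drops
  sites
}

#' Aggregate target sites into per-species target-gene lists
#'
#' Deduplicates target genes within each species and reports the proportion
#' of the species' annotated genes that carry at least one surviving target
#' site, as a percentage.
#'
#' @param sites target-site \code{GRanges} from
#'   \code{\link{callTargetSites}}.
#' @param annotatedGenes named integer vector: number of annotated genes per
#'   species (every species to report, including those with zero surviving
#'   sites). All values must be positive.
#' @return list with two data frames: \code{$species} (\code{species_id},
#'   \code{n_target_genes}, \code{n_annotated_genes},
#'   \code{proportion_pct}) and \code{$genes} (\code{species_id},
#'   \code{gene_id}, \code{n_sites}).
#' @export
aggregateTargetGenes <- function(sites, annotatedGenes) {
  stopifnot(!is.null(names(annotatedGenes)), all(!is.na(annotatedGenes)))
  if (any(annotatedGenes < 1L))
    stop("species with zero annotated genes: ",
         paste(names(annotatedGenes)[annotatedGenes < 1L], collapse = ", "))
  sp <- mcols(sites)$species_id
  unknown <- setdiff(unique(sp), names(annotatedGenes))
  if (length(unknown))
    stop("sites reference species without an annotated-gene total: ",
         paste(unknown, collapse = ", "))
  key <- paste(sp, mcols(sites)$gene_id, sep = "\r")
  if (length(key)) {
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    genes <- data.frame(species_id = parts[, 1L], gene_id = parts[, 2L],
                        n_sites = as.integer(tab), stringsAsFactors = FALSE)
    genes <- genes[order(genes$species_id, genes$gene_id, method = "radix"), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(species_id = character(), gene_id = character(),
                        n_sites = integer(), stringsAsFactors = FALSE)
  }
  ids <- sort(names(annotatedGenes), method = "radix")
  nTarget <- vapply(ids, function(s) sum(genes$species_id == s), 0L)
  species <- data.frame(species_id = ids,
                        n_target_genes = as.integer(nTarget),
                        n_annotated_genes = as.integer(annotatedGenes[ids]),
                        proportion_pct = 100 * nTarget /
                          as.numeric(annotatedGenes[ids]),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(species = species, genes = genes)
}

#' Export per-species foreground/background gene lists
#'
#' Writes, for every species, the two plain-text gene-ID lists a
#' functional-enrichment service needs: the foreground
#' (\code{<species>_target_genes.txt}, one target gene per line, possibly
#' empty) and the background (\code{<species>_background_genes.txt}, all
#' annotated genes of that species).
#'
#' @param sites target-site \code{GRanges} from
#'   \code{\link{callTargetSites}}.
#' @param annotation named list of character vectors: all annotated gene IDs
#'   per species.
#' @param outDir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
exportGeneLists <- function(sites, annotation, outDir) {
  stopifnot(is.list(annotation), !is.null(names(annotation)))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  sp <- mcols(sites)$species_id
  gid <- mcols(sites)$gene_id
  paths <- character(0)
  for (s in sort(names(annotation), method = "radix")) {
    fg <- sort(unique(gid[sp == s]), method = "radix")
    if (!all(fg %in% annotation[[s]]))
      stop("target gene(s) of species ", s, " absent from its annotation: ",
           paste(utils::head(setdiff(fg, annotation[[s]]), 3L), collapse = ", "))
    fgPath <- file.path(outDir, paste0(s, "_target_genes.txt"))
    bgPath <- file.path(outDir, paste0(s, "_background_genes.txt"))
    writeLines(fg, fgPath)
    writeLines(sort(annotation[[s]], method = "radix"), bgPath)
    paths <- c(paths, fgPath, bgPath)
  }
  invisible(paths)
}
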