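#' Accessors for mirSeedScan S4 classes
#'
#' Small accessor generics so that downstream code never touches slots:
#' \code{speciesId}, \code{genomeSeq}, \code{geneRanges},
#' \code{conservationTrack}, \code{repeatMask} and \code{codingMask} read a
#' \code{\linkS4class{SpeciesBundle}}; \code{seedCalls},
#' \code{candidateSeeds}, \code{speciesSummaries}, \code{scanWindows} and
#' \code{scanParams} read a \code{\linkS4class{SeedScanResult}};
#' \code{pValue} and \code{pPoint} read an \code{\linkS4class{OverlapTest}}.
#'
#' @param x the object.
#' @return the corresponding component; \code{candidateSeeds} returns the
#'   sorted character vector of 7-mers called candidate seeds.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("conservationTrack", function(x) standardGeneric("conservationTrack"))
#' @rdname accessors
#' @export
setGeneric("repeatMask", function(x) standardGeneric("repeatMask"))
#' @rdname accessors
#' @export
setGeneric("codingMask", function(x) standardGeneric("codingMask"))
#' @rdname accessors
#' @export
setGeneric("seedCalls", function(x) standardGeneric("seedCalls"))
#' @rdname accessors
#' @export
setGeneric("candidateSeeds", function(x) standardGeneric("candidateSeeds"))
#' @rdname accessors
#' @export
setGeneric("speciesSummaries", function(x) standardGeneric("speciesSummaries"))
#' @rdname accessors
#' @export
setGeneric("scanWindows", function(x) standardGeneric("scanWindows"))
#' @rdname accessors
#' @export
setGeneric("scanParams", function(x) standardGeneric("scanParams"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("pPoint", function(x) standardGeneric("pPoint"))

#' @rdname accessors
setMethod("speciesId", "SpeciesBundle", function(x) x@speciesId)
#' @rdname accessors
setMethod("genomeSeq", "SpeciesBundle", function(x) x@genome)
#' @rdname accessors
setMethod("geneRanges", "SpeciesBundle", function(x) x@genes)
#' @rdname accessors
setMethod("conservationTrack", "SpeciesBundle", function(x) x@conservation)
#' @rdname accessors
setMethod("repeatMask", "SpeciesBundle", function(x) x@repeatMask)
#' @rdname accessors
setMethod("codingMask", "SpeciesBundle", function(x) x@codingMask)

#' @rdname accessors
setMethod("seedCalls", "SeedScanResult", function(x) x@calls)
#' @rdname accessors
setMethod("candidateSeeds", "SeedScanResult", function(x)
  sort(x@calls$seed_7mer[x@calls$is_candidate], method = "radix"))
#' @rdname accessors
setMethod("speciesSummaries", "SeedScanResult", function(x) x@summaries)
#' @rdname accessors
setMethod("scanWindows", "SeedScanResult", function(x) x@windows)
#' @rdname accessors
setMethod("scanParams", "SeedScanResult", function(x) x@params)

#' @rdname accessors
setMethod("pValue", "OverlapTest", function(x) x@pValue)
#' @rdname accessors
setMethod("pPoint", "OverlapTest", function(x) x@pPoint)
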