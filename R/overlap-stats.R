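#' Exact hypergeometric point probability for a seed-set overlap
#'
#' Probability of observing exactly \code{k} shared k-mers between two sets
#' of sizes \code{M} and \code{n} drawn without replacement from a universe
#' of \code{N} possible k-mers:
#' \deqn{P_k = \frac{\binom{M}{k} \binom{N-M}{n-k}}{\binom{N}{n}}}
#' computed in log space so that genome-scale parameters (\eqn{N = 16384})
#' never overflow. Zero outside the support (e.g. when \eqn{n - k > N - M}).
#'
#' @param N universe size (all possible k-mers; 16384 for 7-mers).
#' @param M,n sizes of the two sets.
#' @param k overlap; may be a vector.
#' @return numeric vector of point probabilities.
#' @examples
#' hypergeomPoint(4, 2, 2, 2)   # 1/6
#' hypergeomPoint(4, 2, 2, 1)   # 2/3
#' @export
hypergeomPoint <- function(N, M, n, k) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(n) == 1L,
            N == round(N), M == round(M), n == round(n), all(k == round(k)),
            N >= 0, M >= 0, n >= 0, M <= N, n <= N)
  p <- numeric(length(k))
  ok <- k >= 0 & k <= M & k <= n & (n - k) <= (N - M)
  p[ok] <- exp(lchoose(M, k[ok]) + lchoose(N - M, n - k[ok]) - lchoose(N, n))
  p
}

#' Hypergeometric upper-tail overlap significance from counts
#'
#' Inclusive upper-tail significance of an observed seed-set overlap:
#' \eqn{P(X \ge k) = \sum_{j=k}^{\min(M,n)} P_j} with \eqn{P_j} the exact
#' point probability of \code{\link{hypergeomPoint}}. All four parameters
#' are plain counts, so published set sizes can be tested without the sets
#' themselves.
#'
#' @inheritParams hypergeomPoint
#' @param k observed overlap (single integer).
#' @return an \code{\linkS4class{OverlapTest}}.
#' @examples
#' hypergeomTest(16384, 2649, 29, 11)
#' @export
hypergeomTest <- function(N, M, n, k) {
  stopifnot(length(k) == 1L, k >= 0, k <= min(M, n))
  j <- seq.int(k, min(M, n))
  pts <- hypergeomPoint(N, M, n, j)
  new("OverlapTest", N = as.integer(N), M = as.integer(M), n = as.integer(n),
      k = as.integer(k), pPoint = pts[1L], pValue = min(1, sum(pts)))
}

#' Test whether two seed sets overlap more than expected by chance
#'
#' Computes the observed overlap \eqn{k = |A \cap B|} between two sets of
#' distinct k-mers and its inclusive upper-tail hypergeometric P value over
#' the universe of all \code{N} possible k-mers. Symmetric in its two
#' arguments. This is the test used to compare detected candidate seeds
#' against an independent known-seed list.
#'
#' @param setA,setB character vectors of distinct k-mers over
#'   \code{A,C,G,T} (use \code{\link{readSeedList}} for files).
#' @param N universe size; defaults to \code{4^k} for the k-mer width found
#'   in the sets.
#' @return an \code{\linkS4class{OverlapTest}}.
#' @examples
#' a <- c("AAAAAAA", "CCCCCCC", "GGGGGGG")
#' b <- c("CCCCCCC", "TTTTTTT")
#' overlapTest(a, b)
#' @export
overlapTest <- function(setA, setB, N = NULL) {
  setA <- unique(setA); setB <- unique(setB)
  width <- unique(nchar(c(setA, setB)))
  if (length(width) > 1L)
    stop("seed sets mix k-mer widths: ", paste(width, collapse = ", "))
  bad <- grepl("[^ACGT]", c(setA, setB))
  if (any(bad))
    stop("invalid seed(s), must be k-mers over {A,C,G,T}: ",
         paste(utils::head(c(setA, setB)[bad], 3L), collapse = ", "))
  if (is.null(N)) N <- kmerUniverseSize(if (length(width)) width else 7L)
  if (length(setA) > N || length(setB) > N)
    stop("seed set larger than the k-mer universe")
  hypergeomTest(N, length(setA), length(setB),
                length(intersect(setA, setB)))
}

#' Read a seed list from a plain-text file
#'
#' One sequence per line; \code{#} starts a comment (whole-line or
#' trailing); blank lines ignored. Sequences are uppercased and
#' \code{U -> T} normalised so RNA-alphabet seed lists are accepted, then
#' deduplicated. Any surviving line that is not a k-mer of width \code{k}
#' over \code{A,C,G,T} aborts with its line number.
#'
#' @param path file path.
#' @param k required k-mer width (default 7).
#' @return sorted character vector of distinct k-mers.
#' @export
readSeedList <- function(path, k = 7L) {
  lines <- readLines(path, warn = FALSE)
  seqs <- toupper(trimws(sub("#.*$", "", lines)))
  seqs <- chartr("U", "T", seqs)
  keep <- nzchar(seqs)
  bad <- keep & (nchar(seqs) != k | grepl("[^ACGT]", seqs))
  if (any(bad))
    stop("line ", which(bad)[1L], " of '", path, "' is not a ", k,
         "-mer over {A,C,G,T}: '", lines[which(bad)[1L]], "'")
  sort(unique(seqs[keep]), method = "radix")
}
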