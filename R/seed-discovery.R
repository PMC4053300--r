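#' Per-species WCS percentile thresholds (CS50, CS95)
#'
#' Ranks all retained Window Conservation Scores within one species and
#' returns the 50th percentile (CS50, the high/low-conservation split used
#' by the binomial seed test) and the 95th percentile (CS95, the gate for
#' target-site extraction). Percentiles use linear interpolation between the
#' closest order statistics (\code{stats::quantile} type 7), fixed so the
#' thresholds are deterministic for a given score list.
#'
#' @param wcs numeric vector of WCS values for one species (non-empty, no
#'   \code{NA}: windows with missing scores are never constructed).
#' @param speciesId species label.
#' @return one-row \code{data.frame}: \code{species_id}, \code{n_windows},
#'   \code{cs50}, \code{cs95}.
#' @examples
#' speciesPercentiles(c(0.2, 0.4, 0.6, 0.8), "sp1")  # cs50 = 0.5
#' @export
speciesPercentiles <- function(wcs, speciesId = "species") {
  if (length(wcs) == 0L)
    stop("no retained windows for species '", speciesId,
         "': species excluded (no conservation information)")
  stopifnot(!anyNA(wcs))
  q <- stats::quantile(wcs, c(0.5, 0.95), type = 7, names = FALSE)
  data.frame(species_id = speciesId, n_windows = length(wcs),
             cs50 = q[1], cs95 = q[2], stringsAsFactors = FALSE)
}

#' Tally high- and low-conservation windows per 7-mer, pooled over species
#'
#' Within each species, every retained window is classified against that
#' species' own CS50: \emph{high} if WCS > CS50, \emph{low} if WCS < CS50,
#' and a tie (WCS exactly equal to CS50) is excluded from both counts so the
#' binomial null stays at 1/2. Counts are then summed across species for
#' each distinct site 7-mer; only observed 7-mers appear.
#'
#' @param windowsList named list of window \code{GRanges} (one per species,
#'   names are species ids) from \code{\link{enumerateWindows}}.
#' @param summaries per-species percentile table covering every species in
#'   \code{windowsList} (rows as from \code{\link{speciesPercentiles}}).
#' @param seedOrientation how the reported \code{seed_7mer} is derived from
#'   the site 7-mer; see \code{\link{windowSeed}}.
#' @return \code{data.frame}, one row per observed 7-mer, sorted by
#'   \code{site_7mer} (C-locale): \code{seed_7mer}, \code{site_7mer},
#'   \code{count_high}, \code{count_low}, \code{ties_excluded}.
#' @export
tallySeeds <- function(windowsList, summaries,
                       seedOrientation = c("revcomp", "identity")) {
  seedOrientation <- match.arg(seedOrientation)
  stopifnot(is.list(windowsList), !is.null(names(windowsList)))
  unknown <- setdiff(names(windowsList), summaries$species_id)
  if (length(unknown))
    stop("windows reference species without a percentile summary: ",
         paste(unknown, collapse = ", "))
  cs50 <- stats::setNames(summaries$cs50, summaries$species_id)
  sites <- character(0); status <- integer(0)       # 1 high, 2 low, 3 tie
  for (sp in names(windowsList)) {
    w <- windowsList[[sp]]
    if (length(w) == 0L) next
    wc <- mcols(w)$wcs
    st <- ifelse(wc > cs50[[sp]], 1L, ifelse(wc < cs50[[sp]], 2L, 3L))
    sites <- c(sites, mcols(w)$site_7mer)
    status <- c(status, st)
  }
  if (length(sites) == 0L)
    return(data.frame(seed_7mer = character(), site_7mer = character(),
                      count_high = integer(), count_low = integer(),
                      ties_excluded = integer(), stringsAsFactors = FALSE))
  lev <- sort(unique(sites), method = "radix")      # locale-independent order
  f <- factor(sites, levels = lev)
  agg <- rowsum(cbind(high = status == 1L, low = status == 2L,
                      tie = status == 3L) + 0L, f)
  data.frame(seed_7mer = windowSeed(lev, seedOrientation),
             site_7mer = lev,
             count_high = as.integer(agg[, "high"]),
             count_low = as.integer(agg[, "low"]),
             ties_excluded = as.integer(agg[, "tie"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-tailed binomial test for excess high-conservation windows
#'
#' Under no selective constraint a window falls above or below its species'
#' median WCS with equal probability, so for a 7-mer with pooled counts
#' \eqn{h} high and \eqn{l} low the null is \eqn{X \sim Binomial(h + l, 1/2)}
#' and the one-tailed P value is \eqn{P(X \ge h)}. Evaluation is exact
#' (survival function, no normal approximation) and vectorised; tallies with
#' \eqn{h + l = 0} (all windows tied at CS50) get \code{NA} and are skipped
#' by the caller.
#'
#' @param countHigh,countLow integer vectors of pooled high/low counts.
#' @param log return the natural log of the P value (genome-scale counts can
#'   push the tail below the smallest positive double).
#' @return numeric vector of raw one-tailed P values (or their logs).
#' @examples
#' binomialSeedTest(10, 0)   # (1/2)^10
#' binomialSeedTest(5, 5)    # 638/1024
#' binomialSeedTest(0, 10)   # 1
#' @export
binomialSeedTest <- function(countHigh, countLow, log = FALSE) {
  stopifnot(length(countHigh) == length(countLow),
            all(countHigh >= 0), all(countLow >= 0))
  n <- countHigh + countLow
  p <- stats::pbinom(countHigh - 1, n, 0.5, lower.tail = FALSE, log.p = log)
  p[n == 0] <- NA_real_
  p
}

#' Bonferroni correction and candidate-seed decision
#'
#' Applies \code{p_bonferroni = min(1, p_raw * m)} and calls a 7-mer a
#' candidate seed when the corrected P value is below \code{alpha} \emph{and}
#' its high count exceeds its low count (conservation above background; a
#' depleted 7-mer is never a candidate). The multiplier \code{m} is either
#' \code{"all_kmers"} (every possible k-mer, \eqn{4^7 = 16384} by default —
#' the genome-scale convention), \code{"observed"} (the number of tallied
#' 7-mers, appropriate for small genomes where most 7-mers never occur), or
#' an explicit integer.
#'
#' @param tally tally \code{data.frame} from \code{\link{tallySeeds}} with
#'   \code{p_raw} already attached, or lacking it (then computed here).
#' @param mTests \code{"all_kmers"}, \code{"observed"}, or a positive
#'   integer.
#' @param alpha family-wise significance level (default 0.05).
#' @param k k-mer width used for \code{"all_kmers"} (default 7).
#' @return \code{DataFrame} of seed calls with columns \code{seed_7mer},
#'   \code{site_7mer}, \code{count_high}, \code{count_low},
#'   \code{ties_excluded}, \code{p_raw}, \code{p_bonferroni},
#'   \code{is_candidate}.
#' @export
bonferroniCall <- function(tally, mTests = "all_kmers", alpha = 0.05, k = 7L) {
  if (is.null(tally$p_raw))
    tally$p_raw <- binomialSeedTest(tally$count_high, tally$count_low)
  m <- if (identical(mTests, "all_kmers")) kmerUniverseSize(k)
       else if (identical(mTests, "observed")) max(nrow(tally), 1L)
       else as.integer(mTests)
  if (is.na(m) || m < 1L) stop("mTests must resolve to a positive integer")
  pb <- pmin(1, tally$p_raw * m)
  DataFrame(seed_7mer = tally$seed_7mer, site_7mer = tally$site_7mer,
            count_high = tally$count_high, count_low = tally$count_low,
            ties_excluded = tally$ties_excluded,
            p_raw = tally$p_raw, p_bonferroni = pb,
            is_candidate = !is.na(pb) & pb < alpha &
                           tally$count_high > tally$count_low)
}

#' Size of the k-mer universe
#'
#' @param k k-mer width.
#' @return \code{4^k} as an integer-valued numeric (16384 for the default
#'   7-mers).
#' @export
kmerUniverseSize <- function(k = 7L) as.integer(4)^as.integer(k)

#' Run the full genome-wide seed-discovery scan
#'
#' Deterministic composition of the pipeline over a set of species bundles:
#' define the 3'UTRs, enumerate and score sliding windows (dropping repeat
#' overlaps, \code{N} bases and missing scores), rank WCS within each species
#' to obtain CS50/CS95, pool per-7-mer high/low counts across species, and
#' call candidate seeds with the one-tailed binomial test under Bonferroni
#' correction. Species whose tracks yield no retained window are dropped
#' with a warning, mirroring the removal of genomes without conservation
#' information; if no species survives, the scan stops.
#'
#' @param bundles list of \code{\linkS4class{SpeciesBundle}} objects.
#' @param utrLength 3'UTR length in nt (default 80).
#' @param k seed/window width (default 7).
#' @param seedOrientation \code{"revcomp"} (default) or \code{"identity"};
#'   see \code{\link{windowSeed}}.
#' @param mTests Bonferroni multiplier mode; see \code{\link{bonferroniCall}}.
#' @param alpha significance level (default 0.05).
#' @param repeatOverlapMinBases repeat-exclusion threshold in bases.
#' @param verbose emit per-stage counts via \code{message()}.
#' @return a \code{\linkS4class{SeedScanResult}}.
#' @export
runSeedDiscovery <- function(bundles, utrLength = 80L, k = 7L,
                             seedOrientation = c("revcomp", "identity"),
                             mTests = "all_kmers", alpha = 0.05,
                             repeatOverlapMinBases = 1L, verbose = FALSE) {
  seedOrientation <- match.arg(seedOrientation)
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, is, TRUE, "SpeciesBundle")))
  windowsList <- list()
  sums <- list()
  for (b in bundles) {
    sp <- speciesId(b)
    utrs <- defineUTR(geneRanges(b), genomeSeq(b), utrLength)
    win <- enumerateWindows(utrs, conservationTrack(b), repeatMask(b),
                            k = k, speciesId = sp,
                            repeatOverlapMinBases = repeatOverlapMinBases)
    if (length(win) == 0L) {
      warning("species '", sp, "' retained no scored windows; excluded")
      next
    }
    if (verbose)
      message(sprintf("%s: %d genes, %d windows retained (dropped: %s)",
                      sp, length(geneRanges(b)), length(win),
                      paste(names(metadata(win)$dropped),
                            metadata(win)$dropped, sep = "=", collapse = " ")))
    windowsList[[sp]] <- win
    sums[[sp]] <- speciesPercentiles(mcols(win)$wcs, sp)
  }
  if (length(windowsList) == 0L)
    stop("no species retained any scored windows; cannot run seed discovery")
  summaries <- do.call(rbind, unname(sums))
  tally <- tallySeeds(windowsList, summaries, seedOrientation)
  calls <- bonferroniCall(tally, mTests = mTests, alpha = alpha, k = k)
  if (verbose)
    message(sprintf("%d species retained, %d 7-mer types observed, %d candidates",
                    nrow(summaries), nrow(calls), sum(calls$is_candidate)))
  new("SeedScanResult", calls = calls,
      summaries = DataFrame(summaries),
      windows = windowsList,
      params = list(utrLength = as.integer(utrLength), k = as.integer(k),
                    seedOrientation = seedOrientation, mTests = mTests,
                    alpha = alpha,
                    repeatOverlapMinBases = as.integer(repeatOverlapMinBases)))
}
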