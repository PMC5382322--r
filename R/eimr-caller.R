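# Classification of hormone-induced binding regions (EIMRs) from
# two-condition ChIP-seq tag lanes: per-million lane normalization,
# pseudocounted induction ratio, inclusive ratio threshold (default 2.3),
# and the >=1 bp overlap rule for peak-set matching. A simple Poisson
# sliding-window scanner provides candidate peaks when none are supplied.

#' Normalize a raw tag count to tags per million
#'
#' Read counts are normalized to 1 million uniquely mapping reads:
#' `k * 1e6 / N_lane`.
#'
#' @param k raw tag count(s), `>= 0`.
#' @param laneTotal the lane's total number of uniquely mapped reads.
#' @return Normalized count(s).
#' @examples
#' normalizeCount(50, 1e7)  # 5
#' @export
normalizeCount <- function(k, laneTotal) {
    if (!is.numeric(laneTotal) || length(laneTotal) != 1L ||
        !is.finite(laneTotal) || laneTotal <= 0) {
        stop("invalid lane: 'laneTotal' must be a single positive number",
            call. = FALSE)
    }
    if (any(k < 0)) stop("raw counts must be >= 0", call. = FALSE)
    k * 1e6 / laneTotal
}

#' Count tag 5' positions inside regions
#'
#' A tag is counted when its 5' position lies within the region
#' (inclusive of the first base, exclusive of the BED end coordinate).
#'
#' @param lane a [TagLane-class].
#' @param regions `GRanges` of query regions.
#' @return Integer vector of raw counts, one per region.
#' @export
countTags <- function(lane, regions) {
    stopifnot(methods::is(lane, "TagLane"), methods::is(regions, "GRanges"))
    GenomicRanges::countOverlaps(regions, tagPositions(lane),
        ignore.strand = TRUE)
}

#' Pseudocounted induction ratio between two lanes
#'
#' `r = n_plus / n_minus` where `n = normalizeCount(k + c, N_lane)` and the
#' pseudocount `c` (default 1 raw tag) is added to both conditions before
#' normalization, guaranteeing a finite positive ratio for zero counts.
#'
#' @param kMinus,kPlus raw tag counts in the untreated / treated lane.
#' @param nMinus,nPlus lane totals (uniquely mapped reads) for the two
#'   lanes.
#' @param pseudocount raw tags added to both conditions, default 1.
#' @return Numeric ratio(s) `r > 0`.
#' @examples
#' inductionRatio(99, 229, 1e6, 1e6)  # 230/100 = 2.3
#' @export
inductionRatio <- function(kMinus, kPlus, nMinus, nPlus, pseudocount = 1) {
    assertScalarNumber(nMinus, "nMinus", 0, strict = TRUE)
    assertScalarNumber(nPlus, "nPlus", 0, strict = TRUE)
    normalizeCount(kPlus + pseudocount, nPlus) /
        normalizeCount(kMinus + pseudocount, nMinus)
}

#' Classify peaks as hormone-induced binding regions (EIMRs)
#'
#' For each candidate peak, raw tag counts are taken in both lanes,
#' normalized to tags per million with a shared pseudocount, and the
#' treated/untreated induction ratio is compared against an inclusive
#' threshold (default 2.3): peaks with `r >= threshold` are flagged as
#' induced. When a TSS annotation is supplied each peak is annotated with
#' its nearest gene and signed distance.
#'
#' @param peaks `GRanges` of candidate peaks.
#' @param minusLane,plusLane [TagLane-class] objects for the untreated and
#'   hormone-treated condition.
#' @param threshold inclusive induction-ratio cutoff, default 2.3.
#' @param pseudocount raw tags added to both conditions, default 1.
#' @param tss optional TSS annotation (`GRanges` with `gene_id`), see
#'   [nearestTss()].
#' @return A `GRanges` sorted by chromosome and start with metadata columns
#'   `kMinus`, `kPlus`, `nMinus`, `nPlus`, `ratio`, `induced`, and (when
#'   `tss` is given) `gene_id`, `tssDistance`.
#' @export
classifyEimrs <- function(peaks, minusLane, plusLane, threshold = 2.3,
                          pseudocount = 1, tss = NULL) {
    stopifnot(methods::is(peaks, "GRanges"))
    assertScalarNumber(threshold, "threshold", 0, strict = TRUE)
    if (length(peaks) == 0L) {
        res <- peaks
        S4Vectors::mcols(res) <- S4Vectors::DataFrame(
            kMinus = integer(), kPlus = integer(),
            nMinus = numeric(), nPlus = numeric(),
            ratio = numeric(), induced = logical()
        )
        return(res)
    }
    kMinus <- countTags(minusLane, peaks)
    kPlus <- countTags(plusLane, peaks)
    nMinusTotal <- laneTotal(minusLane)
    nPlusTotal <- laneTotal(plusLane)
    ratio <- inductionRatio(kMinus, kPlus, nMinusTotal, nPlusTotal,
        pseudocount = pseudocount)
    res <- GenomicRanges::granges(peaks)
    S4Vectors::mcols(res) <- S4Vectors::DataFrame(
        kMinus = kMinus,
        kPlus = kPlus,
        nMinus = normalizeCount(kMinus, nMinusTotal),
        nPlus = normalizeCount(kPlus, nPlusTotal),
        ratio = ratio,
        induced = ratio >= threshold
    )
    if (!is.null(tss)) {
        ann <- nearestTss(res, tss)
        res$gene_id <- ann$gene_id
        res$tssDistance <- ann$distance
    }
    GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(res),
        ignore.strand = TRUE)
}

#' Match two peak sets by the >= 1 bp overlap rule
#'
#' Peaks are considered to overlap when they share at least 1 bp. Every
#' overlapping (A, B) pair is reported; an A-peak overlapping two B-peaks
#' yields two pairs. Peaks with no partner are reported as
#' condition-specific.
#'
#' @param setA,setB `GRanges` peak sets on the same genome.
#' @return A list with elements `pairs` (`data.frame` of indices
#'   `queryA`, `subjectB`), `onlyA` and `onlyB` (integer indices of
#'   unmatched peaks).
#' @export
matchPeakSets <- function(setA, setB) {
    stopifnot(methods::is(setA, "GRanges"), methods::is(setB, "GRanges"))
    hits <- GenomicRanges::findOverlaps(setA, setB, minoverlap = 1L,
        ignore.strand = TRUE)
    pairs <- data.frame(
        queryA = S4Vectors::queryHits(hits),
        subjectB = S4Vectors::subjectHits(hits)
    )
    list(
        pairs = pairs,
        onlyA = setdiff(seq_along(setA), pairs$queryA),
        onlyB = setdiff(seq_along(setB), pairs$subjectB)
    )
}

#' Parameters for the Poisson sliding-window peak scanner
#'
#' @param windowWidth window width in bp.
#' @param step window step in bp.
#' @param flank local-background flank width in bp on each side.
#' @param alpha upper-tail Poisson probability below which a window is
#'   retained.
#' @param mergeGap windows closer than this many bp are merged into one
#'   peak.
#' @return A validated named list of scanner parameters.
#' @export
scanParams <- function(windowWidth = 300L, step = 50L, flank = 1000L,
                       alpha = 1e-5, mergeGap = 100L) {
    assertScalarNumber(windowWidth, "windowWidth", 0, strict = TRUE)
    assertScalarNumber(step, "step", 0, strict = TRUE)
    assertScalarNumber(flank, "flank", 0, strict = TRUE)
    assertScalarNumber(mergeGap, "mergeGap", 0, strict = TRUE)
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
        alpha >= 1) {
        stop("'alpha' must lie in (0, 1)", call. = FALSE)
    }
    list(
        windowWidth = as.integer(windowWidth), step = as.integer(step),
        flank = as.integer(flank), alpha = alpha,
        mergeGap = as.integer(mergeGap)
    )
}

#' Call candidate peaks with a Poisson sliding-window scanner
#'
#' Slides fixed-width windows along each chromosome and retains windows
#' whose tag count `k` has upper-tail Poisson probability
#' `P(X >= k | lambda_local) < alpha`, where
#' `lambda_local = max(genome-wide rate, local flank rate) * windowWidth`.
#' Retained windows within `mergeGap` bp of each other are merged. This is
#' deliberately simple plumbing for producing a candidate-peak universe;
#' externally called peaks can be supplied instead wherever candidate peaks
#' are consumed.
#'
#' @param lane a non-empty [TagLane-class].
#' @param seqlengths chromosome lengths (named vector, `Seqinfo`, or
#'   `DNAStringSet`).
#' @param params scanner parameters from [scanParams()].
#' @return `GRanges` of merged candidate peaks.
#' @export
callCandidatePeaks <- function(lane, seqlengths, params = scanParams()) {
    stopifnot(methods::is(lane, "TagLane"))
    sl <- asSeqlengths(seqlengths)
    tags <- tagPositions(lane)
    if (length(tags) == 0L) {
        stop("cannot call peaks on an empty lane", call. = FALSE)
    }
    w <- params$windowWidth
    genomeRate <- length(tags) / sum(sl)
    peakList <- list()
    for (chrom in names(sl)) {
        len <- sl[[chrom]]
        if (w > len) {
            warning("window wider than chromosome ", chrom, "; skipped")
            next
        }
        pos <- sort(GenomicRanges::start(
            tags[GenomeInfoDb::seqnames(tags) == chrom]))
        if (length(pos) == 0L) next
        starts <- seq.int(1L, len - w + 1L, by = params$step)
        ends <- starts + w - 1L
        # window counts via cumulative search on sorted positions
        k <- findInterval(ends, pos) - findInterval(starts - 1L, pos)
        # local background from truncated flanks on both sides
        fl <- params$flank
        loA <- pmax(starts - fl, 1L)
        hiB <- pmin(ends + fl, len)
        leftCnt <- findInterval(starts - 1L, pos) - findInterval(loA - 1L, pos)
        rightCnt <- findInterval(hiB, pos) - findInterval(ends, pos)
        flankLen <- (starts - loA) + (hiB - ends)
        flankRate <- ifelse(flankLen > 0, (leftCnt + rightCnt) / flankLen, 0)
        lambda <- pmax(genomeRate, flankRate) * w
        pval <- ppois(k - 1, lambda, lower.tail = FALSE)
        keep <- k > 0 & pval < params$alpha
        if (!any(keep)) next
        peakList[[chrom]] <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(starts[keep], ends[keep]),
            seqlengths = sl
        )
    }
    if (length(peakList) == 0L) {
        return(GenomicRanges::GRanges(seqlengths = sl))
    }
    merged <- GenomicRanges::reduce(
        unlist(methods::as(peakList, "GRangesList")),
        min.gapwidth = params$mergeGap + 1L
    )
    GenomeInfoDb::seqlevels(merged) <- names(sl)
    GenomeInfoDb::seqlengths(merged) <- sl
    GenomicRanges::sort(merged)
}

#' Write an EIMR classification as BED6 and TSV
#'
#' The BED score column holds the induction ratio rounded to 3 decimals;
#' the TSV mirrors all metadata columns.
#'
#' @param eimrs result of [classifyEimrs()].
#' @param bedPath,tsvPath output paths (either may be `NULL` to skip).
#' @export
writeEimrResults <- function(eimrs, bedPath = NULL, tsvPath = NULL) {
    if (!is.null(bedPath)) {
        out <- GenomicRanges::granges(eimrs)
        out$name <- sprintf("EIMR_%04d", seq_along(eimrs))
        out$score <- round(eimrs$ratio, 3)
        writeBedRegions(out, bedPath)
    }
    if (!is.null(tsvPath)) {
        df <- as.data.frame(eimrs)
        # report BED-convention coordinates in the table
        df$start <- df$start - 1L
        df$strand <- NULL
        write.table(df, tsvPath, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(eimrs)
}
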