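# Motif-enrichment test: observed in-region motif count versus a null
# distribution built from size-matched, randomly placed genomic regions.
# The P value is the one-sided upper tail of a normal approximation using
# the mean and unbiased standard deviation of the simulated sample; the
# add-one empirical tail proportion is reported alongside.

#' Scan a genome for motif hits on both strands
#'
#' In consensus mode every position where the IUPAC consensus matches
#' exactly is reported; in PWM mode every position with log-odds score at
#' or above the model's threshold. Minus-strand hits are reported at their
#' forward-strand coordinates. A window containing `N` never matches.
#' Palindromic motifs yield one hit per strand at the same position.
#'
#' @param genome `DNAStringSet` named by chromosome.
#' @param motif a [MotifModel-class].
#' @return `GRanges` of hits with `strand` set and a `score` column (PWM
#'   mode; `NA` for consensus matches). Warns and returns an empty result
#'   if the motif is wider than every chromosome.
#' @export
scanMotif <- function(genome, motif) {
    validateGenome(genome)
    stopifnot(methods::is(motif, "MotifModel"))
    w <- motifWidth(motif)
    sl <- asSeqlengths(genome)
    if (all(sl < w)) {
        warning("motif wider than every chromosome; no hits possible")
        return(GenomicRanges::GRanges(seqlengths = sl))
    }
    hitList <- list()
    for (chrom in names(genome)) {
        subject <- genome[[chrom]]
        if (length(subject) < w) next
        if (motif@kind == "consensus") {
            fwd <- Biostrings::matchPattern(motif@consensus, subject,
                fixed = FALSE)
            rcCons <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(motif@consensus)))
            rev <- Biostrings::matchPattern(rcCons, subject, fixed = FALSE)
            starts <- c(BiocGenerics::start(fwd), BiocGenerics::start(rev))
            strands <- rep(c("+", "-"), c(length(fwd), length(rev)))
            scores <- rep(NA_real_, length(starts))
        } else {
            # N windows are removed below, so silence the letter warning
            fwd <- suppressWarnings(Biostrings::matchPWM(motif@pwm,
                subject, min.score = motif@threshold, with.score = TRUE))
            rcPwm <- Biostrings::reverseComplement(motif@pwm)
            rev <- suppressWarnings(Biostrings::matchPWM(rcPwm, subject,
                min.score = motif@threshold, with.score = TRUE))
            starts <- c(BiocGenerics::start(fwd), BiocGenerics::start(rev))
            strands <- rep(c("+", "-"), c(length(fwd), length(rev)))
            scores <- c(S4Vectors::mcols(fwd)$score,
                S4Vectors::mcols(rev)$score)
        }
        if (length(starts) == 0L) next
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(starts, width = w),
            strand = strands, score = scores, seqlengths = sl)
        # windows containing N never match
        winSeq <- Biostrings::extractAt(subject,
            IRanges::IRanges(starts, width = w))
        hasN <- Biostrings::vcountPattern("N", winSeq, fixed = TRUE) > 0
        hitList[[chrom]] <- gr[!hasN]
    }
    if (length(hitList) == 0L) {
        return(GenomicRanges::GRanges(seqlengths = sl))
    }
    hits <- unlist(methods::as(hitList, "GRangesList"), use.names = FALSE)
    GenomeInfoDb::seqlevels(hits) <- names(sl)
    GenomeInfoDb::seqlengths(hits) <- sl
    GenomicRanges::sort(hits, ignore.strand = TRUE)
}

#' Count motif hits fully inside a region set
#'
#' A hit is counted when its full footprint lies inside at least one
#' region; hits straddling a region boundary are excluded, and a hit
#' covered by several (possibly duplicated) regions is counted once.
#'
#' @param hits `GRanges` of motif hits (see [scanMotif()]).
#' @param regions `GRanges` of regions.
#' @return Single integer count.
#' @export
countHitsInRegions <- function(hits, regions) {
    stopifnot(methods::is(hits, "GRanges"), methods::is(regions, "GRanges"))
    if (length(hits) == 0L || length(regions) == 0L) {
        return(0L)
    }
    sum(IRanges::overlapsAny(hits, regions, type = "within",
        ignore.strand = TRUE))
}

#' Sample random regions size-matched to an observed set
#'
#' Draws exactly as many regions as observed, with the identical multiset
#' of lengths, each placed uniformly over the genome: the chromosome is
#' chosen with probability proportional to its number of placeable start
#' positions (`length - regionLength + 1`, floored at 0) and the start is
#' uniform among them, so the region always lies entirely within a
#' chromosome. Sampled regions may overlap each other and the observed
#' regions.
#'
#' @param regions observed `GRanges` (only the widths are used) or a
#'   numeric vector of region lengths.
#' @param seqlengths chromosome lengths (named vector, `Seqinfo`, or
#'   `DNAStringSet`).
#' @param seed optional seed for a deterministic draw; `NULL` uses the
#'   current RNG stream.
#' @return `GRanges` of sampled regions, same length multiset as the input.
#' @export
sampleMatchedRegions <- function(regions, seqlengths, seed = NULL) {
    sl <- asSeqlengths(seqlengths)
    lens <- if (methods::is(regions, "GRanges")) {
        GenomicRanges::width(regions)
    } else {
        as.integer(regions)
    }
    if (length(lens) == 0L) {
        return(GenomicRanges::GRanges(seqlengths = sl))
    }
    withSeed(seed, {
        chromOut <- character(length(lens))
        startOut <- integer(length(lens))
        for (L in unique(lens)) {
            placeable <- pmax(sl - L + 1, 0)
            if (sum(placeable) == 0) {
                stop("a region of length ", L,
                    " is longer than every chromosome", call. = FALSE)
            }
            idx <- which(lens == L)
            ci <- sample.int(length(sl), length(idx), replace = TRUE,
                prob = placeable)
            chromOut[idx] <- names(sl)[ci]
            startOut[idx] <- floor(runif(length(idx)) * placeable[ci]) + 1L
        }
        gr <- GenomicRanges::GRanges(chromOut,
            IRanges::IRanges(startOut, width = lens))
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        GenomeInfoDb::seqlengths(gr) <- sl
        gr
    })
}

#' Build the resampling null for in-region motif counts
#'
#' Repeats `B` times: place size-matched random regions with
#' [sampleMatchedRegions()] and count motif hits fully inside them with
#' [countHitsInRegions()]. Summarizes the null with the sample mean and
#' unbiased (n-1) standard deviation, computes the observed count on the
#' real regions, and derives the one-sided normal-approximation and
#' empirical P values.
#'
#' @param regions observed `GRanges` region set.
#' @param hits motif hits from [scanMotif()].
#' @param seqlengths chromosome lengths.
#' @param B number of resampling runs, default 10000.
#' @param seed seed for the resampling stream (recorded in the result).
#' @return A [MotifNull-class].
#' @export
buildNull <- function(regions, hits, seqlengths, B = 10000L, seed = NULL) {
    stopifnot(methods::is(regions, "GRanges"))
    B <- as.integer(B)
    if (B < 2L) stop("B must be >= 2", call. = FALSE)
    sl <- asSeqlengths(seqlengths)
    lens <- GenomicRanges::width(regions)
    cObs <- countHitsInRegions(hits, regions)
    # Fast resampling loop: regions are drawn with the same RNG calls as
    # sampleMatchedRegions() and fixed-width hits are counted against
    # per-chromosome sorted start vectors (deduplicated by hit id, i.e.
    # identical semantics to countHitsInRegions); mixed-width hit sets
    # fall back to the GRanges path.
    hw <- unique(GenomicRanges::width(hits))
    fast <- length(hw) <= 1L
    if (fast) {
        w <- if (length(hw)) hw else 1L
        ord <- order(
            match(as.character(GenomeInfoDb::seqnames(hits)), names(sl)),
            GenomicRanges::start(hits)
        )
        byChrom <- split(
            GenomicRanges::start(hits)[ord],
            factor(as.character(GenomeInfoDb::seqnames(hits))[ord],
                levels = names(sl))
        )
        offs <- cumsum(c(0L, lengths(byChrom)))
    }
    uL <- unique(lens)
    idxByLen <- lapply(uL, function(L) which(lens == L))
    placeableByLen <- lapply(uL, function(L) {
        placeable <- pmax(sl - L + 1, 0)
        if (sum(placeable) == 0) {
            stop("a region of length ", L,
                " is longer than every chromosome", call. = FALSE)
        }
        placeable
    })
    oneRun <- function() {
        chromI <- integer(length(lens))
        st <- integer(length(lens))
        for (j in seq_along(uL)) {
            idx <- idxByLen[[j]]
            placeable <- placeableByLen[[j]]
            ci <- sample.int(length(sl), length(idx), replace = TRUE,
                prob = placeable)
            chromI[idx] <- ci
            st[idx] <- floor(runif(length(idx)) * placeable[ci]) + 1L
        }
        if (fast) {
            ids <- integer(0)
            for (i in seq_along(lens)) {
                v <- byChrom[[chromI[i]]]
                if (length(v) == 0L) next
                lo <- findInterval(st[i] - 1L, v) + 1L
                hi <- findInterval(st[i] + lens[i] - w, v)
                if (hi >= lo) ids <- c(ids, offs[chromI[i]] + lo:hi)
            }
            as.numeric(length(unique(ids)))
        } else {
            rnd <- GenomicRanges::GRanges(
                names(sl)[chromI], IRanges::IRanges(st, width = lens))
            as.numeric(countHitsInRegions(hits, rnd))
        }
    }
    samples <- withSeed(seed, {
        vapply(seq_len(B), function(b) oneRun(), numeric(1))
    })
    mu <- mean(samples)
    sdHat <- sd(samples)
    z <- if (sdHat > 0) (cObs - mu) / sdHat else NA_real_
    pEmp <- (sum(samples >= cObs) + 1) / (B + 1)
    null <- methods::new("MotifNull",
        B = B, samples = samples, observed = as.numeric(cObs),
        mu = mu, sd = sdHat, z = if (is.na(z)) NA_real_ else z,
        pNormal = NA_real_, pEmpirical = pEmp,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
    null@pNormal <- normalPValue(null)
    null
}

#' Normal-approximation enrichment P value
#'
#' One-sided upper-tail probability `1 - Phi((c_obs - mu)/sd)` from the
#' resampled null's mean and unbiased standard deviation. A degenerate
#' null (`sd = 0`) gives `p = 0` when the observed count exceeds the mean
#' and `p = 1` otherwise.
#'
#' @param null a [MotifNull-class].
#' @return The P value.
#' @export
normalPValue <- function(null) {
    stopifnot(methods::is(null, "MotifNull"))
    if (!is.finite(null@sd) || null@sd == 0) {
        return(if (null@observed > null@mu) 0 else 1)
    }
    pnorm((null@observed - null@mu) / null@sd, lower.tail = FALSE)
}

#' Serialize a motif-enrichment result as JSON
#'
#' @param null a [MotifNull-class].
#' @param path output JSON path (`NULL` returns the JSON string).
#' @param samplesTsv optional TSV path for the raw null samples.
#' @return The JSON string, invisibly when written to a file.
#' @export
writeEnrichmentReport <- function(null, path = NULL, samplesTsv = NULL) {
    stopifnot(methods::is(null, "MotifNull"))
    rpt <- list(
        B = null@B,
        seed = if (is.na(null@seed)) NULL else null@seed,
        c_obs = null@observed,
        mu = null@mu,
        sd = null@sd,
        z = null@z,
        p_normal = null@pNormal,
        p_empirical = null@pEmpirical
    )
    json <- jsonlite::toJSON(rpt, auto_unbox = TRUE, digits = NA,
        null = "null")
    if (!is.null(samplesTsv)) {
        write.table(
            data.frame(run = seq_len(null@B), count = null@samples),
            samplesTsv, sep = "\t", quote = FALSE, row.names = FALSE
        )
    }
    if (is.null(path)) {
        return(json)
    }
    writeLines(json, path)
    invisible(json)
}

# ---------------------------------------------------------------------------
# Minimal MEME-format motif I/O
# ---------------------------------------------------------------------------

#' Read a motif from MEME minimal format or a plain IUPAC string
#'
#' Files starting with `MEME version` are parsed as MEME minimal format
#' (first motif, letter-probability matrix, ACGT alphabet); any other
#' single-line file is read as an IUPAC consensus string.
#'
#' @param path motif file.
#' @param threshold PWM score threshold passed to [motifPWM()]; by default
#'   0.8 of the maximum attainable score.
#' @param background background composition for the log-odds conversion.
#' @return A [MotifModel-class].
#' @export
readMotif <- function(path, threshold = 0.8, background = rep(0.25, 4)) {
    assertFileExists(path, "motif file")
    lines <- readLines(path, warn = FALSE)
    if (length(lines) && grepl("^MEME version", lines[1])) {
        return(readMotifMeme(lines, threshold = threshold,
            background = background))
    }
    cons <- trimws(lines[nzchar(trimws(lines))][1])
    motifConsensus(cons, background = background)
}

#' @noRd
readMotifMeme <- function(lines, threshold, background) {
    hdr <- grep("^letter-probability matrix", lines)
    if (length(hdr) == 0L) {
        stop("no letter-probability matrix found in MEME file",
            call. = FALSE)
    }
    hdr <- hdr[1]
    wMatch <- regmatches(lines[hdr],
        regexpr("w= *[0-9]+", lines[hdr]))
    w <- as.integer(sub("w= *", "", wMatch))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(x) {
        as.numeric(strsplit(trimws(x), "[[:space:]]+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    motifPWM(t(mat), threshold = threshold, background = background,
        relative = TRUE)
}

#' Write a PWM motif in MEME minimal format
#'
#' Consensus motifs are written as a 0/1-probability matrix over their
#' unambiguous letters (ambiguous positions share probability equally).
#'
#' @param motif a [MotifModel-class].
#' @param path output file.
#' @param name motif name written in the file.
#' @export
writeMotifMeme <- function(motif, path, name = "motif1") {
    stopifnot(methods::is(motif, "MotifModel"))
    w <- motifWidth(motif)
    if (motif@kind == "consensus") {
        prob <- vapply(strsplit(motif@consensus, "")[[1]], function(l) {
            p <- setNames(numeric(4), c("A", "C", "G", "T"))
            p[IUPAC_SETS[[l]]] <- 1 / length(IUPAC_SETS[[l]])
            p
        }, numeric(4))
    } else {
        # invert log-odds back to probabilities for serialization
        prob <- motif@background * 2^motif@pwm
        prob <- sweep(prob, 2L, colSums(prob), "/")
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "MEME version 4", "",
        "ALPHABET= ACGT", "",
        "strands: + -", "",
        "Background letter frequencies",
        sprintf("A %.5f C %.5f G %.5f T %.5f",
            motif@background[1], motif@background[2],
            motif@background[3], motif@background[4]), "",
        sprintf("MOTIF %s", name),
        sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            w)
    ), con)
    for (j in seq_len(w)) {
        writeLines(sprintf(" %.6f %.6f %.6f %.6f",
            prob[1, j], prob[2, j], prob[3, j], prob[4, j]), con)
    }
    invisible(path)
}
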