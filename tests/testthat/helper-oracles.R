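# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (base enumeration, position-by-position scanning) and
# share no code with the package functions they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

# Build a GRanges from BED-style (0-based half-open) coordinates, the
# convention used throughout the tests because inputs arrive as BED.
bedGR <- function(chrom, start, end, ...) {
    if (length(start) == 0L) {
        return(GRanges())
    }
    GRanges(rep(chrom, length.out = length(start)),
        IRanges(start + 1L, end), ...)
}

# Brute-force overlap oracle: enumerate covered bases of both intervals
# (BED coordinates) and intersect.
bruteOverlap <- function(chromA, startA, endA, chromB, startB, endB) {
    if (chromA != chromB) {
        return(FALSE)
    }
    basesA <- seq.int(startA, endA - 1L)
    basesB <- seq.int(startB, endB - 1L)
    length(intersect(basesA, basesB)) >= 1L
}

# Naive position-by-position motif scanner over a character sequence.
iupacSets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcompChar <- function(s) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
        "")[[1]]), collapse = "")
}

naiveScanOne <- function(seqChar, pattern) {
    # forward-strand starts (1-based) where the IUPAC pattern matches and
    # no N is present in the window
    letters <- strsplit(seqChar, "")[[1]]
    pat <- strsplit(pattern, "")[[1]]
    w <- length(pat)
    L <- length(letters)
    if (L < w) {
        return(integer())
    }
    hits <- integer()
    for (s in seq_len(L - w + 1L)) {
        win <- letters[s:(s + w - 1L)]
        if (any(win == "N")) next
        ok <- TRUE
        for (j in seq_len(w)) {
            if (!win[j] %in% iupacSets[[pat[j]]]) {
                ok <- FALSE
                break
            }
        }
        if (ok) hits <- c(hits, s)
    }
    hits
}

naiveScanConsensus <- function(genome, consensus) {
    # both strands; returns data.frame(chrom, start, strand), 1-based
    out <- list()
    for (chrom in names(genome)) {
        seqChar <- as.character(genome[[chrom]])
        fwd <- naiveScanOne(seqChar, consensus)
        rev <- naiveScanOne(seqChar, revcompChar(consensus))
        n <- length(fwd) + length(rev)
        if (n == 0L) next
        out[[chrom]] <- data.frame(
            chrom = rep(chrom, n), start = c(fwd, rev),
            strand = rep(c("+", "-"), c(length(fwd), length(rev)))
        )
    }
    df <- do.call(rbind, out)
    if (is.null(df)) {
        return(data.frame(chrom = character(), start = integer(),
            strand = character()))
    }
    df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

naiveScanPWM <- function(genome, pwm, threshold) {
    scoreAt <- function(letters, s, mat) {
        w <- ncol(mat)
        win <- letters[s:(s + w - 1L)]
        if (any(win == "N")) {
            return(-Inf)
        }
        sum(mat[cbind(match(win, c("A", "C", "G", "T")), seq_len(w))])
    }
    rcPwm <- pwm[4:1, ncol(pwm):1]
    rownames(rcPwm) <- c("A", "C", "G", "T")
    out <- list()
    for (chrom in names(genome)) {
        letters <- strsplit(as.character(genome[[chrom]]), "")[[1]]
        L <- length(letters)
        w <- ncol(pwm)
        if (L < w) next
        rows <- list()
        for (s in seq_len(L - w + 1L)) {
            if (scoreAt(letters, s, pwm) >= threshold) {
                rows[[length(rows) + 1L]] <-
                    data.frame(chrom = chrom, start = s, strand = "+")
            }
            if (scoreAt(letters, s, rcPwm) >= threshold) {
                rows[[length(rows) + 1L]] <-
                    data.frame(chrom = chrom, start = s, strand = "-")
            }
        }
        out[[chrom]] <- do.call(rbind, rows)
    }
    df <- do.call(rbind, out)
    if (is.null(df)) {
        return(data.frame(chrom = character(), start = integer(),
            strand = character()))
    }
    df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

hitsAsDf <- function(hits) {
    df <- data.frame(
        chrom = as.character(seqnames(hits)),
        start = start(hits),
        strand = as.character(strand(hits))
    )
    df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

randomGenome <- function(sizes, seed) {
    set.seed(seed)
    seqs <- vapply(sizes, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, character(1))
    g <- DNAStringSet(seqs)
    names(g) <- names(sizes)
    g
}

# A lane built directly from BED-style tag positions.
laneFromBed <- function(chrom, bedStarts, total = length(bedStarts),
                        condition = "lane",
                        seqlengths = NULL) {
    gr <- bedGR(chrom, bedStarts, bedStarts + 1L)
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    TagLane(gr, condition = condition, laneTotal = total)
}

# Small simulation config used by unit tests where full default scale is
# unnecessary (the acceptance tests use the defaults).
smallSimConfig <- function() {
    peakStarts <- seq(5000L, by = 12000L, length.out = 8L)
    simConfig(
        seqlengths = c(chrA = 100000, chrB = 100000),
        peaks = data.frame(
            chrom = rep(c("chrA", "chrB"), each = 8L),
            start = rep(peakStarts, 2L),
            end = rep(peakStarts + 800L, 2L),
            ratio = rep(c(3, 1), 8L)
        ),
        nBackgroundMotifs = 40L,
        nInRegionMotifs = 15L
    )
}
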