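# Genomic coordinate model and format I/O. Intervals are GRanges (1-based,
# closed, the Bioconductor convention); BED files are converted at the
# boundary by rtracklayer so half-open 0-based BED semantics are preserved
# on disk. The "overlap" rule used throughout is sharing of at least 1 bp.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome. Only
#'   `A/C/G/T/N` letters are accepted.
#' @export
readGenomeFasta <- function(path) {
    assertFileExists(path, "genome FASTA")
    genome <- Biostrings::readDNAStringSet(path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    validateGenome(genome)
    genome
}

#' Write a genome FASTA
#'
#' @param genome `DNAStringSet` named by chromosome.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    validateGenome(genome)
    Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
    invisible(path)
}

#' @noRd
validateGenome <- function(genome) {
    if (!methods::is(genome, "DNAStringSet")) {
        stop("genome must be a DNAStringSet", call. = FALSE)
    }
    if (length(genome) == 0L || any(Biostrings::width(genome) == 0L)) {
        stop("all genome sequences must be non-empty", call. = FALSE)
    }
    if (is.null(names(genome)) || anyDuplicated(names(genome))) {
        stop("genome sequences must have unique names", call. = FALSE)
    }
    freq <- Biostrings::alphabetFrequency(genome)
    other <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"),
        drop = FALSE])
    if (any(other > 0)) {
        stop("genome alphabet is restricted to A/C/G/T/N", call. = FALSE)
    }
    invisible(genome)
}

#' Read and write two-column chrom.sizes files
#'
#' `readChromSizes()` returns a named numeric vector of chromosome lengths;
#' `writeChromSizes()` writes one, tab-separated and newline-terminated.
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    assertFileExists(path, "chrom.sizes file")
    tab <- read.table(path, sep = "\t", header = FALSE,
        col.names = c("chrom", "size"),
        colClasses = c("character", "numeric"))
    if (anyDuplicated(tab$chrom)) {
        stop("duplicated chromosome names in ", path, call. = FALSE)
    }
    setNames(tab$size, tab$chrom)
}

#' @rdname readChromSizes
#' @param sizes named numeric vector of chromosome lengths.
#' @export
writeChromSizes <- function(sizes, path) {
    sizes <- asSeqlengths(sizes)
    write.table(
        data.frame(chrom = names(sizes), size = as.integer(sizes)),
        file = path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Read intervals from a BED file
#'
#' Thin wrapper over [rtracklayer::import.bed()]; BED's 0-based half-open
#' records become 1-based closed `GRanges`.
#'
#' @param path BED3/BED6 file.
#' @param seqlengths optional named vector (or `Seqinfo`/`DNAStringSet`)
#'   attaching chromosome lengths to the result.
#' @return A `GRanges`.
#' @export
readBedRegions <- function(path, seqlengths = NULL) {
    assertFileExists(path, "BED file")
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(seqlengths)) {
        sl <- asSeqlengths(seqlengths)
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        GenomeInfoDb::seqlengths(gr) <- sl
    }
    gr
}

#' Write intervals to a BED file
#'
#' @param gr `GRanges`, optionally with `name` and `score` metadata columns.
#' @param path output file.
#' @export
writeBedRegions <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Export per-base tag coverage as bedGraph
#'
#' @param lane a [TagLane-class].
#' @param path output bedGraph file.
#' @export
writeTagCoverage <- function(lane, path) {
    cov <- GenomicRanges::coverage(tagPositions(lane))
    gr <- GenomicRanges::GRanges(cov)
    gr <- gr[gr$score > 0]
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a tag lane from BED plus a lane total
#'
#' Tags are stored in BED files as 1-bp intervals holding the 5' position of
#' each uniquely mapped read.
#'
#' @param path tag BED file.
#' @param laneTotal total uniquely mapped reads for the lane (may exceed the
#'   number of stored tags).
#' @param condition condition label.
#' @param seqlengths optional chromosome lengths for bounds checking.
#' @return A [TagLane-class].
#' @export
readTagLane <- function(path, laneTotal, condition,
                        seqlengths = NULL) {
    gr <- readBedRegions(path, seqlengths = seqlengths)
    TagLane(gr, condition = condition, laneTotal = laneTotal)
}

#' Read lane totals from a two-column TSV
#'
#' Expected format: `condition<TAB>N_lane`, no header.
#'
#' @param path TSV file.
#' @return Named numeric vector of lane totals keyed by condition.
#' @export
readLaneTotals <- function(path) {
    assertFileExists(path, "lane totals TSV")
    tab <- read.table(path, sep = "\t", header = FALSE,
        col.names = c("condition", "total"),
        colClasses = c("character", "numeric"))
    if (any(tab$total <= 0)) {
        stop("lane totals must be positive in ", path, call. = FALSE)
    }
    setNames(tab$total, tab$condition)
}

#' Do two intervals overlap by at least one base?
#'
#' Two regions are considered to overlap when they share at least 1 bp on
#' the same chromosome. Strand is ignored. Vectorized over pairs (the two
#' `GRanges` are recycled to a common length and compared element-wise).
#'
#' @param a,b `GRanges` of equal (or recyclable) length.
#' @return Logical vector.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' intervalOverlap(a, b)  # TRUE: positions 200 are shared
#' @export
intervalOverlap <- function(a, b) {
    stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
    n <- max(length(a), length(b))
    if (length(a) != n) a <- rep(a, length.out = n)
    if (length(b) != n) b <- rep(b, length.out = n)
    sameChrom <- as.character(GenomeInfoDb::seqnames(a)) ==
        as.character(GenomeInfoDb::seqnames(b))
    sameChrom &
        GenomicRanges::start(a) <= GenomicRanges::end(b) &
        GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Read a TSS annotation
#'
#' Transcription start sites as width-1 BED intervals with the gene or
#' transcript identifier in the name column. Duplicated gene ids are
#' allowed (internal TSSs).
#'
#' @param path BED file of width-1 TSS records.
#' @return `GRanges` of width-1 sites with a `gene_id` metadata column.
#' @export
readTssAnnotation <- function(path) {
    gr <- readBedRegions(path)
    if (length(gr) == 0L) stop("TSS annotation is empty", call. = FALSE)
    if (any(GenomicRanges::width(gr) != 1L)) {
        stop("TSS records must have width 1", call. = FALSE)
    }
    gene <- if (!is.null(gr$name)) gr$name else paste0("tss_", seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = gene)
    gr
}

#' Nearest TSS for each region
#'
#' For every query region, finds the annotated transcription start site
#' minimizing the distance to the region. A TSS inside the region has
#' distance 0; otherwise the distance is signed and measured between BED
#' (0-based half-open) coordinates: negative `p - start` for a TSS upstream
#' of the region start, positive `p - end` for one downstream of the region
#' end. Ties are broken by the smaller TSS coordinate, then by
#' lexicographic gene id. Regions on chromosomes with no annotated TSS are
#' flagged `"unannotated"` with `NA` distance rather than raising an error.
#'
#' @param regions `GRanges` of query regions.
#' @param tss `GRanges` of width-1 sites with a `gene_id` metadata column
#'   (see [readTssAnnotation()]).
#' @return `data.frame` with columns `gene_id` and `distance`, one row per
#'   region.
#' @export
nearestTss <- function(regions, tss) {
    stopifnot(methods::is(regions, "GRanges"), methods::is(tss, "GRanges"))
    if (length(tss) == 0L) stop("TSS annotation is empty", call. = FALSE)
    if (is.null(tss$gene_id)) {
        stop("TSS annotation needs a 'gene_id' metadata column",
            call. = FALSE)
    }
    tssChrom <- as.character(GenomeInfoDb::seqnames(tss))
    tssPos <- GenomicRanges::start(tss)
    gene <- as.character(tss$gene_id)
    out <- data.frame(
        gene_id = rep(NA_character_, length(regions)),
        distance = rep(NA_real_, length(regions)),
        stringsAsFactors = FALSE
    )
    regChrom <- as.character(GenomeInfoDb::seqnames(regions))
    for (i in seq_along(regions)) {
        onChrom <- tssChrom == regChrom[i]
        if (!any(onChrom)) {
            out$gene_id[i] <- "unannotated"
            next
        }
        p <- tssPos[onChrom]
        g <- gene[onChrom]
        s <- GenomicRanges::start(regions)[i]
        e <- GenomicRanges::end(regions)[i]
        # BED-space signed distance: 0 inside, p-start upstream, p-end down
        d <- ifelse(p < s, p - s, ifelse(p > e, p - 1L - e, 0))
        ord <- order(abs(d), p, g)
        best <- ord[1L]
        out$gene_id[i] <- g[best]
        out$distance[i] <- d[best]
    }
    out
}
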