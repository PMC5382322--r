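# Deterministic generators for every input shape the analyses consume:
# a toy genome with planted motif instances, two-condition Poisson tag
# lanes with spiked enriched regions of known induction ratio, triplicate
# Ct tables, MNase protection tables, and one-phase remodelling time
# courses -- each returned together with its ground truth and fully
# determined by (config, seed).

#' Default synthetic-study configuration
#'
#' The default scale is a toy study that runs in seconds: two 500 kb
#' chromosomes, 40 planted peaks of 1 kb (20 hormone-induced at
#' normalized ratio 3.0 and 20 unchanged at 1.0), roughly 1e5 tags per
#' lane over a background rate of 0.1 tags/bp, a 12 bp nuclear-receptor
#' style consensus motif planted preferentially inside induced regions,
#' triplicate qPCR tables with Ct noise sd 0.2, four-replicate REA time
#' courses at 2.5/5/10/20 min with percent-cut noise sd 2, and a
#' two-region MNase design with 80% and 20% protection loss.
#'
#' @param ... named overrides of any configuration entry.
#' @return A named list of generator settings.
#' @export
simConfig <- function(...) {
    sl <- c(chrA = 500000, chrB = 500000)
    peakStarts <- seq(20000L, by = 24000L, length.out = 20L)
    peaks <- data.frame(
        chrom = rep(c("chrA", "chrB"), each = 20L),
        start = rep(peakStarts, 2L),             # BED-style 0-based
        end = rep(peakStarts + 1000L, 2L),
        ratio = rep(c(3, 1), 20L)
    )
    cfg <- list(
        seqlengths = sl,
        gc = 0.43,
        peaks = peaks,
        backgroundRate = 0.1,
        minusEnrichment = 4,
        outOfAnalysisFraction = 0.25,
        motif = "RGGTCANTGACC",
        nBackgroundMotifs = 150L,
        nInRegionMotifs = 60L,
        ctTruth = data.frame(
            sample = rep(c("GFP RNAi", "dMi-2 RNAi"), each = 3L),
            gene = rep(c("Br-C", "vri", "Hr4"), 2L),
            rel = c(1, 1, 1, 10, 2.5, 2.5)
        ),
        ctNoiseSd = 0.2,
        ctReplicates = 3L,
        reaTruth = data.frame(
            condition = c("dMi-2", "dMi-2+EcR", "EcR"),
            y0 = c(5, 5, 5),
            plateau = c(40, 80, 8),
            k = c(0.08, 0.2, 0.05)
        ),
        reaTimes = c(2.5, 5, 10, 20),
        reaNoiseSd = 2,
        reaReplicates = 4L,
        mnaseTruth = data.frame(
            region = rep(c("vri_A", "vri_D"), each = 2L),
            sample = rep(c("GFP RNAi", "dMi-2 RNAi"), 2L),
            protection = c(1, 0.2, 1, 0.8)
        ),
        mnaseNoiseSd = 0.1
    )
    override <- list(...)
    if (length(override)) {
        bad <- setdiff(names(override), names(cfg))
        if (length(bad)) {
            stop("unknown config entries: ", paste(bad, collapse = ", "),
                call. = FALSE)
        }
        cfg[names(override)] <- override
    }
    cfg
}

#' @noRd
peaksAsGRanges <- function(peaks, seqlengths) {
    gr <- GenomicRanges::GRanges(
        peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
    )
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    gr$ratio <- peaks$ratio
    gr
}

#' Generate a toy genome with planted motif instances
#'
#' Background sequence is i.i.d. with the requested GC content; exact
#' motif instances (the consensus with ambiguous letters resolved at
#' random, written on a random strand) are planted at non-overlapping
#' recorded positions, `nInRegion` uniformly inside the supplied regions
#' and `nBackground` entirely outside them.
#'
#' @param seqlengths named chromosome lengths.
#' @param motif a [MotifModel-class] or IUPAC string.
#' @param nBackground,nInRegion numbers of planted instances.
#' @param regions `GRanges` the in-region instances must fall inside
#'   (needed when `nInRegion > 0`).
#' @param gc genomic GC content, default 0.43.
#' @param seed RNG seed.
#' @return A list with `genome` (`DNAStringSet`) and `truth`
#'   (`data.frame` of planted chrom/start/strand/inRegion, 1-based
#'   starts). Errors if the requested placements do not fit.
#' @export
makeGenome <- function(seqlengths, motif, nBackground = 0L,
                       nInRegion = 0L, regions = NULL, gc = 0.43,
                       seed = NULL) {
    sl <- asSeqlengths(seqlengths)
    if (is.character(motif)) motif <- motifConsensus(motif)
    w <- motifWidth(motif)
    if (nInRegion > 0 && is.null(regions)) {
        stop("'regions' required when planting in-region motifs",
            call. = FALSE)
    }
    withSeed(seed, {
        baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
            T = (1 - gc) / 2)
        seqs <- lapply(sl, function(len) {
            sample(names(baseProb), len, replace = TRUE, prob = baseProb)
        })
        instance <- function() {
            letters <- strsplit(
                if (motif@kind == "consensus") motif@consensus else
                    paste(rownames(motif@pwm)[apply(motif@pwm, 2L,
                        which.max)], collapse = ""),
                "")[[1]]
            vapply(letters, function(l) {
                set <- IUPAC_SETS[[l]]
                set[sample.int(length(set), 1L)]
            }, character(1), USE.NAMES = FALSE)
        }
        # per-chromosome start positions already taken (plain vectors,
        # kept cheap because placement is rejection-sampled)
        placedStarts <- lapply(sl, function(x) integer())
        regChrom <- if (!is.null(regions)) {
            as.character(GenomeInfoDb::seqnames(regions))
        }
        regStart <- if (!is.null(regions)) GenomicRanges::start(regions)
        regEnd <- if (!is.null(regions)) GenomicRanges::end(regions)
        placeOne <- function(inRegion) {
            for (attempt in seq_len(2000L)) {
                if (inRegion) {
                    ww <- GenomicRanges::width(regions) - w + 1L
                    ok <- which(ww > 0)
                    if (length(ok) == 0L) break
                    ri <- ok[sample.int(length(ok), 1L, prob = ww[ok])]
                    chrom <- regChrom[ri]
                    s <- regStart[ri] + sample.int(ww[ri], 1L) - 1L
                } else {
                    placeable <- pmax(sl - w + 1, 0)
                    ci <- sample.int(length(sl), 1L, prob = placeable)
                    chrom <- names(sl)[ci]
                    s <- sample.int(placeable[ci], 1L)
                }
                e <- s + w - 1L
                if (!inRegion && !is.null(regions) &&
                    any(regChrom == chrom & regStart <= e &
                        s <= regEnd)) {
                    next
                }
                prev <- placedStarts[[chrom]]
                if (length(prev) && any(abs(prev - s) < w)) next
                return(list(chrom = chrom, start = s))
            }
            stop("requested motif placements exceed available space",
                call. = FALSE)
        }
        n <- nBackground + nInRegion
        flags <- rep(c(TRUE, FALSE), c(nInRegion, nBackground))
        truth <- data.frame(
            chrom = character(n), start = integer(n),
            strand = character(n), inRegion = flags
        )
        for (i in seq_len(n)) {
            cand <- placeOne(flags[i])
            chrom <- cand$chrom
            s <- cand$start
            placedStarts[[chrom]] <- c(placedStarts[[chrom]], s)
            strand <- sample(c("+", "-"), 1L)
            inst <- instance()
            if (strand == "-") {
                inst <- rev(chartr("ACGT", "TGCA", inst))
            }
            seqs[[chrom]][s:(s + w - 1L)] <- inst
            truth$chrom[i] <- chrom
            truth$start[i] <- s
            truth$strand[i] <- strand
        }
        genome <- Biostrings::DNAStringSet(
            vapply(seqs, paste, character(1), collapse = "")
        )
        names(genome) <- names(sl)
        list(genome = genome, truth = truth)
    })
}

#' Simulate two-condition ChIP tag lanes with spiked peaks
#'
#' Background tags are Poisson over each chromosome with uniform
#' positions; every planted peak receives additional Poisson tags per
#' condition. The treated-lane peak means are calibrated against the
#' expected lane totals (which themselves depend on the spiked tags) so
#' that the expected *normalized* treated/untreated ratio of every peak
#' equals its configured truth. Lane totals are the generated tag counts
#' inflated by an out-of-analysis fraction, mimicking uniquely mapped
#' reads that fall outside the analysed regions.
#'
#' @param seqlengths named chromosome lengths.
#' @param peaks `GRanges` with a `ratio` metadata column (true normalized
#'   induction ratio, `>= 1`), or a `data.frame` with BED-style
#'   `chrom/start/end/ratio` columns.
#' @param backgroundRate background tag rate per bp per lane.
#' @param minusEnrichment fold enrichment of spiked tags over background
#'   inside peaks in the untreated lane.
#' @param outOfAnalysisFraction fraction by which lane totals exceed the
#'   stored tag counts.
#' @param seed RNG seed.
#' @return A list with `minus` and `plus` ([TagLane-class]) and `truth`
#'   (per-peak expected counts and true ratios plus the lane-total scale
#'   factor).
#' @export
simulateTagLanes <- function(seqlengths, peaks, backgroundRate = 0.1,
                             minusEnrichment = 4,
                             outOfAnalysisFraction = 0.25, seed = NULL) {
    sl <- asSeqlengths(seqlengths)
    if (is.data.frame(peaks)) peaks <- peaksAsGRanges(peaks, sl)
    stopifnot(methods::is(peaks, "GRanges"))
    ratio <- peaks$ratio
    if (is.null(ratio) || any(ratio < 1)) {
        stop("peaks need a 'ratio' metadata column with values >= 1",
            call. = FALSE)
    }
    assertScalarNumber(backgroundRate, "backgroundRate", 0, strict = TRUE)
    wPk <- GenomicRanges::width(peaks)
    r <- backgroundRate
    mMean <- (1 + minusEnrichment) * r * wPk       # minus in-peak mean
    A <- sum(sl) * r - sum(r * wPk)
    M <- sum(mMean)
    Q <- sum(ratio * mMean)
    s <- A / (A + M - Q)                            # E[N+]/E[N-]
    pMean <- ratio * mMean * s                      # plus in-peak mean
    extraMinus <- mMean - r * wPk
    extraPlus <- pMean - r * wPk
    if (any(extraPlus < -1e-9)) {
        stop("infeasible enrichment configuration", call. = FALSE)
    }
    extraPlus <- pmax(extraPlus, 0)
    withSeed(seed, {
        drawLane <- function(extras, condition) {
            posList <- lapply(names(sl), function(chrom) {
                n <- rpois(1L, r * sl[[chrom]])
                if (n == 0L) return(integer())
                sample.int(sl[[chrom]], n, replace = TRUE)
            })
            names(posList) <- names(sl)
            for (i in seq_along(peaks)) {
                nE <- rpois(1L, extras[i])
                if (nE == 0L) next
                chrom <- as.character(GenomeInfoDb::seqnames(peaks)[i])
                posList[[chrom]] <- c(
                    posList[[chrom]],
                    GenomicRanges::start(peaks)[i] +
                        sample.int(wPk[i], nE, replace = TRUE) - 1L
                )
            }
            gr <- GenomicRanges::GRanges(
                rep(names(posList), lengths(posList)),
                IRanges::IRanges(unlist(posList, use.names = FALSE),
                    width = 1L)
            )
            GenomeInfoDb::seqlevels(gr) <- names(sl)
            GenomeInfoDb::seqlengths(gr) <- sl
            gr <- GenomicRanges::sort(gr)
            TagLane(gr, condition = condition,
                laneTotal = round(length(gr) *
                    (1 + outOfAnalysisFraction)))
        }
        minus <- drawLane(extraMinus, "minus")
        plus <- drawLane(extraPlus, "plus")
        truth <- data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(peaks)),
            start = GenomicRanges::start(peaks) - 1L,
            end = GenomicRanges::end(peaks),
            trueRatio = ratio,
            expectedMinus = mMean,
            expectedPlus = pMean
        )
        attr(truth, "laneScale") <- s
        list(minus = minus, plus = plus, truth = truth)
    })
}

#' Simulate a qPCR Ct table from known expression levels
#'
#' `Ct_target = ctBase - log2(rel) + N(0, sd)` per replicate; the
#' reference gene is constant up to the same noise. With `sd = 0` the
#' table inverts exactly through [ddct()].
#'
#' @param truth `data.frame` with columns `sample`, `gene`, `rel` (true
#'   expression relative to the calibrator sample, `> 0`).
#' @param reference reference-gene label added to every sample.
#' @param sd Ct noise standard deviation (cycles).
#' @param replicates wells per (sample, gene).
#' @param ctBase Ct of a gene at `rel = 1`.
#' @param refCt Ct of the reference gene.
#' @param seed RNG seed.
#' @return A list with `records` (the Ct table) and `truth`.
#' @export
simulateCtTable <- function(truth, reference = "rp49", sd = 0.2,
                            replicates = 3L, ctBase = 24, refCt = 16,
                            seed = NULL) {
    stopifnot(all(c("sample", "gene", "rel") %in% names(truth)),
        all(truth$rel > 0), replicates >= 1L)
    withSeed(seed, {
        rows <- truth[rep(seq_len(nrow(truth)), each = replicates), ]
        rows$replicate <- rep(seq_len(replicates), nrow(truth))
        rows$ct <- ctBase - log2(rows$rel) +
            rnorm(nrow(rows), 0, sd)
        rows$rel <- NULL
        samples <- unique(truth$sample)
        ref <- data.frame(
            sample = rep(samples, each = replicates),
            gene = reference,
            replicate = rep(seq_len(replicates), length(samples)),
            ct = refCt + rnorm(length(samples) * replicates, 0, sd)
        )
        records <- rbind(rows, ref)
        rownames(records) <- NULL
        list(records = records, truth = truth)
    })
}

#' Simulate REA remodelling time courses
#'
#' Percent-cut values follow the one-phase model plus Gaussian noise,
#' clipped to `[0, 100]`, and are emitted as `(cut, uncut)` band
#' intensities with `cut + uncut = 100` so [percentCut()] inverts the
#' construction exactly.
#'
#' @param truth `data.frame` with columns `condition`, `y0`, `plateau`,
#'   `k` (`0 <= y0 <= plateau <= 100`, `k > 0`).
#' @param times time points in minutes.
#' @param sd percent-cut noise standard deviation.
#' @param replicates independent time courses per condition.
#' @param seed RNG seed.
#' @return A list with `records` (condition, replicate, time_min, cut,
#'   uncut, pct) and `truth`.
#' @export
simulateRea <- function(truth, times = c(2.5, 5, 10, 20), sd = 2,
                        replicates = 4L, seed = NULL) {
    stopifnot(all(c("condition", "y0", "plateau", "k") %in% names(truth)),
        all(truth$y0 >= 0), all(truth$y0 <= truth$plateau),
        all(truth$plateau <= 100), all(truth$k > 0))
    withSeed(seed, {
        grid <- expand.grid(
            i = seq_len(nrow(truth)), replicate = seq_len(replicates),
            time_min = times, KEEP.OUT.ATTRS = FALSE
        )
        tr <- truth[grid$i, ]
        pct <- tr$y0 + (tr$plateau - tr$y0) *
            (1 - exp(-tr$k * grid$time_min))
        pct <- pmin(pmax(pct + rnorm(nrow(grid), 0, sd), 0), 100)
        records <- data.frame(
            condition = tr$condition,
            replicate = grid$replicate,
            time_min = grid$time_min,
            cut = pct, uncut = 100 - pct, pct = pct
        )
        records <- records[order(records$condition, records$replicate,
            records$time_min), ]
        rownames(records) <- NULL
        list(records = records, truth = truth)
    })
}

#' Simulate an MNase protection qPCR table
#'
#' `Ct_digested = Ct_undigested - log2(protection) + N(0, sd)`; noiseless
#' tables invert exactly through [mnaseProtection()] provided each
#' region's maximum true protection is 1.
#'
#' @param truth `data.frame` with columns `region`, `sample`,
#'   `protection` in `(0, 1]`.
#' @param sd Ct noise standard deviation.
#' @param undigestedCt baseline Ct of the undigested sample.
#' @param seed RNG seed.
#' @return A list with `records` (region, sample, ct_digested,
#'   ct_undigested) and `truth`.
#' @export
simulateMnase <- function(truth, sd = 0.1, undigestedCt = 20,
                          seed = NULL) {
    stopifnot(all(c("region", "sample", "protection") %in% names(truth)),
        all(truth$protection > 0), all(truth$protection <= 1))
    withSeed(seed, {
        records <- data.frame(
            region = truth$region,
            sample = truth$sample,
            ct_digested = undigestedCt - log2(truth$protection) +
                rnorm(nrow(truth), 0, sd),
            ct_undigested = undigestedCt
        )
        list(records = records, truth = truth)
    })
}

#' Generate and write a complete synthetic study
#'
#' Produces every input file the pipeline stages consume -- genome FASTA,
#' chrom.sizes, per-condition tag BEDs, lane totals, candidate peak BED,
#' motif (MEME and IUPAC), Ct table, REA table, MNase table -- plus
#' `truth.json` recording all planted ground truth and the seed. Output
#' is a deterministic function of (config, seed).
#'
#' @param outdir output directory (created if needed).
#' @param config a [simConfig()] list.
#' @param seed master seed.
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory truth.
#' @export
writeSimulation <- function(outdir, config = simConfig(), seed = 1L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sl <- asSeqlengths(config$seqlengths)
    peaks <- peaksAsGRanges(config$peaks, sl)
    induced <- peaks[peaks$ratio > 1]
    motif <- motifConsensus(config$motif)
    withSeed(seed, {
        gen <- makeGenome(sl, motif,
            nBackground = config$nBackgroundMotifs,
            nInRegion = config$nInRegionMotifs,
            regions = induced, gc = config$gc, seed = NULL)
        lanes <- simulateTagLanes(sl, peaks,
            backgroundRate = config$backgroundRate,
            minusEnrichment = config$minusEnrichment,
            outOfAnalysisFraction = config$outOfAnalysisFraction,
            seed = NULL)
        ct <- simulateCtTable(config$ctTruth, sd = config$ctNoiseSd,
            replicates = config$ctReplicates, seed = NULL)
        rea <- simulateRea(config$reaTruth, times = config$reaTimes,
            sd = config$reaNoiseSd, replicates = config$reaReplicates,
            seed = NULL)
        mnase <- simulateMnase(config$mnaseTruth,
            sd = config$mnaseNoiseSd, seed = NULL)
        paths <- list(
            genome = file.path(outdir, "genome.fa"),
            chromSizes = file.path(outdir, "chrom.sizes"),
            tagsMinus = file.path(outdir, "tags_minus.bed"),
            tagsPlus = file.path(outdir, "tags_plus.bed"),
            totals = file.path(outdir, "totals.tsv"),
            peaks = file.path(outdir, "peaks.bed"),
            motifMeme = file.path(outdir, "motif.meme"),
            motifIupac = file.path(outdir, "motif.txt"),
            ct = file.path(outdir, "ct.tsv"),
            rea = file.path(outdir, "rea.tsv"),
            mnase = file.path(outdir, "mnase.tsv"),
            truth = file.path(outdir, "truth.json")
        )
        writeGenomeFasta(gen$genome, paths$genome)
        writeChromSizes(sl, paths$chromSizes)
        writeBedRegions(tagPositions(lanes$minus), paths$tagsMinus)
        writeBedRegions(tagPositions(lanes$plus), paths$tagsPlus)
        write.table(
            data.frame(
                condition = c("minus", "plus"),
                total = c(laneTotal(lanes$minus), laneTotal(lanes$plus))
            ),
            paths$totals, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE
        )
        pk <- GenomicRanges::granges(peaks)
        pk$name <- sprintf("peak_%04d", seq_along(pk))
        writeBedRegions(pk, paths$peaks)
        writeMotifMeme(motif, paths$motifMeme)
        writeLines(config$motif, paths$motifIupac)
        write.table(ct$records, paths$ct, sep = "\t", quote = FALSE,
            row.names = FALSE)
        write.table(rea$records, paths$rea, sep = "\t", quote = FALSE,
            row.names = FALSE)
        write.table(mnase$records, paths$mnase, sep = "\t",
            quote = FALSE, row.names = FALSE)
        truth <- list(
            seed = seed,
            peaks = lanes$truth,
            laneScale = attr(lanes$truth, "laneScale"),
            laneTotals = list(minus = laneTotal(lanes$minus),
                plus = laneTotal(lanes$plus)),
            motif = config$motif,
            motifInstances = transform(gen$truth, start = start - 1L),
            ct = ct$truth,
            rea = rea$truth,
            mnase = mnase$truth
        )
        jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
            digits = NA, dataframe = "rows")
        invisible(c(paths, list(truthData = truth)))
    })
}
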