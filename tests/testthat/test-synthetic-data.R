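# Determinism, ground-truth fidelity, and statistical calibration of the
# synthetic-data generators.

test_that("generators are deterministic functions of (config, seed)", {
    cfg <- smallSimConfig()
    d1 <- tempfile()
    d2 <- tempfile()
    writeSimulation(d1, cfg, seed = 5)
    writeSimulation(d2, cfg, seed = 5)
    for (f in c("genome.fa", "chrom.sizes", "tags_minus.bed",
        "tags_plus.bed", "totals.tsv", "peaks.bed", "ct.tsv",
        "rea.tsv", "mnase.tsv", "truth.json")) {
        expect_identical(
            unname(tools::md5sum(file.path(d1, f))),
            unname(tools::md5sum(file.path(d2, f))),
            info = f
        )
    }
    # a different seed changes the stochastic outputs
    d3 <- tempfile()
    writeSimulation(d3, cfg, seed = 6)
    expect_false(identical(
        unname(tools::md5sum(file.path(d1, "genome.fa"))),
        unname(tools::md5sum(file.path(d3, "genome.fa")))
    ))
    unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("planted motifs are placed as recorded and scannable", {
    cfg <- smallSimConfig()
    peaks <- bedGR(cfg$peaks$chrom, cfg$peaks$start, cfg$peaks$end)
    induced <- peaks[cfg$peaks$ratio > 1]
    gen <- makeGenome(cfg$seqlengths, cfg$motif, nBackground = 25,
        nInRegion = 20, regions = induced, seed = 31)
    expect_identical(sum(gen$truth$inRegion), 20L)
    w <- nchar(cfg$motif)
    planted <- GRanges(gen$truth$chrom,
        IRanges(gen$truth$start, width = w))
    # in-region flags are truthful
    inReg <- IRanges::overlapsAny(planted, induced, type = "within")
    expect_identical(inReg, gen$truth$inRegion)
    # every planted instance is found by the scanner
    hits <- scanMotif(gen$genome, motifConsensus(cfg$motif))
    expect_true(all(countOverlaps(planted, hits, type = "equal") > 0))
    # placements never overlap each other
    expect_identical(
        sum(countOverlaps(planted, planted) > 1), 0L)
})

test_that("background-only genomes match the random-hit expectation", {
    # exact consensus with unambiguous letters: per-position match
    # probability is prod(p_base); expectation = 2 strands * sum over
    # placeable positions
    sizes <- c(c1 = 60000, c2 = 60000)
    cons <- "ACGTAC"
    counts <- vapply(1:8, function(s) {
        gen <- makeGenome(sizes, cons, nBackground = 0, nInRegion = 0,
            gc = 0.5, seed = 400 + s)
        length(scanMotif(gen$genome, motifConsensus(cons)))
    }, numeric(1))
    pMatch <- 0.25^6
    positions <- sum(sizes - 6 + 1)
    expected <- 2 * positions * pMatch
    se <- sqrt(expected / length(counts))  # Poisson-ish aggregate error
    expect_lt(abs(mean(counts) - expected), 4 * se + 1)
})

test_that("tag-lane truth calibration yields unbiased normalized ratios", {
    cfg <- smallSimConfig()
    peaks <- bedGR(cfg$peaks$chrom, cfg$peaks$start, cfg$peaks$end)
    ratios1 <- c()
    ratios3 <- c()
    for (seed in 1:12) {
        sim <- simulateTagLanes(cfg$seqlengths, cfg$peaks, seed = seed)
        res <- classifyEimrs(peaks, sim$minus, sim$plus)
        key <- paste(as.character(seqnames(res)), start(res) - 1L)
        tr <- cfg$peaks$ratio[
            match(key, paste(cfg$peaks$chrom, cfg$peaks$start))]
        ratios1 <- c(ratios1, res$ratio[tr == 1])
        ratios3 <- c(ratios3, res$ratio[tr == 3])
    }
    # empirical means within 3 sigma of the configured truths
    expect_lt(abs(mean(ratios1) - 1),
        3 * sd(ratios1) / sqrt(length(ratios1)))
    expect_lt(abs(mean(ratios3) - 3),
        3 * sd(ratios3) / sqrt(length(ratios3)))
})

test_that("zero background rate puts every tag inside a planted peak", {
    cfg <- smallSimConfig()
    peaks <- bedGR(cfg$peaks$chrom, cfg$peaks$start, cfg$peaks$end)
    flat <- cfg$peaks
    flat$ratio <- 1  # placement check; ratio calibration is tested above
    sim <- simulateTagLanes(cfg$seqlengths, flat,
        backgroundRate = 1e-8, minusEnrichment = 1e9, seed = 3)
    for (lane in list(sim$minus, sim$plus)) {
        tags <- tagPositions(lane)
        expect_true(all(IRanges::overlapsAny(tags, peaks)))
    }
})

test_that("noiseless Ct tables invert exactly through ddct", {
    truth <- data.frame(
        sample = c("cal", "cal", "kd", "kd"),
        gene = c("gA", "gB", "gA", "gB"),
        rel = c(1, 1, 4, 0.25)
    )
    sim <- simulateCtTable(truth, sd = 0, replicates = 3, seed = 1)
    expect_identical(
        sum(sim$records$gene == "gA"), 6L)  # 2 samples x 3 replicates
    res <- ddct(sim$records, calibrator = "cal")$summary
    merged <- merge(res, truth, by = c("sample", "gene"))
    expect_equal(merged$rel.x, merged$rel.y, tolerance = 1e-12)
})

test_that("noiseless REA tables invert exactly through the fit", {
    truth <- data.frame(
        condition = c("dMi-2", "dMi-2+EcR"),
        y0 = c(5, 5), plateau = c(40, 80), k = c(0.08, 0.2)
    )
    sim <- simulateRea(truth, sd = 0, replicates = 2, seed = 2)
    # percent_cut inverts the emitted (cut, uncut) pairs exactly
    expect_equal(percentCut(sim$records$cut, sim$records$uncut),
        sim$records$pct, tolerance = 1e-12)
    for (i in seq_len(nrow(truth))) {
        g <- sim$records[sim$records$condition == truth$condition[i], ]
        fit <- fitOnePhaseDecay(g$time_min, g$pct)
        expect_lt(max(abs(coef(fit) -
            c(truth$y0[i], truth$plateau[i], truth$k[i]))), 1e-4)
    }
    # plateau ordering propagates to the stimulation summary
    ss <- stimulationSummary(sim$records, baseline = "dMi-2")
    expect_gt(ss$comparison$plateauDiff[
        ss$comparison$condition == "dMi-2+EcR"], 0)
})

test_that("noiseless MNase tables invert exactly", {
    truth <- data.frame(
        region = c("A", "A", "D", "D"),
        sample = c("GFP", "kd", "GFP", "kd"),
        protection = c(1, 0.2, 1, 0.8)
    )
    sim <- simulateMnase(truth, sd = 0, seed = 1)
    res <- mnaseProtection(sim$records)
    expect_equal(res$protection_rescaled, truth$protection,
        tolerance = 1e-12)
    # uniform protection 1 stays 1 everywhere
    allOne <- truth
    allOne$protection <- 1
    resOne <- mnaseProtection(simulateMnase(allOne, sd = 0,
        seed = 2)$records)
    expect_true(all(resOne$protection_rescaled == 1))
})

test_that("noisy MNase recovery is within 10% at the median", {
    truth <- data.frame(
        region = rep("A", 2), sample = c("GFP", "kd"),
        protection = c(1, 0.3)
    )
    errs <- vapply(1:60, function(seed) {
        sim <- simulateMnase(truth, sd = 0.1, seed = seed)
        res <- mnaseProtection(sim$records)
        est <- res$protection_rescaled[res$sample == "kd"]
        abs(est - 0.3) / 0.3
    }, numeric(1))
    expect_lt(median(errs), 0.10)
})

test_that("truth.json carries enough ground truth to score the study", {
    cfg <- smallSimConfig()
    d <- tempfile()
    writeSimulation(d, cfg, seed = 9)
    truth <- jsonlite::fromJSON(file.path(d, "truth.json"))
    expect_identical(truth$seed, 9L)
    expect_identical(nrow(truth$peaks), nrow(cfg$peaks))
    expect_true(all(c("trueRatio", "expectedMinus", "expectedPlus")
        %in% names(truth$peaks)))
    expect_identical(nrow(truth$motifInstances),
        cfg$nBackgroundMotifs + cfg$nInRegionMotifs)
    expect_identical(truth$motif, cfg$motif)
    expect_true(all(c("minus", "plus") %in% names(truth$laneTotals)))
    unlink(d, recursive = TRUE)
})
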