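# Motif scanning, in-region counting, size-matched resampling, and the
# normal-approximation enrichment P value.

test_that("consensus scanning reports exact matches on both strands", {
    g <- Biostrings::DNAStringSet(c(chr1 = "ACGACGTTTT"))
    # ACGA is not its own reverse complement; expect forward hits only at
    # positions 1 and 4 for ACG-containing pattern of width 4
    hits <- scanMotif(g, motifConsensus("ACGA"))
    fwd <- hits[strand(hits) == "+"]
    expect_identical(start(fwd), 1L)
    # palindrome: one hit per strand at the same position
    g2 <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
    hp <- scanMotif(g2, motifConsensus("ACGT"))
    expect_identical(start(hp), c(1L, 1L))
    expect_setequal(as.character(strand(hp)), c("+", "-"))
})

test_that("N bases never match, in either mode", {
    g <- Biostrings::DNAStringSet(c(chr1 = "ACGTNACGTNNNNN"))
    hits <- scanMotif(g, motifConsensus("ACGT"))
    expect_true(all(start(hits) %in% c(1L, 6L)))
    # even an all-N consensus finds nothing in an N window
    hitsN <- scanMotif(g, motifConsensus("NNNN"))
    winStarts <- unique(start(hitsN))
    expect_true(all(winStarts %in% c(1L, 6L)))
})

test_that("PWM threshold at the maximum reduces to argmax matching", {
    set.seed(5)
    g <- randomGenome(c(c1 = 400), seed = 5)
    pwm <- rbind(
        A = c(2, -1, -1, 0.5), C = c(-1, 2, -1, 0.5),
        G = c(-1, -1, 2, 0.5), T = c(-1, -1, -1, 0.5)
    )
    maxScore <- sum(apply(pwm, 2, max))  # argmax sequence ACGA.. ties on 4th
    # break the tie: make column 4 unique
    pwm["T", 4] <- 1
    maxScore <- sum(apply(pwm, 2, max))
    m <- motifPWM(pwm, threshold = maxScore)
    hits <- scanMotif(g, m)
    cons <- scanMotif(g, motifConsensus("ACGT"))
    expect_identical(hitsAsDf(hits), hitsAsDf(cons))
    expect_true(all(abs(hits$score - maxScore) < 1e-9))
})

test_that("scanMotif agrees with the naive scanner on random sequences", {
    for (i in seq_len(20)) {
        g <- randomGenome(c(c1 = 300, c2 = 150), seed = 1000 + i)
        cons <- c("ACGTRY", "GGKTCA", "TGACNNCA", "RGGTCANTGACC")[
            (i %% 4) + 1]
        expect_identical(
            hitsAsDf(scanMotif(g, motifConsensus(cons))),
            {
                df <- naiveScanConsensus(g, cons)
                rownames(df) <- NULL
                df
            },
            info = paste("seed", 1000 + i, cons)
        )
    }
})

test_that("PWM scanning agrees with the naive scorer", {
    set.seed(33)
    for (i in seq_len(10)) {
        g <- randomGenome(c(c1 = 200), seed = 2000 + i)
        pwm <- matrix(rnorm(4 * 5), 4, 5,
            dimnames = list(c("A", "C", "G", "T"), NULL))
        thr <- 0.5 * sum(apply(pwm, 2, max))
        m <- motifPWM(pwm, threshold = thr)
        df <- naiveScanPWM(g, pwm, thr)
        rownames(df) <- NULL
        expect_identical(hitsAsDf(scanMotif(g, m)), df)
    }
})

test_that("in-region counting uses the fully-inside rule, deduplicated", {
    hits <- c(
        bedGR("c1", 10, 22, strand = "+"),
        bedGR("c1", 95, 107, strand = "+"),
        bedGR("c1", 200, 212, strand = "-")
    )
    regions <- bedGR("c1", 0, 100)
    # footprint straddling the boundary at 100 is not counted
    expect_identical(countHitsInRegions(hits, regions), 1L)
    # a region covering the chromosome counts every hit
    expect_identical(countHitsInRegions(hits, bedGR("c1", 0, 1000)), 3L)
    # duplicated/overlapping regions count each hit once
    dup <- c(bedGR("c1", 0, 1000), bedGR("c1", 0, 1000),
        bedGR("c1", 5, 500))
    expect_identical(countHitsInRegions(hits, dup), 3L)
    expect_identical(countHitsInRegions(hits[0], regions), 0L)
})

test_that("matched sampling conserves lengths, bounds, and determinism", {
    sl <- c(chr1 = 9000, chr2 = 1000)
    regions <- c(bedGR("chr1", 0, 500), bedGR("chr1", 100, 1300))
    a <- sampleMatchedRegions(regions, sl, seed = 4)
    b <- sampleMatchedRegions(regions, sl, seed = 4)
    expect_identical(a, b)
    expect_setequal(width(a), width(regions))
    expect_true(all(start(a) >= 1))
    expect_true(all(end(a) <= sl[as.character(seqnames(a))]))
    # a 1 kb region cannot start anywhere on the 1 kb chromosome with
    # fewer placeable positions than its length... chr2 has exactly 1
    # placeable start; draw many and check bounds always hold
    set.seed(9)
    for (i in seq_len(200)) {
        s <- sampleMatchedRegions(1000, sl)
        expect_true(end(s) <= sl[as.character(seqnames(s))])
    }
    # longer than every chromosome errors
    expect_error(sampleMatchedRegions(10000, sl), "longer than every")
})

test_that("chromosomes with zero placeable positions are excluded", {
    sl <- c(chr1 = 9000, chr2 = 999)
    set.seed(12)
    for (i in seq_len(100)) {
        s <- sampleMatchedRegions(1000, sl)
        expect_identical(as.character(seqnames(s)), "chr1")
    }
})

test_that("buildNull handles degenerate and saturated inputs", {
    sl <- c(c1 = 5000)
    noHits <- GRanges(seqlengths = sl)
    regions <- bedGR("c1", c(0, 2000), c(500, 2500))
    null0 <- buildNull(regions, noHits, sl, B = 50, seed = 1)
    expect_identical(unique(nullSamples(null0)), 0)
    expect_identical(null0@mu, 0)
    expect_identical(null0@sd, 0)
    expect_identical(null0@pNormal, 1)  # observed 0 == mu
    # regions tiling the whole genome: every run counts every hit
    hits <- bedGR("c1", c(10, 100, 3000), c(22, 112, 3012))
    tiling <- bedGR("c1", 0, 5000)
    nullS <- buildNull(tiling, hits, sl, B = 20, seed = 2)
    expect_identical(unique(nullSamples(nullS)), 3)
    expect_identical(observedCount(nullS), 3)
})

test_that("fast null counting equals the GRanges path run for run", {
    set.seed(77)
    sl <- c(c1 = 40000, c2 = 20000)
    hits <- bedGR(
        sample(c("c1", "c2"), 120, replace = TRUE, prob = c(2, 1)),
        hs <- sample.int(19000, 120), hs + 12
    )
    regions <- bedGR(
        rep(c("c1", "c2"), c(6, 4)),
        rs <- c(sample.int(30000, 6), sample.int(15000, 4)),
        rs + sample(c(400, 700, 1000), 10, replace = TRUE)
    )
    null <- buildNull(regions, hits, sl, B = 40, seed = 123)
    # replay the same RNG stream through the public sampler + counter
    set.seed(123)
    replay <- vapply(seq_len(40), function(b) {
        rnd <- sampleMatchedRegions(regions, sl)
        as.numeric(countHitsInRegions(hits, rnd))
    }, numeric(1))
    expect_identical(nullSamples(null), replay)
})

test_that("null mean matches the closed-form placement expectation", {
    # uniformly placed hits, one sampled region of length L on one
    # chromosome: E[count] = nHits * (L - w + 1) / (chromLen - w + 1)
    # approx; use the exact placeable-position argument instead:
    # a width-w hit at start h is inside a random region of length L iff
    # the region start lies in [h - (L - w), h] (clipped), so
    # P = (L - w + 1) / (chromLen - L + 1) for interior hits.
    sl <- c(c1 = 20000)
    w <- 13L
    L <- 1000L
    set.seed(301)
    starts <- sample.int(17000, 60) + 1000L  # keep hits interior
    hits <- GRanges("c1", IRanges(starts, width = w))
    regions <- GRanges("c1", IRanges(1, width = L))
    null <- buildNull(regions, hits, sl, B = 4000, seed = 302)
    pInside <- (L - w + 1) / (sl[["c1"]] - L + 1)
    expected <- length(hits) * pInside
    se <- null@sd / sqrt(null@B)
    expect_lt(abs(null@mu - expected), 3 * se + 1e-9)
})

test_that("normal P value follows the upper-tail convention", {
    mk <- function(samples, obs) {
        null <- buildNull(
            bedGR("c1", 0, 100), GRanges(seqlengths = c(c1 = 1000)),
            c(c1 = 1000), B = length(samples), seed = 1
        )
        null@samples <- samples
        null@mu <- mean(samples)
        null@sd <- sd(samples)
        null@observed <- obs
        null
    }
    base <- c(8, 9, 10, 11, 12)
    expect_equal(normalPValue(mk(base, 10)), 0.5)
    s <- sd(base)
    expect_equal(normalPValue(mk(base, 10 + 3 * s)),
        pnorm(3, lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(normalPValue(mk(base, 10 - s)), pnorm(1),
        tolerance = 1e-12)
    # degenerate null
    expect_identical(normalPValue(mk(rep(5, 5), 6)), 0)
    expect_identical(normalPValue(mk(rep(5, 5), 5)), 1)
})

test_that("planted in-region enrichment is detected at B = 1000", {
    cfg <- smallSimConfig()
    peaks <- bedGR(cfg$peaks$chrom, cfg$peaks$start, cfg$peaks$end)
    induced <- peaks[cfg$peaks$ratio > 1]
    gen <- makeGenome(cfg$seqlengths, cfg$motif,
        nBackground = cfg$nBackgroundMotifs,
        nInRegion = cfg$nInRegionMotifs,
        regions = induced, seed = 8)
    hits <- scanMotif(gen$genome, motifConsensus(cfg$motif))
    # all planted instances are recovered at their recorded positions
    planted <- GRanges(gen$truth$chrom,
        IRanges(gen$truth$start, width = nchar(cfg$motif)))
    expect_true(all(countOverlaps(planted, hits, type = "equal") > 0))
    null <- buildNull(induced, hits, cfg$seqlengths, B = 1000, seed = 9)
    expect_lt(null@pNormal, 1e-4)
    expect_identical(null@seed, 9L)
})

test_that("enrichment report serializes the null faithfully", {
    sl <- c(c1 = 5000)
    hits <- bedGR("c1", c(10, 100), c(22, 112))
    null <- buildNull(bedGR("c1", 0, 2000), hits, sl, B = 30, seed = 3)
    json <- tempfile(fileext = ".json")
    tsv <- tempfile(fileext = ".tsv")
    writeEnrichmentReport(null, json, samplesTsv = tsv)
    rpt <- jsonlite::fromJSON(json)
    expect_identical(rpt$B, 30L)
    expect_equal(rpt$mu, null@mu)
    expect_equal(rpt$p_normal, null@pNormal)
    samples <- read.delim(tsv)
    expect_equal(samples$count, nullSamples(null))
})

test_that("MEME round trip preserves consensus information content", {
    m <- motifConsensus("RGGTCANTGACC")
    p <- tempfile(fileext = ".meme")
    writeMotifMeme(m, p)
    back <- readMotif(p, threshold = 0.999)
    expect_s4_class(back, "MotifModel")
    expect_identical(motifWidth(back), 12L)
    # scanning a genome containing one exact consensus instance finds it
    g <- Biostrings::DNAStringSet(c(
        c1 = paste0(strrep("T", 30), "AGGTCAATGACC", strrep("T", 30))))
    hits <- scanMotif(g, back)
    expect_true(31L %in% start(hits))
    # plain IUPAC files load in consensus mode
    p2 <- tempfile()
    writeLines("RGGTCANTGACC", p2)
    expect_identical(readMotif(p2)@consensus, "RGGTCANTGACC")
})
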