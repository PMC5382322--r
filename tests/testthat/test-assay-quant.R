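# Delta-delta-Ct quantification, fold changes, time-course rescaling, and
# MNase protection.

ctTable <- function(...) {
    # rows: sample, gene, replicate, ct
    df <- rbind(...)
    data.frame(
        sample = df[, 1], gene = df[, 2],
        replicate = as.integer(df[, 3]), ct = as.numeric(df[, 4]),
        stringsAsFactors = FALSE
    )
}

test_that("ddct reproduces hand-computed relative levels", {
    # sample dCt = 5, calibrator dCt = 7 -> ddCt = -2 -> rel = 4
    tab <- ctTable(
        c("cal", "rp49", 1, 16), c("cal", "geneX", 1, 23),
        c("smp", "rp49", 1, 16), c("smp", "geneX", 1, 21)
    )
    res <- ddct(tab, calibrator = "cal")
    expect_equal(
        res$summary$rel[res$summary$sample == "smp"], 4)
    expect_equal(
        res$summary$rel[res$summary$sample == "cal"], 1)
    # lowering the target Ct by one cycle doubles rel
    tab2 <- tab
    tab2$ct[tab2$sample == "smp" & tab2$gene == "geneX"] <- 20
    res2 <- ddct(tab2, calibrator = "cal")
    expect_equal(res2$summary$rel[res2$summary$sample == "smp"], 8)
})

test_that("calibrator mean rel is exactly 1 even with replicate noise", {
    set.seed(21)
    tab <- do.call(rbind, lapply(1:3, function(i) {
        ctTable(
            c("cal", "rp49", i, 16 + rnorm(1, 0, 0.3)),
            c("cal", "tgt", i, 22 + rnorm(1, 0, 0.3)),
            c("kd", "rp49", i, 16 + rnorm(1, 0, 0.3)),
            c("kd", "tgt", i, 19 + rnorm(1, 0, 0.3))
        )
    }))
    res <- ddct(tab, calibrator = "cal")
    expect_identical(
        res$summary$rel[res$summary$sample == "cal"], 1)
    expect_identical(res$summary$n, c(3L, 3L))
    expect_true(all(res$replicates$rel > 0))
})

test_that("ddct is invariant to a constant plate offset", {
    set.seed(22)
    tab <- do.call(rbind, lapply(1:3, function(i) {
        ctTable(
            c("cal", "rp49", i, 16 + rnorm(1, 0, 0.2)),
            c("cal", "tgt", i, 22 + rnorm(1, 0, 0.2)),
            c("kd", "rp49", i, 16 + rnorm(1, 0, 0.2)),
            c("kd", "tgt", i, 20 + rnorm(1, 0, 0.2))
        )
    }))
    shifted <- tab
    shifted$ct <- shifted$ct + 3.7
    expect_equal(
        ddct(tab, calibrator = "cal")$summary$rel,
        ddct(shifted, calibrator = "cal")$summary$rel,
        tolerance = 1e-12
    )
})

test_that("samples missing reference wells are excluded with a warning", {
    tab <- ctTable(
        c("cal", "rp49", 1, 16), c("cal", "tgt", 1, 22),
        c("orphan", "tgt", 1, 20)
    )
    expect_warning(res <- ddct(tab, calibrator = "cal"), "orphan")
    expect_identical(res$excluded, "orphan")
    expect_false("orphan" %in% res$summary$sample)
    expect_error(
        suppressWarnings(ddct(tab, calibrator = "orphan")),
        "calibrator"
    )
})

test_that("noisy triplicates recover true fold changes within 15%", {
    truth <- data.frame(
        sample = rep(c("cal", "kd"), each = 2),
        gene = rep(c("gA", "gB"), 2),
        rel = c(1, 1, 8, 0.5)
    )
    est <- list(gA = c(), gB = c())
    for (seed in 1:40) {
        sim <- simulateCtTable(truth, sd = 0.2, replicates = 3,
            seed = seed)
        res <- ddct(sim$records, calibrator = "cal")$summary
        for (g in c("gA", "gB")) {
            est[[g]] <- c(est[[g]],
                res$rel[res$sample == "kd" & res$gene == g])
        }
    }
    # mean recovered fold change across seeds within 15% of the truth
    for (g in c("gA", "gB")) {
        tru <- truth$rel[truth$sample == "kd" & truth$gene == g]
        expect_lt(abs(mean(est[[g]]) - tru) / tru, 0.15)
    }
})

test_that("fold change versus untreated maps the baseline to 1", {
    rel <- data.frame(
        gene = rep(c("Br-C", "vri", "Hr4"), each = 2),
        treatment = rep(c("untreated", "treated"), 3),
        rel = c(0.5, 5, 2, 2, 1, 3)
    )
    fc <- foldChangeVsUntreated(rel)
    expect_equal(fc$fold[fc$treatment == "untreated"], c(1, 1, 1))
    expect_equal(
        fc$fold[fc$gene == "Br-C" & fc$treatment == "treated"], 10)
    expect_equal(
        fc$fold[fc$gene == "vri" & fc$treatment == "treated"], 1)
    expect_error(
        foldChangeVsUntreated(rel[rel$treatment == "treated", ]),
        "untreated"
    )
})

test_that("time-course rescaling sets control t_max to 100 exactly", {
    tab <- expand.grid(
        condition = c("GFP RNAi", "dMi-2 RNAi"),
        timepoint = c(0, 2, 4, 6), KEEP.OUT.ATTRS = FALSE,
        stringsAsFactors = FALSE
    )
    tab$rel <- c(0.1, 0.4, 1, 3, 2.5, 9, 4, 12)
    out <- timecourseRescale(tab, control = "GFP RNAi")
    expect_identical(
        out$rel[out$condition == "GFP RNAi" & out$timepoint == 6], 100)
    # one global factor: ratios between conditions preserved
    expect_equal(
        out$rel[out$condition == "dMi-2 RNAi"] /
            out$rel[out$condition == "GFP RNAi"],
        tab$rel[tab$condition == "dMi-2 RNAi"] /
            tab$rel[tab$condition == "GFP RNAi"],
        tolerance = 1e-12
    )
    allEq <- tab
    allEq$rel <- 7
    expect_true(all(
        timecourseRescale(allEq, control = "GFP RNAi")$rel == 100))
    zero <- tab
    zero$rel[zero$condition == "GFP RNAi" & zero$timepoint == 6] <- 0
    expect_error(timecourseRescale(zero, control = "GFP RNAi"), "0")
})

test_that("MNase protection follows the 2^-dCt and max-to-1 rules", {
    tab <- data.frame(
        region = c("A", "A", "D", "D"),
        sample = c("GFP", "kd", "GFP", "kd"),
        ct_digested = c(20, 22, 21, 21),
        ct_undigested = c(20, 20, 21, 20)
    )
    res <- mnaseProtection(tab)
    expect_equal(res$protection, c(1, 0.25, 1, 0.5))
    expect_equal(res$protection_rescaled, c(1, 0.25, 1, 0.5))
    # per-region max is 1 even when no sample reaches protection 1
    tab2 <- tab
    tab2$ct_digested <- tab2$ct_digested + 1
    res2 <- mnaseProtection(tab2)
    expect_equal(
        as.numeric(tapply(res2$protection_rescaled, res2$region, max)),
        c(1, 1)
    )
    # monotone decreasing in Ct_digested at fixed Ct_undigested
    expect_true(all(diff(2^(-(seq(20, 24, 0.5) - 20))) < 0))
    prot <- function(ctd) {
        mnaseProtection(data.frame(region = "r", sample = "s",
            ct_digested = ctd, ct_undigested = 20))$protection
    }
    expect_true(prot(21) > prot(22))
})

test_that("incomplete MNase records are dropped with a warning", {
    tab <- data.frame(
        region = c("A", "A"), sample = c("GFP", "kd"),
        ct_digested = c(20, 22), ct_undigested = c(20, NA)
    )
    expect_warning(res <- mnaseProtection(tab), "excluded")
    expect_identical(nrow(res), 1L)
})
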