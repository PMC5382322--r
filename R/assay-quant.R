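# Relative quantification of qPCR assays: the delta-delta-Ct method with a
# reference gene and calibrator sample, fold changes versus untreated,
# time-course rescaling to 100 at the control's last time point, and MNase
# protection with per-region max-to-1 rescaling. Amplification efficiency
# is fixed at 2.0 per cycle throughout (no efficiency correction).

#' Relative expression by the delta-delta-Ct method
#'
#' For every (sample, target-gene) combination, per-replicate
#' `dCt = Ct_target - Ct_reference` is formed (replicates paired by index
#' with the reference-gene wells of the same sample; unpaired replicates
#' fall back to the sample's mean reference Ct). `ddCt` subtracts the
#' calibrator sample's mean `dCt` for that gene and the relative level is
#' `2^(-ddCt)`, computed per replicate before averaging so the reported
#' standard deviation is on the ratio scale. Each gene's values are then
#' rescaled so the calibrator's mean relative level is exactly 1. Samples
#' missing reference-gene wells are excluded with a warning.
#'
#' @param records `data.frame` with columns `sample`, `gene`, `replicate`,
#'   `ct` (additional columns are ignored).
#' @param calibrator calibrator sample label (its mean relative level is
#'   set to 1).
#' @param reference reference-gene label, default `"rp49"`.
#' @return A list with `replicates` (per-replicate `dct`, `ddct`, `rel`)
#'   and `summary` (per sample x gene mean and sd of `rel`), plus
#'   `excluded` (sample labels dropped for missing reference wells).
#' @examples
#' tab <- data.frame(
#'     sample = rep(c("ctrl", "kd"), each = 2),
#'     gene = rep(c("rp49", "vri"), 2),
#'     replicate = 1, ct = c(16, 23, 16, 21)
#' )
#' ddct(tab, calibrator = "ctrl")$summary
#' @export
ddct <- function(records, calibrator, reference = "rp49") {
    required <- c("sample", "gene", "replicate", "ct")
    if (!all(required %in% names(records))) {
        stop("records need columns: ", paste(required, collapse = ", "),
            call. = FALSE)
    }
    if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
        stop("all Ct values must be finite and > 0", call. = FALSE)
    }
    if (!calibrator %in% records$sample) {
        stop("calibrator sample '", calibrator, "' not present",
            call. = FALSE)
    }
    refTab <- records[records$gene == reference, , drop = FALSE]
    haveRef <- unique(refTab$sample)
    excluded <- setdiff(unique(records$sample), haveRef)
    if (length(excluded)) {
        warning("samples without reference-gene Cts excluded: ",
            paste(excluded, collapse = ", "))
        if (calibrator %in% excluded) {
            stop("calibrator has no reference-gene Cts", call. = FALSE)
        }
    }
    tab <- records[records$gene != reference &
        records$sample %in% haveRef, , drop = FALSE]
    refCt <- function(smp, reps) {
        rf <- refTab[refTab$sample == smp, , drop = FALSE]
        m <- rf$ct[match(reps, rf$replicate)]
        m[is.na(m)] <- mean(rf$ct)
        m
    }
    parts <- split(tab, list(tab$sample, tab$gene), drop = TRUE)
    repRows <- do.call(rbind, lapply(parts, function(p) {
        data.frame(
            sample = p$sample, gene = p$gene, replicate = p$replicate,
            dct = p$ct - refCt(p$sample[1], p$replicate),
            stringsAsFactors = FALSE
        )
    }))
    rownames(repRows) <- NULL
    # calibrator mean dCt per gene, then per-replicate rel = 2^(-ddCt)
    out <- do.call(rbind, lapply(split(repRows, repRows$gene), function(g) {
        calRows <- g[g$sample == calibrator, , drop = FALSE]
        if (nrow(calRows) == 0L) {
            warning("no calibrator wells for gene ", g$gene[1],
                "; gene skipped")
            return(NULL)
        }
        g$ddct <- g$dct - mean(calRows$dct)
        g$rel <- 2^(-g$ddct)
        # force the calibrator's mean rel to exactly 1
        g$rel <- g$rel / mean(g$rel[g$sample == calibrator])
        g
    }))
    rownames(out) <- NULL
    summ <- do.call(rbind, lapply(
        split(out, list(out$sample, out$gene), drop = TRUE),
        function(p) {
            data.frame(
                sample = p$sample[1], gene = p$gene[1],
                rel = mean(p$rel),
                sd = if (nrow(p) > 1) sd(p$rel) else NA_real_,
                n = nrow(p), stringsAsFactors = FALSE
            )
        }
    ))
    rownames(summ) <- NULL
    list(replicates = out, summary = summ, excluded = excluded)
}

#' Fold changes relative to the untreated condition
#'
#' Per gene, the untreated relative level is mapped to 1 and the treated
#' level is expressed relative to it. Genes are handled independently.
#'
#' @param rel `data.frame` with columns `gene`, `treatment`, `rel`.
#' @param untreated label of the untreated condition, default
#'   `"untreated"`.
#' @return `data.frame` with columns `gene`, `treatment`, `fold`.
#' @export
foldChangeVsUntreated <- function(rel, untreated = "untreated") {
    required <- c("gene", "treatment", "rel")
    if (!all(required %in% names(rel))) {
        stop("need columns: ", paste(required, collapse = ", "),
            call. = FALSE)
    }
    out <- do.call(rbind, lapply(split(rel, rel$gene), function(g) {
        base <- g$rel[g$treatment == untreated]
        if (length(base) != 1L) {
            stop("gene ", g$gene[1],
                ": exactly one untreated value required", call. = FALSE)
        }
        data.frame(
            gene = g$gene, treatment = g$treatment,
            fold = g$rel / base, stringsAsFactors = FALSE
        )
    }))
    rownames(out) <- NULL
    out
}

#' Rescale an expression time course to 100 at the control's last point
#'
#' Every value is multiplied by `100 / rel(control, t_max)` so the control
#' condition is exactly 100 at the latest time point; ratios between
#' conditions are preserved. When a `gene` column is present the rescaling
#' is done independently per gene.
#'
#' @param rel `data.frame` with columns `condition`, `timepoint`, `rel`
#'   and optionally `gene`.
#' @param control control condition label (e.g. `"GFP RNAi"`).
#' @return The input with `rel` replaced by the rescaled values.
#' @export
timecourseRescale <- function(rel, control) {
    required <- c("condition", "timepoint", "rel")
    if (!all(required %in% names(rel))) {
        stop("need columns: ", paste(required, collapse = ", "),
            call. = FALSE)
    }
    rescaleOne <- function(g) {
        tMax <- max(g$timepoint)
        base <- g$rel[g$condition == control & g$timepoint == tMax]
        if (length(base) == 0L) {
            stop("control '", control, "' has no value at the last ",
                "time point", call. = FALSE)
        }
        base <- mean(base)
        if (base == 0) {
            stop("control value at the last time point is 0",
                call. = FALSE)
        }
        g$rel <- g$rel * (100 / base)
        g
    }
    if ("gene" %in% names(rel)) {
        out <- do.call(rbind, lapply(split(rel, rel$gene), rescaleOne))
        rownames(out) <- NULL
        out
    } else {
        rescaleOne(rel)
    }
}

#' MNase protection with per-region max-to-1 rescaling
#'
#' Protection is the qPCR signal of the digested sample relative to the
#' corresponding undigested sample, `2^(-(Ct_digested - Ct_undigested))`;
#' within each genomic region the values are divided by the maximum over
#' samples so the most protected sample is exactly 1. Records missing
#' either Ct are excluded with a warning.
#'
#' @param records `data.frame` with columns `region`, `sample`,
#'   `ct_digested`, `ct_undigested`.
#' @return `data.frame` with added columns `protection` and
#'   `protection_rescaled`.
#' @export
mnaseProtection <- function(records) {
    required <- c("region", "sample", "ct_digested", "ct_undigested")
    if (!all(required %in% names(records))) {
        stop("need columns: ", paste(required, collapse = ", "),
            call. = FALSE)
    }
    bad <- !is.finite(records$ct_digested) |
        !is.finite(records$ct_undigested)
    if (any(bad)) {
        warning(sum(bad), " record(s) missing a Ct value excluded")
        records <- records[!bad, , drop = FALSE]
    }
    if (nrow(records) == 0L) {
        stop("no complete MNase records", call. = FALSE)
    }
    records$protection <-
        2^(-(records$ct_digested - records$ct_undigested))
    out <- do.call(rbind, lapply(split(records, records$region),
        function(g) {
            g$protection_rescaled <- g$protection / max(g$protection)
            g
        }))
    rownames(out) <- NULL
    out
}
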