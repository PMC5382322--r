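#' @import methods
#' @importFrom stats setNames pnorm ppois sd median coef predict rpois rnorm
#'   runif nls.control
#' @importFrom utils read.table write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# TagLane: one ChIP lane = 5' tag positions + the lane's uniquely-mapped total
# ---------------------------------------------------------------------------

#' TagLane: ChIP-seq tag positions for one condition
#'
#' A `TagLane` stores the 5' positions of uniquely mapped ChIP-seq tags for
#' one experimental condition together with the lane's total number of
#' uniquely mapped reads. The total is carried as metadata rather than
#' recomputed from the stored tags because lane totals include reads that
#' fall outside any analysed region; it is the denominator of the
#' tags-per-million normalization.
#'
#' @slot positions [GenomicRanges::GRanges] of width-1 tag 5' positions.
#' @slot condition single character condition label (e.g. `"plus"`).
#' @slot laneTotal single number, total uniquely mapped reads; must be at
#'   least the number of stored tags and positive.
#'
#' @seealso [TagLane()], [countTags()], [normalizeCount()]
#' @export
setClass("TagLane",
    representation(
        positions = "GRanges",
        condition = "character",
        laneTotal = "numeric"
    )
)

setValidity("TagLane", function(object) {
    msg <- character()
    if (length(object@condition) != 1L || is.na(object@condition)) {
        msg <- c(msg, "'condition' must be a single non-NA label")
    }
    if (length(object@laneTotal) != 1L || !is.finite(object@laneTotal) ||
        object@laneTotal <= 0) {
        msg <- c(msg, "'laneTotal' must be a single positive number")
    }
    if (length(object@positions) > 0 &&
        any(GenomicRanges::width(object@positions) != 1L)) {
        msg <- c(msg, "all tag positions must have width 1")
    }
    if (length(object@laneTotal) == 1L && is.finite(object@laneTotal) &&
        object@laneTotal < length(object@positions)) {
        msg <- c(msg, "'laneTotal' cannot be smaller than the number of tags")
    }
    sl <- GenomeInfoDb::seqlengths(object@positions)
    if (length(sl) && !all(is.na(sl))) {
        known <- !is.na(sl[as.character(
            GenomeInfoDb::seqnames(object@positions))])
        ends <- GenomicRanges::end(object@positions)
        lim <- sl[as.character(GenomeInfoDb::seqnames(object@positions))]
        if (any(known & (ends > lim | GenomicRanges::start(
            object@positions) < 1L))) {
            msg <- c(msg, "tag positions must lie within their chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TagLane
#'
#' @param positions `GRanges` of width-1 tag 5' positions (or any `GRanges`,
#'   which is resized to its 5' start).
#' @param condition condition label.
#' @param laneTotal total uniquely mapped reads for the lane. Defaults to the
#'   number of supplied tags.
#' @return A [TagLane-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 150), width = 1))
#' TagLane(gr, condition = "minus", laneTotal = 1e6)
#' @export
TagLane <- function(positions, condition, laneTotal = length(positions)) {
    if (!methods::is(positions, "GRanges")) {
        stop("'positions' must be a GRanges", call. = FALSE)
    }
    if (length(positions) && any(GenomicRanges::width(positions) != 1L)) {
        positions <- GenomicRanges::resize(positions, width = 1L, fix = "start")
    }
    methods::new("TagLane",
        positions = positions,
        condition = as.character(condition),
        laneTotal = as.numeric(laneTotal)
    )
}

#' @describeIn TagLane-class tag positions as a `GRanges`.
#' @param object,x a `TagLane`.
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))

#' @rdname TagLane-class
#' @export
setMethod("tagPositions", "TagLane", function(x) x@positions)

#' @describeIn TagLane-class the lane's uniquely-mapped read total.
#' @export
setGeneric("laneTotal", function(x) standardGeneric("laneTotal"))

#' @rdname TagLane-class
#' @export
setMethod("laneTotal", "TagLane", function(x) x@laneTotal)

#' @describeIn TagLane-class the condition label.
#' @export
setGeneric("laneCondition", function(x) standardGeneric("laneCondition"))

#' @rdname TagLane-class
#' @export
setMethod("laneCondition", "TagLane", function(x) x@condition)

setMethod("show", "TagLane", function(object) {
    cat("TagLane object\n")
    cat("  condition :", object@condition, "\n")
    cat("  tags      :", length(object@positions), "stored 5' positions\n")
    cat("  laneTotal :", format(object@laneTotal, big.mark = ","),
        "uniquely mapped reads\n")
    invisible(object)
})

# ---------------------------------------------------------------------------
# MotifModel: IUPAC consensus or log-odds PWM with a score threshold
# ---------------------------------------------------------------------------

#' MotifModel: a DNA motif as IUPAC consensus or PWM
#'
#' Describes the motif scanned for by [scanMotif()]. Two modes are
#' supported: an exact IUPAC consensus match, or a position weight matrix
#' (log2-odds scores against a stated background composition) with a score
#' threshold. `N` bases in the genome never match in either mode.
#'
#' @slot kind `"consensus"` or `"pwm"`.
#' @slot consensus IUPAC consensus string (consensus mode; otherwise `""`).
#' @slot pwm 4 x w numeric matrix of log2-odds scores, rows `A,C,G,T`
#'   (PWM mode; otherwise a 0-column matrix).
#' @slot threshold minimum PWM score for a hit (PWM mode).
#' @slot background length-4 background base composition used to build the
#'   log-odds scores (sums to 1).
#' @seealso [motifConsensus()], [motifPWM()], [readMotif()]
#' @export
setClass("MotifModel",
    representation(
        kind = "character",
        consensus = "character",
        pwm = "matrix",
        threshold = "numeric",
        background = "numeric"
    )
)

IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

setValidity("MotifModel", function(object) {
    msg <- character()
    if (!object@kind %in% c("consensus", "pwm")) {
        msg <- c(msg, "kind must be 'consensus' or 'pwm'")
    }
    if (object@kind == "consensus") {
        if (nchar(object@consensus) < 4L) {
            msg <- c(msg, "motif width must be >= 4")
        }
        bad <- setdiff(strsplit(object@consensus, "")[[1]], names(IUPAC_SETS))
        if (length(bad)) {
            msg <- c(msg, paste0("invalid IUPAC letters: ",
                paste(bad, collapse = ",")))
        }
    } else {
        if (ncol(object@pwm) < 4L) msg <- c(msg, "motif width must be >= 4")
        if (!all(is.finite(object@pwm))) {
            msg <- c(msg, "PWM scores must be finite")
        }
        if (!identical(rownames(object@pwm), c("A", "C", "G", "T"))) {
            msg <- c(msg, "PWM rows must be named A,C,G,T")
        }
        maxScore <- sum(apply(object@pwm, 2L, max))
        if (length(object@threshold) != 1L ||
            object@threshold > maxScore + 1e-9) {
            msg <- c(msg, "threshold must not exceed the maximum PWM score")
        }
    }
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-6 ||
        any(object@background <= 0)) {
        msg <- c(msg, "background must be 4 positive frequencies summing to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a consensus MotifModel
#'
#' @param consensus IUPAC consensus string, width >= 4.
#' @param background background base composition (A,C,G,T), default uniform.
#' @return A [MotifModel-class] in consensus mode.
#' @examples
#' motifConsensus("RGKTCANTGACMY")
#' @export
motifConsensus <- function(consensus, background = rep(0.25, 4)) {
    methods::new("MotifModel",
        kind = "consensus",
        consensus = toupper(as.character(consensus)),
        pwm = matrix(numeric(), nrow = 4L, ncol = 0L,
            dimnames = list(c("A", "C", "G", "T"), NULL)),
        threshold = NA_real_,
        background = as.numeric(background)
    )
}

#' Construct a PWM MotifModel
#'
#' Probability matrices are converted to log2-odds against the background
#' with a small pseudo-probability to keep scores finite; matrices that
#' already contain negative values are taken to be log-odds scores.
#'
#' @param matrix 4 x w numeric matrix, rows A,C,G,T: either base
#'   probabilities (columns summing to 1) or log2-odds scores.
#' @param threshold minimum score for [scanMotif()] to report a hit. May be
#'   given as a fraction of the maximum attainable score via `relative =
#'   TRUE`.
#' @param background background base composition (A,C,G,T), default uniform.
#' @param relative if `TRUE`, interpret `threshold` as a fraction (0-1] of
#'   the maximum attainable score.
#' @return A [MotifModel-class] in PWM mode.
#' @export
motifPWM <- function(matrix, threshold, background = rep(0.25, 4),
                     relative = FALSE) {
    m <- as.matrix(matrix)
    if (nrow(m) != 4L) stop("PWM must have 4 rows (A,C,G,T)", call. = FALSE)
    rownames(m) <- c("A", "C", "G", "T")
    isProb <- all(m >= 0) && all(abs(colSums(m) - 1) < 1e-3)
    if (isProb) {
        eps <- 1e-4
        p <- sweep(m + eps, 2L, colSums(m + eps), "/")
        m <- log2(p / background)
    }
    maxScore <- sum(apply(m, 2L, max))
    thr <- if (relative) threshold * maxScore else threshold
    methods::new("MotifModel",
        kind = "pwm", consensus = "",
        pwm = m, threshold = as.numeric(thr),
        background = as.numeric(background)
    )
}

#' @describeIn MotifModel-class motif width in base pairs.
#' @param x a `MotifModel`.
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname MotifModel-class
#' @export
setMethod("motifWidth", "MotifModel", function(x) {
    if (x@kind == "consensus") nchar(x@consensus) else ncol(x@pwm)
})

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel (", object@kind, " mode), width ",
        motifWidth(object), " bp\n", sep = "")
    if (object@kind == "consensus") {
        cat("  consensus:", object@consensus, "\n")
    } else {
        cat("  score threshold:", format(object@threshold, digits = 4),
            "(max", format(sum(apply(object@pwm, 2L, max)), digits = 4),
            ")\n")
    }
    invisible(object)
})

# ---------------------------------------------------------------------------
# MotifNull: resampled null distribution of in-region motif counts
# ---------------------------------------------------------------------------

#' MotifNull: resampling null for in-region motif counts
#'
#' The result of [buildNull()]: `B` motif counts obtained by placing
#' size-matched random regions across the genome, summary statistics, the
#' observed count, and the normal-approximation and empirical enrichment
#' P values (upper tail).
#'
#' @slot B number of resampling runs.
#' @slot samples numeric vector of the `B` null motif counts.
#' @slot observed observed in-region motif count.
#' @slot mu,sd sample mean and unbiased (n-1) standard deviation of
#'   `samples`.
#' @slot z standardized observed count `(observed - mu)/sd`.
#' @slot pNormal one-sided upper-tail normal P value.
#' @slot pEmpirical add-one empirical tail proportion
#'   `(#\{samples >= observed\} + 1)/(B + 1)`.
#' @slot seed the seed used for the resampling (NA if none given).
#' @seealso [buildNull()], [normalPValue()]
#' @export
setClass("MotifNull",
    representation(
        B = "integer",
        samples = "numeric",
        observed = "numeric",
        mu = "numeric",
        sd = "numeric",
        z = "numeric",
        pNormal = "numeric",
        pEmpirical = "numeric",
        seed = "integer"
    )
)

setValidity("MotifNull", function(object) {
    msg <- character()
    if (object@B < 2L) msg <- c(msg, "B must be >= 2")
    if (length(object@samples) != object@B) {
        msg <- c(msg, "length(samples) must equal B")
    }
    if (is.finite(object@sd) && object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (is.finite(object@pNormal) &&
        (object@pNormal < 0 || object@pNormal > 1)) {
        msg <- c(msg, "pNormal must lie in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MotifNull-class the null sample counts.
#' @param x a `MotifNull`.
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname MotifNull-class
#' @export
setMethod("nullSamples", "MotifNull", function(x) x@samples)

#' @describeIn MotifNull-class the observed in-region count.
#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))

#' @rdname MotifNull-class
#' @export
setMethod("observedCount", "MotifNull", function(x) x@observed)

setMethod("show", "MotifNull", function(object) {
    cat("MotifNull:", object@B, "resampling runs\n")
    cat(sprintf("  null mean %.3f, sd %.3f\n", object@mu, object@sd))
    cat(sprintf("  observed %g (z = %.3f)\n", object@observed, object@z))
    cat(sprintf("  P(normal, upper tail) = %.4g; P(empirical) = %.4g\n",
        object@pNormal, object@pEmpirical))
    invisible(object)
})

# ---------------------------------------------------------------------------
# DecayFit: one-phase exponential fit of a remodelling time course
# ---------------------------------------------------------------------------

#' DecayFit: one-phase exponential fit
#'
#' Parameters of the one-phase model
#' `Y(t) = Y0 + (Plateau - Y0) * (1 - exp(-K * t))`
#' fitted by [fitOnePhaseDecay()] to percent-cut remodelling time courses.
#'
#' @slot y0 fitted percent cut at t = 0.
#' @slot plateau fitted asymptotic percent cut.
#' @slot k fitted rate constant (per minute), positive.
#' @slot rss residual sum of squares at the solution.
#' @slot converged logical convergence flag.
#' @slot data the (time, pct) points the model was fitted to.
#' @seealso [fitOnePhaseDecay()], [stimulationSummary()]
#' @export
setClass("DecayFit",
    representation(
        y0 = "numeric",
        plateau = "numeric",
        k = "numeric",
        rss = "numeric",
        converged = "logical",
        data = "data.frame"
    )
)

setValidity("DecayFit", function(object) {
    msg <- character()
    if (is.finite(object@k) && object@k <= 0) msg <- c(msg, "K must be > 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn DecayFit-class fitted parameters as a named vector
#'   `c(y0, plateau, k)`.
#' @param object a `DecayFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "DecayFit", function(object, ...) {
    c(y0 = object@y0, plateau = object@plateau, k = object@k)
})

#' @describeIn DecayFit-class model percent-cut values at times `newtimes`
#'   (defaults to the fitted time points).
#' @param newtimes numeric vector of times (minutes).
#' @export
setMethod("predict", "DecayFit", function(object,
                                          newtimes = object@data$time, ...) {
    object@y0 + (object@plateau - object@y0) * (1 - exp(-object@k * newtimes))
})

setMethod("show", "DecayFit", function(object) {
    cat("DecayFit: Y(t) = Y0 + (Plateau - Y0)(1 - exp(-K t))\n")
    cat(sprintf("  Y0 = %.4f  Plateau = %.4f  K = %.5f /min\n",
        object@y0, object@plateau, object@k))
    cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
        object@rss, nrow(object@data), object@converged))
    invisible(object)
})
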