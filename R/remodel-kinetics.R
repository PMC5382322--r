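# Restriction-enzyme-accessibility (REA) remodelling kinetics: percent-cut
# quantification of gel bands and one-phase exponential fits
# Y(t) = Y0 + (Plateau - Y0)(1 - exp(-K t)) per condition, with a
# comparison table against a baseline condition.

#' Percent cut DNA from band intensities
#'
#' The ratio of cut to total DNA: `100 * cut / (cut + uncut)`.
#'
#' @param cut,uncut non-negative band intensities (vectorized).
#' @return Percent cut values in `[0, 100]`.
#' @examples
#' percentCut(30, 70)  # 30
#' @export
percentCut <- function(cut, uncut) {
    if (any(cut < 0) || any(uncut < 0)) {
        stop("band intensities must be >= 0", call. = FALSE)
    }
    total <- cut + uncut
    if (any(total == 0)) {
        stop("cut + uncut must be > 0", call. = FALSE)
    }
    100 * cut / total
}

#' Fit the one-phase exponential model to a remodelling time course
#'
#' Nonlinear least squares of
#' `Y(t) = Y0 + (Plateau - Y0) * (1 - exp(-K * t))`
#' against percent-cut values, by box-constrained Levenberg-Marquardt
#' (`0 <= Y0 <= 100`, `0 <= Plateau <= 100`, `K > 0`). Initialization is
#' deterministic: `Y0` from the earliest point, `Plateau` from the latest,
#' `K = log(2) / median(t)`. Repeated time values are treated as
#' replicates; with `average = TRUE` (the default, matching how time
#' courses are usually plotted) replicate percent-cut values are averaged
#' per time point before fitting, otherwise all points enter the fit
#' individually. Flat data are handled exactly
#' (`Y0 = Plateau = value`, `RSS = 0`).
#'
#' @param time time points in minutes (at least 3 distinct values).
#' @param pct percent-cut values, same length as `time`.
#' @param average average replicate values per time point before fitting.
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @return A [DecayFit-class]; non-convergence is flagged, not an error.
#' @examples
#' t <- c(2.5, 5, 10, 20)
#' y <- 5 + (80 - 5) * (1 - exp(-0.2 * t))
#' coef(fitOnePhaseDecay(t, y))
#' @export
fitOnePhaseDecay <- function(time, pct, average = TRUE, maxIter = 1000L) {
    stopifnot(length(time) == length(pct))
    keep <- is.finite(time) & is.finite(pct)
    time <- time[keep]
    pct <- pct[keep]
    if (length(unique(time)) < 3L) {
        stop("under-determined fit: need >= 3 distinct time points",
            call. = FALSE)
    }
    if (any(pct < -1e-9) || any(pct > 100 + 1e-9)) {
        stop("percent-cut values must lie in [0, 100]", call. = FALSE)
    }
    if (average) {
        agg <- tapply(pct, time, mean)
        time <- as.numeric(names(agg))
        pct <- as.numeric(agg)
    }
    ord <- order(time)
    time <- time[ord]
    pct <- pct[ord]
    dat <- data.frame(time = time, pct = pct)
    if (diff(range(pct)) < 1e-12) {
        return(methods::new("DecayFit",
            y0 = pct[1], plateau = pct[1], k = log(2) / median(time),
            rss = 0, converged = TRUE, data = dat
        ))
    }
    start <- list(
        y0 = min(max(pct[1], 0), 100),
        plateau = min(max(pct[length(pct)], 0), 100),
        k = log(2) / median(time)
    )
    fit <- tryCatch(
        minpack.lm::nlsLM(
            pct ~ y0 + (plateau - y0) * (1 - exp(-k * time)),
            data = dat, start = start,
            lower = c(y0 = 0, plateau = 0, k = 1e-8),
            upper = c(y0 = 100, plateau = 100, k = Inf),
            control = minpack.lm::nls.lm.control(
                maxiter = as.integer(maxIter), ftol = 1e-12, ptol = 1e-12
            )
        ),
        error = function(e) NULL
    )
    if (is.null(fit)) {
        return(methods::new("DecayFit",
            y0 = start$y0, plateau = start$plateau, k = start$k,
            rss = sum((pct - (start$y0 + (start$plateau - start$y0) *
                (1 - exp(-start$k * time))))^2),
            converged = FALSE, data = dat
        ))
    }
    est <- coef(fit)
    methods::new("DecayFit",
        y0 = unname(est["y0"]), plateau = unname(est["plateau"]),
        k = unname(est["k"]),
        rss = sum(stats::residuals(fit)^2),
        converged = fit$convInfo$isConv, data = dat
    )
}

#' Fit and compare remodelling kinetics across conditions
#'
#' Fits the one-phase model per condition (on replicate means by default)
#' and reports each condition's parameters together with its rate-constant
#' ratio and plateau difference versus a baseline condition, plus
#' per-timepoint mean and s.e.m. across replicates.
#'
#' @param tc `data.frame` with columns `condition`, `replicate`,
#'   `time_min`, and either `pct` or both `cut` and `uncut`.
#' @param baseline baseline condition label (must be present).
#' @param average fit replicate means (default) or all points pooled.
#' @return A list with `fits` (named list of [DecayFit-class]),
#'   `comparison` (`data.frame` of Y0/Plateau/K, `kRatio`,
#'   `plateauDiff`), and `timepoints` (per condition x time mean, sd,
#'   sem, n).
#' @export
stimulationSummary <- function(tc, baseline, average = TRUE) {
    required <- c("condition", "replicate", "time_min")
    if (!all(required %in% names(tc))) {
        stop("need columns: ", paste(required, collapse = ", "),
            call. = FALSE)
    }
    if (!"pct" %in% names(tc)) {
        if (!all(c("cut", "uncut") %in% names(tc))) {
            stop("need either 'pct' or both 'cut' and 'uncut' columns",
                call. = FALSE)
        }
        tc$pct <- percentCut(tc$cut, tc$uncut)
    }
    if (!baseline %in% tc$condition) {
        stop("baseline condition '", baseline, "' missing", call. = FALSE)
    }
    conds <- unique(tc$condition)
    fits <- lapply(setNames(conds, conds), function(cc) {
        g <- tc[tc$condition == cc, , drop = FALSE]
        fitOnePhaseDecay(g$time_min, g$pct, average = average)
    })
    base <- fits[[baseline]]
    comparison <- do.call(rbind, lapply(conds, function(cc) {
        f <- fits[[cc]]
        data.frame(
            condition = cc,
            y0 = f@y0, plateau = f@plateau, k = f@k,
            kRatio = f@k / base@k,
            plateauDiff = f@plateau - base@plateau,
            converged = f@converged,
            stringsAsFactors = FALSE
        )
    }))
    rownames(comparison) <- NULL
    timepoints <- do.call(rbind, lapply(
        split(tc, list(tc$condition, tc$time_min), drop = TRUE),
        function(g) {
            n <- nrow(g)
            s <- if (n > 1) sd(g$pct) else NA_real_
            data.frame(
                condition = g$condition[1], time_min = g$time_min[1],
                mean = mean(g$pct), sd = s,
                sem = if (n > 1) s / sqrt(n) else NA_real_, n = n,
                stringsAsFactors = FALSE
            )
        }
    ))
    timepoints <- timepoints[order(timepoints$condition,
        timepoints$time_min), ]
    rownames(timepoints) <- NULL
    list(fits = fits, comparison = comparison, timepoints = timepoints)
}
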