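# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random-number stream. A `NULL` seed evaluates the
#' code under the current stream.
#' @noRd
withSeed <- function(seed, code) {
    if (is.null(seed)) {
        return(force(code))
    }
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            },
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    force(code)
}

#' @noRd
assertScalarNumber <- function(x, name, lower = -Inf, strict = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        (if (strict) x > lower else x >= lower)
    if (!ok) {
        stop(sprintf(
            "'%s' must be a single finite number %s %s", name,
            if (strict) ">" else ">=", format(lower)
        ), call. = FALSE)
    }
    invisible(x)
}

#' @noRd
assertFileExists <- function(path, what = "input file") {
    if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
        stop(sprintf("%s not found: %s", what, paste(path, collapse = ", ")),
            call. = FALSE)
    }
    invisible(path)
}

#' Chromosome lengths from assorted inputs
#'
#' Accepts a named numeric vector, a `Seqinfo` object, or a `DNAStringSet`
#' genome and returns a named numeric vector of chromosome lengths.
#' @noRd
asSeqlengths <- function(x) {
    if (methods::is(x, "Seqinfo")) {
        sl <- GenomeInfoDb::seqlengths(x)
    } else if (methods::is(x, "DNAStringSet")) {
        sl <- stats::setNames(Biostrings::width(x), names(x))
    } else if (is.numeric(x) && !is.null(names(x))) {
        sl <- x
    } else {
        stop("cannot interpret chromosome sizes; supply a named numeric ",
            "vector, a Seqinfo, or a DNAStringSet", call. = FALSE)
    }
    if (any(is.na(sl)) || any(sl <= 0)) {
        stop("all chromosome lengths must be positive and known", call. = FALSE)
    }
    sl
}
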