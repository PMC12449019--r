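#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps
#' @importFrom Biostrings DNAStringSet reverseComplement subseq
#'   matchPattern readDNAStringSet writeXStringSet
#' @importFrom GenomeInfoDb seqlevels
NULL

#' MiRNASpace: an exact-match reference over hairpin precursors
#'
#' A `MiRNASpace` holds the union of hairpin precursor sequences (known and
#' predicted) together with the hairpin-local coordinates of their mature
#' miRNAs, and optionally an exact-occurrence index over all hairpin
#' substrings in a fixed length window.  Reads are matched sense-only within
#' hairpins; mature coordinates are hairpin-local, 0-based, half-open,
#' counted from the hairpin 5' end.
#'
#' @slot hairpins A named [Biostrings::DNAStringSet] of hairpin sequences,
#'   5'->3' on the hairpin (i.e. reverse-complemented from the genome for
#'   minus-strand loci).
#' @slot hairpinRanges A [GenomicRanges::GRanges] with one range per
#'   hairpin (1-based, as is native to `GRanges`), carrying metadata columns
#'   `hairpin_id` and `origin` (`"known"` or `"predicted"`).
#' @slot matures A `data.frame` with columns `name`, `hairpin_id`,
#'   `local_start`, `local_end` (0-based half-open within the hairpin) and
#'   `sequence`.
#' @slot index An environment mapping a substring to a `data.frame` of
#'   `(hairpin_id, offset)` exact sense-strand occurrences; empty until
#'   [buildSpaceIndex()] is called.
#' @slot indexParams List with elements `min_len` and `max_len`, the length
#'   window covered by the index.
#'
#' @seealso [loadAnnotation()], [buildSpaceIndex()], [spaceLookup()],
#'   [tagLocation()]
#' @export
setClass("MiRNASpace",
    representation(
        hairpins = "DNAStringSet",
        hairpinRanges = "GRanges",
        matures = "data.frame",
        index = "environment",
        indexParams = "list"
    ),
    prototype(
        matures = data.frame(
            name = character(), hairpin_id = character(),
            local_start = integer(), local_end = integer(),
            sequence = character(), stringsAsFactors = FALSE
        ),
        indexParams = list()
    )
)

setValidity("MiRNASpace", function(object) {
    msg <- character()
    hp <- object@hairpins
    ids <- names(hp)
    if (length(hp) && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msg <- c(msg, "all hairpins must be named")
    if (anyDuplicated(ids))
        msg <- c(msg, paste0("duplicate hairpin ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    m <- object@matures
    need <- c("name", "hairpin_id", "local_start", "local_end", "sequence")
    if (!all(need %in% names(m))) {
        msg <- c(msg, "matures must have columns name, hairpin_id, local_start, local_end, sequence")
    } else if (nrow(m)) {
        bad <- !(m$hairpin_id %in% ids)
        if (any(bad))
            msg <- c(msg, paste0("mature(s) reference unknown hairpin: ",
                paste(m$name[bad], collapse = ", ")))
        ok <- m$hairpin_id %in% ids
        if (any(ok)) {
            hlen <- width(hp)[match(m$hairpin_id[ok], ids)]
            ms <- m[ok, , drop = FALSE]
            oob <- ms$local_start < 0L | ms$local_end > hlen |
                ms$local_start >= ms$local_end
            if (any(oob))
                msg <- c(msg, paste0("mature coordinates outside hairpin bounds: ",
                    paste(ms$name[oob], collapse = ", ")))
            if (!any(oob)) {
                sub <- substr(as.character(hp[match(ms$hairpin_id, ids)]),
                    ms$local_start + 1L, ms$local_end)
                mis <- sub != toupper(gsub("U", "T", ms$sequence))
                if (any(mis))
                    msg <- c(msg, paste0("mature sequence does not match hairpin substring: ",
                        paste(ms$name[mis], collapse = ", ")))
            }
        }
        short <- (m$local_end - m$local_start) < 17L
        if (any(short))
            msg <- c(msg, paste0("mature shorter than 17 nt: ",
                paste(m$name[short], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MiRNASpace Number of hairpins in the space.
#' @param x,object A `MiRNASpace`.
#' @export
setMethod("length", "MiRNASpace", function(x) length(x@hairpins))

#' Accessors for MiRNASpace components
#'
#' `hairpins()` returns the hairpin sequences, `hairpinRanges()` their
#' genomic ranges, and `matures()` the mature reference table.
#'
#' @param x A [MiRNASpace] object.
#' @return `hairpins()`: a named `DNAStringSet`; `hairpinRanges()`: a
#'   `GRanges`; `matures()`: a `data.frame`.
#' @name MiRNASpace-accessors
#' @export
hairpins <- function(x) {
    stopifnot(is(x, "MiRNASpace"))
    x@hairpins
}

#' @rdname MiRNASpace-accessors
#' @export
hairpinRanges <- function(x) {
    stopifnot(is(x, "MiRNASpace"))
    x@hairpinRanges
}

#' @rdname MiRNASpace-accessors
#' @export
matures <- function(x) {
    stopifnot(is(x, "MiRNASpace"))
    x@matures
}

setMethod("show", "MiRNASpace", function(object) {
    idx <- length(object@indexParams)
    cat("MiRNASpace with", length(object@hairpins), "hairpin(s) and",
        nrow(object@matures), "mature reference(s)\n")
    if (length(object@hairpinRanges))
        cat("  genomic ranges on:",
            paste(seqlevels(object@hairpinRanges), collapse = ", "), "\n")
    if (idx) {
        cat("  occurrence index: lengths [", object@indexParams$min_len,
            ", ", object@indexParams$max_len, "], ",
            length(ls(object@index)), " distinct substrings\n", sep = "")
    } else {
        cat("  occurrence index: not built (see buildSpaceIndex())\n")
    }
})

#' TruthBundle: a synthetic reference with generating labels
#'
#' Container produced by the synthetic-data generators: a random genome
#' with embedded hairpin loci, the matching [MiRNASpace], declared repeat
#' intervals, and the ground-truth tables used to validate placement,
#' classification and specificity scoring.
#'
#' @slot genome A named [Biostrings::DNAStringSet] of chromosomes.
#' @slot space The [MiRNASpace] built over the embedded hairpins.
#' @slot repeats A [GenomicRanges::GRanges] of declared repeat intervals.
#' @slot truth A `data.frame` of per-mature ground truth (expected
#'   exclusivity and repeat overlap).
#' @slot params Generator parameters, including the seed.
#' @export
setClass("TruthBundle",
    representation(
        genome = "DNAStringSet",
        space = "MiRNASpace",
        repeats = "GRanges",
        truth = "data.frame",
        params = "list"
    )
)

setMethod("show", "TruthBundle", function(object) {
    cat("TruthBundle:", sum(width(object@genome)), "bp genome over",
        length(object@genome), "chromosome(s);",
        length(object@space), "hairpins;",
        length(object@repeats), "repeat interval(s)\n")
    cat("  seed:", object@params$seed, "\n")
})

#' @describeIn TruthBundle Accessor for the genome sequences.
#' @param x,object A `TruthBundle`.
#' @export
bundleGenome <- function(x) {
    stopifnot(is(x, "TruthBundle"))
    x@genome
}

#' @describeIn TruthBundle Accessor for the embedded [MiRNASpace].
#' @export
bundleSpace <- function(x) {
    stopifnot(is(x, "TruthBundle"))
    x@space
}

#' @describeIn TruthBundle Accessor for the declared repeat intervals.
#' @export
bundleRepeats <- function(x) {
    stopifnot(is(x, "TruthBundle"))
    x@repeats
}

#' @describeIn TruthBundle Accessor for the ground-truth table.
#' @export
bundleTruth <- function(x) {
    stopifnot(is(x, "TruthBundle"))
    x@truth
}

#' @describeIn TruthBundle Accessor for the generator parameters.
#' @export
bundleParams <- function(x) {
    stopifnot(is(x, "TruthBundle"))
    x@params
}
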