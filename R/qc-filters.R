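#' Read length filter
#'
#' Retains reads whose length lies in `[minLen, maxLen]`, the window in
#' which mature miRNAs and their isomiRs are expected (shorter fragments
#' are degradation products; longer ones are other small-RNA species).
#'
#' @param reads `data.frame` with a `sequence` column (other columns are
#'   carried through), or a character vector.
#' @param minLen,maxLen Inclusive length bounds (defaults 17 and 25).
#' @return The retained subset, same type as the input.
#' @export
lengthFilter <- function(reads, minLen = 17L, maxLen = 25L) {
    if (minLen > maxLen)
        stop("minLen must be <= maxLen")
    sq <- if (is.data.frame(reads)) reads$sequence else reads
    keep <- nchar(sq) >= minLen & nchar(sq) <= maxLen
    if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Low-depth sample filter on the unbiased MAD of log2 read counts
#'
#' Flags samples whose log2 post-filtered read count falls more than
#' `k` unbiased median absolute deviations below the median across all
#' samples.  The unbiased MAD is the raw MAD scaled by the
#' normal-consistency constant 1.4826; the filter is one-sided, removing
#' only low-depth outliers.
#'
#' @param postFilteredReads Named numeric vector of post-filtered read
#'   counts per sample (all positive).
#' @param k Multiplier on the unbiased MAD (default 3).
#' @param unbiased Scale the MAD by 1.4826 (default `TRUE`); set `FALSE`
#'   for the raw MAD.
#' @return Named logical vector: `TRUE` = pass, `FALSE` = excluded.  The
#'   cutoff used is attached as attribute `"cutoff"` (on the log2 scale).
#' @examples
#' reads <- 2^c(a = 18, b = 19, c = 20, d = 21, e = 22, f = 5)
#' madSampleFilter(reads)  # only the 2^5 sample fails
#' @export
madSampleFilter <- function(postFilteredReads, k = 3, unbiased = TRUE) {
    if (length(postFilteredReads) < 2L)
        stop("at least 2 samples are required")
    if (any(postFilteredReads <= 0))
        stop("all post-filtered read counts must be positive (log2 undefined)")
    y <- log2(postFilteredReads)
    m <- stats::median(y)
    madStar <- stats::mad(y, constant = if (unbiased) 1.4826 else 1)
    cutoff <- m - k * madStar
    pass <- !(y < cutoff)
    structure(pass, cutoff = cutoff, names = names(postFilteredReads))
}

#' miRNA biotype-fraction sample filter
#'
#' Flags samples in which fewer than `minFraction` of post-filtered reads
#' were assigned to miRNA biotypes (as estimated upstream by a biotype
#' counter); such libraries are dominated by other RNA species and carry
#' little miRNA signal.  The comparison is strict: a fraction exactly at
#' the threshold passes.
#'
#' @param fraction Named numeric vector of per-sample miRNA biotype
#'   fractions in `[0, 1]`.
#' @param minFraction Threshold (default 0.10).
#' @return Named logical vector: `TRUE` = pass.
#' @export
biotypeFilter <- function(fraction, minFraction = 0.10) {
    if (any(fraction < 0 | fraction > 1))
        stop("biotype fractions must lie in [0, 1]")
    structure(fraction >= minFraction, names = names(fraction))
}

#' Missingness sample filter
#'
#' Flags samples in which at least `maxZeroFraction` of features have an
#' RPM of zero (the comparison is inclusive: exactly 90% zeros fails at
#' the default).
#'
#' @param rpm Numeric matrix, features x samples.
#' @param maxZeroFraction Threshold (default 0.90).
#' @return Named logical vector over samples: `TRUE` = pass.
#' @export
missingnessFilter <- function(rpm, maxZeroFraction = 0.90) {
    if (!is.matrix(rpm) || nrow(rpm) < 1L)
        stop("rpm must be a matrix with at least one feature")
    zeroFrac <- colMeans(rpm == 0)
    structure(zeroFrac < maxZeroFraction, names = colnames(rpm))
}

#' Feature expression filter
#'
#' Keeps a feature only when its RPM exceeds `minRpm` in at least
#' `minSamples` samples.  The comparison is strict (`>`) by default,
#' matching the atlas-level retention rule; set `inclusive = TRUE` for the
#' `>=` variant used when screening predicted hairpins.
#'
#' @param rpm Numeric matrix, features x samples.
#' @param minRpm RPM threshold (default 20).
#' @param minSamples Minimum number of qualifying samples (default 2).
#' @param inclusive Use `>=` instead of `>` (default `FALSE`).
#' @return Named logical vector over features: `TRUE` = keep.
#' @export
expressionFilter <- function(rpm, minRpm = 20, minSamples = 2L,
        inclusive = FALSE) {
    if (minSamples < 1L)
        stop("minSamples must be at least 1")
    n <- if (inclusive) rowSums(rpm >= minRpm) else rowSums(rpm > minRpm)
    structure(n >= minSamples, names = rownames(rpm))
}

#' Low-signal sample filter
#'
#' Flags samples in which fewer than `minNonzeroFraction` of retained
#' features have non-zero RPM.  Applied after feature-level filtering, it
#' removes libraries that barely sample the retained miRNA repertoire.
#' A fraction exactly at the threshold passes.
#'
#' @param rpm Numeric matrix, features x samples (post feature filtering).
#' @param minNonzeroFraction Threshold (default 0.10).
#' @return Named logical vector over samples: `TRUE` = pass.
#' @export
lowSignalSampleFilter <- function(rpm, minNonzeroFraction = 0.10) {
    if (!is.matrix(rpm) || nrow(rpm) < 1L)
        stop("rpm must be a matrix with at least one feature")
    nz <- colMeans(rpm != 0)
    structure(nz >= minNonzeroFraction, names = colnames(rpm))
}

#' Minimum independent samples per tissue
#'
#' Drops tissues with fewer than `minN` surviving samples; tissue-level
#' summaries from a single library are not reproducible measurements.
#'
#' @param tissue Character vector of tissue labels, one per surviving
#'   sample.
#' @param minN Minimum sample count per tissue (default 2).
#' @return Named logical vector over unique tissues: `TRUE` = keep.
#' @export
tissueMinSamples <- function(tissue, minN = 2L) {
    tab <- table(tissue)
    keep <- as.vector(tab) >= minN
    structure(keep, names = names(tab))
}

#' Run the full QC filter cascade
#'
#' Applies, in order: read length filter, MAD depth filter, biotype
#' filter, tissue minimum-sample check, feature expression filter,
#' low-signal sample filter, missingness sample filter, and a final
#' tissue minimum-sample re-check (sample-level drops can strand a
#' tissue below the minimum).  Every step is recorded with before/after
#' counts so the attrition is fully auditable.
#'
#' @param rpm Numeric matrix of RPMs, features x samples.
#' @param sampleInfo `data.frame` with columns `sample`, `tissue`,
#'   `post_filtered_reads`, `mirna_biotype_fraction`; one row per column
#'   of `rpm`.
#' @param reads Optional `data.frame` of reads with a `sequence` column
#'   for the length step; when `NULL` the step is recorded as a no-op.
#' @param config Named list overriding defaults: `min_len`, `max_len`,
#'   `mad_k`, `mad_unbiased`, `min_biotype_fraction`, `tissue_min_n`,
#'   `min_rpm`, `min_expr_samples`, `expr_inclusive`,
#'   `min_nonzero_fraction`, `max_zero_fraction`.
#' @return A list with:
#'   \describe{
#'     \item{report}{`data.frame` with one row per step: `step`, `unit`,
#'       `before`, `after`, `removed`.}
#'     \item{samples}{surviving sample ids.}
#'     \item{features}{surviving feature ids.}
#'     \item{tissues}{surviving tissue labels.}
#'     \item{reads}{the length-filtered read table (or `NULL`).}
#'     \item{rpm}{the surviving submatrix.}
#'     \item{config}{the resolved configuration.}
#'   }
#' @export
runQCCascade <- function(rpm, sampleInfo, reads = NULL, config = list()) {
    cfg <- utils::modifyList(list(
        min_len = 17L, max_len = 25L, mad_k = 3, mad_unbiased = TRUE,
        min_biotype_fraction = 0.10, tissue_min_n = 2L,
        min_rpm = 20, min_expr_samples = 2L, expr_inclusive = FALSE,
        min_nonzero_fraction = 0.10, max_zero_fraction = 0.90), config)
    stopifnot(is.matrix(rpm),
        all(c("sample", "tissue", "post_filtered_reads",
            "mirna_biotype_fraction") %in% names(sampleInfo)))
    if (!setequal(colnames(rpm), sampleInfo$sample))
        stop("rpm columns and sampleInfo$sample disagree")
    sampleInfo <- sampleInfo[match(colnames(rpm), sampleInfo$sample), ]

    steps <- list()
    note <- function(step, unit, before, after) {
        steps[[length(steps) + 1L]] <<- data.frame(step = step, unit = unit,
            before = before, after = after, removed = before - after,
            stringsAsFactors = FALSE)
    }

    # 1. read length
    if (!is.null(reads)) {
        n0 <- nrow(reads)
        reads <- lengthFilter(reads, cfg$min_len, cfg$max_len)
        note("length", "reads", n0, nrow(reads))
    } else {
        note("length", "reads", 0L, 0L)
    }

    samples <- sampleInfo$sample

    # 2. MAD depth
    depth <- stats::setNames(sampleInfo$post_filtered_reads, samples)
    pass <- madSampleFilter(depth, k = cfg$mad_k,
        unbiased = cfg$mad_unbiased)
    note("mad_depth", "samples", length(samples), sum(pass))
    samples <- samples[pass]

    # 3. biotype fraction
    frac <- stats::setNames(sampleInfo$mirna_biotype_fraction,
        sampleInfo$sample)[samples]
    pass <- biotypeFilter(frac, cfg$min_biotype_fraction)
    note("biotype", "samples", length(samples), sum(pass))
    samples <- samples[pass]

    # 4. tissue minimum (first pass)
    tissueOf <- stats::setNames(sampleInfo$tissue, sampleInfo$sample)
    allTissues <- unique(sampleInfo$tissue)
    keepT <- tissueMinSamples(tissueOf[samples], cfg$tissue_min_n)
    tissues <- names(keepT)[keepT]
    note("tissue_min", "tissues", length(allTissues), length(tissues))
    samples <- samples[tissueOf[samples] %in% tissues]

    # 5. feature expression
    sub <- rpm[, samples, drop = FALSE]
    keepF <- expressionFilter(sub, cfg$min_rpm, cfg$min_expr_samples,
        cfg$expr_inclusive)
    note("expression", "features", nrow(sub), sum(keepF))
    features <- rownames(sub)[keepF]
    sub <- sub[features, , drop = FALSE]

    # 6. low-signal samples
    pass <- lowSignalSampleFilter(sub, cfg$min_nonzero_fraction)
    note("low_signal", "samples", length(samples), sum(pass))
    samples <- samples[pass]
    sub <- sub[, samples, drop = FALSE]

    # 7. missingness
    pass <- missingnessFilter(sub, cfg$max_zero_fraction)
    note("missingness", "samples", length(samples), sum(pass))
    samples <- samples[pass]
    sub <- sub[, samples, drop = FALSE]

    # 8. tissue minimum re-check
    keepT <- tissueMinSamples(tissueOf[samples], cfg$tissue_min_n)
    tissues2 <- names(keepT)[keepT]
    note("tissue_min_recheck", "tissues", length(tissues), length(tissues2))
    samples <- samples[tissueOf[samples] %in% tissues2]
    sub <- sub[, samples, drop = FALSE]

    report <- do.call(rbind, steps)
    rownames(report) <- NULL
    list(report = report, samples = samples, features = features,
        tissues = tissues2, reads = reads, rpm = sub, config = cfg)
}
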