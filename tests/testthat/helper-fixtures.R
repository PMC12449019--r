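# Hand-built fixtures and independent oracles.  The oracles deliberately
# avoid the package's own code paths (and Biostrings where practical) so
# they can arbitrate disagreements.

# Reverse complement via plain string reversal -- independent of
# Biostrings::reverseComplement().
oracleRevcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# All exact occurrences of `query` in a single sequence string, 1-based
# start positions, overlapping matches included (naive substring scan).
oracleFindAll <- function(query, subject) {
    L <- nchar(query)
    n <- nchar(subject)
    if (n < L) return(integer())
    starts <- seq_len(n - L + 1L)
    starts[substring(subject, starts, starts + L - 1L) == query]
}

# Both-strand genome occurrence oracle; genome is a named character
# vector.  Returns a data.frame(chrom, start, end, strand), 1-based
# inclusive, strand = strand on which the query reads 5'->3'.
oracleGenomeScan <- function(query, genomeChr) {
    out <- list()
    for (chrom in names(genomeChr)) {
        for (st in oracleFindAll(query, genomeChr[[chrom]]))
            out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                start = st, end = st + nchar(query) - 1L, strand = "+",
                stringsAsFactors = FALSE)
        for (st in oracleFindAll(oracleRevcomp(query), genomeChr[[chrom]]))
            out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                start = st, end = st + nchar(query) - 1L, strand = "-",
                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
            end = integer(), strand = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

# Naive (hairpin, offset) scan over a named character vector of hairpin
# sequences -- the oracle for the occurrence index.
oracleHairpinScan <- function(query, hairpinChr) {
    out <- list()
    for (id in names(hairpinChr)) {
        for (st in oracleFindAll(query, hairpinChr[[id]]))
            out[[length(out) + 1L]] <- data.frame(hairpin_id = id,
                offset = st - 1L, stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(hairpin_id = character(), offset = integer(),
            stringsAsFactors = FALSE))
    do.call(rbind, out)
}

# Low-depth MAD filter recomputed from first principles (sort-based
# median, no stats::mad / stats::median).
oracleMadFilter <- function(counts, k = 3) {
    med <- function(v) {
        v <- sort(v)
        n <- length(v)
        if (n %% 2L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
    }
    y <- log(counts, base = 2)
    m <- med(y)
    madStar <- 1.4826 * med(abs(y - m))
    !(y < m - k * madStar)
}

# A 60-nt hairpin fixture engineered by hand for the placement and
# classification examples.  The mature occupies local [10, 32) (22 nt)
# and the continuation base just past the mature 3' end is "G", so a
# read of mature+"A" must carry a non-templated tail while mature+"G"
# is the templated 1-nt 3' extension.
fixtureSpace <- function() {
    mature <- "TGAGGTAGTAGGTTGTATAGTT"           # 22 nt (let-7 family)
    hp1 <- paste0("CCTGGCATGA", mature, "GGGAACTATACAACCTACTACCTCAACC")
    stopifnot(nchar(hp1) == 60,
        substr(hp1, 11, 32) == mature,
        substr(hp1, 33, 33) == "G")
    # second hairpin shares no 17-mer with hp1
    hp2 <- paste0("ATTCGTACGG", "ACCGTTCAAGTCCAGCAATCAG",
        "TTGTCCGAATGGCTACAAATTCGATCAA")
    stopifnot(nchar(hp2) == 60)
    matureTab <- data.frame(
        name = c("fix-miR-1", "fix-miR-2"),
        hairpin_id = c("fix-hp-1", "fix-hp-2"),
        local_start = c(10L, 10L),
        local_end = c(32L, 32L),
        stringsAsFactors = FALSE)
    buildSpaceIndex(MiRNASpaceFromSeqs(
        c("fix-hp-1" = hp1, "fix-hp-2" = hp2), matureTab))
}

fixtureMature <- function(space = fixtureSpace(), name = "fix-miR-1") {
    m <- matures(space)
    m[m$name == name, ]
}

# QC cascade fixture engineered so that each of the seven distinct filter
# steps removes exactly one item and the final tissue re-check removes
# none.  See test-qc-filters.R for the arithmetic.
fixtureCascade <- function() {
    samples <- paste0("s", 1:8)
    tissue <- c("TA", "TA", rep("TB", 6))
    depth <- 2^c(5, 18, 19, 20, 21, 22, 20, 21)
    biotype <- c(0.5, 0.05, rep(0.5, 6))
    sampleInfo <- data.frame(sample = samples, tissue = tissue,
        post_filtered_reads = depth, mirna_biotype_fraction = biotype,
        stringsAsFactors = FALSE)
    features <- paste0("f", 1:11)
    rpm <- matrix(0, 11, 8, dimnames = list(features, samples))
    rpm[1:10, c("s3", "s4", "s7", "s8")] <- 100   # broadly expressed
    rpm["f1", "s6"] <- 30                         # s6's single signal
    rpm["f11", "s3"] <- 100                       # one-sample feature
    rpm[1:10, c("s1", "s2")] <- 50                # irrelevant: dropped early
    reads <- data.frame(
        sequence = c(strrep("A", 16), strrep("C", 17), strrep("G", 20),
            strrep("T", 25), strrep("A", 22)),
        stringsAsFactors = FALSE)
    list(rpm = rpm, sampleInfo = sampleInfo, reads = reads)
}
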