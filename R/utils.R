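# Internal helpers shared across modules.

# Normalize a nucleotide string to the internal DNA alphabet: uppercase,
# U -> T.  Rejects characters outside A,C,G,T,U,N.
.normSeq <- function(x, allowN = TRUE) {
    x <- toupper(x)
    x <- chartr("U", "T", x)
    alphabet <- if (allowN) "ACGTN" else "ACGT"
    bad <- grepl(sprintf("[^%s]", alphabet), x)
    if (any(bad))
        stop("sequence contains characters outside {A,C,G,T/U",
            if (allowN) ",N", "}: ",
            paste(utils::head(x[bad], 3L), collapse = ", "))
    x
}

# Render internal DNA strings as RNA (T -> U) when requested.
.renderSeq <- function(x, alphabet = c("DNA", "RNA")) {
    alphabet <- match.arg(alphabet)
    if (alphabet == "RNA") chartr("T", "U", x) else x
}

.revcomp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

# All exact occurrences of `pattern` (sense string) on both strands of a
# DNAStringSet genome.  Returns a GRanges (1-based) with strand set to the
# strand on which the sense pattern reads 5'->3'.
.genomeOccurrences <- function(pattern, genome) {
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
    pattern <- .normSeq(pattern, allowN = FALSE)
    hits <- list()
    rc <- .revcomp(pattern)
    for (chrom in names(genome)) {
        fwd <- matchPattern(pattern, genome[[chrom]])
        if (length(fwd))
            hits[[length(hits) + 1L]] <- GRanges(chrom,
                IRanges(start(fwd), end(fwd)), strand = "+")
        rev <- matchPattern(rc, genome[[chrom]])
        if (length(rev))
            hits[[length(hits) + 1L]] <- GRanges(chrom,
                IRanges(start(rev), end(rev)), strand = "-")
    }
    if (!length(hits))
        return(GRanges())
    suppressWarnings(do.call(c, hits))
}

# Write a matrix as a TSV with a provenance header comment.
.writeMatrixTSV <- function(mat, file, what = "matrix", params = list()) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader(what, params), con)
    df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

.readMatrixTSV <- function(file) {
    df <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
        check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    mat
}

.provenanceHeader <- function(what, params = list()) {
    ver <- tryCatch(as.character(utils::packageVersion("isomiRatlas")),
        error = function(e) "dev")
    ptxt <- if (length(params)) {
        paste(names(params), vapply(params, function(p)
            paste(format(p), collapse = ","), character(1)),
            sep = "=", collapse = "; ")
    } else "none"
    phash <- substr(.stringDigest(ptxt), 1L, 12L)
    c(sprintf("# isomiRatlas %s :: %s", ver, what),
      sprintf("# parameters: %s", ptxt),
      sprintf("# parameter_hash: %s", phash))
}

# md5 of a string via tools::md5sum on a temp file (no extra deps).
.stringDigest <- function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(x, tf)
    unname(tools::md5sum(tf))
}
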