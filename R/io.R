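#' Export a MiRNASpace annotation as GFF3
#'
#' Writes hairpins as `miRNA_primary_transcript` features and matures as
#' `miRNA` features with `Derives_from` attributes, converting
#' hairpin-local mature offsets back to genomic coordinates (GFF3 is
#' 1-based inclusive; `rtracklayer` performs the conversion from the
#' `GRanges` representation).  Reimporting the file with
#' [loadAnnotation()] reproduces identical hairpin sequences.
#'
#' @param space A [MiRNASpace] with genomic `hairpinRanges`.
#' @param file Output GFF3 path.
#' @return `file`, invisibly.
#' @export
exportAnnotationGFF3 <- function(space, file) {
    stopifnot(is(space, "MiRNASpace"))
    hp <- space@hairpinRanges
    if (!length(hp))
        stop("space carries no genomic hairpin ranges")
    S4Vectors::mcols(hp) <- S4Vectors::DataFrame(
        type = "miRNA_primary_transcript", ID = hp$hairpin_id,
        origin = hp$origin)
    m <- space@matures
    if (nrow(m)) {
        j <- match(m$hairpin_id, space@hairpinRanges$hairpin_id)
        plus <- as.character(strand(space@hairpinRanges))[j] == "+"
        gStart <- ifelse(plus, start(space@hairpinRanges)[j] + m$local_start,
            end(space@hairpinRanges)[j] - m$local_end + 1L)
        gEnd <- ifelse(plus, start(space@hairpinRanges)[j] + m$local_end - 1L,
            end(space@hairpinRanges)[j] - m$local_start)
        mt <- GRanges(seqnames(space@hairpinRanges)[j],
            IRanges(gStart, gEnd),
            strand = strand(space@hairpinRanges)[j],
            type = "miRNA", ID = m$name, Derives_from = m$hairpin_id)
        gr <- c(hp, mt)
    } else {
        gr <- hp
    }
    rtracklayer::export(gr, file, format = "gff3")
    invisible(file)
}

#' Serialize / load a miRNA-space bundle directory
#'
#' `writeSpaceBundle()` writes the hairpin FASTA, the mature table TSV, a
#' GFF3 of genomic coordinates when available, and a JSON manifest with
#' per-file md5 checksums and the index parameters.  `readSpaceBundle()`
#' reconstructs the (indexed) [MiRNASpace], verifying the checksums.
#'
#' @param space A [MiRNASpace].
#' @param dir Bundle directory (created if needed).
#' @return `writeSpaceBundle()`: `dir`, invisibly; `readSpaceBundle()`:
#'   a [MiRNASpace].
#' @export
writeSpaceBundle <- function(space, dir) {
    stopifnot(is(space, "MiRNASpace"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fastaFile <- file.path(dir, "hairpins.fa")
    writeXStringSet(space@hairpins, fastaFile)
    matureFile <- file.path(dir, "matures.tsv")
    utils::write.table(space@matures, matureFile, sep = "\t",
        quote = FALSE, row.names = FALSE)
    files <- c(fastaFile, matureFile)
    if (length(space@hairpinRanges)) {
        gffFile <- file.path(dir, "annotation.gff3")
        exportAnnotationGFF3(space, gffFile)
        files <- c(files, gffFile)
    }
    manifest <- list(
        format = "isomiRatlas-space-bundle",
        version = as.character(utils::packageVersion("isomiRatlas")),
        index_params = space@indexParams,
        checksums = as.list(stats::setNames(
            unname(tools::md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' @rdname writeSpaceBundle
#' @export
readSpaceBundle <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
    for (f in names(manifest$checksums)) {
        path <- file.path(dir, f)
        if (!file.exists(path))
            stop("bundle file missing: ", f)
        if (unname(tools::md5sum(path)) != manifest$checksums[[f]])
            stop("bundle checksum mismatch for ", f)
    }
    hp <- readDNAStringSet(file.path(dir, "hairpins.fa"))
    names(hp) <- sub("\\s.*$", "", names(hp))
    m <- utils::read.table(file.path(dir, "matures.tsv"), sep = "\t",
        header = TRUE, stringsAsFactors = FALSE)
    gffFile <- file.path(dir, "annotation.gff3")
    ranges <- if (file.exists(gffFile)) {
        gr <- rtracklayer::import(gffFile)
        gr <- gr[as.character(gr$type) == "miRNA_primary_transcript"]
        GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
            strand = strand(gr), hairpin_id = gr$ID,
            origin = if ("origin" %in% names(S4Vectors::mcols(gr)))
                as.character(gr$origin) else "known")
    } else GRanges()
    space <- new("MiRNASpace", hairpins = hp, hairpinRanges = ranges,
        matures = m, index = new.env(parent = emptyenv()),
        indexParams = list())
    ip <- manifest$index_params
    if (length(ip))
        space <- buildSpaceIndex(space, ip$min_len, ip$max_len)
    space
}

#' Read collapsed reads as (sequence, count) pairs
#'
#' Accepts a 2-column TSV (`sequence`, `count`), or FASTA/FASTQ in which
#' each record counts once (duplicate sequences are aggregated).  `U` is
#' accepted and stored as `T`.
#'
#' @param file Input path; format inferred from the extension
#'   (`.tsv`/`.txt` vs `.fa`/`.fasta`/`.fq`/`.fastq`, optionally `.gz`).
#' @return `data.frame` with columns `sequence` and `count`.
#' @export
readSequenceCounts <- function(file) {
    base <- sub("\\.gz$", "", file)
    ext <- tolower(tools::file_ext(base))
    if (ext %in% c("tsv", "txt")) {
        df <- utils::read.table(file, sep = "\t", header = TRUE,
            comment.char = "#", stringsAsFactors = FALSE)
        if (!all(c("sequence", "count") %in% names(df)))
            stop("sequence-count TSV needs columns 'sequence' and 'count'")
        return(df[c("sequence", "count")])
    }
    fmt <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
    seqs <- as.character(readDNAStringSet(file, format = fmt))
    tab <- table(.normSeq(seqs))
    data.frame(sequence = names(tab), count = as.integer(tab),
        stringsAsFactors = FALSE)
}

#' Write a variant annotation table in a miRGFF3-style tab dialect
#'
#' One row per (sequence, parent) with a compact variant string
#' (`iso_5p:<d5>;iso_3p:<d3>;iso_add3p:<nt_len>`, or `NA` for canonical
#' reads), the class label and, when available, the location tag.  The
#' header carries tool version and parameter hash comments.
#'
#' @param assignments The `assignments` table from [quantifySample()].
#' @param file Output path.
#' @param location Optional location-tag table from [tagLocation()],
#'   joined by `sequence`.
#' @return `file`, invisibly.
#' @export
writeMirGFF3Table <- function(assignments, file, location = NULL) {
    variant <- ifelse(assignments$class == "canonical", "NA",
        sprintf("iso_5p:%+d;iso_3p:%+d;iso_add3p:%d",
            assignments$d5, assignments$d3, assignments$nt_len))
    out <- data.frame(
        sequence = assignments$sequence,
        uid = assignments$uid,
        parent = assignments$mature,
        variant = variant,
        class = assignments$class,
        stringsAsFactors = FALSE)
    if (!is.null(location)) {
        j <- match(out$sequence, location$sequence)
        out$location <- ifelse(is.na(j), "untagged",
            ifelse(location$repeat_overlap[j],
                paste0(location$exclusivity[j], ";repeat"),
                location$exclusivity[j]))
    }
    out$count <- assignments$count
    out$rpm <- assignments$rpm
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(.provenanceHeader("miRGFF3-style variant table"), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(file)
}

#' Write / read expression matrices as TSV with provenance headers
#'
#' Features are rows and samples columns; `#`-prefixed header comments
#' carry the tool version and a parameter hash, and the column order is
#' stable for a fixed input.
#'
#' @param mat Numeric matrix with row and column names.
#' @param file TSV path.
#' @param what Short label written into the header comment.
#' @param params Named list recorded (hashed) in the header.
#' @return `writeExpressionMatrix()`: `file`, invisibly;
#'   `readExpressionMatrix()`: the matrix.
#' @export
writeExpressionMatrix <- function(mat, file, what = "expression matrix",
        params = list()) {
    .writeMatrixTSV(mat, file, what, params)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(file) {
    .readMatrixTSV(file)
}
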