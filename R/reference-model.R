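#' Load a hairpin/mature annotation against a genome into a MiRNASpace
#'
#' Reads hairpin precursor loci and mature miRNA coordinates, extracts
#' strand-correct hairpin sequences from the genome (minus-strand loci are
#' reverse-complemented so every hairpin string reads 5'->3'), and converts
#' mature coordinates to hairpin-local 0-based half-open offsets counted
#' from the hairpin 5' end.  `T` and `U` are treated as equivalent on input
#' and stored internally as DNA letters.
#'
#' Two annotation layouts are accepted:
#' \itemize{
#'   \item a single GFF3 file (or `GRanges`) with feature types
#'     `miRNA_primary_transcript` (attribute `ID`) and `miRNA`
#'     (attributes `ID` and `Derives_from` naming the parent hairpin);
#'   \item a hairpin BED file (or `GRanges`) plus a mature BED via
#'     `matureAnnotation`; matures are then linked to the hairpin whose
#'     interval contains them on the same strand.
#' }
#'
#' @param annotation Path to a GFF3/BED file, or a `GRanges`.  BED
#'   coordinates are 0-based half-open on disk; `rtracklayer` converts them
#'   to the 1-based `GRanges` convention on import.
#' @param genome Path to a FASTA file or a named
#'   [Biostrings::DNAStringSet].
#' @param matureAnnotation Optional mature loci (path or `GRanges`) when
#'   `annotation` carries only hairpins.
#' @param origin Origin label recorded per hairpin when the annotation does
#'   not carry an `origin` attribute: `"known"` or `"predicted"`.
#' @return A [MiRNASpace] (occurrence index not yet built).
#' @examples
#' bundle <- makeReference(seed = 1, nHairpins = 4, genomeLen = 5000)
#' space <- bundleSpace(bundle)
#' space
#' @export
loadAnnotation <- function(annotation, genome, matureAnnotation = NULL,
        origin = c("known", "predicted")) {
    origin <- match.arg(origin)
    genome <- .loadGenome(genome)
    ann <- .loadRanges(annotation)

    if ("type" %in% names(S4Vectors::mcols(ann)) &&
            any(as.character(ann$type) == "miRNA_primary_transcript")) {
        type <- as.character(ann$type)
        hp <- ann[type == "miRNA_primary_transcript"]
        mt <- ann[type == "miRNA"]
        hpIds <- .annField(hp, c("ID", "Name", "name"))
        mtNames <- .annField(mt, c("ID", "Name", "name"))
        mtParent <- .annField(mt, c("Derives_from", "Parent"))
    } else {
        hp <- ann
        hpIds <- .annField(hp, c("ID", "Name", "name"))
        if (is.null(matureAnnotation)) {
            mt <- GRanges()
            mtNames <- mtParent <- character()
        } else {
            mt <- .loadRanges(matureAnnotation)
            mtNames <- .annField(mt, c("ID", "Name", "name"))
            ov <- findOverlaps(mt, hp, type = "within")
            sameStrand <- as.character(strand(mt))[S4Vectors::queryHits(ov)] ==
                as.character(strand(hp))[S4Vectors::subjectHits(ov)]
            ov <- ov[sameStrand]
            if (length(unique(S4Vectors::queryHits(ov))) < length(mt)) {
                orphan <- setdiff(seq_along(mt), S4Vectors::queryHits(ov))
                stop("mature locus not contained in any same-strand hairpin: ",
                    paste(mtNames[orphan], collapse = ", "))
            }
            mt <- mt[S4Vectors::queryHits(ov)]
            mtNames <- mtNames[S4Vectors::queryHits(ov)]
            mtParent <- hpIds[S4Vectors::subjectHits(ov)]
        }
    }

    if (anyDuplicated(hpIds))
        stop("duplicate hairpin ids: ",
            paste(unique(hpIds[duplicated(hpIds)]), collapse = ", "))

    hpOrigin <- if ("origin" %in% names(S4Vectors::mcols(hp)))
        as.character(hp$origin) else rep(origin, length(hp))

    badChrom <- !(as.character(seqnames(hp)) %in% names(genome))
    if (any(badChrom))
        stop("hairpin chromosome missing from genome FASTA: ",
            paste(hpIds[badChrom], " (", as.character(seqnames(hp))[badChrom],
                ")", sep = "", collapse = ", "))
    chromLen <- width(genome)[match(as.character(seqnames(hp)), names(genome))]
    oob <- start(hp) < 1L | end(hp) > chromLen
    if (any(oob))
        stop("hairpin coordinates exceed chromosome bounds: ",
            paste(hpIds[oob], collapse = ", "))

    hpSeq <- vapply(seq_along(hp), function(i) {
        s <- as.character(subseq(genome[[as.character(seqnames(hp))[i]]],
            start(hp)[i], end(hp)[i]))
        if (as.character(strand(hp))[i] == "-") .revcomp(s) else s
    }, character(1))
    hairpinSeqs <- DNAStringSet(.normSeq(hpSeq))
    names(hairpinSeqs) <- hpIds

    hpGR <- GRanges(seqnames(hp), IRanges(start(hp), end(hp)),
        strand = strand(hp), hairpin_id = hpIds, origin = hpOrigin)

    if (length(mt)) {
        if (!exists("mtParent") || anyNA(mtParent))
            stop("mature record without a Derives_from/Parent hairpin")
        mtParent <- as.character(mtParent)
        orphan <- !(mtParent %in% hpIds)
        if (any(orphan))
            stop("mature references undeclared hairpin: ",
                paste(mtNames[orphan], collapse = ", "))
        j <- match(mtParent, hpIds)
        plus <- as.character(strand(hp))[j] == "+"
        localStart <- ifelse(plus, start(mt) - start(hp)[j],
            end(hp)[j] - end(mt))
        localEnd <- ifelse(plus, end(mt) - start(hp)[j] + 1L,
            end(hp)[j] - start(mt) + 1L)
        bad <- localStart < 0L | localEnd > width(hairpinSeqs)[j]
        if (any(bad))
            stop("mature outside hairpin bounds: ",
                paste(mtNames[bad], collapse = ", "))
        matureTab <- data.frame(
            name = mtNames, hairpin_id = mtParent,
            local_start = as.integer(localStart),
            local_end = as.integer(localEnd),
            sequence = substr(as.character(hairpinSeqs)[j],
                localStart + 1L, localEnd),
            stringsAsFactors = FALSE)
    } else {
        matureTab <- data.frame(name = character(), hairpin_id = character(),
            local_start = integer(), local_end = integer(),
            sequence = character(), stringsAsFactors = FALSE)
    }

    new("MiRNASpace", hairpins = hairpinSeqs, hairpinRanges = hpGR,
        matures = matureTab, index = new.env(parent = emptyenv()),
        indexParams = list())
}

.loadGenome <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        if (is.null(names(genome)))
            stop("genome DNAStringSet must be named by chromosome")
        # FASTA headers may carry descriptions; keep the first token
        names(genome) <- sub("\\s.*$", "", names(genome))
        return(genome)
    }
    if (!file.exists(genome))
        stop("genome FASTA not found: ", genome)
    g <- readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

.loadRanges <- function(x) {
    if (is(x, "GRanges")) return(x)
    if (!file.exists(x))
        stop("annotation file not found: ", x)
    rtracklayer::import(x)
}

.annField <- function(gr, candidates) {
    mc <- S4Vectors::mcols(gr)
    for (f in candidates) {
        if (f %in% names(mc)) {
            v <- mc[[f]]
            if (is(v, "List") || is.list(v))
                v <- vapply(v, function(e)
                    if (length(e)) as.character(e[[1]]) else NA_character_,
                    character(1))
            v <- as.character(v)
            if (!all(is.na(v))) return(v)
        }
    }
    if (!length(gr)) return(character())
    stop("annotation lacks any of the attributes: ",
        paste(candidates, collapse = ", "))
}

#' Construct a MiRNASpace directly from sequences
#'
#' Convenience constructor for programmatic use (simulation, tests) when no
#' genome is involved: hairpin sequences plus a mature table with
#' hairpin-local 0-based half-open coordinates.
#'
#' @param hairpinSeqs Named character vector or `DNAStringSet` of hairpin
#'   sequences (5'->3').
#' @param matureTab `data.frame` with columns `name`, `hairpin_id`,
#'   `local_start`, `local_end`; the `sequence` column is derived.
#' @param hairpinRanges Optional `GRanges` of genomic coordinates.
#' @return A [MiRNASpace].
#' @export
MiRNASpaceFromSeqs <- function(hairpinSeqs, matureTab,
        hairpinRanges = GRanges()) {
    seqs <- .normSeq(as.character(hairpinSeqs))
    hp <- DNAStringSet(seqs)
    names(hp) <- names(hairpinSeqs)
    matureTab$sequence <- substr(
        seqs[match(matureTab$hairpin_id, names(hp))],
        matureTab$local_start + 1L, matureTab$local_end)
    new("MiRNASpace", hairpins = hp, hairpinRanges = hairpinRanges,
        matures = matureTab, index = new.env(parent = emptyenv()),
        indexParams = list())
}

#' Build the exact-occurrence index over a MiRNASpace
#'
#' Enumerates every substring of every hairpin with length in
#' `[minLen, maxLen]` and records its sense-strand occurrences as
#' `(hairpin_id, offset)` pairs (offset 0-based from the hairpin 5' end).
#' After indexing, [spaceLookup()] answers exact-match queries in O(1).
#'
#' The window defaults mirror the read-length filters used throughout the
#' pipeline: reads shorter than 17 nt or longer than 25 nt are excluded
#' upstream, so only that window needs indexing.
#'
#' @param space A [MiRNASpace].
#' @param minLen,maxLen Substring length window (defaults 17 and 25).
#' @return The `MiRNASpace` with its index populated.
#' @export
buildSpaceIndex <- function(space, minLen = 17L, maxLen = 25L) {
    stopifnot(is(space, "MiRNASpace"))
    if (minLen > maxLen)
        stop("minLen must be <= maxLen")
    seqs <- as.character(space@hairpins)
    ids <- names(space@hairpins)
    pieces <- vector("list", length(seqs) * (maxLen - minLen + 1L))
    k <- 0L
    for (i in seq_along(seqs)) {
        n <- nchar(seqs[i])
        for (L in minLen:maxLen) {
            if (n < L) next
            starts <- seq_len(n - L + 1L)
            k <- k + 1L
            pieces[[k]] <- data.frame(
                seq = substring(seqs[i], starts, starts + L - 1L),
                hairpin_id = ids[i], offset = starts - 1L,
                stringsAsFactors = FALSE)
        }
    }
    idx <- new.env(parent = emptyenv(), size = 4096L)
    if (k) {
        all <- do.call(rbind, pieces[seq_len(k)])
        sp <- split(all[c("hairpin_id", "offset")], all$seq)
        for (s in names(sp)) {
            v <- sp[[s]]
            rownames(v) <- NULL
            assign(s, v, envir = idx)
        }
    }
    space@index <- idx
    space@indexParams <- list(min_len = as.integer(minLen),
        max_len = as.integer(maxLen))
    methods::validObject(space)
    space
}

#' Look up exact sense-strand occurrences of a sequence in the miRNA-space
#'
#' @param space An indexed [MiRNASpace] (see [buildSpaceIndex()]).
#' @param sequence Query string (DNA or RNA letters).
#' @return A `data.frame` with columns `hairpin_id` and `offset` (0-based);
#'   zero rows when the sequence does not occur or its length falls outside
#'   the indexed window.
#' @export
spaceLookup <- function(space, sequence) {
    stopifnot(is(space, "MiRNASpace"))
    if (!length(space@indexParams))
        stop("occurrence index not built; call buildSpaceIndex() first")
    sequence <- .normSeq(sequence, allowN = FALSE)
    empty <- data.frame(hairpin_id = character(), offset = integer(),
        stringsAsFactors = FALSE)
    if (nchar(sequence) < space@indexParams$min_len ||
            nchar(sequence) > space@indexParams$max_len)
        return(empty)
    hit <- get0(sequence, envir = space@index, inherits = FALSE)
    if (is.null(hit)) empty else hit
}

#' Tag sequences by genomic exclusivity and repeat overlap
#'
#' Scans both strands of the genome for exact occurrences of each query.
#' A sequence is `exclusive` when every genomic occurrence lies within a
#' hairpin interval of the miRNA-space, and `ambiguous` when at least one
#' occurrence falls outside it.  `repeat_overlap` is set when any
#' occurrence overlaps a declared repeat interval by at least one base.
#'
#' @param sequences Character vector of query sequences (lengths within the
#'   space's indexed window).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param space A [MiRNASpace] with genomic `hairpinRanges`.
#' @param repeats A [GenomicRanges::GRanges] of repeat intervals (possibly
#'   empty), or a BED path.
#' @return A `data.frame` with columns `sequence`, `exclusivity`
#'   (`"exclusive"`/`"ambiguous"`), `repeat_overlap` (logical) and
#'   `n_occurrences`.
#' @export
tagLocation <- function(sequences, genome, space, repeats = GRanges()) {
    stopifnot(is(space, "MiRNASpace"))
    genome <- .loadGenome(genome)
    if (!is(repeats, "GRanges")) repeats <- .loadRanges(repeats)
    sequences <- .normSeq(sequences, allowN = FALSE)
    if (length(space@indexParams)) {
        lo <- space@indexParams$min_len
        hi <- space@indexParams$max_len
        out <- nchar(sequences) < lo | nchar(sequences) > hi
        if (any(out))
            stop("query length outside the space window [", lo, ", ", hi,
                "]: ", paste(utils::head(sequences[out], 3L), collapse = ", "))
    }
    hpGR <- space@hairpinRanges
    # harmonize sequence levels so overlap counting never has to merge
    # disjoint Seqinfo objects
    allLevels <- unique(c(names(genome), seqlevels(hpGR),
        if (length(repeats)) seqlevels(repeats)))
    GenomeInfoDb::seqlevels(hpGR) <- allLevels
    if (length(repeats))
        GenomeInfoDb::seqlevels(repeats) <- allLevels
    res <- lapply(sequences, function(s) {
        occ <- .genomeOccurrences(s, genome)
        if (length(occ))
            GenomeInfoDb::seqlevels(occ) <- allLevels
        inside <- if (length(occ))
            countOverlaps(occ, hpGR, type = "within",
                ignore.strand = TRUE) > 0L else logical()
        inRep <- if (length(occ) && length(repeats))
            countOverlaps(occ, repeats, minoverlap = 1L,
                ignore.strand = TRUE) > 0L else rep(FALSE, length(occ))
        data.frame(
            exclusivity = if (all(inside)) "exclusive" else "ambiguous",
            repeat_overlap = any(inRep),
            n_occurrences = length(occ),
            stringsAsFactors = FALSE)
    })
    cbind(data.frame(sequence = sequences, stringsAsFactors = FALSE),
        do.call(rbind, res))
}

#' Summarize the mature/hairpin composition of a MiRNASpace
#'
#' Reports hairpin and mature counts, the number of distinct mature
#' sequences emitted by more than one hairpin, and the maximum
#' mature-to-hairpin multiplicity.  Useful for sanity-checking an imported
#' annotation database.
#'
#' @param space A [MiRNASpace].
#' @return A list with elements `n_hairpins`, `n_matures`,
#'   `n_distinct_mature_seqs`, `n_multi_hairpin_matures`,
#'   `max_hairpins_per_mature`.
#' @export
annotationSummary <- function(space) {
    stopifnot(is(space, "MiRNASpace"))
    m <- space@matures
    perSeq <- if (nrow(m))
        tapply(m$hairpin_id, m$sequence, function(h) length(unique(h)))
    else integer()
    list(
        n_hairpins = length(space@hairpins),
        n_matures = nrow(m),
        n_distinct_mature_seqs = length(unique(m$sequence)),
        n_multi_hairpin_matures = sum(perSeq > 1L),
        max_hairpins_per_mature = if (length(perSeq)) max(perSeq) else 0L
    )
}
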