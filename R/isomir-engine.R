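#' Place a read in the miRNA-space by exact prefix match
#'
#' Finds every placement of `sequence` where a prefix of length at least
#' `nchar(sequence) - maxNtTail` matches a hairpin exactly on the sense
#' strand; any remainder is reported as a 3' non-templated tail.  Only
#' longest-templated-prefix placements are returned, so a tail is never
#' emitted when the same bases could be read from the hairpin (templated
#' interpretation preferred): the first tail base always differs from the
#' hairpin continuation base, or the templated segment ends at the hairpin
#' 3' end.
#'
#' @param sequence Read sequence (DNA or RNA letters, no `N`).
#' @param space An indexed [MiRNASpace].
#' @param maxNtTail Maximum non-templated 3' tail length (default 3,
#'   covering the mono- to tri-nucleotide uridylation/adenylation typical
#'   of small-RNA 3' modification).
#' @return A `data.frame` with columns `hairpin_id`, `start` (0-based
#'   hairpin-local), `templated_len`, `nt_tail`; zero rows when the read
#'   cannot be placed.
#' @export
matchRead <- function(sequence, space, maxNtTail = 3L) {
    stopifnot(is(space, "MiRNASpace"))
    if (!length(space@indexParams))
        stop("occurrence index not built; call buildSpaceIndex() first")
    sequence <- .normSeq(sequence, allowN = FALSE)
    L <- nchar(sequence)
    minLen <- space@indexParams$min_len
    maxLen <- space@indexParams$max_len
    empty <- data.frame(hairpin_id = character(), start = integer(),
        templated_len = integer(), nt_tail = character(),
        stringsAsFactors = FALSE)
    if (L < minLen || L > maxLen + maxNtTail)
        return(empty)
    hpSeqs <- as.character(space@hairpins)
    for (tailLen in 0:maxNtTail) {
        tlen <- L - tailLen
        if (tlen < minLen) break
        prefix <- substr(sequence, 1L, tlen)
        probeLen <- min(tlen, maxLen)
        hits <- get0(substr(prefix, 1L, probeLen), envir = space@index,
            inherits = FALSE)
        if (is.null(hits) || !nrow(hits)) next
        hseq <- hpSeqs[hits$hairpin_id]
        # verify the part of the prefix beyond the indexed probe, if any
        fullMatch <- if (probeLen < tlen) {
            substr(hseq, hits$offset + 1L, hits$offset + tlen) == prefix
        } else rep(TRUE, nrow(hits))
        tail <- substr(sequence, tlen + 1L, L)
        if (tailLen > 0L) {
            contPos <- hits$offset + tlen + 1L
            cont <- substr(hseq, contPos, contPos)
            valid <- fullMatch & (cont == "" | cont != substr(tail, 1L, 1L))
        } else {
            valid <- fullMatch
        }
        if (any(valid)) {
            out <- data.frame(hairpin_id = hits$hairpin_id[valid],
                start = hits$offset[valid],
                templated_len = tlen,
                nt_tail = tail,
                stringsAsFactors = FALSE)
            rownames(out) <- NULL
            return(out)
        }
    }
    empty
}

#' Classify a placement relative to a mature miRNA reference
#'
#' Computes the 5' and templated 3' offsets of a placed read relative to a
#' mature reference on the same hairpin and assigns the isomiR class:
#' \describe{
#'   \item{canonical}{identical ends, no tail (`d5 == 0`, `d3 == 0`,
#'     `nt_len == 0`).}
#'   \item{iso_5p}{5' shift only; the seed (residues 2-8) is shifted.}
#'   \item{iso_3p}{templated 3' length change only.}
#'   \item{iso_3p_nontemplated}{canonical 5' end with a non-templated 3'
#'     tail (any templated 3' offset).}
#'   \item{mixed}{5' shift combined with any 3' change.}
#' }
#' Sign convention: `d5 > 0` means the read starts inside the mature
#' (5' trim), `d5 < 0` a 5' extension; `d3` is the read's templated 3' end
#' minus the mature 3' end.
#'
#' @param placement One placement as returned by [matchRead()] (one-row
#'   `data.frame` or list with `hairpin_id`, `start`, `templated_len`,
#'   `nt_tail`).
#' @param mature One mature record (row of [matures()]).
#' @return A list with `d5`, `d3`, `nt_len`, `class_label`, `seed_shifted`.
#' @export
classifyVariant <- function(placement, mature) {
    if (placement$hairpin_id != mature$hairpin_id)
        stop("placement and mature reference different hairpins: ",
            placement$hairpin_id, " vs ", mature$hairpin_id)
    d5 <- as.integer(placement$start - mature$local_start)
    d3 <- as.integer((placement$start + placement$templated_len) -
        mature$local_end)
    nt <- nchar(placement$nt_tail)
    label <- if (d5 == 0L && d3 == 0L && nt == 0L) "canonical"
        else if (d5 != 0L && d3 == 0L && nt == 0L) "iso_5p"
        else if (d5 == 0L && d3 != 0L && nt == 0L) "iso_3p"
        else if (d5 == 0L && nt > 0L) "iso_3p_nontemplated"
        else "mixed"
    list(d5 = d5, d3 = d3, nt_len = as.integer(nt), class_label = label,
        seed_shifted = d5 != 0L)
}

#' Extract the seed region (residues 2-8) of a mature sequence
#'
#' The seed is the 7-mer at 1-based positions 2-8 of the 5'->3' sequence,
#' the principal determinant of target recognition; any 5' offset shifts
#' it.
#'
#' @param sequence Character vector of sequences, each at least 8 nt.
#' @return Character vector of 7-mers (same alphabet as the input).
#' @export
seedOf <- function(sequence) {
    if (any(nchar(sequence) < 8L))
        stop("seedOf() requires sequences of at least 8 nt")
    substr(sequence, 2L, 8L)
}

.UID_B32 <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ234567", "")[[1]]

#' Nucleotide-based unique sequence identifiers
#'
#' `encodeUid()` packs a sequence into 2 bits per base (A=00, C=01, G=10,
#' T/U=11, big-endian), zero-pads the bit string to whole 5-bit symbols and
#' renders it in a fixed base-32 alphabet, producing IDs of the form
#' `iso-<length>-<code>`.  The map is deterministic, injective and
#' invertible: `decodeUid()` recovers the exact sequence.
#'
#' @param sequence Character vector over \{A,C,G,T/U\} (no `N`; ambiguous
#'   reads are excluded upstream).
#' @param uid Character vector of identifiers produced by `encodeUid()`.
#' @return `encodeUid()`: character vector of identifiers; `decodeUid()`:
#'   character vector of DNA sequences.
#' @examples
#' u <- encodeUid("TGAGGTAGTAGGTTGTATAGTT")
#' decodeUid(u)
#' @export
encodeUid <- function(sequence) {
    sequence <- .normSeq(sequence, allowN = FALSE)
    vapply(sequence, function(s) {
        vals <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
        bits <- as.vector(rbind(vals %/% 2L, vals %% 2L))
        pad <- (5L - length(bits) %% 5L) %% 5L
        bits <- c(bits, integer(pad))
        symVals <- colSums(matrix(bits, nrow = 5L) * c(16L, 8L, 4L, 2L, 1L))
        sprintf("iso-%d-%s", nchar(s),
            paste(.UID_B32[symVals + 1L], collapse = ""))
    }, character(1), USE.NAMES = FALSE)
}

#' @rdname encodeUid
#' @export
decodeUid <- function(uid) {
    vapply(uid, function(u) {
        parts <- regmatches(u, regexec("^iso-([0-9]+)-([A-Z2-7]+)$", u))[[1]]
        if (length(parts) != 3L)
            stop("malformed uid: ", u)
        n <- as.integer(parts[2])
        sym <- match(strsplit(parts[3], "")[[1]], .UID_B32) - 1L
        if (anyNA(sym))
            stop("malformed uid code: ", u)
        if (length(sym) != ceiling(2L * n / 5L))
            stop("uid code length inconsistent with sequence length: ", u)
        bits <- as.vector(vapply(sym, function(v)
            (v %/% c(16L, 8L, 4L, 2L, 1L)) %% 2L, integer(5)))
        padBits <- bits[-seq_len(2L * n)]
        if (length(padBits) && any(padBits != 0L))
            stop("nonzero padding bits in uid: ", u)
        vals <- bits[seq(1L, 2L * n, 2L)] * 2L + bits[seq(2L, 2L * n, 2L)]
        paste(c("A", "C", "G", "T")[vals + 1L], collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# Matures on the placement's hairpin whose interval overlaps the templated
# interval by >= 1 base and whose end offsets fall within the assignment
# windows.  Returns the subset of matureTab.
.assignableMatures <- function(placement, matureTab, maxD5 = 5L,
        max3p = 5L) {
    cand <- matureTab[matureTab$hairpin_id == placement$hairpin_id, ,
        drop = FALSE]
    if (!nrow(cand)) return(cand)
    tStart <- placement$start
    tEnd <- placement$start + placement$templated_len
    ntLen <- nchar(placement$nt_tail)
    overlap <- pmin(tEnd, cand$local_end) - pmax(tStart, cand$local_start)
    d5 <- tStart - cand$local_start
    d3 <- tEnd - cand$local_end
    keep <- overlap >= 1L & abs(d5) <= maxD5 & abs(d3 + ntLen) <= max3p
    cand[keep, , drop = FALSE]
}

#' Quantify one sample's collapsed reads against the miRNA-space
#'
#' Places each distinct read sequence with [matchRead()], assigns it to the
#' mature references whose interval its templated segment overlaps (within
#' the 5'/3' offset windows), classifies each (read, mature) pair with
#' [classifyVariant()], and normalizes counts to reads per million using
#' the sample's total post-filtered, length-selected read count.
#'
#' @param reads `data.frame` with columns `sequence` and `count`
#'   (positive integers); duplicate sequences are aggregated.
#' @param space An indexed [MiRNASpace].
#' @param sampleTotal Total post-filtered and length-selected reads in the
#'   sample, the RPM denominator.  Must be at least the sum of `count`.
#' @param maxNtTail Maximum non-templated tail length (see [matchRead()]).
#' @param maxD5,max3p Assignment windows: a read is assigned to a mature
#'   when `|d5| <= maxD5` and `|d3 + nt_len| <= max3p` and the templated
#'   interval overlaps the mature by at least one base.  Placed reads with
#'   no assignable mature are reported as unassigned hairpin fragments.
#' @return A list with elements:
#'   \describe{
#'     \item{records}{one row per distinct placed sequence: `sequence`,
#'       `uid`, `count`, `rpm`, `n_placements`, `hairpins`, `parents`
#'       (comma-separated; empty for unassigned fragments).}
#'     \item{assignments}{long table, one row per (sequence, placement,
#'       mature): adds `hairpin_id`, `start`, `templated_len`, `nt_tail`,
#'       `mature`, `d5`, `d3`, `nt_len`, `class`, `seed_shifted`.}
#'     \item{unplaced}{sequences with no placement and the `reason`.}
#'   }
#' @export
quantifySample <- function(reads, space, sampleTotal, maxNtTail = 3L,
        maxD5 = 5L, max3p = 5L) {
    stopifnot(is.data.frame(reads),
        all(c("sequence", "count") %in% names(reads)))
    if (sampleTotal == 0)
        stop("sampleTotal must be positive")
    if (any(reads$count <= 0) || any(reads$count != round(reads$count)))
        stop("read counts must be positive integers")
    hasN <- grepl("[^ACGTUacgtu]", reads$sequence)
    agg <- stats::aggregate(count ~ sequence,
        data = data.frame(sequence = .normSeq(reads$sequence[!hasN],
            allowN = FALSE), count = reads$count[!hasN]), FUN = sum)
    if (sum(reads$count) > sampleTotal)
        stop("sampleTotal is smaller than the summed read counts")
    minLen <- space@indexParams$min_len
    maxLen <- space@indexParams$max_len

    recs <- vector("list", nrow(agg))
    asg <- vector("list", nrow(agg))
    unpl <- vector("list", nrow(agg))
    for (i in seq_len(nrow(agg))) {
        s <- agg$sequence[i]
        cnt <- agg$count[i]
        L <- nchar(s)
        if (L < minLen || L > maxLen + maxNtTail) {
            unpl[[i]] <- data.frame(sequence = s, count = cnt,
                reason = "length_out_of_range", stringsAsFactors = FALSE)
            next
        }
        pl <- matchRead(s, space, maxNtTail = maxNtTail)
        if (!nrow(pl)) {
            unpl[[i]] <- data.frame(sequence = s, count = cnt,
                reason = "no_exact_match", stringsAsFactors = FALSE)
            next
        }
        rpm <- cnt / sampleTotal * 1e6
        rows <- vector("list", nrow(pl))
        for (j in seq_len(nrow(pl))) {
            p <- pl[j, ]
            mt <- .assignableMatures(p, space@matures, maxD5, max3p)
            if (!nrow(mt)) next
            vc <- lapply(seq_len(nrow(mt)), function(k)
                classifyVariant(p, mt[k, ]))
            rows[[j]] <- data.frame(
                sequence = s,
                hairpin_id = p$hairpin_id, start = p$start,
                templated_len = p$templated_len, nt_tail = p$nt_tail,
                mature = mt$name,
                d5 = vapply(vc, `[[`, integer(1), "d5"),
                d3 = vapply(vc, `[[`, integer(1), "d3"),
                nt_len = vapply(vc, `[[`, integer(1), "nt_len"),
                class = vapply(vc, `[[`, character(1), "class_label"),
                seed_shifted = vapply(vc, `[[`, logical(1), "seed_shifted"),
                count = cnt, rpm = rpm,
                stringsAsFactors = FALSE)
        }
        rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
        parents <- if (!is.null(rows)) unique(rows$mature) else character()
        recs[[i]] <- data.frame(
            sequence = s, uid = encodeUid(s), count = cnt, rpm = rpm,
            n_placements = nrow(pl),
            hairpins = paste(unique(pl$hairpin_id), collapse = ","),
            parents = paste(parents, collapse = ","),
            stringsAsFactors = FALSE)
        if (!is.null(rows)) asg[[i]] <- rows
    }
    bindOr <- function(lst, template) {
        lst <- lst[!vapply(lst, is.null, logical(1))]
        if (length(lst)) {
            out <- do.call(rbind, lst)
            rownames(out) <- NULL
            out
        } else template
    }
    records <- bindOr(recs, data.frame(sequence = character(),
        uid = character(), count = numeric(), rpm = numeric(),
        n_placements = integer(), hairpins = character(),
        parents = character(), stringsAsFactors = FALSE))
    assignments <- bindOr(asg, data.frame(sequence = character(),
        hairpin_id = character(), start = integer(),
        templated_len = integer(), nt_tail = character(),
        mature = character(), d5 = integer(), d3 = integer(),
        nt_len = integer(), class = character(), seed_shifted = logical(),
        count = numeric(), rpm = numeric(), stringsAsFactors = FALSE))
    if (!nrow(assignments))
        assignments$uid <- character()
    else
        assignments$uid <- encodeUid(assignments$sequence)
    unplacedTmpl <- data.frame(sequence = character(), count = numeric(),
        reason = character(), stringsAsFactors = FALSE)
    if (any(hasN))
        unpl[[length(unpl) + 1L]] <- data.frame(
            sequence = toupper(reads$sequence[hasN]),
            count = reads$count[hasN], reason = "ambiguous_base",
            stringsAsFactors = FALSE)
    unplaced <- bindOr(unpl, unplacedTmpl)
    list(records = records, assignments = assignments, unplaced = unplaced)
}

#' Collapse identical sequences across hairpin loci
#'
#' Identical mature/isomiR sequences can be processed from several hairpin
#' loci; this collapses a per-(sequence, parent) assignment table to one
#' row per distinct sequence, retaining the union of all parent names and
#' hairpins.  Counts are never multiplied by placement multiplicity: each
#' read is counted once per sample regardless of how many loci could have
#' produced it.
#'
#' @param assignments The `assignments` table from [quantifySample()].
#' @return A `data.frame` with one row per distinct sequence: `sequence`,
#'   `uid`, `parents`, `n_parents`, `hairpins`, `n_hairpins`, `count`,
#'   `rpm`.
#' @export
collapseIdentical <- function(assignments) {
    if (!nrow(assignments))
        return(data.frame(sequence = character(), uid = character(),
            parents = character(), n_parents = integer(),
            hairpins = character(), n_hairpins = integer(),
            count = numeric(), rpm = numeric(), stringsAsFactors = FALSE))
    sp <- split(assignments, assignments$sequence)
    out <- lapply(sp, function(g) {
        if (length(unique(g$count)) != 1L)
            stop("inconsistent counts for sequence ", g$sequence[1])
        data.frame(
            sequence = g$sequence[1],
            uid = if ("uid" %in% names(g)) g$uid[1]
                else encodeUid(g$sequence[1]),
            parents = paste(sort(unique(g$mature)), collapse = ","),
            n_parents = length(unique(g$mature)),
            hairpins = paste(sort(unique(g$hairpin_id)), collapse = ","),
            n_hairpins = length(unique(g$hairpin_id)),
            count = g$count[1], rpm = g$rpm[1],
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[order(out$sequence), , drop = FALSE]
}

#' Count distinct seed sequences per mature reference
#'
#' For each mature reference (Ref-miR), counts the number of distinct seed
#' 7-mers (residues 2-8) among its retained canonical and isomiR
#' sequences.  Only 5' offsets change the seed, so a Ref-miR whose
#' variants are all 3'-sided has exactly one seed.
#'
#' @param assignments The `assignments` table from [quantifySample()] (or a
#'   concatenation across samples).
#' @return A `data.frame` with columns `mature` and `n_seeds`.
#' @export
seedVariantCensus <- function(assignments) {
    if (!nrow(assignments))
        return(data.frame(mature = character(), n_seeds = integer(),
            stringsAsFactors = FALSE))
    seeds <- seedOf(assignments$sequence)
    tab <- tapply(seeds, assignments$mature,
        function(s) length(unique(s)))
    data.frame(mature = names(tab), n_seeds = as.integer(tab),
        row.names = NULL, stringsAsFactors = FALSE)
}
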