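# Run expr with a private, seeded RNG stream, leaving the caller's
# .Random.seed untouched.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

#' Group predicted hairpin loci that overlap by more than a threshold
#'
#' Two loci on the same chromosome (and, by default, strand) belong to one
#' group when they share more than `overlapThreshold` bases; grouping is
#' transitive.  The default threshold of 17 is the minimum mature miRNA
#' length: two predictions sharing more than one full minimal mature
#' sequence describe the same locus.
#'
#' @param loci A [GenomicRanges::GRanges] of predicted hairpin loci with a
#'   `locus_id` metadata column (or names).
#' @param overlapThreshold Merge when shared bases exceed this value
#'   (default 17).  Set `inclusive = TRUE` to merge at `>=` instead.
#' @param respectStrand Require equal strand for merging (default `TRUE`).
#' @param inclusive Merge at `>= overlapThreshold` shared bases instead of
#'   strictly more.
#' @return Integer vector of group ids, one per locus (order-stable:
#'   groups are numbered by first occurrence).
#' @export
mergeLoci <- function(loci, overlapThreshold = 17L, respectStrand = TRUE,
        inclusive = FALSE) {
    stopifnot(is(loci, "GRanges"))
    if (any(width(loci) < 1L))
        stop("malformed locus intervals")
    n <- length(loci)
    minov <- if (inclusive) as.integer(overlapThreshold)
        else as.integer(overlapThreshold) + 1L
    ov <- findOverlaps(loci, loci, minoverlap = minov,
        ignore.strand = !respectStrand)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    for (e in seq_along(q)) {
        a <- find(q[e]); b <- find(s[e])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

#' Select the representative locus of a merged group
#'
#' Returns the locus with the highest total read count across all samples;
#' exact ties are broken by a seeded uniform draw so the choice is random
#' yet reproducible.
#'
#' @param totalCounts Named numeric vector of total counts, one per locus
#'   in the group.
#' @param seed Integer seed for the tie-break draw.
#' @return The name of the selected locus.
#' @export
selectRepresentative <- function(totalCounts, seed = 1L) {
    if (!length(totalCounts))
        stop("empty locus group")
    if (is.null(names(totalCounts)))
        stop("totalCounts must be named by locus id")
    top <- names(totalCounts)[totalCounts == max(totalCounts)]
    if (length(top) == 1L)
        return(top)
    .withSeed(seed, top[sample.int(length(top), 1L)])
}

#' Expression screen for predicted hairpins
#'
#' Keeps hairpins with RPM at or above `minRpm` in at least `minSamples`
#' samples (inclusive comparison, the screen used for predicted loci, in
#' contrast to the strict `>` used for the final atlas retention).
#'
#' @param lociIds Character vector of locus ids to screen.
#' @param rpm Numeric RPM matrix with loci as rows.
#' @param minRpm,minSamples Thresholds (defaults 20 and 2).
#' @return The subset of `lociIds` that passes.
#' @export
filterExpressedHairpins <- function(lociIds, rpm, minRpm = 20,
        minSamples = 2L) {
    missing <- setdiff(lociIds, rownames(rpm))
    if (length(missing))
        stop("locus absent from RPM matrix: ",
            paste(missing, collapse = ", "))
    keep <- expressionFilter(rpm[lociIds, , drop = FALSE], minRpm,
        minSamples, inclusive = TRUE)
    lociIds[keep]
}

#' Remove candidates overlapping the known hairpin annotation
#'
#' Drops a candidate locus when it shares more than `overlapThreshold`
#' bases with any known hairpin on the same chromosome.  The comparison is
#' strand-agnostic by default: a known miRNA locus on either strand makes
#' a co-located prediction suspect.
#'
#' @param candidates A `GRanges` of candidate loci.
#' @param known A `GRanges` of known hairpin loci.
#' @param overlapThreshold Tolerated overlap in bases (default 17).
#' @param respectStrand Restrict the comparison to equal strands.
#' @return Logical vector over candidates: `TRUE` = keep.
#' @export
removeKnownOverlap <- function(candidates, known, overlapThreshold = 17L,
        respectStrand = FALSE) {
    stopifnot(is(candidates, "GRanges"), is(known, "GRanges"))
    hits <- countOverlaps(candidates, known,
        minoverlap = as.integer(overlapThreshold) + 1L,
        ignore.strand = !respectStrand)
    hits == 0L
}

#' Genomic multiplicity cap for candidate hairpin sequences
#'
#' Counts exact occurrences of each candidate hairpin sequence on both
#' genome strands and keeps sequences with at most `maxHits` occurrences;
#' highly repetitive sequences cannot be confidently assigned a locus.
#'
#' @param sequences Named character vector of candidate hairpin sequences.
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param maxHits Maximum allowed occurrences (default 15).
#' @return Named logical vector: `TRUE` = keep.  Occurrence counts are
#'   attached as attribute `"hits"`.
#' @export
multiplicityFilter <- function(sequences, genome, maxHits = 15L) {
    genome <- .loadGenome(genome)
    hits <- vapply(sequences, function(s)
        length(.genomeOccurrences(s, genome)), integer(1))
    structure(hits <= maxHits, hits = hits, names = names(sequences))
}

#' Ortholog-based naming of consolidated novel loci
#'
#' From a tabular similarity-hit file (BLAST outfmt-6-like with added
#' `species`, `query_coverage` and `q_value` columns), retains hits with
#' `q_value < maxQ` and `query_coverage > minCoverage`, selects the
#' highest-percent-identity subject(s), and when those span several
#' species picks the earliest in `speciesPriority` (the evolutionarily
#' closest).  Candidates with no surviving hit keep their original
#' predicted id.
#'
#' @param candidateIds Character vector of candidate locus ids.
#' @param hits `data.frame` with columns `query_id`, `subject_id`,
#'   `species`, `percent_identity`, `query_coverage` (fraction in
#'   `[0, 1]`), `q_value`.
#' @param speciesPriority Ordered character vector, closest species
#'   first.  Hits from species absent from the list are dropped with a
#'   warning.
#' @param maxQ,minCoverage Retention thresholds (defaults 0.01 and 0.80).
#' @return `data.frame` with columns `id`, `name`, `ortholog_subject`,
#'   `ortholog_species`, `named` (logical).
#' @export
assignNames <- function(candidateIds, hits,
        speciesPriority = c("cow", "sheep", "pig", "dog", "human", "mouse"),
        maxQ = 0.01, minCoverage = 0.80) {
    need <- c("query_id", "subject_id", "species", "percent_identity",
        "query_coverage", "q_value")
    stopifnot(all(need %in% names(hits)))
    unknown <- setdiff(unique(hits$species), speciesPriority)
    if (length(unknown)) {
        warning("hits from species absent from the priority list ignored: ",
            paste(unknown, collapse = ", "))
        hits <- hits[hits$species %in% speciesPriority, , drop = FALSE]
    }
    hits <- hits[hits$q_value < maxQ & hits$query_coverage > minCoverage, ,
        drop = FALSE]
    out <- lapply(candidateIds, function(id) {
        h <- hits[hits$query_id == id, , drop = FALSE]
        if (!nrow(h))
            return(data.frame(id = id, name = id,
                ortholog_subject = NA_character_,
                ortholog_species = NA_character_, named = FALSE,
                stringsAsFactors = FALSE))
        h <- h[h$percent_identity == max(h$percent_identity), , drop = FALSE]
        if (length(unique(h$species)) > 1L) {
            pri <- match(h$species, speciesPriority)
            h <- h[pri == min(pri), , drop = FALSE]
        }
        h <- h[1L, ]
        data.frame(id = id, name = h$subject_id,
            ortholog_subject = h$subject_id, ortholog_species = h$species,
            named = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Consolidate predicted novel hairpin loci end to end
#'
#' Runs the full consolidation: group overlapping predictions
#' ([mergeLoci()]), cap genomic multiplicity ([multiplicityFilter()]),
#' screen for expression ([filterExpressedHairpins()]), pick one
#' representative per group ([selectRepresentative()]), drop candidates
#' overlapping the known annotation ([removeKnownOverlap()]), and
#' optionally honour an upstream non-miRNA exclusion column.
#'
#' @param loci `GRanges` of predicted loci with metadata columns
#'   `locus_id`, `sequence` and optionally `exclude` (logical, upstream
#'   non-miRNA flag).
#' @param counts Numeric count matrix, loci x samples.
#' @param rpm Numeric RPM matrix, loci x samples.
#' @param known `GRanges` of known hairpin loci.
#' @param genome Genome (`DNAStringSet` or FASTA path) for the
#'   multiplicity cap.
#' @param seed Seed for representative tie-breaks (recorded in the
#'   report).
#' @param overlapThreshold,maxHits,minRpm,minSamples See the individual
#'   steps.
#' @return List with `kept` (`GRanges` of surviving representatives),
#'   `groups` (the group assignment) and `report` (per-step attrition).
#' @export
consolidateNovelLoci <- function(loci, counts, rpm, known, genome,
        seed = 1L, overlapThreshold = 17L, maxHits = 15L, minRpm = 20,
        minSamples = 2L) {
    stopifnot(is(loci, "GRanges"), "locus_id" %in% names(S4Vectors::mcols(loci)))
    ids <- loci$locus_id
    report <- list()
    note <- function(step, before, after)
        report[[length(report) + 1L]] <<- data.frame(step = step,
            before = before, after = after, removed = before - after,
            stringsAsFactors = FALSE)

    # order-stable grouping key: sort loci canonically before grouping so
    # permuted inputs yield identical groups and representatives
    ord <- order(as.character(seqnames(loci)), start(loci), end(loci),
        as.character(strand(loci)), ids)
    loci <- loci[ord]
    ids <- loci$locus_id
    groups <- mergeLoci(loci, overlapThreshold)
    note("merge", length(loci), length(unique(groups)))

    mult <- multiplicityFilter(
        stats::setNames(loci$sequence, ids), genome, maxHits)
    note("multiplicity", length(ids), sum(mult))
    keepIds <- ids[mult]

    expressed <- filterExpressedHairpins(keepIds, rpm, minRpm, minSamples)
    note("expression", length(keepIds), length(expressed))

    if ("exclude" %in% names(S4Vectors::mcols(loci))) {
        excl <- stats::setNames(as.logical(loci$exclude), ids)
        nBefore <- length(expressed)
        expressed <- expressed[!excl[expressed]]
        note("non_mirna_exclusion", nBefore, length(expressed))
    }

    reps <- character()
    for (g in unique(groups)) {
        members <- intersect(ids[groups == g], expressed)
        if (!length(members)) next
        tot <- rowSums(counts[members, , drop = FALSE])
        reps <- c(reps, selectRepresentative(stats::setNames(tot, members),
            seed = seed + g))
    }
    note("representative", length(expressed), length(reps))

    cand <- loci[match(reps, ids)]
    keep <- removeKnownOverlap(cand, known, overlapThreshold)
    note("known_overlap", length(cand), sum(keep))
    kept <- cand[keep]

    rep <- do.call(rbind, report)
    rownames(rep) <- NULL
    list(kept = kept, groups = stats::setNames(groups, ids), report = rep,
        seed = seed)
}
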