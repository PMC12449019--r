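.randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with embedded hairpin loci
#'
#' Builds a random genome and plants hairpin precursors (length 60-90 nt,
#' on either strand) each carrying one mature miRNA (length 20-23 nt,
#' placed with at least 5 nt of hairpin flank on each side).  Optionally,
#' some hairpin loci are copied verbatim to unannotated positions, which
#' makes their sequences ambiguous with respect to the miRNA-space, and
#' some are placed inside declared repeat intervals.  The uniqueness of
#' every other mature sequence is verified by a brute-force both-strand
#' genome scan before the bundle is emitted.
#'
#' @param seed Integer seed; the bundle is byte-identical for equal seeds.
#' @param nHairpins Number of annotated hairpin loci.
#' @param genomeLen Total genome length (split over `nChroms`).
#' @param nRepeatHairpins Hairpins placed inside repeat intervals.
#' @param nDuplicated Hairpins whose genomic segment is copied verbatim to
#'   an unannotated location (forcing `ambiguous` location tags).
#' @param nChroms Number of chromosomes.
#' @param minusFraction Fraction of hairpins on the minus strand.
#' @return A [TruthBundle].
#' @export
makeReference <- function(seed = 1L, nHairpins = 12L, genomeLen = 50000L,
        nRepeatHairpins = 2L, nDuplicated = 2L, nChroms = 2L,
        minusFraction = 0.5) {
    stopifnot(nRepeatHairpins + nDuplicated <= nHairpins)
    .withSeed(seed, {
        nSlots <- nHairpins + nDuplicated
        chromLen <- rep(genomeLen %/% nChroms, nChroms)
        names(chromLen) <- paste0("chr", seq_len(nChroms))
        if (genomeLen < nSlots * 120L)
            stop("genome too small to place ", nSlots,
                " loci without overlap; increase genomeLen")
        genome <- vapply(chromLen, .randSeq, character(1))

        # non-overlapping slots (10 nt margin), bounded retries
        slots <- data.frame(chrom = character(), start = integer(),
            end = integer(), stringsAsFactors = FALSE)
        placeSlot <- function(len) {
            for (try in 1:200) {
                chrom <- sample(names(chromLen), 1L)
                st <- sample.int(chromLen[[chrom]] - len - 10L, 1L) + 5L
                en <- st + len - 1L
                clash <- slots$chrom == chrom &
                    slots$start <= en + 10L & slots$end >= st - 10L
                if (!any(clash)) {
                    slots[nrow(slots) + 1L, ] <<- list(chrom, st, en)
                    return(c(chrom = chrom, start = st, end = en))
                }
            }
            stop("could not place locus after 200 tries; ",
                "increase genomeLen")
        }

        hpLen <- sample(60:90, nHairpins, replace = TRUE)
        hpStrand <- ifelse(stats::runif(nHairpins) < minusFraction, "-", "+")
        mLen <- sample(20:23, nHairpins, replace = TRUE)
        hpSeq <- character(nHairpins)
        hpChrom <- character(nHairpins)
        hpStart <- hpEnd <- integer(nHairpins)
        localStart <- integer(nHairpins)

        writeSegment <- function(chrom, st, en, seg) {
            substr(genome[[chrom]], st, en) <<- seg
        }

        for (i in seq_len(nHairpins)) {
            pos <- placeSlot(hpLen[i])
            hpChrom[i] <- pos[["chrom"]]
            hpStart[i] <- as.integer(pos[["start"]])
            hpEnd[i] <- as.integer(pos[["end"]])
            hpSeq[i] <- .randSeq(hpLen[i])
            localStart[i] <- sample(5:(hpLen[i] - mLen[i] - 5L), 1L)
            seg <- if (hpStrand[i] == "-") .revcomp(hpSeq[i]) else hpSeq[i]
            writeSegment(hpChrom[i], hpStart[i], hpEnd[i], seg)
        }
        hpIds <- sprintf("syn-hairpin-%02d", seq_len(nHairpins))

        # roles: first nRepeatHairpins live in repeats, the next
        # nDuplicated are copied verbatim elsewhere (unannotated)
        repIdx <- seq_len(nRepeatHairpins)
        dupIdx <- if (nDuplicated)
            nRepeatHairpins + seq_len(nDuplicated) else integer()
        for (i in dupIdx) {
            pos <- placeSlot(hpLen[i])
            seg <- if (hpStrand[i] == "-") .revcomp(hpSeq[i]) else hpSeq[i]
            writeSegment(pos[["chrom"]], as.integer(pos[["start"]]),
                as.integer(pos[["end"]]), seg)
        }

        repeats <- if (length(repIdx)) {
            pad <- sample(3:15, length(repIdx), replace = TRUE)
            GRanges(hpChrom[repIdx],
                IRanges(pmax(1L, hpStart[repIdx] - pad),
                    hpEnd[repIdx] + pad),
                strand = "*", repeat_class = "synthetic_repeat")
        } else GRanges()

        genomeSet <- DNAStringSet(genome)
        names(genomeSet) <- names(chromLen)

        matureTab <- data.frame(
            name = sprintf("syn-miR-%02d", seq_len(nHairpins)),
            hairpin_id = hpIds,
            local_start = localStart,
            local_end = localStart + mLen,
            stringsAsFactors = FALSE)
        space <- MiRNASpaceFromSeqs(
            stats::setNames(hpSeq, hpIds), matureTab,
            hairpinRanges = GRanges(hpChrom, IRanges(hpStart, hpEnd),
                strand = hpStrand, hairpin_id = hpIds, origin = "known"))

        # brute-force uniqueness check for matures of non-duplicated loci
        nonDup <- setdiff(seq_len(nHairpins), dupIdx)
        for (i in nonDup) {
            occ <- .genomeOccurrences(space@matures$sequence[i], genomeSet)
            if (length(occ) != 1L)
                stop("mature ", matureTab$name[i],
                    " is not unique in the genome (", length(occ),
                    " occurrences); re-run with a different seed or a ",
                    "larger genome")
        }

        space <- buildSpaceIndex(space)
        truth <- data.frame(
            name = matureTab$name,
            hairpin_id = hpIds,
            sequence = space@matures$sequence,
            expected_exclusive = !(seq_len(nHairpins) %in% dupIdx),
            expected_repeat = seq_len(nHairpins) %in% repIdx,
            stringsAsFactors = FALSE)
        new("TruthBundle", genome = genomeSet, space = space,
            repeats = repeats, truth = truth,
            params = list(seed = seed, nHairpins = nHairpins,
                genomeLen = genomeLen, nRepeatHairpins = nRepeatHairpins,
                nDuplicated = nDuplicated, nChroms = nChroms,
                minusFraction = minusFraction))
    })
}

#' Simulate labelled small-RNA reads from a TruthBundle
#'
#' Draws reads from the bundle's mature miRNAs with a declared isomiR
#' profile and stores the generating labels, so classifier output can be
#' compared against ground truth.  Offsets are drawn from `d5` in
#' \{-2,...,2\}\\\{0\} and `d3` in \{-3,...,3\}\\\{0\}; non-templated tails
#' are 1-3 nt over \{A, T\} with the first base chosen to differ from the
#' hairpin continuation base.  Draws whose templated segment would leave
#' the 17-25 nt window (or the hairpin) are resampled and counted in the
#' `resampled` attribute.
#'
#' @param bundle A [TruthBundle] from [makeReference()].
#' @param profile Named numeric vector of category probabilities with
#'   names among `canonical`, `iso_5p`, `iso_3p`, `nt_tail`; any remainder
#'   (probabilities must sum to at most 1) is the `mixed` class.
#' @param nReads Number of reads to draw.
#' @param seed Integer seed.
#' @param abundance Optional named weights over mature names (uniform by
#'   default).
#' @return `data.frame` with one row per read: `sequence`, `parent`,
#'   `class`, `d5`, `d3`, `nt_tail`.
#' @export
simulateReads <- function(bundle, profile = c(canonical = 0.5,
        iso_5p = 0.1, iso_3p = 0.2, nt_tail = 0.1), nReads = 1000L,
        seed = 1L, abundance = NULL) {
    stopifnot(is(bundle, "TruthBundle"))
    known <- c("canonical", "iso_5p", "iso_3p", "nt_tail")
    if (!all(names(profile) %in% known))
        stop("profile names must be among: ", paste(known, collapse = ", "))
    p <- stats::setNames(numeric(4), known)
    p[names(profile)] <- profile
    if (sum(p) > 1 + 1e-12)
        stop("profile probabilities must sum to at most 1")
    pMixed <- 1 - sum(p)
    cats <- c(known, "mixed")
    probs <- c(p, mixed = pMixed)

    space <- bundle@space
    mt <- space@matures
    hpSeqs <- as.character(space@hairpins)
    if (is.null(abundance))
        abundance <- stats::setNames(rep(1, nrow(mt)), mt$name)
    w <- abundance[mt$name]
    w[is.na(w)] <- 0

    .withSeed(seed, {
        parentIdx <- sample.int(nrow(mt), nReads, replace = TRUE,
            prob = w / sum(w))
        category <- sample(cats, nReads, replace = TRUE, prob = probs)
        resampled <- 0L
        rows <- vector("list", nReads)
        for (i in seq_len(nReads)) {
            m <- mt[parentIdx[i], ]
            hp <- hpSeqs[[m$hairpin_id]]
            hpLen <- nchar(hp)
            repeat {
                d5 <- 0L; d3 <- 0L; tail <- ""
                cat_i <- category[i]
                if (cat_i %in% c("iso_5p", "mixed"))
                    d5 <- sample(c(-2L, -1L, 1L, 2L), 1L)
                wantTail <- cat_i == "nt_tail" ||
                    (cat_i == "mixed" && stats::runif(1) < 0.5)
                if (cat_i == "iso_3p" || (cat_i == "mixed" && !wantTail))
                    d3 <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1L)
                tStart <- m$local_start + d5
                tEnd <- m$local_end + d3
                tlen <- tEnd - tStart
                if (tStart < 0L || tEnd > hpLen || tlen < 17L ||
                        tlen > 25L) {
                    resampled <- resampled + 1L
                    next
                }
                if (wantTail) {
                    tailLen <- sample(1:3, 1L)
                    cont <- if (tEnd < hpLen)
                        substr(hp, tEnd + 1L, tEnd + 1L) else ""
                    first <- sample(setdiff(c("A", "T"), cont), 1L)
                    rest <- if (tailLen > 1L)
                        paste(sample(c("A", "T"), tailLen - 1L,
                            replace = TRUE), collapse = "") else ""
                    tail <- paste0(first, rest)
                }
                break
            }
            classLabel <- switch(category[i],
                canonical = "canonical", iso_5p = "iso_5p",
                iso_3p = "iso_3p", nt_tail = "iso_3p_nontemplated",
                mixed = "mixed")
            rows[[i]] <- data.frame(
                sequence = paste0(substr(hp, tStart + 1L, tEnd), tail),
                parent = m$name, class = classLabel,
                d5 = d5, d3 = d3, nt_tail = tail,
                stringsAsFactors = FALSE)
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        attr(out, "resampled") <- resampled
        out
    })
}

#' Simulate a multi-organ expression matrix with planted specificity
#'
#' Generates per-sample RPM values for miRNAs planted as either
#' `ubiquitous` (equal organ means) or `specific` (one dominant organ at
#' `dominance` times the background mean), with multiplicative lognormal
#' noise of coefficient of variation `noiseCv` (mean-preserving).  The
#' planted labels form the ground truth for specificity-recovery checks.
#'
#' @param mirnas Character vector of miRNA names, a [TruthBundle] (its
#'   mature names are used), or an integer count.
#' @param nOrgans Number of organs (tissues map 1:1 to organs here); must
#'   be at least 2 for the enrichment index to be defined.
#' @param samplesPerTissue Samples per organ.
#' @param nSpecific,nUbiquitous Numbers of planted specific and ubiquitous
#'   miRNAs (together at most the miRNA count); any remaining miRNAs get
#'   independent lognormal organ means and the truth label `other`.
#' @param noiseCv Lognormal coefficient of variation of per-sample noise.
#' @param dominance Ratio of the dominant organ mean to the background
#'   mean for specific miRNAs (default 20).
#' @param baseMean Organ mean for ubiquitous miRNAs (RPM).
#' @param background Background organ mean for specific miRNAs (RPM).
#' @param seed Integer seed.
#' @return A list with `rpm` (miRNAs x samples), `meta` (`sample`,
#'   `tissue`), `truth` (`mirna`, `label`, `dominant_organ`) and `params`.
#' @export
simulateAtlas <- function(mirnas, nOrgans = 10L, samplesPerTissue = 8L,
        nSpecific = 5L, nUbiquitous = 5L, noiseCv = 0.2, dominance = 20,
        baseMean = 200, background = 25, seed = 1L) {
    if (nOrgans < 2L)
        stop("the organ-enrichment index is undefined for fewer than 2 organs")
    if (is(mirnas, "TruthBundle"))
        mirnas <- mirnas@space@matures$name
    if (is.numeric(mirnas) && length(mirnas) == 1L)
        mirnas <- sprintf("syn-miR-%03d", seq_len(mirnas))
    nm <- length(mirnas)
    if (nSpecific + nUbiquitous > nm)
        stop("nSpecific + nUbiquitous exceeds the number of miRNAs")
    organs <- sprintf("organ%02d", seq_len(nOrgans))
    label <- rep("other", nm)
    label[seq_len(nSpecific)] <- "specific"
    label[nSpecific + seq_len(nUbiquitous)] <- "ubiquitous"
    dominant <- rep(NA_character_, nm)
    dominant[label == "specific"] <-
        organs[(seq_len(nSpecific) - 1L) %% nOrgans + 1L]

    .withSeed(seed, {
        means <- matrix(0, nm, nOrgans, dimnames = list(mirnas, organs))
        for (j in seq_len(nm)) {
            means[j, ] <- switch(label[j],
                ubiquitous = rep(baseMean, nOrgans),
                specific = {
                    v <- rep(background, nOrgans)
                    v[match(dominant[j], organs)] <- dominance * background
                    v
                },
                other = stats::rlnorm(nOrgans, log(baseMean / 4), 1))
        }
        sdlog <- sqrt(log(1 + noiseCv^2))
        sampleIds <- as.vector(t(outer(organs, seq_len(samplesPerTissue),
            function(o, k) sprintf("%s_s%d", o, k))))
        tissueOf <- rep(organs, each = samplesPerTissue)
        noise <- if (noiseCv > 0)
            matrix(stats::rlnorm(nm * length(sampleIds),
                -sdlog^2 / 2, sdlog), nm)
        else matrix(1, nm, length(sampleIds))
        rpm <- means[, match(tissueOf, organs), drop = FALSE] * noise
        dimnames(rpm) <- list(mirnas, sampleIds)
        list(rpm = rpm,
            meta = data.frame(sample = sampleIds, tissue = tissueOf,
                stringsAsFactors = FALSE),
            truth = data.frame(mirna = mirnas, label = label,
                dominant_organ = dominant, stringsAsFactors = FALSE),
            params = list(seed = seed, nOrgans = nOrgans,
                samplesPerTissue = samplesPerTissue,
                nSpecific = nSpecific, nUbiquitous = nUbiquitous,
                noiseCv = noiseCv, dominance = dominance,
                baseMean = baseMean, background = background))
    })
}
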