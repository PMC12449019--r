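space <- fixtureSpace()
mature1 <- fixtureMature(space)
matureSeq <- mature1$sequence   # TGAGGTAGTAGGTTGTATAGTT at local [10, 32)

test_that("a read identical to the mature places at the mature start with
           no tail", {
    pl <- matchRead(matureSeq, space)
    expect_equal(nrow(pl), 1L)
    expect_equal(pl$hairpin_id, "fix-hp-1")
    expect_equal(pl$start, 10L)
    expect_equal(pl$templated_len, 22L)
    expect_equal(pl$nt_tail, "")
})

test_that("a 3' addition mismatching the hairpin continuation is called a
           non-templated tail", {
    # continuation base after the mature is G, so +A cannot be templated
    pl <- matchRead(paste0(matureSeq, "A"), space)
    expect_equal(nrow(pl), 1L)
    expect_equal(pl$templated_len, 22L)
    expect_equal(pl$nt_tail, "A")
})

test_that("a 3' addition equal to the continuation base is read as
           templated (maximality)", {
    pl <- matchRead(paste0(matureSeq, "G"), space)
    expect_equal(nrow(pl), 1L)
    expect_equal(pl$templated_len, 23L)
    expect_equal(pl$nt_tail, "")
})

test_that("unplaceable and out-of-window reads yield no placements", {
    expect_equal(nrow(matchRead(strrep("A", 22), space)), 0L)
    expect_equal(nrow(matchRead(strrep("A", 16), space)), 0L)  # too short
    expect_equal(nrow(matchRead(strrep("A", 30), space)), 0L)  # too long
})

test_that("classification recovers canonical, 3' templated and mixed
           calls from coordinate arithmetic", {
    canonical <- matchRead(matureSeq, space)[1, ]
    vc <- classifyVariant(canonical, mature1)
    expect_equal(vc[c("d5", "d3", "nt_len")], list(d5 = 0L, d3 = 0L,
        nt_len = 0L))
    expect_equal(vc$class_label, "canonical")
    expect_false(vc$seed_shifted)

    hp1 <- as.character(hairpins(space)[["fix-hp-1"]])
    ext2 <- substr(hp1, 11, 34)               # mature + 2 templated bases
    vc <- classifyVariant(matchRead(ext2, space)[1, ], mature1)
    expect_equal(vc$d3, 2L)
    expect_equal(vc$class_label, "iso_3p")

    # one base inside at the 5' end, one-base non-templated tail:
    # trimmed read ends at the mature end, where the continuation is G
    trimmedTail <- paste0(substr(hp1, 12, 32), "A")
    vc <- classifyVariant(matchRead(trimmedTail, space)[1, ], mature1)
    expect_equal(vc$d5, 1L)
    expect_equal(vc$nt_len, 1L)
    expect_equal(vc$class_label, "mixed")
    expect_true(vc$seed_shifted)

    expect_error(classifyVariant(canonical, fixtureMature(space, "fix-miR-2")),
        "different hairpins")
})

test_that("every placed read gets exactly one class label and the labels
           partition on (d5, d3, nt)", {
    bundle <- makeReference(seed = 31, nHairpins = 8, genomeLen = 20000,
        nRepeatHairpins = 0, nDuplicated = 0)
    rd <- simulateReads(bundle, profile = c(canonical = 0.3, iso_5p = 0.2,
        iso_3p = 0.2, nt_tail = 0.15), nReads = 2000, seed = 32)
    agg <- stats::aggregate(count ~ sequence,
        data.frame(sequence = rd$sequence, count = 1L), sum)
    q <- quantifySample(agg, bundleSpace(bundle), sum(agg$count))
    a <- q$assignments
    expect_gt(nrow(a), 0)
    relabel <- ifelse(a$d5 == 0 & a$d3 == 0 & a$nt_len == 0, "canonical",
        ifelse(a$d5 != 0 & a$d3 == 0 & a$nt_len == 0, "iso_5p",
        ifelse(a$d5 == 0 & a$d3 != 0 & a$nt_len == 0, "iso_3p",
        ifelse(a$d5 == 0 & a$nt_len > 0, "iso_3p_nontemplated", "mixed"))))
    expect_identical(a$class, relabel)
    expect_identical(a$seed_shifted, a$d5 != 0L)
})

test_that("no emitted placement carries a tail whose first base matches
           the hairpin continuation", {
    bundle <- makeReference(seed = 33, nHairpins = 8, genomeLen = 20000,
        nRepeatHairpins = 0, nDuplicated = 0)
    space <- bundleSpace(bundle)
    rd <- simulateReads(bundle, profile = c(nt_tail = 1), nReads = 500,
        seed = 34)
    hp <- as.character(hairpins(space))
    for (s in unique(rd$sequence)) {
        pl <- matchRead(s, space)
        withTail <- pl[nchar(pl$nt_tail) > 0, , drop = FALSE]
        for (j in seq_len(nrow(withTail))) {
            p <- withTail[j, ]
            contPos <- p$start + p$templated_len + 1L
            cont <- substr(hp[[p$hairpin_id]], contPos, contPos)
            expect_true(cont == "" || cont != substr(p$nt_tail, 1, 1))
        }
    }
})

test_that("seed extraction follows 1-based residues 2-8", {
    expect_identical(seedOf("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUAG")
    expect_identical(seedOf("ACGTACGT"), "CGTACGT")
    # invariant to bases beyond position 8
    expect_identical(seedOf("ACGTACGTAAAA"), seedOf("ACGTACGTCCCC"))
    expect_error(seedOf("ACGTACG"), "at least 8")
})

test_that("sequence identifiers round-trip, are injective and scale as
           one symbol per 5 bits", {
    set.seed(7)
    seqs <- vapply(sample(17:28, 1000, replace = TRUE), function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    expect_identical(decodeUid(encodeUid(seqs)), seqs)
    # exhaustive injectivity over all 4^8 8-mers
    all8 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 8),
        stringsAsFactors = FALSE))
    uids <- encodeUid(all8)
    expect_equal(anyDuplicated(uids), 0L)
    # code length is ceiling(2n / 5) symbols
    n <- nchar(seqs)
    code <- sub("^iso-[0-9]+-", "", encodeUid(seqs))
    expect_equal(nchar(code), ceiling(2 * n / 5))
    expect_identical(encodeUid("UGAGG"), encodeUid("TGAGG"))
    expect_error(encodeUid("ACGTN"), "characters")
    expect_error(decodeUid("iso-8-!!"), "malformed")
})

test_that("RPM normalization uses the post-filtered sample total", {
    reads <- data.frame(sequence = matureSeq, count = 2L)
    q <- quantifySample(reads, space, 1e6)
    expect_equal(q$records$rpm, 2.0)
    q <- quantifySample(data.frame(sequence = matureSeq, count = 5L),
        space, 5e5)
    expect_equal(q$records$rpm, 10.0)
    expect_error(quantifySample(reads, space, 0), "positive")
    expect_error(quantifySample(reads, space, 1), "smaller")
    expect_error(quantifySample(data.frame(sequence = matureSeq,
        count = 1.5), space, 10), "positive integers")
})

test_that("counts are conserved and unplaced reads are reported with a
           reason", {
    hp1 <- as.character(hairpins(space)[["fix-hp-1"]])
    reads <- data.frame(
        sequence = c(matureSeq, paste0(matureSeq, "A"), strrep("A", 20),
            strrep("C", 30), "ACGTNACGTNACGTNACGTN"),
        count = c(3L, 2L, 4L, 1L, 2L))
    q <- quantifySample(reads, space, 100)
    expect_lte(sum(q$records$count), 100)
    expect_equal(sum(q$records$count) + sum(q$unplaced$count),
        sum(reads$count))
    expect_setequal(q$unplaced$reason,
        c("no_exact_match", "length_out_of_range", "ambiguous_base"))
    # per-sample RPM conservation: sum(rpm) over distinct sequences equals
    # 1e6 * placed / total
    expect_equal(sum(q$records$rpm), 1e6 * sum(q$records$count) / 100)
})

test_that("identical sequences across loci collapse to one row with the
           union of parents and unchanged counts", {
    shared <- "ACGTACGTTAGCCTAGGATCAT"
    h1 <- paste0(strrep("C", 12), shared, strrep("G", 26))
    h2 <- paste0(strrep("T", 5), shared, strrep("A", 33))
    tab <- data.frame(name = c("m1", "m2"), hairpin_id = c("h1", "h2"),
        local_start = c(12L, 5L), local_end = c(34L, 27L),
        stringsAsFactors = FALSE)
    sp2 <- buildSpaceIndex(MiRNASpaceFromSeqs(c(h1 = h1, h2 = h2), tab))
    q <- quantifySample(data.frame(sequence = shared, count = 7L), sp2, 100)
    expect_equal(nrow(q$assignments), 2L)       # one per parent
    col <- collapseIdentical(q$assignments)
    expect_equal(nrow(col), 1L)
    expect_equal(col$n_parents, 2L)
    expect_equal(col$parents, "m1,m2")
    expect_equal(col$count, 7)                  # never multiplied
})

test_that("collapsing all-distinct records is the identity on rows and
           conserves totals", {
    bundle <- makeReference(seed = 35, nHairpins = 6, genomeLen = 20000,
        nRepeatHairpins = 0, nDuplicated = 0)
    rd <- simulateReads(bundle, nReads = 800, seed = 36)
    agg <- stats::aggregate(count ~ sequence,
        data.frame(sequence = rd$sequence, count = 1L), sum)
    q <- quantifySample(agg, bundleSpace(bundle), 800)
    col <- collapseIdentical(q$assignments)
    expect_equal(nrow(col), length(unique(q$assignments$sequence)))
    expect_equal(sum(col$count),
        sum(q$records$count[q$records$parents != ""]))
})

test_that("seed census counts only 5'-shifted variants as new seeds", {
    hp1 <- as.character(hairpins(space)[["fix-hp-1"]])
    threePrime <- data.frame(         # canonical plus 3'-only variants
        sequence = c(substr(hp1, 11, 32), substr(hp1, 11, 34),
            paste0(substr(hp1, 11, 32), "A")),
        count = 1L)
    q <- quantifySample(threePrime, space, 10)
    census <- seedVariantCensus(q$assignments)
    expect_equal(census$n_seeds[census$mature == "fix-miR-1"], 1L)

    fivePrime <- data.frame(          # d5 in {-1, 0, +1}
        sequence = c(substr(hp1, 10, 32), substr(hp1, 11, 32),
            substr(hp1, 12, 32)),
        count = 1L)
    q <- quantifySample(fivePrime, space, 10)
    census <- seedVariantCensus(q$assignments)
    expect_equal(census$n_seeds[census$mature == "fix-miR-1"], 3L)
    expect_true(all(census$n_seeds >= 1L))
})
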