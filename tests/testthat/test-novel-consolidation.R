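library(GenomicRanges)
library(Biostrings)

test_that("loci merge only when sharing more than the overlap threshold", {
    # 0-based half-open [100,180) and [160,240): 20 shared bases -> merge
    a <- GRanges("chr1", IRanges(101, 180), strand = "+")
    b <- GRanges("chr1", IRanges(161, 240), strand = "+")
    expect_equal(mergeLoci(c(a, b)), c(1L, 1L))
    # [100,180) and [165,240): 15 shared bases -> separate
    b2 <- GRanges("chr1", IRanges(166, 240), strand = "+")
    expect_equal(mergeLoci(c(a, b2)), c(1L, 2L))
    # exactly 17 shared bases is tolerated; 18 merges
    b17 <- GRanges("chr1", IRanges(164, 240), strand = "+")
    expect_equal(mergeLoci(c(a, b17)), c(1L, 2L))
    b18 <- GRanges("chr1", IRanges(163, 240), strand = "+")
    expect_equal(mergeLoci(c(a, b18)), c(1L, 1L))
    expect_equal(mergeLoci(c(a, b18), inclusive = TRUE)[2], 1L)
    expect_equal(mergeLoci(c(a, b17), inclusive = TRUE), c(1L, 1L))
})

test_that("merging respects strand and chromosome and is transitive", {
    a <- GRanges("chr1", IRanges(101, 180), strand = "+")
    bMinus <- GRanges("chr1", IRanges(121, 200), strand = "-")
    expect_equal(mergeLoci(c(a, bMinus)), c(1L, 2L))
    expect_equal(mergeLoci(c(a, bMinus), respectStrand = FALSE), c(1L, 1L))
    twoChrom <- GRanges(c("chr1", "chr2"), IRanges(c(101, 101),
        c(180, 180)), strand = "+")
    expect_equal(mergeLoci(twoChrom), c(1L, 2L))
    # chain a-b-c where a and c do not overlap directly
    chain <- GRanges("chr1", IRanges(c(1, 61, 121), c(100, 160, 220)),
        strand = "+")
    expect_equal(mergeLoci(chain), c(1L, 1L, 1L))
    disjoint <- GRanges("chr1", IRanges(c(1, 500, 900), c(80, 580, 980)),
        strand = "+")
    expect_equal(mergeLoci(disjoint), 1:3)
})

test_that("representative selection takes the count maximum with a
           seeded, reproducible tie-break", {
    expect_equal(selectRepresentative(c(A = 500, B = 300)), "A")
    expect_equal(selectRepresentative(c(only = 12)), "only")
    picks <- vapply(1:20, function(i)
        selectRepresentative(c(A = 400, B = 400), seed = 77), character(1))
    expect_equal(length(unique(picks)), 1L)
    expect_true(picks[1] %in% c("A", "B"))
    expect_error(selectRepresentative(numeric()), "empty")
})

test_that("expression screen for predicted hairpins is inclusive at the
           RPM threshold", {
    rpm <- rbind(h1 = c(20, 20, 0), h2 = c(21, 0, 0), h3 = c(100, 100, 100))
    colnames(rpm) <- paste0("s", 1:3)
    expect_equal(filterExpressedHairpins(rownames(rpm), rpm),
        c("h1", "h3"))
    expect_error(filterExpressedHairpins(c("h1", "hX"), rpm), "hX")
})

test_that("candidates overlapping known hairpins beyond the tolerance are
           removed", {
    known <- GRanges("chr1", IRanges(101, 180), strand = "+")
    cand18 <- GRanges("chr1", IRanges(163, 240), strand = "-")  # 18 shared
    cand17 <- GRanges("chr1", IRanges(164, 240), strand = "-")  # 17 shared
    nested <- GRanges("chr1", IRanges(120, 160), strand = "+")
    far <- GRanges("chr1", IRanges(900, 980), strand = "+")
    keep <- removeKnownOverlap(c(cand18, cand17, nested, far), known)
    expect_identical(keep, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("the genomic multiplicity cap counts both strands exactly", {
    set.seed(55)
    bg <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
        collapse = "")
    planted <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
        collapse = "")
    plantAt <- function(g, s, pos) {
        substr(g, pos, pos + nchar(s) - 1L) <- s
        g
    }
    g16 <- bg
    for (k in 0:15) g16 <- plantAt(g16, planted, 100 + k * 200)
    g15 <- bg
    for (k in 0:14) g15 <- plantAt(g15, planted, 100 + k * 200)
    unique1 <- plantAt(bg, planted, 100)
    keep <- multiplicityFilter(c(x = planted),
        DNAStringSet(c(chr1 = g16)))
    expect_false(keep[["x"]])
    expect_equal(attr(keep, "hits")[["x"]], 16L)
    expect_true(multiplicityFilter(c(x = planted),
        DNAStringSet(c(chr1 = g15)))[["x"]])
    expect_true(multiplicityFilter(c(x = planted),
        DNAStringSet(c(chr1 = unique1)))[["x"]])
    # a reverse-complement copy counts toward the cap
    gRC <- plantAt(unique1, oracleRevcomp(planted), 4000)
    expect_equal(attr(multiplicityFilter(c(x = planted),
        DNAStringSet(c(chr1 = gRC))), "hits")[["x"]], 2L)
})

ORTHO_HITS <- data.frame(
    query_id = c("c1", "c2", "c2", "c3", "c4"),
    subject_id = c("bta-mir-1", "ssc-mir-9", "bta-mir-9", "hsa-mir-7",
        "mmu-mir-5"),
    species = c("cow", "pig", "cow", "human", "mouse"),
    percent_identity = c(98, 95, 95, 99, 97),
    query_coverage = c(0.85, 0.9, 0.9, 0.95, 0.85),
    q_value = c(0.005, 0.001, 0.001, 0.02, 0.009),
    stringsAsFactors = FALSE)

test_that("ortholog naming honours q-value, coverage and species
           priority", {
    res <- assignNames(c("c1", "c2", "c3", "c5"), ORTHO_HITS)
    expect_equal(res$name[res$id == "c1"], "bta-mir-1")
    # equal identity in cow and pig: cow is earlier in the priority list
    expect_equal(res$name[res$id == "c2"], "bta-mir-9")
    expect_equal(res$ortholog_species[res$id == "c2"], "cow")
    # q = 0.02 fails the threshold: original id retained
    expect_equal(res$name[res$id == "c3"], "c3")
    expect_false(res$named[res$id == "c3"])
    # no hits at all
    expect_equal(res$name[res$id == "c5"], "c5")
})

test_that("no emitted name is supported by a hit violating the
           thresholds, and unknown species warn", {
    low <- ORTHO_HITS
    low$query_coverage[1] <- 0.5
    res <- assignNames(c("c1", "c2"), low)
    for (i in which(res$named)) {
        sup <- low[low$query_id == res$id[i] &
            low$subject_id == res$ortholog_subject[i], ]
        expect_true(all(sup$q_value < 0.01 & sup$query_coverage > 0.80))
    }
    odd <- ORTHO_HITS
    odd$species[5] <- "axolotl"
    expect_warning(assignNames("c4", odd), "axolotl")
})

makeConsolidationFixture <- function() {
    set.seed(77)
    bg <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
        collapse = "")
    seqs <- vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"),
        70, replace = TRUE), collapse = ""), character(1))
    # loc1/loc2 overlap by 50 (one group, loc1 has more counts);
    # loc3 overlaps a known hairpin; loc4 is repetitive; loc5 is clean
    starts <- c(1000, 1020, 3000, 5000, 9000)
    g <- bg
    for (i in c(1, 3, 5)) {
        substr(g, starts[i], starts[i] + 69) <- seqs[i]
    }
    seqs[2] <- substr(g, 1020, 1089)      # loc2 sequence as in genome
    for (k in 0:16)                       # 17 scattered copies of loc4
        substr(g, 11000 + k * 400, 11000 + k * 400 + 69) <- seqs[4]
    substr(g, 5000, 5069) <- seqs[4]
    loci <- GRanges("chr1", IRanges(starts, starts + 69), strand = "+",
        locus_id = paste0("loc", 1:5), sequence = seqs)
    counts <- matrix(50, 5, 3,
        dimnames = list(paste0("loc", 1:5), paste0("s", 1:3)))
    counts["loc1", ] <- c(300, 200, 100)
    counts["loc2", ] <- c(100, 100, 100)
    rpm <- matrix(50, 5, 3, dimnames = dimnames(counts))
    known <- GRanges("chr1", IRanges(3010, 3090), strand = "+")
    list(loci = loci, counts = counts, rpm = rpm, known = known,
        genome = DNAStringSet(c(chr1 = g)))
}

test_that("the consolidation pipeline removes exactly the planted
           violations", {
    fx <- makeConsolidationFixture()
    res <- consolidateNovelLoci(fx$loci, fx$counts, fx$rpm, fx$known,
        fx$genome, seed = 9)
    expect_setequal(res$kept$locus_id, c("loc1", "loc5"))
    expect_equal(res$groups[["loc1"]], res$groups[["loc2"]])
    steps <- setNames(res$report$removed, res$report$step)
    expect_equal(unname(steps["multiplicity"]), 1)   # loc4
    expect_equal(unname(steps["known_overlap"]), 1)  # loc3
})

test_that("group assignment and representatives are stable under input
           permutation", {
    fx <- makeConsolidationFixture()
    res1 <- consolidateNovelLoci(fx$loci, fx$counts, fx$rpm, fx$known,
        fx$genome, seed = 9)
    perm <- c(4, 2, 5, 1, 3)
    res2 <- consolidateNovelLoci(fx$loci[perm], fx$counts, fx$rpm,
        fx$known, fx$genome, seed = 9)
    expect_setequal(res1$kept$locus_id, res2$kept$locus_id)
    g1 <- unname(split(names(res1$groups), res1$groups))
    g2 <- unname(split(names(res2$groups), res2$groups))
    expect_true(setequal(lapply(g1, sort), lapply(g2, sort)))
})
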