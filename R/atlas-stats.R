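#' Pool samples into organ groups and compute mean RPM per organ
#'
#' Tissue types originating from the same organ (e.g. heart chambers,
#' kidney regions, skin sections, brain subregions) are collapsed into one
#' organ group; all other tissues stand alone.  The organ mean is the
#' pooled mean over every sample of every tissue in the group (not a mean
#' of tissue means), so tissues with more samples weigh proportionally.
#'
#' @param rpm Numeric RPM matrix, miRNAs x samples.
#' @param meta `data.frame` with columns `sample` and `tissue` covering
#'   every column of `rpm`.
#' @param grouping Named list or named character vector mapping tissue ->
#'   organ; tissues absent from the map keep their own label (identity
#'   mapping by default).  Pass `strict = TRUE` to require every tissue to
#'   be listed.
#' @param strict Require an explicit mapping for every tissue.
#' @return A list with `means` (miRNAs x organs matrix), `grouping`
#'   (tissue -> organ map used) and `n` (number of organs).
#' @export
groupOrgans <- function(rpm, meta, grouping = NULL, strict = FALSE) {
    stopifnot(is.matrix(rpm), all(c("sample", "tissue") %in% names(meta)))
    missing <- setdiff(colnames(rpm), meta$sample)
    if (length(missing))
        stop("samples absent from metadata: ",
            paste(missing, collapse = ", "))
    meta <- meta[match(colnames(rpm), meta$sample), ]
    map <- unlist(grouping)
    tissues <- unique(meta$tissue)
    if (strict) {
        unmapped <- setdiff(tissues, names(map))
        if (length(unmapped))
            stop("tissues without an organ mapping: ",
                paste(unmapped, collapse = ", "))
    }
    organOf <- ifelse(meta$tissue %in% names(map),
        unname(map[meta$tissue]), meta$tissue)
    organs <- unique(organOf)
    means <- vapply(organs, function(o)
        rowMeans(rpm[, organOf == o, drop = FALSE]),
        numeric(nrow(rpm)))
    if (nrow(rpm) == 1L) {
        means <- matrix(means, nrow = 1L,
            dimnames = list(rownames(rpm), organs))
    }
    fullMap <- stats::setNames(
        ifelse(tissues %in% names(map), unname(map[tissues]), tissues),
        tissues)
    list(means = means, grouping = fullMap, n = length(organs))
}

#' Organ-enrichment index (OEI)
#'
#' A 0-1 specificity score per miRNA, analogous to the tissue-specificity
#' index tau.  With `x[j, i]` the mean RPM of miRNA `j` in organ `i`
#' scaled by its maximum over organs, the index is
#' `oei_j = sum_i (1 - x[j, i]) / (N - 1)` over the `N` organs: 0 for a
#' perfectly uniform (housekeeping) miRNA and 1 for expression confined to
#' a single organ.  Only miRNAs whose mean RPM exceeds `minMeanRpm` in at
#' least one organ are scored; the rest are reported with
#' `included = FALSE` and no index.
#'
#' @param means Numeric matrix of organ means, miRNAs x organs (at least
#'   two organs), e.g. from [groupOrgans()].
#' @param minMeanRpm Inclusion threshold (default 20, strict `>`).
#' @return `data.frame` with columns `mirna`, `included`, `oei`, `class`
#'   (from [classifyOEI()]; `NA` when not included).
#' @examples
#' m <- rbind(specific = c(100, 0, 0), shared = c(100, 50, 0))
#' colnames(m) <- paste0("organ", 1:3)
#' computeOEI(m)
#' @export
computeOEI <- function(means, minMeanRpm = 20) {
    stopifnot(is.matrix(means))
    if (ncol(means) < 2L)
        stop("OEI requires at least 2 organs")
    if (any(means < 0))
        stop("organ means must be non-negative")
    n <- ncol(means)
    mx <- apply(means, 1L, max)
    included <- mx > minMeanRpm
    oei <- rep(NA_real_, nrow(means))
    idx <- which(included)
    if (length(idx)) {
        x <- means[idx, , drop = FALSE] / mx[idx]
        oei[idx] <- rowSums(1 - x) / (n - 1)
    }
    data.frame(
        mirna = if (!is.null(rownames(means))) rownames(means)
            else as.character(seq_len(nrow(means))),
        included = included,
        oei = oei,
        class = ifelse(included, classifyOEI(oei), NA_character_),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify OEI values into specificity bands
#'
#' `oei < 0.15` is ubiquitous, `oei > 0.85` tissue-specific, and anything
#' in between (boundaries included) intermediate.
#'
#' @param oei Numeric vector of OEI values in `[0, 1]` (`NA` allowed).
#' @return Character vector of `"ubiquitous"`, `"intermediate"`,
#'   `"tissue_specific"` (or `NA`).
#' @export
classifyOEI <- function(oei) {
    ifelse(is.na(oei), NA_character_,
        ifelse(oei < 0.15, "ubiquitous",
            ifelse(oei > 0.85, "tissue_specific", "intermediate")))
}

#' Robust rank aggregation score for one item
#'
#' Given an item's 1-based ranks in `m` independent ranked lists, the
#' normalized ranks `r_k = rank_k / length_k` are sorted ascending and
#' each compared with the null distribution of the k-th order statistic of
#' `m` independent uniforms: `B_k = P(Beta(k, m - k + 1) <= r_(k))`.  The
#' score is `rho = min_k B_k`, and the Bonferroni-corrected significance
#' over the `m` order statistics considered is `p = min(1, m * rho)` — a
#' conservative p-value for the item ranking better than chance.
#'
#' @param ranks Integer vector of the item's ranks, one per list in which
#'   it appears.
#' @param listLengths Integer vector of the corresponding list lengths
#'   (recycled if scalar).
#' @return A list with `rho`, `p_value`, `r` (sorted normalized ranks) and
#'   `m`.
#' @examples
#' rraScore(c(1, 1), c(10, 10))  # rho = 0.01, p = 0.02
#' @export
rraScore <- function(ranks, listLengths) {
    m <- length(ranks)
    if (!m)
        stop("item absent from every list: score undefined")
    listLengths <- rep_len(listLengths, m)
    if (any(ranks < 1L) || any(ranks > listLengths))
        stop("ranks must lie within their list lengths")
    r <- sort(ranks / listLengths)
    B <- stats::pbeta(r, seq_len(m), m - seq_len(m) + 1L)
    rho <- min(B)
    list(rho = rho, p_value = min(1, m * rho), r = r, m = m)
}

# Vectorized rho over a matrix of normalized ranks (rows = items, columns
# already sorted ascending per row); used by the aggregators.
.rraRho <- function(R) {
    m <- ncol(R)
    B <- matrix(stats::pbeta(as.vector(R),
        rep(seq_len(m), each = nrow(R)),
        rep(m - seq_len(m) + 1L, each = nrow(R))), nrow = nrow(R))
    do.call(pmin, lapply(seq_len(m), function(j) B[, j]))
}

#' Aggregate per-sample ranked miRNA lists
#'
#' Each sample contributes one ranked list (by descending expression).
#' Every item appearing in at least one list is scored with [rraScore()];
#' items missing from a list contribute no rank there (their `m` is the
#' number of lists containing them) rather than an imputed worst rank.
#'
#' @param lists A list of character vectors, each a ranked list (best
#'   first).
#' @return `data.frame` with columns `item`, `rho`, `p_value`, `m`,
#'   sorted by `p_value`, then `rho`, then item id.
#' @export
rraAggregate <- function(lists) {
    stopifnot(is.list(lists), length(lists) >= 1L)
    items <- unique(unlist(lists))
    lens <- lengths(lists)
    rankOf <- lapply(lists, function(l) stats::setNames(seq_along(l), l))
    res <- lapply(items, function(it) {
        pos <- vapply(rankOf, function(r)
            if (it %in% names(r)) r[[it]] else NA_integer_, integer(1))
        inL <- !is.na(pos)
        sc <- rraScore(pos[inL], lens[inL])
        data.frame(item = it, rho = sc$rho, p_value = sc$p_value,
            m = sc$m, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out[order(out$p_value, out$rho, out$item), , drop = FALSE]
}

#' Top-N miRNAs per tissue by robust rank aggregation
#'
#' For each tissue, every sample contributes a ranked miRNA list
#' (descending RPM, ties broken by miRNA id so lists are total orders,
#' optionally truncated at `listDepth`).  Items are aggregated with
#' [rraAggregate()] and the `n` items with the smallest p-value are
#' reported (ties by smaller `rho`, then id).
#'
#' @param rpm Numeric RPM matrix, miRNAs x samples.
#' @param meta `data.frame` with columns `sample` and `tissue`.
#' @param n Number of top items per tissue (default 5).
#' @param listDepth Truncate each sample's list at this depth
#'   (default `Inf`, full list).
#' @return `data.frame` with columns `tissue`, `rank`, `mirna`, `rho`,
#'   `p_value`, `m`.
#' @export
topTissueMiRNAs <- function(rpm, meta, n = 5L, listDepth = Inf) {
    if (n < 1L)
        stop("n must be at least 1")
    stopifnot(is.matrix(rpm), all(c("sample", "tissue") %in% names(meta)))
    meta <- meta[match(colnames(rpm), meta$sample), ]
    out <- lapply(unique(meta$tissue), function(tis) {
        cols <- which(meta$tissue == tis)
        lists <- lapply(cols, function(j) {
            v <- rpm[, j]
            ord <- order(-v, rownames(rpm))
            ids <- rownames(rpm)[ord]
            if (is.finite(listDepth)) ids <- utils::head(ids, listDepth)
            ids
        })
        agg <- rraAggregate(lists)
        top <- utils::head(agg, n)
        data.frame(tissue = tis, rank = seq_len(nrow(top)),
            mirna = top$item, rho = top$rho, p_value = top$p_value,
            m = top$m, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
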