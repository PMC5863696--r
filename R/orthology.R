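#' Bidirectional best hits
#'
#' A pair (a, b) is a BBH iff b is a's best-scoring subject within b's
#' species and a is b's best within a's species. "Best" means maximum
#' bitscore, ties broken by smaller E-value, then lexicographically smaller
#' subject identifier.
#'
#' @param hits data.frame (`query`, `subject`, `evalue`, `bitscore`),
#'   already filtered to the E-value threshold of interest.
#' @param speciesOf named character vector mapping gene id to species.
#' @return data.frame with columns `gene_a`, `gene_b` (each unordered pair
#'   listed once, `gene_a` < `gene_b` lexicographically).
#' @export
computeBbh <- function(hits, speciesOf) {
    if (!nrow(hits))
        return(data.frame(gene_a = character(0), gene_b = character(0)))
    h <- hits
    h$qsp <- unname(speciesOf[h$query])
    h$ssp <- unname(speciesOf[h$subject])
    h <- h[!is.na(h$qsp) & !is.na(h$ssp) & h$qsp != h$ssp, , drop = FALSE]
    if (!nrow(h))
        return(data.frame(gene_a = character(0), gene_b = character(0)))
    ## best subject per (query, subject-species)
    o <- order(h$query, h$ssp, -h$bitscore, h$evalue, h$subject)
    h <- h[o, , drop = FALSE]
    best <- h[!duplicated(paste(h$query, h$ssp, sep = "\r")), , drop = FALSE]
    key <- paste(best$query, best$subject, sep = "\r")
    rkey <- paste(best$subject, best$query, sep = "\r")
    mutual <- key[key %in% rkey]
    if (!length(mutual))
        return(data.frame(gene_a = character(0), gene_b = character(0)))
    a <- sub("\r.*", "", mutual); b <- sub(".*\r", "", mutual)
    ga <- pmin(a, b); gb <- pmax(a, b)
    out <- unique(data.frame(gene_a = ga, gene_b = gb))
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fraction of a gene inside a segment region
#'
#' Base-overlap fraction of the gene interval with the segment's region on
#' the gene's genome; 0 when chromosome (or genome) differ.
#'
#' @param geneChrom,geneStart,geneEnd the gene interval (1-based closed).
#' @param regionChrom,regionStart,regionEnd the segment region.
#' @return fraction in \[0, 1\].
#' @export
geneSegmentOverlap <- function(geneChrom, geneStart, geneEnd,
                               regionChrom, regionStart, regionEnd) {
    if (geneChrom != regionChrom) return(0)
    ov <- min(geneEnd, regionEnd) - max(geneStart, regionStart) + 1
    max(ov, 0) / (geneEnd - geneStart + 1)
}

#' Orthologous pair support score
#'
#' `OPSS = M + 0.5 * P + B`, where M is the degree (n of the n-way level,
#' pairwise = 2, absent = 0) of the best supporting MAA-based collinear
#' segment, P the analogous degree for gene-based segments, and B is 2 for
#' a bidirectional best hit and 0 otherwise.
#'
#' @param m_score,p_score 0 or an integer degree in 2..S.
#' @param b_score 0 or 2.
#' @return the composite score.
#' @examples
#' scoreOpss(2, 0, 0)   # pairwise MAA support only -> 2 (< 3)
#' scoreOpss(10, 2, 2)  # deep multi-species support plus BBH -> 13
#' @export
scoreOpss <- function(m_score, p_score, b_score) {
    stopifnot(length(m_score) == length(p_score),
              length(p_score) == length(b_score))
    if (any(!(m_score == 0 | m_score >= 2)) ||
        any(!(p_score == 0 | p_score >= 2)))
        stop("m_score and p_score must be 0 or a degree >= 2")
    if (any(!b_score %in% c(0, 2))) stop("b_score must be 0 or 2")
    m_score + 0.5 * p_score + b_score
}

## coverage fraction of gene intervals in the nested n-way regions.
## Returns, per gene, the maximal n (>= 3) whose cumulative region covers
## at least minOverlap of the gene, or 0.
.nwayDegree <- function(genesGr, nWay, minOverlap) {
    if (!length(nWay) || !length(genesGr))
        return(integer(length(genesGr)))
    ns <- sort(unique(S4Vectors::mcols(nWay)$n))
    deg <- integer(length(genesGr))
    gw <- GenomicRanges::width(genesGr)
    for (n in ns) {
        ## I_n = union of maximal-level regions with level >= n
        reg <- GenomicRanges::reduce(nWay[S4Vectors::mcols(nWay)$n >= n])
        ov <- GenomicRanges::findOverlaps(genesGr, reg)
        if (!length(ov)) next
        wov <- GenomicRanges::width(GenomicRanges::pintersect(
            genesGr[S4Vectors::queryHits(ov)], reg[S4Vectors::subjectHits(ov)]))
        covered <- vapply(split(wov, S4Vectors::queryHits(ov)), sum, 0)
        gi <- as.integer(names(covered))
        hit <- gi[covered / gw[gi] >= minOverlap]
        deg[hit] <- pmax(deg[hit], n)
    }
    deg
}

## For one segment set (one marker type): which (gene_a, gene_b) candidate
## pairs have both genes >= minOverlap inside the two sides of a segment,
## and the degree of the best such support.
.segmentSupport <- function(cand, genes, segments, classification, order,
                            minOverlap) {
    support <- logical(nrow(cand))
    degree <- integer(nrow(cand))
    if (!length(segments)) return(list(support = support, degree = degree))
    tb <- segTable(segments)
    gm <- S4Vectors::mcols(genes)
    gchrom <- as.character(GenomicRanges::seqnames(genes))
    gstart <- GenomicRanges::start(genes)
    gend <- GenomicRanges::end(genes)
    gidx <- setNames(seq_along(genes), gm$gene_id)
    d <- dIndex(order)
    ## per-gene degree from the n-way classification (reference side)
    ia <- gidx[cand$gene_a]
    nd <- .nwayDegree(genes[ia], classification$n_way, minOverlap)
    for (si in seq_len(nrow(tb))) {
        s <- tb[si, ]
        rows <- which(cand$species_b == s$species_b)
        if (!length(rows)) next
        ga <- gidx[cand$gene_a[rows]]
        gb <- gidx[cand$gene_b[rows]]
        fa <- ifelse(gchrom[ga] == s$chrom_a,
                     pmax(pmin(gend[ga], s$end_a) -
                          pmax(gstart[ga], s$start_a) + 1, 0) /
                     (gend[ga] - gstart[ga] + 1), 0)
        fb <- ifelse(gchrom[gb] == s$chrom_b,
                     pmax(pmin(gend[gb], s$end_b) -
                          pmax(gstart[gb], s$start_b) + 1, 0) /
                     (gend[gb] - gstart[gb] + 1), 0)
        ok <- fa >= minOverlap & fb >= minOverlap
        if (!any(ok)) next
        hit <- rows[ok]
        support[hit] <- TRUE
        ## pairwise support contributes degree 2; the n-way elevation below
        ## may raise it
        degree[hit] <- pmax(degree[hit], 2L)
    }
    ## elevate supported pairs by the n-way degree of the reference gene,
    ## allowed only up to prefixes that include the partner species
    ds <- unname(d[cand$species_b])
    up <- support & nd >= pmax(ds, 3L)
    degree[up] <- pmax(degree[up], nd[up])
    list(support = support, degree = degree)
}

#' Infer orthologous protein-coding gene pairs (OPPs)
#'
#' A cross-species gene pair is emitted iff (i) a homology hit at
#' `evalueMax` links the two genes and (ii) at least `minOverlap` of both
#' gene lengths lies inside the two sides of one MAA-based collinear
#' segment. Two optional evidence types are recorded without being
#' required: (iii) the pair is a bidirectional best hit and (iv) condition
#' (ii) also holds for gene-based collinear segments. The M-score is the
#' maximal degree over supporting MAA-based segments (n of the deepest
#' n-way level whose region covers the reference gene, with the partner
#' species inside the n-prefix; plain pairwise support counts 2), the
#' P-score the analogue for gene-based segments, the B-score is 2 for BBH
#' pairs, and `OPSS = M + 0.5 P + B`.
#'
#' @param genes GRanges of all gene models (mcols `gene_id`, `species`).
#' @param maaSegments [CollinearSegments-class] from MAA markers
#'   (reference on side A).
#' @param geneSegments [CollinearSegments-class] from gene markers, or
#'   `NULL`.
#' @param hits homology hit data.frame.
#' @param order [PhyloOrder-class].
#' @param minOverlap condition-(ii) overlap threshold (default 0.5).
#' @param evalueMax condition-(i) E-value threshold (default 1e-5).
#' @return data.frame with one row per OPP: `gene_a`, `gene_b`,
#'   `species_b`, evidence flags (`has_similarity`, `maa_overlap_ok`,
#'   `is_bbh`, `protein_collinear_ok`), `m_score`, `p_score`, `b_score`,
#'   `opss`.
#' @export
inferOpps <- function(genes, maaSegments, geneSegments, hits, order,
                      minOverlap = 0.5, evalueMax = 1e-5) {
    gm <- S4Vectors::mcols(genes)
    speciesOf <- setNames(as.character(gm$species), gm$gene_id)
    ref <- refSpecies(order)
    h <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    h <- h[h$query %in% names(speciesOf) & h$subject %in% names(speciesOf), ,
           drop = FALSE]
    empty <- data.frame(gene_a = character(0), gene_b = character(0),
                        species_b = character(0), has_similarity = logical(0),
                        maa_overlap_ok = logical(0), is_bbh = logical(0),
                        protein_collinear_ok = logical(0),
                        m_score = integer(0), p_score = integer(0),
                        b_score = numeric(0), opss = numeric(0))
    if (!nrow(h)) return(empty)
    qsp <- unname(speciesOf[h$query]); ssp <- unname(speciesOf[h$subject])
    ## orient candidate pairs reference -> partner
    fwd <- h[qsp == ref & ssp != ref, c("query", "subject")]
    rev <- h[ssp == ref & qsp != ref, c("subject", "query")]
    names(fwd) <- names(rev) <- c("gene_a", "gene_b")
    cand <- unique(rbind(fwd, rev))
    if (!nrow(cand)) return(empty)
    cand$species_b <- unname(speciesOf[cand$gene_b])
    maaClass <- classifyLevels(maaSegments, order)
    msup <- .segmentSupport(cand, genes, maaSegments, maaClass, order,
                            minOverlap)
    keep <- msup$support
    if (!any(keep)) return(empty)
    cand <- cand[keep, , drop = FALSE]
    m <- msup$degree[keep]
    if (!is.null(geneSegments) && length(geneSegments)) {
        geneClass <- classifyLevels(geneSegments, order)
        psup <- .segmentSupport(cand, genes, geneSegments, geneClass, order,
                                minOverlap)
        p <- psup$degree
        pflag <- psup$support
    } else {
        p <- integer(nrow(cand)); pflag <- logical(nrow(cand))
    }
    bbh <- computeBbh(h, speciesOf)
    bkey <- paste(bbh$gene_a, bbh$gene_b, sep = "\r")
    ckey <- paste(pmin(cand$gene_a, cand$gene_b),
                  pmax(cand$gene_a, cand$gene_b), sep = "\r")
    isBbh <- ckey %in% bkey
    b <- ifelse(isBbh, 2, 0)
    out <- data.frame(gene_a = cand$gene_a, gene_b = cand$gene_b,
                      species_b = cand$species_b, has_similarity = TRUE,
                      maa_overlap_ok = TRUE, is_bbh = isBbh,
                      protein_collinear_ok = pflag,
                      m_score = m, p_score = p, b_score = b,
                      opss = scoreOpss(m, p, b))
    out <- out[order(out$species_b, out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Histogram of OPSS values
#'
#' @param opps OPP data.frame from [inferOpps()].
#' @param breaks bin breakpoints passed to [cut()] (right-open bins).
#' @return data.frame with `bin`, `count`, `fraction` (fractions sum to 1
#'   for non-empty input).
#' @export
opssDistribution <- function(opps, breaks = seq(0, 20, by = 1)) {
    bins <- cut(opps$opss, breaks = breaks, right = FALSE,
                include.lowest = TRUE)
    counts <- table(bins)
    data.frame(bin = names(counts), count = as.integer(counts),
               fraction = if (nrow(opps)) as.integer(counts) / nrow(opps)
                          else rep(0, length(counts)))
}
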