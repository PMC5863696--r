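# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive every quantity from first principles rather
# than calling the implementation paths they check.

# Enumerate ALL monotone chains (any length >= 2) among candidate anchor
# pairs of one chromosome pair, by naive recursive extension; then keep the
# set-maximal ones, apply the anchor-point minimum and an independently
# computed binomial-tail significance filter. Returns a list of chains,
# each a data.frame row subset of `v` in chain order.
oracleChains <- function(v, gap, anchorPoints, probCutoff, density,
                         nChromA, nChromB) {
    n <- nrow(v)
    if (n < 2L) return(list())
    ra <- v$ra; rb <- v$rb
    # a directed step i -> j is legal when both rank gaps fit and rb moves
    # in the chain's direction; legal[i, j] computed from the raw
    # definition for all vertex pairs at once
    da <- outer(ra, ra, function(x, y) y - x)
    db <- outer(rb, rb, function(x, y) y - x)
    aOk <- da > 0 & da - 1 <= gap
    chains <- list()
    for (inv in c(FALSE, TRUE)) {
        legal <- if (inv) aOk & db < 0 & -db - 1 <= gap
                 else aOk & db > 0 & db - 1 <= gap
        # start only from vertices no legal step can reach, end at dead
        # ends: every set-maximal chain is such an inextensible path (a
        # skipped middle vertex is handled by the containment filter below)
        canReach <- apply(legal, 2L, any)
        extend <- function(idx) {
            nxt <- which(legal[idx[length(idx)], ])
            if (!length(nxt)) {
                if (length(idx) >= 2L)
                    chains[[length(chains) + 1L]] <<- idx
                return()
            }
            for (j in nxt) extend(c(idx, j))
        }
        for (i in which(!canReach)) extend(i)
    }
    if (!length(chains)) return(list())
    sets <- lapply(chains, sort)
    keys <- vapply(sets, paste, "", collapse = ",")
    keep <- !duplicated(keys)
    chains <- chains[keep]; sets <- sets[keep]
    sizes <- lengths(sets)
    # subset test via pairwise intersection sizes on a membership matrix
    M <- matrix(0L, length(sets), n)
    for (i in seq_along(sets)) M[i, sets[[i]]] <- 1L
    inter <- tcrossprod(M)
    maximal <- vapply(seq_along(sets), function(i)
        !any(sizes > sizes[i] & inter[i, ] == sizes[i]), TRUE)
    chains <- chains[maximal]
    out <- list()
    for (idx in chains) {
        k <- length(idx)
        if (k < anchorPoints) next
        spanA <- max(v$ra[idx]) - min(v$ra[idx]) + 1
        spanB <- max(v$rb[idx]) - min(v$rb[idx]) + 1
        nwin <- max(1, nChromA - spanA + 1) * max(1, nChromB - spanB + 1)
        ncell <- spanA * spanB
        # tail probability by direct summation
        praw <- sum(vapply(k:ncell, function(x)
            stats::dbinom(x, ncell, density), 0))
        p <- min(1, nwin * praw)
        if (p > probCutoff) next
        out[[length(out) + 1L]] <- v[idx, , drop = FALSE]
    }
    out
}

# canonical signature of a chain / segment anchor table for set comparison
chainKey <- function(df) {
    o <- order(df$rank_a)
    paste(df$marker_a[o], df$marker_b[o], sep = "~", collapse = "|")
}

# random pairwise marker instance on a single chromosome per genome
randomInstance <- function(seed, nA = 40L, nB = 40L, nPairs = 26L) {
    set.seed(seed)
    mapA <- data.frame(marker = sprintf("a%02d", seq_len(nA)),
                       chrom = "c1",
                       start = seq_len(nA) * 1000,
                       end = seq_len(nA) * 1000 + 500,
                       rank = seq_len(nA))
    mapB <- data.frame(marker = sprintf("b%02d", seq_len(nB)),
                       chrom = "c1",
                       start = seq_len(nB) * 1000,
                       end = seq_len(nB) * 1000 + 500,
                       rank = seq_len(nB))
    cells <- expand.grid(a = mapA$marker, b = mapB$marker,
                         stringsAsFactors = FALSE)
    pairs <- cells[sample(nrow(cells), nPairs), , drop = FALSE]
    # plant one clean diagonal run so that long chains actually occur
    i0 <- sample(nA - 6L, 1L); j0 <- sample(nB - 6L, 1L)
    run <- data.frame(a = mapA$marker[i0 + 0:5], b = mapB$marker[j0 + 0:5])
    pairs <- unique(rbind(pairs, run))
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
    rownames(pairs) <- NULL
    list(mapA = mapA, mapB = mapB, pairs = pairs)
}

# run the oracle on a full instance and return the set of chain keys
oracleSegmentKeys <- function(inst, params) {
    v <- data.frame(
        a = inst$pairs$a, b = inst$pairs$b,
        ra = inst$mapA$rank[match(inst$pairs$a, inst$mapA$marker)],
        rb = inst$mapB$rank[match(inst$pairs$b, inst$mapB$marker)])
    density <- min(nrow(inst$pairs) / (nrow(inst$mapA) * nrow(inst$mapB)), 1)
    chains <- oracleChains(v, params$gap_size, params$anchor_points,
                           params$prob_cutoff, density,
                           nrow(inst$mapA), nrow(inst$mapB))
    vapply(chains, function(cf) {
        df <- data.frame(marker_a = cf$a, marker_b = cf$b, rank_a = cf$ra)
        chainKey(df)
    }, "")
}

# Wang S-values by exhaustive enumeration of all directed child->parent
# paths: S_t(u) = max over paths t -> u of the product of edge weights.
oracleWangSValues <- function(dag, term) {
    ed <- dag@edges
    w <- dag@weights
    s <- c()
    walk <- function(node, val) {
        if (is.null(s[node]) || is.na(s[node]) || val > s[node])
            s[node] <<- val
        up <- ed[ed$child == node, , drop = FALSE]
        for (i in seq_len(nrow(up)))
            walk(up$parent[i], val * unname(w[up$relation[i]]))
    }
    walk(term, 1)
    s
}

oracleWangSim <- function(dag, a, b) {
    sA <- oracleWangSValues(dag, a)
    sB <- oracleWangSValues(dag, b)
    shared <- intersect(names(sA), names(sB))
    sum(sA[shared] + sB[shared]) / (sum(sA) + sum(sB))
}

# random layered DAG within one namespace
randomDag <- function(seed, nTerms = 12L) {
    set.seed(seed)
    ids <- sprintf("T%03d", seq_len(nTerms))
    edges <- NULL
    for (i in seq(2L, nTerms)) {
        pars <- sample(seq_len(i - 1L), min(sample(1:2, 1L), i - 1L))
        edges <- rbind(edges, data.frame(
            child = ids[i], parent = ids[pars],
            relation = sample(c("is_a", "part_of"), length(pars),
                              replace = TRUE, prob = c(0.8, 0.2))))
    }
    ontologyDag(data.frame(id = ids, name = ids, namespace = "BP"), edges)
}

# per-base n-way classification oracle over a reference genome
oracleNwayPerBase <- function(segTable, order, genomeLen, chrom = "chr1") {
    sp <- synortho::speciesOrder(order)
    partners <- sp[-1L]
    covered <- matrix(FALSE, genomeLen, length(partners),
                      dimnames = list(NULL, partners))
    for (i in seq_len(nrow(segTable))) {
        s <- segTable[i, ]
        if (s$chrom_a != chrom) next
        covered[s$start_a:s$end_a, s$species_b] <- TRUE
    }
    lev <- integer(genomeLen)
    for (base in seq_len(genomeLen)) {
        n <- 0L
        for (k in seq_along(partners)) {
            if (covered[base, k]) n <- k + 1L else break
        }
        lev[base] <- if (n >= 3L) n else 0L
    }
    lev
}
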