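#' Collinearity detection parameters
#'
#' @param anchor_points minimum homologous marker pairs per segment (>= 2).
#' @param gap_size maximum number of intervening non-homologous markers
#'   allowed between consecutive anchor points, on both genomes.
#' @param prob_cutoff significance threshold on the segment p-value.
#' @return validated list of parameters.
#' @examples
#' detectionParams(anchor_points = 3, gap_size = 30, prob_cutoff = 0.01)
#' @export
detectionParams <- function(anchor_points = 3L, gap_size = 10L,
                            prob_cutoff = 0.01) {
    stopifnot(anchor_points >= 2L, gap_size >= 1L,
              prob_cutoff > 0, prob_cutoff <= 1)
    list(anchor_points = as.integer(anchor_points),
         gap_size = as.integer(gap_size), prob_cutoff = prob_cutoff)
}

#' Marker map from a GRanges
#'
#' @param gr GRanges of markers; `idCol` names the mcols column holding the
#'   marker identifier shared between genomes (gene id, or alignment block
#'   id for MAA markers).
#' @param idCol mcols column with the marker identifier.
#' @return data.frame with columns `marker`, `chrom`, `start`, `end`,
#'   `rank` (per-chromosome ordinal by start).
#' @export
markerMap <- function(gr, idCol = "marker") {
    df <- data.frame(marker = as.character(S4Vectors::mcols(gr)[[idCol]]),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr))
    df$rank <- assignRanks(gr)
    df[order(df$chrom, df$rank), , drop = FALSE]
}

#' MAA marker maps per genome
#'
#' Projects alignment blocks onto each requested species; the shared marker
#' identifier is the alignment block, so the two per-genome projections of
#' one block are homologous by construction.
#'
#' @param blocks alignment blocks ([readMaf()] layout).
#' @param species species to project onto.
#' @return named list of marker data.frames (see [markerMap()]).
#' @export
maaMarkerMaps <- function(blocks, species) {
    out <- list()
    for (sp in species) {
        rows <- blocks[blocks$species == sp, , drop = FALSE]
        gr <- GenomicRanges::GRanges(rows$chrom,
                                     IRanges::IRanges(rows$start, rows$end))
        S4Vectors::mcols(gr)$marker <- sprintf("blk%06d", rows$block)
        out[[sp]] <- markerMap(gr)
    }
    out
}

#' Candidate homologous marker pairs
#'
#' For gene markers, hits are filtered at the E-value threshold and
#' restricted to markers present in both maps; for MAA markers (no hits
#' supplied) the two per-genome projections of the same alignment block are
#' paired by identity.
#'
#' @param mapA,mapB marker maps ([markerMap()] data.frames).
#' @param hits optional homology hit data.frame (`query`, `subject`,
#'   `evalue`, `bitscore`).
#' @param evalueMax E-value threshold applied to `hits`.
#' @return data.frame with columns `a`, `b` (marker identifiers), unique
#'   unordered set keyed by the pair.
#' @export
buildHomologyPairs <- function(mapA, mapB, hits = NULL, evalueMax = 1e-5) {
    if (is.null(hits)) {
        shared <- intersect(mapA$marker, mapB$marker)
        out <- data.frame(a = shared, b = shared)
    } else {
        keep <- hits$evalue <= evalueMax
        h <- hits[keep, , drop = FALSE]
        fwd <- h[h$query %in% mapA$marker & h$subject %in% mapB$marker,
                 c("query", "subject")]
        rev <- h[h$query %in% mapB$marker & h$subject %in% mapA$marker,
                 c("subject", "query")]
        names(fwd) <- names(rev) <- c("a", "b")
        out <- unique(rbind(fwd, rev))
    }
    out <- out[order(out$a, out$b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Statistical significance of a collinear segment
#'
#' Probability of observing at least `k` co-oriented homologous pairs in a
#' `span_a` x `span_b` marker window under a binomial null with per-cell
#' probability `density`, Bonferroni-scaled by the number of windows tested
#' (`n_windows`). The p-value decreases monotonically in `k` and increases
#' in `density`.
#'
#' @param k number of anchor points in the chain (>= 2).
#' @param span_a,span_b marker-rank spans of the chain on the two genomes
#'   (each >= k).
#' @param density background probability that a random marker pair is
#'   homologous, in (0, 1].
#' @param n_windows number of windows of this size testable in the marker
#'   maps (Bonferroni factor).
#' @return p-value in (0, 1].
#' @export
segmentSignificance <- function(k, span_a, span_b, density, n_windows = 1) {
    stopifnot(k >= 2L, span_a >= k, span_b >= k, n_windows >= 1)
    if (density <= 0 || density > 1)
        stop("density must lie in (0, 1]")
    praw <- stats::pbinom(k - 1, span_a * span_b, density,
                          lower.tail = FALSE)
    min(1, n_windows * praw)
}

## Enumerate all set-maximal monotone chains among candidate vertices of one
## chromosome pair. Vertices: data.frame ra, rb (ranks). Returns list of
## integer vectors (row indices into the vertex table, in chain order).
.maximalChains <- function(ra, rb, gap) {
    n <- length(ra)
    if (n < 2L) return(list())
    ord <- order(ra, rb)
    ra <- ra[ord]; rb <- rb[ord]
    succs <- function(i, inverted) {
        da <- ra - ra[i]
        if (inverted) {
            ok <- da > 0 & da - 1 <= gap & rb < rb[i] & (rb[i] - rb - 1) <= gap
        } else {
            ok <- da > 0 & da - 1 <= gap & rb > rb[i] & (rb - rb[i] - 1) <= gap
        }
        which(ok)
    }
    paths <- list()
    for (inverted in c(FALSE, TRUE)) {
        succList <- lapply(seq_len(n), succs, inverted = inverted)
        hasPred <- logical(n)
        for (i in seq_len(n)) hasPred[succList[[i]]] <- TRUE
        walk <- function(path) {
            nxt <- succList[[path[length(path)]]]
            if (!length(nxt)) {
                if (length(path) >= 2L)
                    paths[[length(paths) + 1L]] <<- path
                return()
            }
            for (j in nxt) walk(c(path, j))
        }
        for (i in which(!hasPred)) walk(i)
    }
    if (!length(paths)) return(list())
    ## set-maximality filter: drop chains whose vertex set is a strict
    ## subset of another chain's set
    sets <- lapply(paths, sort)
    keys <- vapply(sets, paste, "", collapse = ",")
    uni <- !duplicated(keys)
    paths <- paths[uni]; sets <- sets[uni]
    sizes <- lengths(sets)
    o <- order(-sizes)
    paths <- paths[o]; sets <- sets[o]; sizes <- sizes[o]
    keep <- rep(TRUE, length(paths))
    for (i in seq_along(paths)) {
        if (!keep[i]) next
        for (j in seq_len(i - 1L)) {
            if (keep[j] && sizes[i] < sizes[j] &&
                all(sets[[i]] %in% sets[[j]])) {
                keep[i] <- FALSE
                break
            }
        }
    }
    lapply(paths[keep], function(p) ord[p])
}

#' Detect pairwise collinear segments by anchor chaining
#'
#' Finds all set-maximal chains of candidate homologous marker pairs with
#' strictly monotone ranks on both genomes (descending on genome B for
#' inverted segments) and at most `gap_size` intervening non-homologous
#' markers between consecutive anchors on either side. Maximal chains with
#' at least `anchor_points` anchors are then kept if their binomial-tail
#' significance ([segmentSignificance()], Bonferroni-scaled over the
#' windows of the hosting chromosome pair) passes `prob_cutoff`. Output
#' order is deterministic (by genome A position, then genome B).
#'
#' @param mapA,mapB marker maps ([markerMap()]) of the two genomes.
#' @param pairs candidate pair data.frame from [buildHomologyPairs()].
#' @param params detection parameters ([detectionParams()]).
#' @param speciesA,speciesB labels stored in the segment table.
#' @return A [CollinearSegments-class].
#' @export
detectSegments <- function(mapA, mapB, pairs,
                           params = detectionParams(),
                           speciesA = "A", speciesB = "B") {
    empty <- new("CollinearSegments",
                 table = data.frame(segment_id = character(0),
                                    species_a = character(0),
                                    species_b = character(0),
                                    chrom_a = character(0),
                                    start_a = numeric(0), end_a = numeric(0),
                                    chrom_b = character(0),
                                    start_b = numeric(0), end_b = numeric(0),
                                    n_anchors = integer(0),
                                    orientation = character(0),
                                    p_value = numeric(0)),
                 anchors = list(), params = params)
    if (!nrow(pairs)) return(empty)
    ia <- match(pairs$a, mapA$marker)
    ib <- match(pairs$b, mapB$marker)
    ok <- !is.na(ia) & !is.na(ib)
    if (!any(ok)) return(empty)
    v <- data.frame(a = pairs$a[ok], b = pairs$b[ok],
                    chrom_a = mapA$chrom[ia[ok]], ra = mapA$rank[ia[ok]],
                    sa = mapA$start[ia[ok]], ea = mapA$end[ia[ok]],
                    chrom_b = mapB$chrom[ib[ok]], rb = mapB$rank[ib[ok]],
                    sb = mapB$start[ib[ok]], eb = mapB$end[ib[ok]])
    density <- min(nrow(pairs) / (nrow(mapA) * nrow(mapB)), 1)
    nA <- table(mapA$chrom)
    nB <- table(mapB$chrom)
    rows <- list(); anch <- list()
    for (key in unique(paste(v$chrom_a, v$chrom_b, sep = "\r"))) {
        ca <- sub("\r.*", "", key); cb <- sub(".*\r", "", key)
        vi <- v[v$chrom_a == ca & v$chrom_b == cb, , drop = FALSE]
        chains <- .maximalChains(vi$ra, vi$rb, params$gap_size)
        for (chain in chains) {
            k <- length(chain)
            if (k < params$anchor_points) next
            cv <- vi[chain, , drop = FALSE]
            span_a <- max(cv$ra) - min(cv$ra) + 1L
            span_b <- max(cv$rb) - min(cv$rb) + 1L
            nwin <- max(1, nA[[ca]] - span_a + 1) *
                max(1, nB[[cb]] - span_b + 1)
            p <- segmentSignificance(k, span_a, span_b, density, nwin)
            if (p > params$prob_cutoff) next
            rows[[length(rows) + 1L]] <- data.frame(
                species_a = speciesA, species_b = speciesB,
                chrom_a = ca, start_a = min(cv$sa), end_a = max(cv$ea),
                chrom_b = cb, start_b = min(cv$sb), end_b = max(cv$eb),
                n_anchors = k,
                orientation = if (cv$rb[2L] > cv$rb[1L]) "same"
                              else "inverted",
                p_value = p)
            anch[[length(anch) + 1L]] <- data.frame(
                marker_a = cv$a, marker_b = cv$b,
                rank_a = cv$ra, rank_b = cv$rb)
        }
    }
    if (!length(rows)) return(empty)
    tb <- do.call(rbind, rows)
    o <- order(tb$chrom_a, tb$start_a, tb$chrom_b, tb$start_b,
               tb$orientation)
    tb <- tb[o, , drop = FALSE]
    anch <- anch[o]
    tb <- cbind(segment_id = sprintf("seg%05d", seq_len(nrow(tb))), tb)
    rownames(tb) <- NULL
    new("CollinearSegments", table = tb, anchors = anch, params = params)
}

#' Combine segment sets from several species pairs
#'
#' @param ... [CollinearSegments-class] objects sharing the reference on
#'   side A.
#' @return one [CollinearSegments-class] with re-numbered segment ids.
#' @export
combineSegments <- function(...) {
    xs <- list(...)
    xs <- xs[vapply(xs, length, 0L) > 0L]
    if (!length(xs))
        return(detectSegments(data.frame(marker = character(0),
                                         chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         rank = integer(0)),
                              data.frame(marker = character(0),
                                         chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         rank = integer(0)),
                              data.frame(a = character(0), b = character(0))))
    tb <- do.call(rbind, lapply(xs, segTable))
    anch <- do.call(c, lapply(xs, segAnchors))
    tb$segment_id <- sprintf("seg%05d", seq_len(nrow(tb)))
    rownames(tb) <- NULL
    new("CollinearSegments", table = tb, anchors = anch,
        params = xs[[1L]]@params)
}

#' Classify segments into n-way and pairwise (2way-d) levels
#'
#' Every segment against partner species `s` contributes a `2way-d` record
#' with `d = dIndex(order)[s]`. n-way regions (n >= 3) are the maximal
#' reference regions simultaneously covered by segments with each of the
#' first n-1 non-reference partners in the phylogenetic order (species
#' incorporated sequentially with the reference as origin); a region is
#' reported only at the maximal n it satisfies.
#'
#' @param segments a [CollinearSegments-class] whose side A is the
#'   reference species throughout.
#' @param order a [PhyloOrder-class].
#' @return list with `n_way` (GRanges on the reference with mcols `n`) and
#'   `pairwise` (data.frame `segment_id`, `species_b`, `d`).
#' @export
classifyLevels <- function(segments, order) {
    tb <- segTable(segments)
    sp <- speciesOrder(order)
    if (nrow(tb)) {
        if (!all(tb$species_a == refSpecies(order)))
            stop("side A of every segment must be the reference species")
        bad <- setdiff(unique(tb$species_b), sp)
        if (length(bad))
            stop("species absent from the phylogenetic order: ",
                 paste(bad, collapse = ", "))
    }
    d <- dIndex(order)
    pairwise <- data.frame(segment_id = tb$segment_id,
                           species_b = tb$species_b,
                           d = unname(d[tb$species_b]))
    ## per-partner coverage of the reference
    cover <- lapply(sp[-1L], function(s) {
        rows <- tb[tb$species_b == s, , drop = FALSE]
        if (!nrow(rows)) return(GenomicRanges::GRanges())
        GenomicRanges::reduce(GenomicRanges::GRanges(
            rows$chrom_a, IRanges::IRanges(rows$start_a, rows$end_a)))
    })
    S <- length(sp)
    nway <- GenomicRanges::GRanges()
    if (S >= 3L) {
        ## I[[n]] = region covered by all of the first n-1 partners
        I <- vector("list", S + 1L)
        I[[3L]] <- if (length(cover) >= 2L)
            GenomicRanges::intersect(cover[[1L]], cover[[2L]])
            else GenomicRanges::GRanges()
        if (S > 3L) for (n in 4L:S)
            I[[n]] <- GenomicRanges::intersect(I[[n - 1L]], cover[[n - 1L]])
        I[[S + 1L]] <- GenomicRanges::GRanges()
        parts <- list()
        for (n in 3L:S) {
            reg <- GenomicRanges::setdiff(I[[n]], I[[n + 1L]])
            if (length(reg)) {
                S4Vectors::mcols(reg)$n <- n
                parts[[length(parts) + 1L]] <- reg
            }
        }
        if (length(parts))
            nway <- GenomicRanges::sort(do.call(c, parts),
                                        ignore.strand = TRUE)
    }
    list(n_way = nway, pairwise = pairwise)
}

#' Summarise classified segment levels
#'
#' One row per level value present: n-way rows measure the maximal-level
#' reference regions, 2way-d rows the reference extents of the pairwise
#' segments.
#'
#' @param classification result of [classifyLevels()].
#' @param segments the classified [CollinearSegments-class] (needed for the
#'   pairwise lengths).
#' @return data.frame with columns `level`, `count`, `total_length`,
#'   `mean_length`.
#' @export
segmentSummary <- function(classification, segments = NULL) {
    out <- list()
    nw <- classification$n_way
    if (length(nw)) {
        for (n in sort(unique(S4Vectors::mcols(nw)$n))) {
            reg <- nw[S4Vectors::mcols(nw)$n == n]
            w <- GenomicRanges::width(reg)
            out[[length(out) + 1L]] <- data.frame(
                level = sprintf("%d-way", n), count = length(reg),
                total_length = sum(w), mean_length = mean(w))
        }
    }
    pw <- classification$pairwise
    if (!is.null(segments) && nrow(pw)) {
        tb <- segTable(segments)
        len <- tb$end_a - tb$start_a + 1
        names(len) <- tb$segment_id
        for (dd in sort(unique(pw$d))) {
            ids <- pw$segment_id[pw$d == dd]
            w <- len[ids]
            out[[length(out) + 1L]] <- data.frame(
                level = sprintf("2way-%d", dd), count = length(ids),
                total_length = sum(w), mean_length = mean(w))
        }
    }
    if (!length(out))
        return(data.frame(level = character(0), count = integer(0),
                          total_length = numeric(0), mean_length = numeric(0)))
    ans <- do.call(rbind, out)
    rownames(ans) <- NULL
    ans
}
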