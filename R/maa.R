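#' Extract multiple-alignment anchors (MAAs)
#'
#' An MAA is an alignment block conserved across the required species set,
#' projected onto the reference genome. Each qualifying block yields exactly
#' one anchor (overlapping reference projections are deliberately not
#' merged); anchors are returned sorted by reference position.
#'
#' @param blocks alignment blocks in the long data.frame layout of
#'   [readMaf()].
#' @param requiredSpecies character vector of species that must all be
#'   present in a block; must contain `referenceSpecies`.
#' @param referenceSpecies the reference genome identifier.
#' @return GRanges of anchors on the reference, with mcols `anchor_id`,
#'   `n_species` and `kind = "MAA"`.
#' @export
extractMaas <- function(blocks, requiredSpecies, referenceSpecies) {
    if (!referenceSpecies %in% requiredSpecies)
        stop("requiredSpecies must contain the reference species '",
             referenceSpecies, "'")
    if (!nrow(blocks))
        return(GenomicRanges::GRanges())
    spPerBlock <- split(blocks$species, blocks$block)
    keep <- names(spPerBlock)[vapply(spPerBlock, function(s)
        all(requiredSpecies %in% s), TRUE)]
    ref <- blocks[blocks$block %in% as.integer(keep) &
                  blocks$species == referenceSpecies, , drop = FALSE]
    if (!nrow(ref)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(ref$chrom,
                                 IRanges::IRanges(ref$start, ref$end),
                                 strand = ref$strand)
    S4Vectors::mcols(gr)$block <- ref$block
    S4Vectors::mcols(gr)$n_species <- vapply(
        as.character(ref$block),
        function(b) length(unique(spPerBlock[[b]])), 0L)
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))]
    S4Vectors::mcols(gr)$anchor_id <- sprintf("maa%06d", seq_along(gr))
    S4Vectors::mcols(gr)$kind <- "MAA"
    gr
}

#' Summary statistics for a marker set
#'
#' Lengths are in bp; genome coverage is computed on the union of the
#' marker intervals, so bases under overlapping markers count once.
#'
#' @param anchors non-empty GRanges of markers.
#' @param referenceGenomeLength total reference genome length in bp.
#' @return list with `count`, `mean_length`, `median_length`, `min_length`,
#'   `max_length` and `genome_coverage` (fraction).
#' @export
markerStats <- function(anchors, referenceGenomeLength) {
    if (!length(anchors)) stop("no markers: statistics undefined")
    w <- GenomicRanges::width(anchors)
    if (referenceGenomeLength < max(GenomicRanges::end(anchors)))
        stop("genome length smaller than the last marker end")
    covered <- sum(GenomicRanges::width(GenomicRanges::reduce(anchors)))
    list(count = length(anchors), mean_length = mean(w),
         median_length = stats::median(w), min_length = min(w),
         max_length = max(w),
         genome_coverage = covered / referenceGenomeLength)
}

.gcFraction <- function(seqs) {
    f <- Biostrings::letterFrequency(seqs, c("G", "C"))
    rowSums(f) / Biostrings::width(seqs)
}

#' GC enrichment of anchors over the genomic background
#'
#' Per-anchor GC fractions are compared against an equal-count sample of
#' random length-matched windows drawn uniformly from the same genome, by a
#' two-sided Mann-Whitney rank-sum test. Length matching removes the
#' length-GC confound; the rank-sum test is distribution free.
#'
#' @param anchors GRanges of anchors.
#' @param genomeSequences a [Biostrings::DNAStringSet] named by chromosome
#'   and covering all anchor intervals.
#' @param seed optional integer seed for the background sampling.
#' @return list with `gc_anchor` and `gc_background` (mean fractions),
#'   `p_value`, and the per-anchor / per-window fraction vectors.
#' @export
gcEnrichment <- function(anchors, genomeSequences, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    chrom <- as.character(GenomicRanges::seqnames(anchors))
    if (!all(chrom %in% names(genomeSequences)))
        stop("anchor chromosome missing from genomeSequences")
    lens <- setNames(Biostrings::width(genomeSequences),
                     names(genomeSequences))
    if (any(GenomicRanges::end(anchors) > lens[chrom]))
        stop("anchor outside sequence bounds")
    anchorSeq <- Biostrings::DNAStringSet(mapply(
        function(ch, s, e) Biostrings::subseq(genomeSequences[[ch]], s, e),
        chrom, GenomicRanges::start(anchors), GenomicRanges::end(anchors)))
    gcA <- .gcFraction(anchorSeq)
    ## length-matched random windows, one per anchor, chromosome chosen
    ## proportionally to the number of valid start positions
    w <- GenomicRanges::width(anchors)
    gcB <- vapply(w, function(wi) {
        avail <- pmax(lens - wi + 1, 0)
        if (all(avail == 0)) stop("window longer than every chromosome")
        ch <- sample(names(lens), 1L, prob = avail)
        s <- sample.int(avail[ch], 1L)
        .gcFraction(Biostrings::DNAStringSet(
            Biostrings::subseq(genomeSequences[[ch]], s, s + wi - 1)))
    }, 0)
    p <- if (length(gcA) >= 2L)
        suppressWarnings(stats::wilcox.test(gcA, gcB)$p.value) else NA_real_
    list(gc_anchor = mean(gcA), gc_background = mean(gcB), p_value = p,
         anchor_gc = gcA, background_gc = gcB)
}

#' Uniformity of marker placement along chromosomes
#'
#' One-sample Kolmogorov-Smirnov test of the marker midpoints against the
#' uniform distribution on (0, chromosome length), per chromosome.
#' Chromosomes carrying fewer than `minMarkers` markers are skipped with a
#' warning.
#'
#' @param markers GRanges of markers.
#' @param chromosomeLengths named numeric vector of chromosome lengths.
#' @param minMarkers minimum markers required to test a chromosome.
#' @return data.frame with columns `chrom`, `n`, `D` (KS statistic), `p`.
#' @export
uniformityTest <- function(markers, chromosomeLengths, minMarkers = 8L) {
    chrom <- as.character(GenomicRanges::seqnames(markers))
    mid <- (GenomicRanges::start(markers) + GenomicRanges::end(markers)) / 2
    out <- list()
    for (ch in names(chromosomeLengths)) {
        x <- mid[chrom == ch]
        if (length(x) < minMarkers) {
            warning("chromosome ", ch, " skipped: only ", length(x),
                    " markers")
            next
        }
        kt <- suppressWarnings(
            stats::ks.test(x / chromosomeLengths[[ch]], "punif"))
        out[[ch]] <- data.frame(chrom = ch, n = length(x),
                                D = unname(kt$statistic), p = kt$p.value)
    }
    if (!length(out))
        return(data.frame(chrom = character(0), n = integer(0),
                          D = numeric(0), p = numeric(0)))
    ans <- do.call(rbind, out)
    rownames(ans) <- NULL
    ans
}

#' Build disjoint genome feature classes
#'
#' Produces the per-base feature partition used by [featureComposition()]:
#' CDS > UTR > ncRNA > intron > intergenic, applied in precedence order so
#' overlapping annotations classify deterministically. Intergenic stretches
#' longer than `desertMin` bp are relabelled `gene_desert`.
#'
#' @param genes GRanges of gene bodies.
#' @param cds,utr,ncrna GRanges of the respective features (may be empty).
#' @param chromosomeLengths named numeric vector.
#' @param desertMin minimum intergenic run length (bp) to count as gene
#'   desert.
#' @return GRanges covering the genome with mcols `class`.
#' @export
buildFeatureClasses <- function(genes, cds = GenomicRanges::GRanges(),
                                utr = GenomicRanges::GRanges(),
                                ncrna = GenomicRanges::GRanges(),
                                chromosomeLengths, desertMin = 30000) {
    genome <- GenomicRanges::GRanges(
        names(chromosomeLengths),
        IRanges::IRanges(1L, unname(chromosomeLengths)))
    taken <- GenomicRanges::GRanges()
    out <- list()
    grab <- function(region, cls) {
        region <- GenomicRanges::reduce(
            GenomicRanges::granges(region), ignore.strand = TRUE)
        region <- GenomicRanges::setdiff(region, taken, ignore.strand = TRUE)
        if (length(region)) {
            S4Vectors::mcols(region)$class <- cls
            out[[length(out) + 1L]] <<- region
            taken <<- GenomicRanges::reduce(
                GenomicRanges::union(taken, region, ignore.strand = TRUE))
        }
    }
    grab(cds, "CDS")
    grab(utr, "UTR")
    grab(ncrna, "ncRNA")
    intron <- GenomicRanges::setdiff(
        GenomicRanges::granges(genes), taken, ignore.strand = TRUE)
    if (length(intron)) {
        S4Vectors::mcols(intron)$class <- "intron"
        out[[length(out) + 1L]] <- intron
        taken <- GenomicRanges::reduce(GenomicRanges::union(taken, intron))
    }
    inter <- GenomicRanges::setdiff(genome, taken, ignore.strand = TRUE)
    if (length(inter)) {
        cls <- ifelse(GenomicRanges::width(inter) > desertMin,
                      "gene_desert", "intergenic")
        S4Vectors::mcols(inter)$class <- cls
        out[[length(out) + 1L]] <- inter
    }
    ans <- do.call(c, out)
    GenomicRanges::sort(ans, ignore.strand = TRUE)
}

#' Feature composition of anchor bases
#'
#' Fraction of anchor bases falling in each feature class. Anchor bases are
#' counted once (union semantics); when the classes partition the genome
#' the fractions sum to one.
#'
#' @param anchors GRanges of anchors.
#' @param featureClasses GRanges with mcols `class`, e.g. from
#'   [buildFeatureClasses()].
#' @return named numeric vector of fractions, one per feature class present
#'   in `featureClasses`.
#' @export
featureComposition <- function(anchors, featureClasses) {
    cov <- GenomicRanges::reduce(GenomicRanges::granges(anchors),
                                 ignore.strand = TRUE)
    total <- sum(GenomicRanges::width(cov))
    classes <- unique(S4Vectors::mcols(featureClasses)$class)
    out <- setNames(numeric(length(classes)), classes)
    if (total == 0) return(out)
    for (cls in classes) {
        region <- GenomicRanges::reduce(
            featureClasses[S4Vectors::mcols(featureClasses)$class == cls],
            ignore.strand = TRUE)
        out[cls] <- sum(GenomicRanges::width(
            GenomicRanges::intersect(cov, region, ignore.strand = TRUE))) /
            total
    }
    out
}
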