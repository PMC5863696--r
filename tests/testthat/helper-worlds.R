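# Shared fixtures: configured synthetic worlds and in-memory detection
# shortcuts used across test files.

noiseFreeConfig <- function(seed, decoy_rate = 0, ...) {
    worldConfig(seed = seed, noise_marker_rate = 0, rearrangement_rate = 0,
                ortholog_dropout_rate = 0, decoy_rate = decoy_rate, ...)
}

# per-species gene marker maps of a world
worldGeneMaps <- function(world) {
    gm <- S4Vectors::mcols(world@genes)
    sp <- speciesOrder(world@order)
    maps <- lapply(sp, function(s)
        markerMap(world@genes[gm$species == s], idCol = "gene_id"))
    names(maps) <- sp
    maps
}

# combined reference-vs-partner segments for one marker type
worldSegments <- function(world, markers = c("gene", "maa"),
                          params = NULL) {
    markers <- match.arg(markers)
    sp <- speciesOrder(world@order); ref <- refSpecies(world@order)
    if (markers == "maa") {
        maps <- maaMarkerMaps(world@alignBlocks, sp)
        if (is.null(params)) params <- detectionParams(3L, 30L, 0.01)
        per <- lapply(sp[-1L], function(s) detectSegments(
            maps[[ref]], maps[[s]],
            buildHomologyPairs(maps[[ref]], maps[[s]]),
            params, speciesA = ref, speciesB = s))
    } else {
        maps <- worldGeneMaps(world)
        if (is.null(params)) params <- detectionParams(3L, 10L, 0.01)
        per <- lapply(sp[-1L], function(s) detectSegments(
            maps[[ref]], maps[[s]],
            buildHomologyPairs(maps[[ref]], maps[[s]], world@hits),
            params, speciesA = ref, speciesB = s))
    }
    do.call(combineSegments, per)
}

# full in-memory ortholog inference for a world
worldOpps <- function(world, ...) {
    inferOpps(world@genes, worldSegments(world, "maa"),
              worldSegments(world, "gene"), world@hits, world@order, ...)
}

pairKey <- function(df, a = "gene_a", b = "gene_b") paste(df[[a]], df[[b]])

# wrap a bare segment table into a CollinearSegments object (anchors are
# placeholders; used where only regions matter)
fakeSegments <- function(tb) {
    anch <- lapply(seq_len(nrow(tb)), function(i)
        data.frame(marker_a = letters[1:3], marker_b = letters[1:3],
                   rank_a = 1:3, rank_b = 1:3))
    tb$segment_id <- sprintf("seg%05d", seq_len(nrow(tb)))
    tb$n_anchors <- 3L
    tb$orientation <- "same"
    tb$p_value <- 1e-4
    cols <- c("segment_id", "species_a", "species_b", "chrom_a", "start_a",
              "end_a", "chrom_b", "start_b", "end_b", "n_anchors",
              "orientation", "p_value")
    new("CollinearSegments", table = tb[, cols], anchors = anch,
        params = detectionParams())
}

# random pairwise-segment table on a 2 kb reference chromosome
randomSegmentTable <- function(seed, genomeLen = 2000L) {
    set.seed(seed)
    S <- sample(3:6, 1L)
    ord <- phyloOrder(sprintf("sp%d", seq_len(S)))
    rows <- list()
    for (s in sprintf("sp%d", 2:S)) {
        for (k in seq_len(sample(0:3, 1L))) {
            st <- sample(genomeLen - 100L, 1L)
            en <- min(genomeLen, st + sample(50:600, 1L))
            rows[[length(rows) + 1L]] <- data.frame(
                species_a = "sp1", species_b = s, chrom_a = "chr1",
                start_a = st, end_a = en, chrom_b = "chr1",
                start_b = st, end_b = en)
        }
    }
    list(order = ord,
         table = if (length(rows)) do.call(rbind, rows) else NULL,
         genomeLen = genomeLen)
}

# minimal two-species scenario in which exactly one gene pair is supported
# solely by a pairwise MAA-based collinear segment (competing hit defeats
# the BBH status, no gene-based segments exist)
pairwiseOnlyScenario <- function() {
    genes <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1", "chr9"),
        IRanges::IRanges(c(2000, 8000, 2100, 100),
                         c(2999, 8999, 3099, 1099)))
    S4Vectors::mcols(genes)$gene_id <- c("ra_1", "ra_2", "pb_1", "pb_2")
    S4Vectors::mcols(genes)$species <- c("refsp", "refsp", "partner",
                                         "partner")
    S4Vectors::mcols(genes)$rank <- c(1L, 2L, 1L, 1L)
    # three shared MAA anchors bracketing the gene pair on both genomes,
    # plus unrelated species-private anchors elsewhere (the background that
    # makes a 3-anchor chain non-trivial)
    mkMap <- function(starts, private) rbind(
        data.frame(marker = c("m1", "m2", "m3"), chrom = "chr1",
                   start = starts, end = starts + 119, rank = 1:3),
        data.frame(marker = sprintf("%s%02d", private, 1:7), chrom = "chr2",
                   start = 1000 * (1:7), end = 1000 * (1:7) + 119,
                   rank = 1:7))
    mapA <- mkMap(c(1000, 4000, 7000), "ua")
    mapB <- mkMap(c(1100, 4100, 7100), "ub")
    segs <- detectSegments(mapA, mapB,
                           buildHomologyPairs(mapA, mapB),
                           detectionParams(3L, 30L, 0.01),
                           speciesA = "refsp", speciesB = "partner")
    # ra_1 ~ pb_1 passes (i) and (ii); the stronger ra_2 hit steals pb_1's
    # best-hit slot so the pair is not a BBH
    hits <- data.frame(
        query = c("ra_1", "pb_1", "ra_2", "pb_1"),
        subject = c("pb_1", "ra_1", "pb_1", "ra_2"),
        evalue = c(1e-30, 1e-30, 1e-60, 1e-60),
        bitscore = c(150, 150, 400, 400))
    list(genes = genes, segments = segs, hits = hits,
         order = phyloOrder(c("refsp", "partner")))
}
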