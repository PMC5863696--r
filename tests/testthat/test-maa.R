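makeBlocks <- function(speciesPerBlock, ref = "sp1") {
    do.call(rbind, lapply(seq_along(speciesPerBlock), function(b) {
        sp <- speciesPerBlock[[b]]
        data.frame(block = b, species = sp, chrom = "chr1",
                   start = 1000 * b, end = 1000 * b + 99, strand = "+",
                   src_size = 1e5, text = NA_character_)
    }))
}

test_that("anchors are exactly the blocks conserved in the required set", {
    allSp <- sprintf("sp%d", 1:15)
    blocks <- makeBlocks(list(allSp, allSp, allSp[1:14]))
    a <- extractMaas(blocks, allSp, "sp1")
    expect_length(a, 2L)
    expect_equal(unique(a$n_species), 15L)
    ## vacuous filter: reference only
    expect_length(extractMaas(blocks, "sp1", "sp1"), 3L)
    expect_error(extractMaas(blocks, c("sp2", "sp3"), "sp1"), "reference")
})

test_that("extraction equals the brute-force filter and is monotone", {
    for (seed in 1:10) {
        w <- generateWorld(worldConfig(seed = seed, n_species = 4L,
                                       genes_per_genome = 120L,
                                       n_planted_blocks = 4L))
        sp <- speciesOrder(w@order)
        for (req in list(sp, sp[1:3], sp[1:2])) {
            a <- extractMaas(w@alignBlocks, req, sp[1L])
            bySp <- split(w@alignBlocks$species, w@alignBlocks$block)
            want <- names(bySp)[vapply(bySp, function(x) all(req %in% x),
                                       TRUE)]
            expect_setequal(as.character(a$block), want)
        }
        nAll <- length(extractMaas(w@alignBlocks, sp, sp[1L]))
        nTwo <- length(extractMaas(w@alignBlocks, sp[1:2], sp[1L]))
        expect_lte(nAll, nTwo)
    }
})

test_that("marker statistics use union coverage", {
    a <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 201), c(100, 250)))
    s <- markerStats(a, 1000)
    expect_equal(s$mean_length, 75)
    expect_equal(s$median_length, 75)
    expect_equal(s$genome_coverage, 0.15)
    ## identical intervals count once
    dup <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 1), c(100, 100)))
    expect_equal(markerStats(dup, 1000)$genome_coverage, 0.1)
    expect_error(markerStats(GenomicRanges::GRanges(), 1000), "no markers")
})

test_that("coverage matches per-base counting on small random sets", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(1:12, 1L)
        st <- sample(900, n, replace = TRUE)
        en <- pmin(1000, st + sample(5:80, n, replace = TRUE))
        a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, en))
        hit <- logical(1000)
        for (i in seq_len(n)) hit[st[i]:en[i]] <- TRUE
        expect_equal(markerStats(a, 1000)$genome_coverage,
                     sum(hit) / 1000)
    }
})

test_that("GC enrichment separates extreme compositions and is null-safe", {
    gc <- strrep("GC", 500)
    at <- strrep("AT", 5000)
    seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(gc, at)))
    a <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(seq(1, 901, 100),
                                                 seq(100, 1000, 100)))
    ## background windows land in the AT bulk with overwhelming probability
    r <- gcEnrichment(a, seqs, seed = 1)
    expect_equal(r$gc_anchor, 1)
    expect_lt(r$gc_background, 0.25)
    expect_lt(r$p_value, 1e-3)
    expect_error(
        gcEnrichment(GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(1, 99999)),
                     seqs), "bounds")
})

test_that("a planted +15pp GC shift in anchors is detected", {
    det <- 0L
    nRuns <- 25L
    for (s in seq_len(nRuns)) {
        set.seed(s)
        seqv <- sample(c("A", "C", "G", "T"), 60000, replace = TRUE,
                       prob = c(0.325, 0.175, 0.175, 0.325))
        starts <- sample(59000, 200)
        for (i in seq_along(starts))
            seqv[starts[i]:(starts[i] + 149)] <-
                sample(c("A", "C", "G", "T"), 150, replace = TRUE)
        seqs <- Biostrings::DNAStringSet(
            c(chr1 = paste(seqv, collapse = "")))
        anch <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(starts, starts + 149))
        if (gcEnrichment(anch, seqs, seed = 500 + s)$p_value < 0.001)
            det <- det + 1L
    }
    expect_gte(det / nRuns, 0.95)
})

test_that("uniformity test flags clustering and matches the ECDF oracle", {
    grid <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(seq(5, 995, 10) - 1, seq(5, 995, 10) + 1))
    r <- uniformityTest(grid, c(chr1 = 1000))
    expect_lte(r$D, 0.01)
    clustered <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(seq(1, 91, 10), seq(3, 93, 10)))
    r2 <- uniformityTest(clustered, c(chr1 = 1000))
    expect_gte(r2$D, 0.9)
    ## brute-force sup |ECDF - U| on seeded marker sets
    for (seed in 1:50) {
        set.seed(seed)
        n <- sample(8:40, 1L)
        mid <- sort(sample(10:990, n))
        gr <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(mid - 1, mid + 1))
        u <- sort(mid / 1000)
        dPlus <- max(seq_len(n) / n - u)
        dMinus <- max(u - (seq_len(n) - 1) / n)
        expect_equal(uniformityTest(gr, c(chr1 = 1000))$D,
                     max(dPlus, dMinus), tolerance = 1e-12)
    }
    expect_warning(
        uniformityTest(GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(1:3, 2:4)), c(chr1 = 1000)),
        "skipped")
})

test_that("feature composition counts anchor bases with precedence", {
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
    cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
    classes <- buildFeatureClasses(genes, cds = cds,
                                   chromosomeLengths = c(chr1 = 1000))
    ## anchor fully inside the CDS
    expect_equal(
        featureComposition(GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(120, 180)), classes)[["CDS"]], 1)
    ## anchor half in CDS (151..200), half in intron (201..250)
    comp <- featureComposition(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(151, 250)), classes)
    expect_equal(comp[["CDS"]], 0.5)
    expect_equal(comp[["intron"]], 0.5)
    expect_equal(sum(comp), 1)
})

test_that("feature fractions match per-base classification on fixtures", {
    for (seed in 1:10) {
        set.seed(seed)
        L <- 2000L
        gs <- sort(sample(seq(1, L - 200, 50), 3))
        genes <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(gs, gs + 180))
        cds <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(gs + 20, gs + 100))
        classes <- buildFeatureClasses(genes, cds = cds,
                                       chromosomeLengths = c(chr1 = L),
                                       desertMin = 400)
        st <- sample(L - 60, 6)
        anch <- GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(st, st + 50))
        comp <- featureComposition(anch, classes)
        ## per-base oracle
        lab <- rep("intergenic", L)
        inter <- rep(TRUE, L)
        for (i in 1:3) {
            lab[gs[i]:(gs[i] + 180)] <- "intron"
            inter[gs[i]:(gs[i] + 180)] <- FALSE
        }
        for (i in 1:3) lab[(gs[i] + 20):(gs[i] + 100)] <- "CDS"
        runs <- rle(inter)
        pos <- cumsum(c(1, runs$lengths))
        for (k in seq_along(runs$values))
            if (runs$values[k] && runs$lengths[k] > 400)
                lab[pos[k]:(pos[k + 1] - 1)] <- "gene_desert"
        covered <- logical(L)
        for (i in seq_along(st)) covered[st[i]:(st[i] + 50)] <- TRUE
        want <- table(factor(lab[covered],
                             levels = names(comp))) / sum(covered)
        expect_equal(unname(comp), as.numeric(want), tolerance = 1e-12)
        expect_equal(sum(comp), 1)
    }
})
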