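simpleMap <- function(n, prefix, chrom = "c1") data.frame(
    marker = sprintf("%s%02d", prefix, seq_len(n)), chrom = chrom,
    start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
    rank = seq_len(n))

test_that("candidate pairs respect the E-value threshold and marker maps", {
    mapA <- simpleMap(5, "a"); mapB <- simpleMap(5, "b")
    hits <- data.frame(query = c("a01", "a02", "a03", "zz"),
                       subject = c("b01", "b02", "b03", "b04"),
                       evalue = c(1e-10, 1e-4, 1e-6, 1e-30),
                       bitscore = c(100, 100, 100, 100))
    p <- buildHomologyPairs(mapA, mapB, hits)
    ## E = 1e-4 fails the 1e-5 threshold; unknown marker dropped
    expect_equal(p, data.frame(a = c("a01", "a03"), b = c("b01", "b03")))
    ## MAA identity pairing: shared block markers
    mA <- simpleMap(3, "m"); mB <- simpleMap(3, "m")
    expect_equal(nrow(buildHomologyPairs(mA, mB)), 3L)
})

test_that("candidate pairs equal the brute-force hit filter", {
    for (seed in 1:50) {
        set.seed(seed)
        mapA <- simpleMap(12, "a"); mapB <- simpleMap(12, "b")
        hits <- data.frame(
            query = sample(mapA$marker, 20, TRUE),
            subject = sample(mapB$marker, 20, TRUE),
            evalue = 10^-sample(3:12, 20, TRUE), bitscore = 100)
        got <- buildHomologyPairs(mapA, mapB, hits)
        want <- unique(hits[hits$evalue <= 1e-5, c("query", "subject")])
        expect_setequal(paste(got$a, got$b),
                        paste(want$query, want$subject))
    }
})

test_that("a planted co-oriented run is found as a single segment", {
    mapA <- simpleMap(20, "a"); mapB <- simpleMap(20, "b")
    pairs <- data.frame(a = sprintf("a%02d", 5:9), b = sprintf("b%02d", 5:9))
    segs <- detectSegments(mapA, mapB, pairs, detectionParams(3, 10, 0.01))
    expect_equal(length(segs), 1L)
    tb <- segTable(segs)
    expect_equal(tb$n_anchors, 5L)
    expect_equal(tb$orientation, "same")
    expect_lte(tb$p_value, 0.01)
    ## only two pairs anywhere: below the three-anchor minimum
    segs2 <- detectSegments(mapA, mapB, pairs[1:2, ],
                            detectionParams(3, 10, 0.01))
    expect_equal(length(segs2), 0L)
    ## empty pair set
    expect_equal(length(detectSegments(mapA, mapB, pairs[0, ],
                                       detectionParams())), 0L)
})

test_that("inverted runs are detected with descending partner ranks", {
    mapA <- simpleMap(20, "a"); mapB <- simpleMap(20, "b")
    pairs <- data.frame(a = sprintf("a%02d", 5:9),
                        b = sprintf("b%02d", 14:10))
    segs <- detectSegments(mapA, mapB, pairs, detectionParams(3, 10, 0.01))
    expect_equal(length(segs), 1L)
    expect_equal(segTable(segs)$orientation, "inverted")
    expect_equal(segTable(segs)$n_anchors, 5L)
})

test_that("detection is deterministic across repeated runs", {
    inst <- randomInstance(11)
    params <- detectionParams(3, 10, 0.01)
    s1 <- detectSegments(inst$mapA, inst$mapB, inst$pairs, params)
    s2 <- detectSegments(inst$mapA, inst$mapB, inst$pairs, params)
    expect_identical(segTable(s1), segTable(s2))
    expect_identical(segAnchors(s1), segAnchors(s2))
})

test_that("detected segments equal the exhaustive chain oracle", {
    ## the full 100-seed sweep runs in the acceptance suite; this spot
    ## check keeps the unit suite fast
    for (seed in c(2, 17, 23, 31, 47)) {
        inst <- randomInstance(seed)
        for (gap in c(3L, 10L)) {
            params <- detectionParams(3L, gap, 0.01)
            det <- detectSegments(inst$mapA, inst$mapB, inst$pairs, params)
            expect_setequal(vapply(segAnchors(det), chainKey, ""),
                            oracleSegmentKeys(inst, params))
        }
    }
})

test_that("segment significance behaves like a corrected binomial tail", {
    ## saturated null: everything homologous carries no signal
    expect_equal(segmentSignificance(5, 5, 5, 1), 1)
    ## monotone in k and in density
    p1 <- vapply(2:8, segmentSignificance, 0, span_a = 10, span_b = 10,
                 density = 0.05)
    expect_true(all(diff(p1) <= 0))
    p2 <- vapply(c(0.01, 0.05, 0.2, 0.5), function(d)
        segmentSignificance(4, 10, 10, d), 0)
    expect_true(all(diff(p2) >= 0))
    expect_error(segmentSignificance(4, 10, 10, 0), "density")
    expect_error(segmentSignificance(4, 10, 10, 1.2), "density")
})

test_that("binomial significance matches a permutation null within 2-fold", {
    set.seed(42)
    nA <- 30L; nB <- 30L; P <- 40L
    cells <- sample(nA * nB, P)
    aIdx <- (cells - 1L) %/% nB + 1L
    bIdx <- (cells - 1L) %% nB + 1L
    grid <- expand.grid(k = c(2, 3, 4), sa = c(5, 10), sb = c(5, 10))[1:10, ]
    nPerm <- 10000L
    for (r in seq_len(nrow(grid))) {
        k <- grid$k[r]; sa <- grid$sa[r]; sb <- grid$sb[r]
        cnt <- 0L
        for (it in seq_len(nPerm)) {
            pa <- sample(nA); pb <- sample(nB)
            if (sum(pa[aIdx] <= sa & pb[bIdx] <= sb) >= k) cnt <- cnt + 1L
        }
        pmc <- max(cnt / nPerm, 1 / nPerm)
        pbin <- segmentSignificance(k, sa, sb, P / (nA * nB))
        expect_lt(abs(log2(pbin / pmc)), 1)
    }
})

test_that("gap and anchor-point parameters act monotonically", {
    for (seed in 1:10) {
        inst <- randomInstance(seed)
        anchored <- function(gap) {
            segs <- detectSegments(inst$mapA, inst$mapB, inst$pairs,
                                   detectionParams(3L, gap, 1))
            length(unique(unlist(lapply(segAnchors(segs), function(a)
                paste(a$marker_a, a$marker_b)))))
        }
        expect_lte(anchored(3L), anchored(6L))
        expect_lte(anchored(6L), anchored(12L))
        counts <- vapply(c(3L, 4L, 5L), function(ap)
            length(detectSegments(inst$mapA, inst$mapB, inst$pairs,
                                  detectionParams(ap, 10L, 1))), 0L)
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("level classification produces 2way-d and prefix n-way regions", {
    ord <- phyloOrder(c("ref", "melo", "lana", "malus"))
    tb <- data.frame(
        species_a = "ref", species_b = c("melo", "lana"),
        chrom_a = "chr1", start_a = c(100, 200), end_a = c(500, 600),
        chrom_b = "chr1", start_b = c(1, 1), end_b = c(401, 401))
    cl <- classifyLevels(fakeSegments(tb), ord)
    ## the second-listed species maps to d = 2
    expect_equal(cl$pairwise$d[cl$pairwise$species_b == "melo"], 2L)
    expect_equal(cl$pairwise$d[cl$pairwise$species_b == "lana"], 3L)
    ## overlap of the d=2 and d=3 covers: one 3-way region 200..500
    expect_equal(length(cl$n_way), 1L)
    expect_equal(S4Vectors::mcols(cl$n_way)$n, 3L)
    expect_equal(GenomicRanges::start(cl$n_way), 200)
    expect_equal(GenomicRanges::end(cl$n_way), 500)
    tb2 <- tb[1, ]
    expect_error(classifyLevels(fakeSegments(transform(
        tb2, species_b = "stranger")), ord), "absent")
})

test_that("n-way regions match the per-base oracle and nest", {
    for (seed in 1:20) {
        fix <- randomSegmentTable(seed)
        if (is.null(fix$table)) next
        segs <- fakeSegments(fix$table)
        cl <- classifyLevels(segs, fix$order)
        lev <- oracleNwayPerBase(segTable(segs), fix$order, fix$genomeLen)
        lev2 <- integer(fix$genomeLen)
        nw <- cl$n_way
        if (length(nw)) for (i in seq_along(nw))
            lev2[GenomicRanges::start(nw)[i]:GenomicRanges::end(nw)[i]] <-
                S4Vectors::mcols(nw)$n[i]
        expect_identical(lev2, lev)
        ## nesting: bases at level >= n+1 are contained in those >= n
        if (length(nw)) {
            ns <- sort(unique(S4Vectors::mcols(nw)$n))
            for (n in ns[-1L])
                expect_true(all(which(lev2 >= n) %in% which(lev2 >= n - 1L)))
        }
        ## every pairwise segment lands in exactly one 2way-d bucket
        expect_equal(nrow(cl$pairwise), nrow(segTable(segs)))
        expect_false(anyNA(cl$pairwise$d))
    }
})

test_that("segment summaries aggregate per level", {
    ord <- phyloOrder(c("ref", "s2", "s3"))
    nw <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 5000),
                                                  c(1000, 8000)))
    S4Vectors::mcols(nw)$n <- 3L
    sm <- segmentSummary(list(n_way = nw,
                              pairwise = data.frame(segment_id = character(0),
                                                    species_b = character(0),
                                                    d = integer(0))))
    expect_equal(sm$count, 2L)
    expect_equal(sm$mean_length, 2000.5)
    empty <- segmentSummary(list(n_way = GenomicRanges::GRanges(),
                                 pairwise = data.frame()))
    expect_equal(nrow(empty), 0L)
})
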