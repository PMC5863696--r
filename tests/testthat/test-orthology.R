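test_that("bidirectional best hits require mutual argmax", {
    spOf <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
    hits <- data.frame(query = c("a1", "b1"), subject = c("b1", "a1"),
                       evalue = 1e-20, bitscore = c(300, 300))
    expect_equal(computeBbh(hits, spOf),
                 data.frame(gene_a = "a1", gene_b = "b1"))
    ## a's best is b but b prefers a2: no BBH
    hits2 <- rbind(hits, data.frame(query = "b1", subject = "a2",
                                    evalue = 1e-40, bitscore = 500))
    expect_equal(nrow(computeBbh(hits2, spOf)), 0L)
})

test_that("BBH equals the per-gene argmax oracle on random hit tables", {
    for (seed in 1:100) {
        set.seed(seed)
        genes <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6))
        spOf <- setNames(rep(c("A", "B"), each = 6L), genes)
        n <- sample(5:25, 1L)
        hits <- data.frame(query = sample(genes, n, TRUE),
                           subject = sample(genes, n, TRUE),
                           evalue = 10^-sample(6:40, n, TRUE),
                           bitscore = sample(50:500, n, TRUE))
        got <- computeBbh(hits, spOf)
        ## oracle: direct argmax scan per gene
        h <- hits[spOf[hits$query] != spOf[hits$subject], , drop = FALSE]
        bestOf <- function(g) {
            hh <- h[h$query == g, , drop = FALSE]
            if (!nrow(hh)) return(NA_character_)
            hh <- hh[order(-hh$bitscore, hh$evalue, hh$subject), ,
                     drop = FALSE]
            hh$subject[1L]
        }
        want <- character(0)
        for (g in genes) {
            b <- bestOf(g)
            if (is.na(b)) next
            if (!is.na(bestOf(b)) && bestOf(b) == g)
                want <- c(want, paste(min(g, b), max(g, b)))
        }
        expect_setequal(paste(got$gene_a, got$gene_b), unique(want))
    }
})

test_that("gene-in-segment overlap is a base fraction", {
    expect_equal(geneSegmentOverlap("c1", 100, 200, "c1", 0, 1000), 1)
    ## boundary: exactly half overlap satisfies 'at least 50%'
    expect_equal(geneSegmentOverlap("c1", 100, 199, "c1", 150, 1000), 0.5)
    expect_equal(geneSegmentOverlap("c1", 100, 200, "c2", 0, 1000), 0)
    for (seed in 1:30) {
        set.seed(seed)
        gs <- sample(500, 1L); ge <- gs + sample(10:100, 1L)
        rs <- sample(500, 1L); re <- rs + sample(10:400, 1L)
        want <- sum(seq(gs, ge) %in% seq(rs, re)) / (ge - gs + 1)
        expect_equal(geneSegmentOverlap("c1", gs, ge, "c1", rs, re), want)
    }
})

test_that("the support score follows its closed form", {
    expect_equal(scoreOpss(15, 2, 2), 18)
    expect_equal(scoreOpss(10, 2, 2), 13)
    expect_equal(scoreOpss(2, 0, 0), 2)
    expect_error(scoreOpss(1, 0, 0), "degree")
    expect_error(scoreOpss(2, 0, 1), "b_score")
})

test_that("a pair supported only by a pairwise anchor segment scores 2", {
    sc <- pairwiseOnlyScenario()
    opps <- inferOpps(sc$genes, sc$segments, NULL, sc$hits, sc$order)
    hit <- opps[opps$gene_a == "ra_1" & opps$gene_b == "pb_1", ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$m_score, 2L)
    expect_equal(hit$p_score, 0L)
    expect_equal(hit$b_score, 0)
    expect_false(hit$is_bbh)
    expect_equal(hit$opss, 2)
    expect_lt(hit$opss, 3)
    ## the competing gene outside the segment never forms a pair
    expect_false(any(opps$gene_a == "ra_2"))
})

test_that("insufficient overlap on either gene vetoes the pair", {
    sc <- pairwiseOnlyScenario()
    ## move ra_1 so only ~12% of it lies inside the segment (region ends
    ## at the last anchor, base 7119)
    genes <- sc$genes
    idx <- which(genes$gene_id == "ra_1")
    GenomicRanges::ranges(genes)[idx] <- IRanges::IRanges(7000, 7999)
    opps <- inferOpps(genes, sc$segments, NULL, sc$hits, sc$order)
    expect_false(any(opps$gene_a == "ra_1"))
})

test_that("adding evidence raises the score; BBH is worth exactly 2", {
    sc <- pairwiseOnlyScenario()
    base <- inferOpps(sc$genes, sc$segments, NULL, sc$hits, sc$order)
    base <- base[base$gene_a == "ra_1", ]
    ## drop the competing hit: the pair becomes a BBH
    hits2 <- sc$hits[sc$hits$query %in% c("ra_1", "pb_1") &
                     sc$hits$subject %in% c("ra_1", "pb_1"), ]
    withBbh <- inferOpps(sc$genes, sc$segments, NULL, hits2, sc$order)
    withBbh <- withBbh[withBbh$gene_a == "ra_1", ]
    expect_true(withBbh$is_bbh)
    expect_equal(withBbh$opss - base$opss, 2)
    ## add a gene-based segment covering the pair: P-score appears
    withP <- inferOpps(sc$genes, sc$segments, sc$segments, hits2, sc$order)
    withP <- withP[withP$gene_a == "ra_1", ]
    expect_true(withP$protein_collinear_ok)
    expect_equal(withP$p_score, 2L)
    expect_equal(withP$opss, 2 + 0.5 * 2 + 2)
})

test_that("orthologs are recovered from noise-free worlds", {
    ## the 50-seed sweep runs in the acceptance suite
    for (seed in 1:5) {
        w <- generateWorld(noiseFreeConfig(seed))
        opps <- worldOpps(w)
        truth <- pairKey(w@truthOrthologs)
        got <- pairKey(opps)
        tp <- sum(got %in% truth)
        expect_gte(tp / length(got), 0.95)
        expect_gte(tp / length(truth), 0.95)
        ## every emitted pair satisfies the two essential conditions
        expect_true(all(opps$has_similarity))
        expect_true(all(opps$maa_overlap_ok))
    }
})

test_that("decoy paralogs score below true orthologs on average", {
    for (seed in 1:5) {
        w <- generateWorld(noiseFreeConfig(seed, decoy_rate = 0.4))
        opps <- worldOpps(w)
        truth <- pairKey(w@truthOrthologs)
        isTrue <- pairKey(opps) %in% truth
        if (!any(!isTrue)) next
        expect_gt(mean(opps$opss[isTrue]), mean(opps$opss[!isTrue]))
    }
})

test_that("the OPSS histogram bins and normalises", {
    opps <- data.frame(opss = rep(2, 7))
    h <- opssDistribution(opps, breaks = 0:5)
    expect_equal(sum(h$count), 7L)
    expect_equal(h$count[h$bin == "[2,3)"], 7L)
    expect_equal(sum(h$fraction), 1)
    h0 <- opssDistribution(data.frame(opss = numeric(0)), breaks = 0:5)
    expect_true(all(h0$count == 0L))
})
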