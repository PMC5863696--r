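test_that("MAF parsing converts coordinates and counts blocks", {
    path <- withr::local_tempfile(fileext = ".maf")
    writeLines(c(
        "##maf version=1", "",
        "a score=1",
        "s csa.chr1 10 50 + 1000 ACGT",
        "s cme.chr2 5 50 - 200 ACGT", "",
        "a score=2",
        "s csa.chr1 100 20 + 1000 ACGT",
        "s cla.chr3 7 20 + 500 ACGT"), path)
    b <- readMaf(path)
    expect_equal(length(unique(b$block)), 2L)
    expect_equal(nrow(b), 4L)
    ## 0-based start 10, length 50 -> closed interval [11, 60]
    r1 <- b[b$species == "csa" & b$block == 1L, ]
    expect_equal(c(r1$start, r1$end), c(11, 60))
    ## minus strand: forward start0 = 200 - (5 + 50) = 145
    r2 <- b[b$species == "cme", ]
    expect_equal(c(r2$start, r2$end, r2$strand), c("146", "195", "-"))
})

test_that("MAF round-trips through write/read on seeded synthetic blocks", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(3:8, 1L)
        rows <- do.call(rbind, lapply(seq_len(n), function(bk) {
            k <- sample(2:5, 1L)
            start <- sample(1000, k)
            w <- sample(50:300, k, replace = TRUE)
            data.frame(block = bk,
                       species = sprintf("sp%d", seq_len(k)),
                       chrom = sample(c("c1", "c2"), k, replace = TRUE),
                       start = start, end = start + w - 1,
                       strand = sample(c("+", "-"), k, replace = TRUE),
                       src_size = 5000, text = NA_character_)
        }))
        path <- withr::local_tempfile(fileext = ".maf")
        writeMaf(rows, path)
        back <- readMaf(path)
        expect_equal(back[, c("block", "species", "chrom", "start", "end",
                              "strand", "src_size")],
                     rows[, c("block", "species", "chrom", "start", "end",
                              "strand", "src_size")],
                     ignore_attr = TRUE)
    }
})

test_that("malformed MAF lines and empty files are handled", {
    path <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a", "s csa.chr1 ten 50 + 1000 ACGT"), path)
    expect_error(readMaf(path), "line 2")
    writeLines(character(0), path)
    expect_equal(nrow(readMaf(path)), 0L)
})

test_that("gene models read identically from GFF3 and BED with ranks", {
    gr <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(101, 501, 51), c(200, 700, 90)))
    S4Vectors::mcols(gr)$gene_id <- c("gA", "gB", "gC")
    gff <- withr::local_tempfile(fileext = ".gff3")
    bed <- withr::local_tempfile(fileext = ".bed")
    writeGff3(gr, gff)
    writeBed(gr, bed)
    g1 <- readGeneModels(gff, "gff3", species = "sp")
    g2 <- readGeneModels(bed, "bed", species = "sp")
    ## GFF3 gene at 101..200 stays [101, 200]; BED (100, 200) converts back
    expect_equal(GenomicRanges::start(g1[g1$gene_id == "gA"]), 101)
    expect_equal(GenomicRanges::end(g1[g1$gene_id == "gA"]), 200)
    expect_identical(as.data.frame(g1)[, c("seqnames", "start", "end",
                                           "gene_id", "rank")],
                     as.data.frame(g2)[, c("seqnames", "start", "end",
                                           "gene_id", "rank")])
    ## ranks follow start order: 51 < 101 < 501
    expect_equal(g1$rank[match(c("gC", "gA", "gB"), g1$gene_id)], 1:3)
})

test_that("duplicate gene identifiers are reported", {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 100), c(50, 150)))
    S4Vectors::mcols(gr)$gene_id <- c("dup", "dup")
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeGff3(gr, gff)
    expect_error(readGeneModels(gff, "gff3"), "dup")
})

test_that("OBO reading builds the DAG, drops obsolete terms, finds cycles", {
    path <- withr::local_tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: T1", "name: root", "namespace: BP", "",
        "[Term]", "id: T2", "name: mid", "namespace: BP", "is_a: T1", "",
        "[Term]", "id: T3", "name: leaf", "namespace: BP", "is_a: T2",
        "relationship: part_of T1", "",
        "[Term]", "id: T4", "name: kid", "namespace: BP", "is_a: T2", "",
        "[Term]", "id: T9", "name: gone", "namespace: BP", "is_a: T1",
        "is_obsolete: true", ""), path)
    dag <- readObo(path)
    expect_equal(nrow(dag@terms), 4L)
    expect_false("T9" %in% dag@terms$id)
    expect_equal(sum(dag@edges$relation == "is_a"), 3L)
    expect_equal(sum(dag@edges$relation == "part_of"), 1L)
    ## a cycle must be rejected with a named cycle
    writeLines(c(
        "[Term]", "id: A", "name: a", "namespace: BP", "is_a: B", "",
        "[Term]", "id: B", "name: b", "namespace: BP", "is_a: A", ""), path)
    expect_error(readObo(path), "cycle")
})

test_that("annotation tables deduplicate and project to G and GO", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("g1\tt1", "g1\tt2", "g2\tt1", "g1\tt1", "g3\tt3"), path)
    ann <- readAnnotationTable(path)
    expect_equal(nrow(annPairs(ann)), 4L)
    expect_setequal(annGenes(ann), c("g1", "g2", "g3"))
    expect_setequal(annTerms(ann), c("t1", "t2", "t3"))
    dag <- ontologyDag(data.frame(id = "t1", name = "t1", namespace = "BP"))
    expect_warning(readAnnotationTable(path, dag = dag), "t2")
})

test_that("G and GO never exceed P on random annotation tables", {
    for (seed in 1:50) {
        set.seed(seed)
        n <- sample(1:40, 1L)
        df <- data.frame(gene = sample(sprintf("g%d", 1:15), n, TRUE),
                         term = sample(sprintf("t%d", 1:10), n, TRUE))
        ann <- annotationSet(df)
        expect_lte(length(annGenes(ann)), nrow(annPairs(ann)))
        expect_lte(length(annTerms(ann)), nrow(annPairs(ann)))
        expect_equal(nrow(annPairs(ann)),
                     nrow(unique(df)))
    }
})

test_that("expression matrices are typed, rectangular and non-negative", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tleaf\troot", "g1\t1.5\t2", "g2\t0\t3.25",
                 "g3\t7\t0.1"), path)
    X <- readExpressionMatrix(path)
    expect_equal(dim(X), c(3L, 2L))
    expect_equal(X["g2", "root"], 3.25)
    writeLines(c("gene\tleaf\troot", "g1\t-1\t2"), path)
    expect_error(readExpressionMatrix(path), "negative")
    writeLines(c("gene\tleaf\troot", "g1\t1\t2\t3"), path)
    expect_error(readExpressionMatrix(path), "ragged")
})

test_that("homology tables parse outfmt-6 columns", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste(c("qa", "sb", 99, 100, 0, 0, 1, 100, 1, 100,
                       "1e-30", 250), collapse = "\t"), path)
    h <- readHomologyTable(path)
    expect_equal(h$evalue, 1e-30)
    expect_equal(h$bitscore, 250)
    writeLines(c(paste(rep("x", 12), collapse = "\t"),
                 paste(rep("x", 11), collapse = "\t")), path)
    expect_error(readHomologyTable(path), "ragged")
})

test_that("species order reader keeps the reference first", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# comment", "csa", "cme", "", "cla"), path)
    ord <- readPhyloOrder(path)
    expect_equal(refSpecies(ord), "csa")
    expect_equal(unname(dIndex(ord)[c("cme", "cla")]), c(2L, 3L))
})
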