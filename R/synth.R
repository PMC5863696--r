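#' Configuration of a synthetic comparative-genomics world
#'
#' The defaults describe a small world that the full pipeline traverses in
#' seconds: five species (the first is the reference), seven planted
#' collinear blocks of 5-12 ortholog families each laid out on their own
#' chromosomes, 5-15 alignment anchors spread across each block (a
#' conserved fraction present in every species, the rest in
#' divergence-ordered prefixes), species-specific noise genes, and an
#' expression matrix over ten tissues in which a few annotation terms carry
#' a planted shared latent factor.
#'
#' @param n_species number of species including the reference.
#' @param genes_per_genome target gene count per species (block genes plus
#'   species-specific filler).
#' @param n_planted_blocks number of planted collinear blocks.
#' @param block_size_range integer range of ortholog families per block.
#' @param noise_marker_rate probability of a species-specific noise gene in
#'   each within-block slot.
#' @param rearrangement_rate per-species, per-block probability of an
#'   inversion (and of participating in a chromosome-label translocation).
#' @param ortholog_dropout_rate maximal per-gene dropout probability
#'   (scaled linearly with the divergence index d).
#' @param maa_per_block_range integer range of alignment anchors per block.
#' @param maa_conserved_frac fraction of each block's anchors conserved in
#'   all species (the flanking anchors always are).
#' @param decoy_rate fraction of families receiving a borderline decoy
#'   paralog hit.
#' @param n_terms number of ontology terms (split over BP/MF/CC).
#' @param term_size_range integer range of families annotated per term.
#' @param n_coexpressed_terms number of terms with a planted co-expression
#'   module.
#' @param latent_factor_sd standard deviation of the shared latent factor.
#' @param noise_sd residual expression noise standard deviation.
#' @param n_tissues number of expression columns.
#' @param seed integer seed; a fixed seed yields a byte-identical world.
#' @return validated configuration list.
#' @export
worldConfig <- function(n_species = 5L, genes_per_genome = 200L,
                        n_planted_blocks = 7L, block_size_range = c(5L, 12L),
                        noise_marker_rate = 0.1, rearrangement_rate = 0.05,
                        ortholog_dropout_rate = 0.1,
                        maa_per_block_range = c(5L, 15L),
                        maa_conserved_frac = 0.7, decoy_rate = 0.1,
                        n_terms = 60L, term_size_range = c(5L, 15L),
                        n_coexpressed_terms = 5L, latent_factor_sd = 1,
                        noise_sd = 0.3, n_tissues = 10L, seed = 1L) {
    cfg <- list(n_species = as.integer(n_species),
                genes_per_genome = as.integer(genes_per_genome),
                n_planted_blocks = as.integer(n_planted_blocks),
                block_size_range = as.integer(block_size_range),
                noise_marker_rate = noise_marker_rate,
                rearrangement_rate = rearrangement_rate,
                ortholog_dropout_rate = ortholog_dropout_rate,
                maa_per_block_range = as.integer(maa_per_block_range),
                maa_conserved_frac = maa_conserved_frac,
                decoy_rate = decoy_rate, n_terms = as.integer(n_terms),
                term_size_range = as.integer(term_size_range),
                n_coexpressed_terms = as.integer(n_coexpressed_terms),
                latent_factor_sd = latent_factor_sd, noise_sd = noise_sd,
                n_tissues = as.integer(n_tissues), seed = as.integer(seed))
    stopifnot(cfg$n_species >= 2L, cfg$n_planted_blocks >= 1L,
              length(cfg$block_size_range) == 2L,
              cfg$block_size_range[1L] >= 2L,
              diff(cfg$block_size_range) >= 0L,
              length(cfg$maa_per_block_range) == 2L,
              cfg$maa_per_block_range[1L] >= 2L,
              diff(cfg$maa_per_block_range) >= 0L,
              cfg$n_tissues >= 2L)
    rates <- c(cfg$noise_marker_rate, cfg$rearrangement_rate,
               cfg$ortholog_dropout_rate, cfg$maa_conserved_frac,
               cfg$decoy_rate)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (cfg$n_planted_blocks * cfg$block_size_range[2L] >
        cfg$genes_per_genome)
        stop("infeasible configuration: planted blocks exceed the genome ",
             "size (n_planted_blocks * max block size > genes_per_genome)")
    cfg
}

.GENE_W <- 1000L
.MAA_W <- 120L

## lay out an ordered item list on a chromosome; returns the items with
## start/end columns added and the chromosome length
.layout <- function(items) {
    n <- nrow(items)
    gaps <- floor(stats::runif(n, 100, 500))
    w <- ifelse(items$type == "maa", .MAA_W, .GENE_W)
    start <- cumsum(gaps + c(0, w[-n]))[seq_len(n)] + 1
    items$start <- start
    items$end <- start + w - 1
    attr(items, "chromLen") <- items$end[n] + 500
    items
}

#' Generate a synthetic comparative-genomics world
#'
#' See [worldConfig()] for the planted structure. Determinism: calling with
#' the same configuration (including its seed) reproduces the world
#' exactly.
#'
#' @param config configuration from [worldConfig()].
#' @return A [SyntheticWorld-class].
#' @export
generateWorld <- function(config = worldConfig()) {
    set.seed(config$seed)
    S <- config$n_species
    sp <- sprintf("sp%d", seq_len(S))
    order <- phyloOrder(sp)
    ref <- sp[1L]
    B <- config$n_planted_blocks
    gB <- sample(seq(config$block_size_range[1L],
                     config$block_size_range[2L]), B, replace = TRUE)
    mB <- sample(seq(config$maa_per_block_range[1L],
                     config$maa_per_block_range[2L]), B, replace = TRUE)
    ## per-block ancestral item sequences and conservation patterns
    blocks <- vector("list", B)
    for (b in seq_len(B)) {
        fams <- sprintf("fam_b%d_%d", b, seq_len(gB[b]))
        ## anchor j sits after slot(j) genes; flanks pinned to the ends
        slot <- round((seq_len(mB[b]) - 1L) * gB[b] / (mB[b] - 1L))
        nCons <- max(2L, ceiling(config$maa_conserved_frac * mB[b]))
        consIdx <- unique(round(seq(1L, mB[b], length.out = nCons)))
        dMax <- rep(S, mB[b])
        nonCons <- setdiff(seq_len(mB[b]), consIdx)
        dMax[nonCons] <- sample(2:S, length(nonCons), replace = TRUE)
        ## ancestral order: anchors interleaved with genes by slot
        items <- rbind(
            data.frame(type = "gene", id = fams, key = fams,
                       pos = seq_len(gB[b]), sub = 1),
            data.frame(type = "maa",
                       id = sprintf("maa_b%d_%d", b, seq_len(mB[b])),
                       key = sprintf("maa_b%d_%d", b, seq_len(mB[b])),
                       pos = slot, sub = 2))
        items <- items[order(items$pos, items$sub), , drop = FALSE]
        blocks[[b]] <- list(fams = fams, items = items, dMax = dMax,
                            maaIds = sprintf("maa_b%d_%d", b, seq_len(mB[b])))
    }
    dropRate <- function(d) if (S == 2L) config$ortholog_dropout_rate
        else config$ortholog_dropout_rate * (d - 1) / (S - 1)
    ## per-species realisation
    geneRows <- list(); maaRows <- list()
    chromLengths <- list()
    famGene <- list()   # species -> named map family -> gene_id
    inverted <- matrix(FALSE, B, S, dimnames = list(NULL, sp))
    for (si in seq_len(S)) {
        s <- sp[si]
        gcount <- 0L
        rowsG <- list(); rowsM <- list()
        lens <- c()
        fmap <- character(0)
        ## optional chromosome-label translocation: swap two block labels
        chromOf <- sprintf("chr%d", seq_len(B))
        if (si > 1L && B >= 2L &&
            stats::runif(1) < config$rearrangement_rate) {
            swap <- sample(B, 2L)
            chromOf[swap] <- chromOf[rev(swap)]
        }
        for (b in seq_len(B)) {
            bl <- blocks[[b]]
            items <- bl$items
            if (si > 1L) {
                ## gene dropout scaled with divergence
                keepG <- items$type != "gene" |
                    stats::runif(nrow(items)) >= dropRate(si)
                ## anchor conservation by divergence prefix
                maaD <- setNames(bl$dMax, bl$maaIds)
                keepM <- items$type != "maa" | maaD[items$id] >= si
                items <- items[keepG & keepM, , drop = FALSE]
                if (stats::runif(1) < config$rearrangement_rate) {
                    items <- items[rev(seq_len(nrow(items))), , drop = FALSE]
                    inverted[b, si] <- TRUE
                }
            }
            ## species-specific noise genes between items
            if (config$noise_marker_rate > 0 && nrow(items) > 1L) {
                ins <- which(stats::runif(nrow(items) - 1L) <
                             config$noise_marker_rate)
                if (length(ins)) {
                    noise <- data.frame(
                        type = "gene",
                        id = sprintf("noise_b%d_%d", b, seq_along(ins)),
                        key = NA_character_, pos = NA_real_, sub = NA_real_)
                    pieces <- list()
                    prev <- 0L
                    for (k in seq_along(ins)) {
                        pieces[[length(pieces) + 1L]] <-
                            items[(prev + 1L):ins[k], , drop = FALSE]
                        pieces[[length(pieces) + 1L]] <- noise[k, ,
                                                               drop = FALSE]
                        prev <- ins[k]
                    }
                    pieces[[length(pieces) + 1L]] <-
                        items[(prev + 1L):nrow(items), , drop = FALSE]
                    items <- do.call(rbind, pieces)
                }
            }
            items <- .layout(items)
            ch <- chromOf[b]
            lens[ch] <- attr(items, "chromLen")
            isG <- items$type == "gene"
            ids <- character(nrow(items))
            ids[isG] <- sprintf("%s_g%04d", s, gcount + seq_len(sum(isG)))
            gcount <- gcount + sum(isG)
            gidx <- which(isG)
            rowsG[[length(rowsG) + 1L]] <- data.frame(
                gene_id = ids[gidx], species = s, chrom = ch,
                start = items$start[gidx], end = items$end[gidx],
                family = items$key[gidx], block = b)
            fams <- items$key[gidx]
            ok <- !is.na(fams)
            fmap[fams[ok]] <- ids[gidx][ok]
            midx <- which(!isG)
            if (length(midx))
                rowsM[[length(rowsM) + 1L]] <- data.frame(
                    maa = items$id[midx], species = s, chrom = ch,
                    start = items$start[midx], end = items$end[midx],
                    strand = if (inverted[b, si]) "-" else "+", block = b)
        }
        ## filler chromosome with species-specific genes
        placed <- gcount
        fill <- max(config$genes_per_genome - placed, 0L)
        if (fill > 0L) {
            items <- .layout(data.frame(
                type = "gene", id = sprintf("fill_%d", seq_len(fill)),
                key = NA_character_, pos = NA_real_, sub = NA_real_))
            lens["chrU"] <- attr(items, "chromLen")
            rowsG[[length(rowsG) + 1L]] <- data.frame(
                gene_id = sprintf("%s_g%04d", s, placed + seq_len(fill)),
                species = s, chrom = "chrU",
                start = items$start, end = items$end,
                family = NA_character_, block = NA_integer_)
        }
        geneRows[[si]] <- do.call(rbind, rowsG)
        maaRows[[si]] <- do.call(rbind, rowsM)
        chromLengths[[s]] <- lens
        famGene[[s]] <- fmap
    }
    genesDf <- do.call(rbind, geneRows)
    maaDf <- do.call(rbind, maaRows)
    genes <- GenomicRanges::GRanges(
        genesDf$chrom, IRanges::IRanges(genesDf$start, genesDf$end))
    S4Vectors::mcols(genes)$gene_id <- genesDf$gene_id
    S4Vectors::mcols(genes)$species <- genesDf$species
    S4Vectors::mcols(genes)$family <- genesDf$family
    ## ranks per species and chromosome
    rk <- integer(length(genes))
    for (s in sp) {
        idx <- which(genesDf$species == s)
        rk[idx] <- assignRanks(genes[idx])
    }
    S4Vectors::mcols(genes)$rank <- rk
    ## alignment blocks: one per anchor, rows for the species carrying it
    maaDf$blockIdx <- match(maaDf$maa, unique(maaDf$maa))
    alignBlocks <- data.frame(
        block = maaDf$blockIdx, species = maaDf$species,
        chrom = maaDf$chrom, start = maaDf$start, end = maaDf$end,
        strand = maaDf$strand,
        src_size = vapply(seq_len(nrow(maaDf)), function(i)
            unname(chromLengths[[maaDf$species[i]]][maaDf$chrom[i]]), 0),
        text = NA_character_)
    alignBlocks <- alignBlocks[order(alignBlocks$block,
                                     match(alignBlocks$species, sp)), ,
                               drop = FALSE]
    rownames(alignBlocks) <- NULL
    ## truth orthologs (reference-centric) and hits
    truth <- list(); hitRows <- list()
    refMap <- famGene[[ref]]
    for (si in 2:S) {
        s <- sp[si]
        shared <- intersect(names(refMap), names(famGene[[s]]))
        if (!length(shared)) next
        ga <- unname(refMap[shared]); gb <- unname(famGene[[s]][shared])
        truth[[length(truth) + 1L]] <- data.frame(
            gene_a = ga, gene_b = gb, species_b = s, family = shared)
        bs <- round(stats::runif(length(ga), 200, 500), 1)
        ev <- 10^-stats::runif(length(ga), 20, 50)
        hitRows[[length(hitRows) + 1L]] <- data.frame(
            query = c(ga, gb), subject = c(gb, ga),
            evalue = c(ev, ev), bitscore = c(bs, bs))
    }
    ## decoy paralog hits: borderline E-value, low bitscore, same block
    if (config$decoy_rate > 0) {
        for (b in seq_len(B)) {
            fams <- blocks[[b]]$fams
            if (length(fams) < 2L) next
            pick <- which(stats::runif(length(fams)) < config$decoy_rate)
            for (i in pick) {
                partner <- fams[(i %% length(fams)) + 1L]
                s <- sample(sp[-1L], 1L)
                if (!fams[i] %in% names(refMap) ||
                    !partner %in% names(famGene[[s]])) next
                ga <- unname(refMap[fams[i]])
                gb <- unname(famGene[[s]][partner])
                bs <- round(stats::runif(1, 60, 150), 1)
                ev <- 10^-stats::runif(1, 6, 9)
                hitRows[[length(hitRows) + 1L]] <- data.frame(
                    query = c(ga, gb), subject = c(gb, ga),
                    evalue = c(ev, ev), bitscore = c(bs, bs))
            }
        }
    }
    truthOrthologs <- if (length(truth)) do.call(rbind, truth)
        else data.frame(gene_a = character(0), gene_b = character(0),
                        species_b = character(0), family = character(0))
    hits <- if (length(hitRows)) do.call(rbind, hitRows)
        else data.frame(query = character(0), subject = character(0),
                        evalue = numeric(0), bitscore = numeric(0))
    rownames(hits) <- NULL
    ## truth block extents per species
    tb <- list()
    for (si in seq_len(S)) {
        s <- sp[si]
        gd <- geneRows[[si]]; md <- maaRows[[si]]
        for (b in seq_len(B)) {
            gsel <- gd[!is.na(gd$block) & gd$block == b, , drop = FALSE]
            msel <- md[md$block == b, , drop = FALSE]
            st <- min(c(gsel$start, msel$start))
            en <- max(c(gsel$end, msel$end))
            tb[[length(tb) + 1L]] <- data.frame(
                block_id = b, species = s,
                chrom = unique(c(gsel$chrom, msel$chrom))[1L],
                start = st, end = en,
                n_genes = sum(!is.na(gsel$family)),
                n_maas = nrow(msel),
                inverted = inverted[b, si])
        }
    }
    truthBlocks <- do.call(rbind, tb)
    ## ontology: layered random DAG over three namespaces
    nt <- config$n_terms
    ns <- rep(c("BP", "MF", "CC"), length.out = nt)
    ids <- sprintf("SGO:%07d", seq_len(nt))
    termDf <- data.frame(id = ids, name = sprintf("synthetic term %d",
                                                  seq_len(nt)),
                         namespace = ns)
    edges <- list()
    for (nsx in unique(ns)) {
        members <- which(ns == nsx)
        for (k in seq_along(members)[-1L]) {
            i <- members[k]
            nPar <- sample(1:2, 1L)
            pars <- sample(members[seq_len(k - 1L)],
                           min(nPar, k - 1L))
            for (p in pars)
                edges[[length(edges) + 1L]] <- data.frame(
                    child = ids[i], parent = ids[p],
                    relation = if (stats::runif(1) < 0.85) "is_a"
                               else "part_of")
        }
    }
    dag <- ontologyDag(termDf, do.call(rbind, edges))
    ## annotations: terms annotate families; species sets follow presence
    allFams <- unlist(lapply(blocks, `[[`, "fams"))
    roots <- setdiff(ids, unique(do.call(rbind, edges)$child))
    annotatable <- setdiff(ids, roots)
    termFams <- list()
    for (t in annotatable) {
        size <- sample(seq(config$term_size_range[1L],
                           min(config$term_size_range[2L], length(allFams))),
                       1L)
        termFams[[t]] <- sample(allFams, size)
    }
    annotations <- list()
    for (s in sp) {
        fmap <- famGene[[s]]
        rows <- list()
        for (t in names(termFams)) {
            g <- unname(fmap[intersect(termFams[[t]], names(fmap))])
            if (length(g))
                rows[[length(rows) + 1L]] <- data.frame(gene = g, term = t)
        }
        annotations[[s]] <- annotationSet(
            if (length(rows)) do.call(rbind, rows)
            else data.frame(gene = character(0), term = character(0)))
    }
    ## expression over reference genes with planted co-expressed terms
    refGenes <- genesDf$gene_id[genesDf$species == ref]
    m <- config$n_tissues
    X <- matrix(pmax(stats::rnorm(length(refGenes) * m, 5, 1), 0),
                nrow = length(refGenes), ncol = m,
                dimnames = list(refGenes,
                                sprintf("tissue%02d", seq_len(m))))
    ## co-expressed modules are planted on terms with mutually disjoint
    ## family sets, so every module follows a single latent factor
    nCo <- min(config$n_coexpressed_terms, length(annotatable))
    truthCoexpr <- character(0)
    claimedFams <- character(0)
    for (t in sample(names(termFams))) {
        if (length(truthCoexpr) >= nCo) break
        if (any(termFams[[t]] %in% claimedFams)) next
        truthCoexpr <- c(truthCoexpr, t)
        claimedFams <- c(claimedFams, termFams[[t]])
        g <- unname(refMap[intersect(termFams[[t]], names(refMap))])
        if (!length(g)) next
        f <- stats::rnorm(m, 0, config$latent_factor_sd)
        for (gg in g)
            X[gg, ] <- pmax(5 + f + stats::rnorm(m, 0, config$noise_sd), 0)
    }
    new("SyntheticWorld", genes = genes, alignBlocks = alignBlocks,
        hits = hits, truthOrthologs = truthOrthologs,
        truthBlocks = truthBlocks, ontology = dag,
        annotations = annotations, expression = X,
        truthCoexpr = truthCoexpr, order = order,
        chromLengths = chromLengths, config = config)
}

#' Write a synthetic world to disk
#'
#' Pipeline inputs go under `<dir>/input` (MAF, per-species GFF3, hits TSV,
#' OBO, per-species annotation TSVs, expression TSV, species order), truth
#' files under `<dir>/truth`; truth never leaks into the input
#' subdirectory. Every emitted file re-parses through the package readers.
#'
#' @param world A [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return data.frame manifest with columns `path` (relative) and `md5`.
#' @export
writeWorld <- function(world, dir) {
    inputDir <- file.path(dir, "input")
    truthDir <- file.path(dir, "truth")
    dir.create(inputDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(truthDir, recursive = TRUE, showWarnings = FALSE)
    sp <- speciesOrder(world@order)
    paths <- character(0); rels <- character(0)
    add <- function(p) {
        paths <<- c(paths, p)
        rels <<- c(rels, file.path(basename(dirname(p)), basename(p)))
    }
    p <- file.path(inputDir, "alignments.maf")
    writeMaf(world@alignBlocks, p); add(p)
    gm <- S4Vectors::mcols(world@genes)
    for (s in sp) {
        g <- world@genes[gm$species == s]
        p <- file.path(inputDir, sprintf("genes_%s.gff3", s))
        writeGff3(g, p); add(p)
    }
    p <- file.path(inputDir, "hits.tsv")
    writeHomologyTable(world@hits, p); add(p)
    p <- file.path(inputDir, "ontology.obo")
    writeObo(world@ontology, p); add(p)
    for (s in setdiff(names(world@annotations), refSpecies(world@order))) {
        p <- file.path(inputDir, sprintf("annotations_%s.tsv", s))
        writeAnnotationTable(world@annotations[[s]], p); add(p)
    }
    p <- file.path(inputDir, "expression.tsv")
    writeExpressionMatrix(world@expression, p); add(p)
    p <- file.path(inputDir, "species_order.txt")
    writeLines(sp, p); add(p)
    p <- file.path(inputDir, "chrom_lengths.tsv")
    cl <- do.call(rbind, lapply(sp, function(s) data.frame(
        species = s, chrom = names(world@chromLengths[[s]]),
        length = unname(world@chromLengths[[s]]))))
    utils::write.table(cl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(p)
    p <- file.path(truthDir, "orthologs.tsv")
    utils::write.table(world@truthOrthologs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(p)
    p <- file.path(truthDir, "blocks.tsv")
    utils::write.table(world@truthBlocks, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(p)
    p <- file.path(truthDir, "coexpressed_terms.txt")
    writeLines(world@truthCoexpr, p); add(p)
    refSp <- refSpecies(world@order)
    if (refSp %in% names(world@annotations)) {
        p <- file.path(truthDir, sprintf("annotations_%s.tsv", refSp))
        writeAnnotationTable(world@annotations[[refSp]], p); add(p)
    }
    data.frame(path = rels, md5 = unname(tools::md5sum(paths)),
               row.names = NULL)
}
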