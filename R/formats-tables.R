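#' Read gene models from GFF3 or BED
#'
#' GFF3 rows of type `gene` (1-based inclusive) or BED6 rows (0-based
#' half-open) are converted to a GRanges of gene models. Ranks are assigned
#' per chromosome in start order, so genes double as ordered genomic
#' markers for collinearity detection.
#'
#' @param path path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param species species identifier stored in `mcols(x)$species`.
#' @return GRanges with mcols `gene_id`, `species`, `rank`.
#' @export
readGeneModels <- function(path, format = c("gff3", "bed"), species = "ref") {
    format <- match.arg(format)
    gr <- rtracklayer::import(path, format = format)
    if (format == "gff3") {
        gr <- gr[gr$type == "gene"]
        ids <- as.character(gr$ID)
    } else {
        ids <- as.character(gr$name)
    }
    if (anyNA(ids) || any(ids == ""))
        stop("gene models without an identifier")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene_id within species '", species, "': ",
             paste(dup, collapse = ", "))
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr), IRanges::ranges(gr),
        strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out)$gene_id <- ids
    S4Vectors::mcols(out)$species <- species
    out <- out[order(as.character(GenomicRanges::seqnames(out)),
                     GenomicRanges::start(out))]
    S4Vectors::mcols(out)$rank <- assignRanks(out)
    out
}

#' Assign per-chromosome ranks to markers
#'
#' @param gr a GRanges.
#' @return integer vector: 1-based ordinal position of each range along its
#'   chromosome, by start coordinate.
#' @export
assignRanks <- function(gr) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)
    rk <- integer(length(gr))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        rk[idx] <- rank(st[idx], ties.method = "first")
    }
    rk
}

#' Read a BLAST tabular (outfmt 6) homology table
#'
#' Takes the standard 12-column layout; only `qseqid`, `sseqid`, `evalue`
#' and `bitscore` are retained.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
readHomologyTable <- function(path) {
    stopifnot(file.exists(path))
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
    if (length(nf) == 0L)
        return(data.frame(query = character(0), subject = character(0),
                          evalue = numeric(0), bitscore = numeric(0)))
    if (length(unique(nf)) > 1L)
        stop("ragged hit table: row ", which(nf != nf[1L])[1L],
             " has ", nf[which(nf != nf[1L])[1L]], " fields")
    if (nf[1L] < 12L) stop("expected >= 12 outfmt-6 columns, got ", nf[1L])
    tb <- utils::read.delim(path, header = FALSE, comment.char = "#")
    data.frame(query = as.character(tb[[1L]]), subject = as.character(tb[[2L]]),
               evalue = as.numeric(tb[[11L]]), bitscore = as.numeric(tb[[12L]]))
}

#' Read an expression matrix
#'
#' TSV with a header row naming the tissues and gene identifiers in the
#' first column; values are FPKM-like and must be non-negative numbers.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes as rows (rownames), tissues as columns.
#' @export
readExpressionMatrix <- function(path) {
    stopifnot(file.exists(path))
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1L)
        stop("ragged expression matrix: row ",
             which(nf != nf[1L])[1L], " has a different field count")
    tb <- utils::read.delim(path, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    if (anyDuplicated(rownames(tb))) stop("duplicated gene identifiers")
    m <- as.matrix(tb)
    if (!is.numeric(m)) {
        bad <- rownames(tb)[apply(tb, 1L, function(r)
            anyNA(suppressWarnings(as.numeric(r))))]
        stop("non-numeric expression values for gene(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (anyNA(m)) stop("missing expression values")
    if (any(m < 0)) stop("negative FPKM values are not allowed")
    m
}

#' Read an annotation table into an AnnotationSet
#'
#' TSV of `gene_id`, `term_id` and an optional third (evidence) column;
#' duplicated pairs in the file are collapsed. If an [OntologyDag-class] is
#' supplied, pairs whose term is absent from the DAG trigger a warning but
#' are retained.
#'
#' @param path path to the TSV (no header).
#' @param dag optional [OntologyDag-class] used to check term ids.
#' @return An [AnnotationSet-class].
#' @export
readAnnotationTable <- function(path, dag = NULL) {
    stopifnot(file.exists(path))
    tb <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            colClasses = "character")
    if (ncol(tb) < 2L) stop("annotation table needs >= 2 columns")
    ann <- annotationSet(data.frame(gene = tb[[1L]], term = tb[[2L]]))
    if (!is.null(dag)) {
        missing <- setdiff(annTerms(ann), dag@terms$id)
        if (length(missing))
            warning("terms absent from the ontology: ",
                    paste(missing, collapse = ", "))
    }
    ann
}

#' Read a GAF-style annotation file
#'
#' Maps GAF columns 2 (DB object id) and 5 (term id) into the minimal
#' gene-term representation used throughout the package.
#'
#' @inheritParams readAnnotationTable
#' @return An [AnnotationSet-class].
#' @export
readGaf <- function(path, dag = NULL) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines))
        return(annotationSet(data.frame(gene = character(0),
                                        term = character(0))))
    f <- strsplit(lines, "\t", fixed = TRUE)
    ann <- annotationSet(data.frame(
        gene = vapply(f, `[`, "", 2L), term = vapply(f, `[`, "", 5L)))
    if (!is.null(dag)) {
        missing <- setdiff(annTerms(ann), dag@terms$id)
        if (length(missing))
            warning("terms absent from the ontology: ",
                    paste(missing, collapse = ", "))
    }
    ann
}

#' Read a plain-text species order
#'
#' One species per line, reference first, '#' comments allowed.
#'
#' @param path path to the file.
#' @return A [PhyloOrder-class].
#' @export
readPhyloOrder <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    phyloOrder(lines)
}

#' Write simple TSV outputs
#'
#' `writeAnnotationTable` writes the P pairs of an annotation set as a
#' 2-column TSV; `writeExpressionMatrix` the genes x tissues matrix with a
#' header row; `writeHomologyTable` a 12-column outfmt-6 style table (unused
#' middle columns zero-filled); `writeSegmentsTsv` the segment table of a
#' [CollinearSegments-class].
#'
#' @param x object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeAnnotationTable <- function(x, path) {
    utils::write.table(annPairs(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writers
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writers
#' @export
writeHomologyTable <- function(x, path) {
    out <- data.frame(x$query, x$subject, 0, 0, 0, 0, 0, 0, 0, 0,
                      format(x$evalue, scientific = TRUE, digits = 6),
                      x$bitscore)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writers
#' @export
writeSegmentsTsv <- function(x, path) {
    utils::write.table(segTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export anchors as BED6
#'
#' The score column carries the number of species the anchor is conserved
#' in; coordinates follow BED's 0-based half-open convention.
#'
#' @param anchors GRanges with mcols `anchor_id` and `n_species`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnchorsBed <- function(anchors, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(anchors)),
        start = GenomicRanges::start(anchors) - 1L,
        end = GenomicRanges::end(anchors),
        name = S4Vectors::mcols(anchors)$anchor_id,
        score = S4Vectors::mcols(anchors)$n_species,
        strand = as.character(GenomicRanges::strand(anchors)))
    df$strand[df$strand == "*"] <- "+"
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with mcols `gene_id` (1-based closed coordinates).
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genes, path, source = "synortho") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (length(genes)) {
        strand <- as.character(GenomicRanges::strand(genes))
        strand[strand == "*"] <- "+"
        writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                           as.character(GenomicRanges::seqnames(genes)),
                           source,
                           GenomicRanges::start(genes),
                           GenomicRanges::end(genes), strand,
                           S4Vectors::mcols(genes)$gene_id), con)
    }
    invisible(path)
}

#' Write gene models as BED6
#'
#' @inheritParams writeGff3
#' @return `path`, invisibly.
#' @export
writeBed <- function(genes, path) {
    strand <- as.character(GenomicRanges::strand(genes))
    strand[strand == "*"] <- "+"
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(genes)),
        start = GenomicRanges::start(genes) - 1L,
        end = GenomicRanges::end(genes),
        name = S4Vectors::mcols(genes)$gene_id,
        score = 0L, strand = strand)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
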