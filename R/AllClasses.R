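#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' Phylogenetic species order
#'
#' Ordered species list with the reference genome first. The divergence index
#' `d` of the k-th species in the list is simply `k` (so the closest relative
#' of the reference has `d = 2`), mirroring how pairwise collinear segments
#' are labelled `2way-d` with `d` increasing with divergence from the
#' reference.
#'
#' @slot species character vector of species identifiers, reference first.
#' @export
setClass("PhyloOrder", representation(species = "character"))

setValidity("PhyloOrder", function(object) {
    sp <- object@species
    if (length(sp) < 1L) return("need at least one species")
    if (anyDuplicated(sp)) return("duplicated species identifiers")
    if (any(is.na(sp) | sp == "")) return("empty species identifier")
    TRUE
})

#' Construct a PhyloOrder
#'
#' @param species character vector, reference species first, remaining species
#'   in increasing order of divergence from the reference.
#' @return A [PhyloOrder-class] object.
#' @examples
#' phyloOrder(c("csa", "cme", "cla"))
#' @export
phyloOrder <- function(species) new("PhyloOrder", species = as.character(species))

#' Ontology DAG
#'
#' A directed acyclic graph of ontology terms with typed child-to-parent
#' edges (`is_a`, `part_of`), the substrate for Wang semantic similarity.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot weights named numeric, semantic contribution factor per relation,
#'   each in (0, 1).
#' @export
setClass("OntologyDag", representation(
    terms = "data.frame", edges = "data.frame", weights = "numeric"))

.dagTopoOrder <- function(ids, edges) {
    ## Kahn's algorithm on child -> parent edges; NULL if a cycle exists.
    indeg <- setNames(integer(length(ids)), ids)
    tab <- table(factor(edges$parent, levels = ids))
    indeg[names(tab)] <- as.integer(tab)
    kids <- split(edges$parent, factor(edges$child, levels = ids))
    queue <- ids[indeg == 0L]
    out <- character(0)
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        out <- c(out, v)
        for (p in kids[[v]]) {
            indeg[p] <- indeg[p] - 1L
            if (indeg[p] == 0L) queue <- c(queue, p)
        }
    }
    if (length(out) != length(ids)) NULL else out
}

.dagFindCycle <- function(ids, edges) {
    ## one representative cycle, for error reporting
    parents <- split(edges$parent, factor(edges$child, levels = ids))
    state <- setNames(integer(length(ids)), ids)  # 0 white 1 grey 2 black
    path <- character(0)
    found <- NULL
    visit <- function(v) {
        if (!is.null(found)) return()
        state[v] <<- 1L
        path <<- c(path, v)
        for (p in parents[[v]]) {
            if (state[p] == 1L) {
                found <<- c(path[which(path == p)[1L]:length(path)], p)
                return()
            }
            if (state[p] == 0L) visit(p)
            if (!is.null(found)) return()
        }
        state[v] <<- 2L
        path <<- path[-length(path)]
    }
    for (v in ids) if (state[v] == 0L) visit(v)
    found
}

setValidity("OntologyDag", function(object) {
    tm <- object@terms; ed <- object@edges
    if (!all(c("id", "name", "namespace") %in% names(tm)))
        return("terms needs columns id, name, namespace")
    if (!all(c("child", "parent", "relation") %in% names(ed)))
        return("edges needs columns child, parent, relation")
    if (anyDuplicated(tm$id)) return("duplicated term ids")
    if (nrow(ed)) {
        if (!all(ed$child %in% tm$id) || !all(ed$parent %in% tm$id))
            return("edge references unknown term")
        if (!all(ed$relation %in% names(object@weights)))
            return("edge relation without a weight")
    }
    if (any(object@weights <= 0 | object@weights >= 1))
        return("relation weights must lie in (0, 1)")
    if (is.null(.dagTopoOrder(tm$id, ed))) {
        cyc <- .dagFindCycle(tm$id, ed)
        return(paste0("cycle detected: ", paste(cyc, collapse = " -> ")))
    }
    TRUE
})

#' Construct an OntologyDag
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (child-to-parent direction).
#' @param weights named numeric vector of semantic contribution factors per
#'   relation; defaults to the canonical Wang constants `is_a = 0.8`,
#'   `part_of = 0.6`.
#' @return An [OntologyDag-class].
#' @export
ontologyDag <- function(terms, edges = NULL,
                        weights = c(is_a = 0.8, part_of = 0.6)) {
    if (is.null(edges) || !nrow(edges))
        edges <- data.frame(child = character(0), parent = character(0),
                            relation = character(0))
    terms <- data.frame(id = as.character(terms$id),
                        name = as.character(terms$name),
                        namespace = as.character(terms$namespace))
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        relation = as.character(edges$relation))
    new("OntologyDag", terms = terms, edges = edges, weights = weights)
}

#' Annotation set
#'
#' An annotation result as the triplet (P, G, GO): the de-duplicated
#' gene-term pairs P, the covered genes G and the covered terms GO (G and GO
#' are projections of P and are derived, not stored). Optional provenance
#' records which ortholog contributed each transferred pair and with what
#' support score.
#'
#' @slot pairs data.frame with columns `gene`, `term`, unique rows.
#' @slot provenance data.frame with columns `gene`, `term`, `source_gene`,
#'   `source_species`, `opss` (possibly zero rows).
#' @export
setClass("AnnotationSet", representation(
    pairs = "data.frame", provenance = "data.frame"))

setValidity("AnnotationSet", function(object) {
    p <- object@pairs
    if (!all(c("gene", "term") %in% names(p)))
        return("pairs needs columns gene, term")
    if (anyDuplicated(paste(p$gene, p$term, sep = "\r")))
        return("duplicated gene-term pairs")
    pr <- object@provenance
    need <- c("gene", "term", "source_gene", "source_species", "opss")
    if (!all(need %in% names(pr)))
        return("provenance needs columns gene, term, source_gene, source_species, opss")
    if (nrow(pr)) {
        key <- paste(p$gene, p$term, sep = "\r")
        if (!all(paste(pr$gene, pr$term, sep = "\r") %in% key))
            return("provenance entry for a pair not in P")
    }
    TRUE
})

.emptyProvenance <- function()
    data.frame(gene = character(0), term = character(0),
               source_gene = character(0), source_species = character(0),
               opss = numeric(0))

#' Construct an AnnotationSet
#'
#' @param pairs data.frame with columns `gene`, `term`; duplicate rows are
#'   collapsed.
#' @param provenance optional data.frame with columns `gene`, `term`,
#'   `source_gene`, `source_species`, `opss`.
#' @return An [AnnotationSet-class].
#' @examples
#' annotationSet(data.frame(gene = c("g1", "g1", "g2"),
#'                          term = c("T1", "T2", "T1")))
#' @export
annotationSet <- function(pairs, provenance = NULL) {
    pairs <- data.frame(gene = as.character(pairs$gene),
                        term = as.character(pairs$term))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs$gene, pairs$term), , drop = FALSE]
    rownames(pairs) <- NULL
    if (is.null(provenance)) provenance <- .emptyProvenance()
    new("AnnotationSet", pairs = pairs, provenance = provenance)
}

#' Collinear segment set
#'
#' The result of anchor chaining between two (or more) genomes: one row per
#' detected segment plus, per segment, the ordered list of homologous marker
#' pairs (the anchor points) it chains.
#'
#' @slot table data.frame, one row per segment, with columns `segment_id`,
#'   `species_a`, `species_b`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `n_anchors`, `orientation`, `p_value`.
#' @slot anchors list (parallel to `table` rows) of data.frames with columns
#'   `marker_a`, `marker_b`, `rank_a`, `rank_b`.
#' @slot params list of the detection parameters used.
#' @export
setClass("CollinearSegments", representation(
    table = "data.frame", anchors = "list", params = "list"))

setValidity("CollinearSegments", function(object) {
    tb <- object@table
    need <- c("segment_id", "species_a", "species_b", "chrom_a", "start_a",
              "end_a", "chrom_b", "start_b", "end_b", "n_anchors",
              "orientation", "p_value")
    if (!all(need %in% names(tb)))
        return(paste("table missing columns:",
                     paste(setdiff(need, names(tb)), collapse = ", ")))
    if (length(object@anchors) != nrow(tb))
        return("anchors list length != number of segments")
    if (nrow(tb) && !all(tb$orientation %in% c("same", "inverted")))
        return("orientation must be 'same' or 'inverted'")
    if (nrow(tb) && any(tb$n_anchors != vapply(object@anchors, nrow, 0L)))
        return("n_anchors inconsistent with anchor tables")
    TRUE
})

#' Synthetic comparative-genomics world
#'
#' A seeded bundle of everything the pipeline consumes, with planted truth:
#' gene models for every species, alignment blocks covering planted anchors,
#' homology hits (true orthologs plus decoy paralogs), a layered ontology,
#' per-species truth annotations, and an expression matrix with planted
#' co-expressed term modules.
#'
#' @slot genes GRanges of all gene models (mcols: `gene_id`, `species`,
#'   `family`, `rank`).
#' @slot alignBlocks data.frame of alignment blocks in long format (columns
#'   `block`, `species`, `chrom`, `start`, `end`, `strand`, `src_size`,
#'   `text`).
#' @slot hits data.frame of homology hits (`query`, `subject`, `evalue`,
#'   `bitscore`).
#' @slot truthOrthologs data.frame of planted ortholog pairs (`gene_a`,
#'   `gene_b`, `species_b`, `family`).
#' @slot truthBlocks data.frame of planted collinear block extents per
#'   species.
#' @slot ontology an [OntologyDag-class].
#' @slot annotations named list of [AnnotationSet-class], one per annotated
#'   species.
#' @slot expression numeric matrix, genes x tissues, FPKM-like values.
#' @slot truthCoexpr character vector of term ids with planted co-expression.
#' @slot order a [PhyloOrder-class].
#' @slot chromLengths named list: species -> named numeric vector of
#'   chromosome lengths.
#' @slot config list, the generating configuration.
#' @export
setClass("SyntheticWorld", representation(
    genes = "GRanges", alignBlocks = "data.frame", hits = "data.frame",
    truthOrthologs = "data.frame", truthBlocks = "data.frame",
    ontology = "OntologyDag", annotations = "list", expression = "matrix",
    truthCoexpr = "character", order = "PhyloOrder", chromLengths = "list",
    config = "list"))

setValidity("SyntheticWorld", function(object) {
    if (nrow(object@expression) && any(object@expression < 0))
        return("expression values must be non-negative")
    if (!all(names(object@annotations) %in% object@order@species))
        return("annotation for species absent from the phylo order")
    TRUE
})
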