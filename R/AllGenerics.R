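#' @include AllClasses.R
NULL

#' Accessors for synortho classes
#'
#' `refSpecies` returns the reference species of a [PhyloOrder-class];
#' `speciesOrder` the full ordered species vector; `dIndex` the divergence
#' index map (species -> d, reference excluded). `annPairs`, `annGenes` and
#' `annTerms` return the P, G and GO components of an
#' [AnnotationSet-class]; `annProvenance` its provenance table. `segTable`
#' and `segAnchors` return the segment table and anchor-pair list of a
#' [CollinearSegments-class].
#'
#' @param x the object.
#' @return See the description per accessor.
#' @examples
#' ord <- phyloOrder(c("csa", "cme", "cla"))
#' refSpecies(ord)
#' dIndex(ord)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refSpecies", function(x) standardGeneric("refSpecies"))
#' @rdname accessors
#' @export
setGeneric("speciesOrder", function(x) standardGeneric("speciesOrder"))
#' @rdname accessors
#' @export
setGeneric("dIndex", function(x) standardGeneric("dIndex"))
#' @rdname accessors
#' @export
setGeneric("annPairs", function(x) standardGeneric("annPairs"))
#' @rdname accessors
#' @export
setGeneric("annGenes", function(x) standardGeneric("annGenes"))
#' @rdname accessors
#' @export
setGeneric("annTerms", function(x) standardGeneric("annTerms"))
#' @rdname accessors
#' @export
setGeneric("annProvenance", function(x) standardGeneric("annProvenance"))
#' @rdname accessors
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))
#' @rdname accessors
#' @export
setGeneric("segAnchors", function(x) standardGeneric("segAnchors"))

#' @rdname accessors
setMethod("refSpecies", "PhyloOrder", function(x) x@species[1L])
#' @rdname accessors
setMethod("speciesOrder", "PhyloOrder", function(x) x@species)
#' @rdname accessors
setMethod("dIndex", "PhyloOrder", function(x) {
    if (length(x@species) < 2L) return(setNames(integer(0), character(0)))
    setNames(seq_along(x@species)[-1L], x@species[-1L])
})

#' @rdname accessors
setMethod("annPairs", "AnnotationSet", function(x) x@pairs)
#' @rdname accessors
setMethod("annGenes", "AnnotationSet", function(x) sort(unique(x@pairs$gene)))
#' @rdname accessors
setMethod("annTerms", "AnnotationSet", function(x) sort(unique(x@pairs$term)))
#' @rdname accessors
setMethod("annProvenance", "AnnotationSet", function(x) x@provenance)

#' @rdname accessors
setMethod("segTable", "CollinearSegments", function(x) x@table)
#' @rdname accessors
setMethod("segAnchors", "CollinearSegments", function(x) x@anchors)

setMethod("length", "CollinearSegments", function(x) nrow(x@table))

setMethod("show", "PhyloOrder", function(object) {
    cat("PhyloOrder with", length(object@species), "species\n")
    cat("  reference:", object@species[1L], "\n")
    if (length(object@species) > 1L)
        cat("  partners (d=2..):",
            paste(object@species[-1L], collapse = ", "), "\n")
})

setMethod("show", "OntologyDag", function(object) {
    cat("OntologyDag:", nrow(object@terms), "terms,",
        nrow(object@edges), "edges\n")
    ns <- table(object@terms$namespace)
    cat("  namespaces:",
        paste(sprintf("%s (%d)", names(ns), as.integer(ns)), collapse = ", "),
        "\n")
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet: |P| =", nrow(object@pairs),
        "pairs, |G| =", length(unique(object@pairs$gene)),
        "genes, |GO| =", length(unique(object@pairs$term)), "terms\n")
    if (nrow(object@provenance))
        cat("  with provenance for", nrow(object@provenance), "entries\n")
})

setMethod("show", "CollinearSegments", function(object) {
    cat("CollinearSegments:", nrow(object@table), "segments\n")
    if (nrow(object@table)) {
        cat("  species pairs:",
            paste(unique(paste(object@table$species_a, object@table$species_b,
                               sep = "~")), collapse = ", "), "\n")
        cat("  anchors per segment:",
            paste(range(object@table$n_anchors), collapse = "-"), "\n")
    }
})

setMethod("show", "SyntheticWorld", function(object) {
    cat("SyntheticWorld:", length(speciesOrder(object@order)), "species,",
        length(object@genes), "gene models,",
        length(unique(object@alignBlocks$block)), "alignment blocks\n")
    cat("  truth:", nrow(object@truthOrthologs), "ortholog pairs,",
        length(unique(object@truthBlocks$block_id)), "planted blocks,",
        length(object@truthCoexpr), "co-expressed terms\n")
})
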