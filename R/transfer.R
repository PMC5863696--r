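#' Transfer ontology annotations through ortholog pairs
#'
#' Each target-species gene receives the union of the terms of all its
#' orthologs in annotated species; pairs to species without an annotation
#' set are skipped silently. Provenance records every contributing ortholog
#' together with its OPSS.
#'
#' @param opps OPP data.frame from [inferOpps()] (`gene_a` is the target
#'   side, `gene_b`/`species_b` the source side).
#' @param sourceAnnotations named list of [AnnotationSet-class], keyed by
#'   source species.
#' @param targetSpecies label recorded for the target (informational).
#' @return An [AnnotationSet-class] for the target species, with
#'   provenance.
#' @export
transferAnnotations <- function(opps, sourceAnnotations,
                                targetSpecies = "ref") {
    prov <- list()
    for (sp in names(sourceAnnotations)) {
        rows <- opps[opps$species_b == sp, , drop = FALSE]
        if (!nrow(rows)) next
        src <- annPairs(sourceAnnotations[[sp]])
        m <- merge(rows[, c("gene_a", "gene_b", "opss")], src,
                   by.x = "gene_b", by.y = "gene")
        if (!nrow(m)) next
        prov[[length(prov) + 1L]] <- data.frame(
            gene = m$gene_a, term = m$term, source_gene = m$gene_b,
            source_species = sp, opss = m$opss)
    }
    if (!length(prov))
        return(annotationSet(data.frame(gene = character(0),
                                        term = character(0))))
    prov <- do.call(rbind, prov)
    prov <- prov[order(prov$gene, prov$term, prov$source_species,
                       prov$source_gene), , drop = FALSE]
    rownames(prov) <- NULL
    annotationSet(prov[, c("gene", "term")], provenance = prov)
}

#' Filter terms by annotated gene count
#'
#' A term is retained iff its gene count in the annotation set lies in
#' `[minGenes, maxGenes]` (the defaults drop terms with fewer than five or
#' more than 300 associated genes); P, G and GO are re-derived after the
#' removal, and provenance is restricted to the surviving pairs.
#'
#' @param annset An [AnnotationSet-class].
#' @param minGenes,maxGenes inclusive retention bounds on the per-term gene
#'   count.
#' @return the filtered [AnnotationSet-class].
#' @export
filterTermSizes <- function(annset, minGenes = 5L, maxGenes = 300L) {
    p <- annPairs(annset)
    sz <- vapply(split(p$gene, p$term), function(g) length(unique(g)), 0L)
    keep <- names(sz)[sz >= minGenes & sz <= maxGenes]
    p2 <- p[p$term %in% keep, , drop = FALSE]
    prov <- annProvenance(annset)
    if (nrow(prov))
        prov <- prov[prov$term %in% keep, , drop = FALSE]
    annotationSet(p2, provenance = prov)
}

#' Summary statistics of an annotation set
#'
#' @param annset An [AnnotationSet-class].
#' @param geneUniverse optional character vector (or count) of the gene
#'   universe used for the coverage fraction.
#' @return list with `n_genes`, `n_terms`, `n_pairs`,
#'   `mean_terms_per_gene`, `mean_genes_per_term` and `coverage` (fraction
#'   of the universe annotated; `NA` without a universe).
#' @export
annotationSummary <- function(annset, geneUniverse = NULL) {
    p <- annPairs(annset)
    nG <- length(unique(p$gene)); nT <- length(unique(p$term))
    universe <- if (is.null(geneUniverse)) NA_real_
                else if (is.numeric(geneUniverse)) geneUniverse
                else length(unique(geneUniverse))
    list(n_genes = nG, n_terms = nT, n_pairs = nrow(p),
         mean_terms_per_gene = if (nG) nrow(p) / nG else 0,
         mean_genes_per_term = if (nT) nrow(p) / nT else 0,
         coverage = if (is.na(universe)) NA_real_ else nG / universe)
}
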