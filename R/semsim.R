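#' Jaccard similarity of two sets
#'
#' `|A n B| / |A u B|`, defined as 1 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return value in \[0, 1\].
#' @examples
#' jaccardIndex(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
}

## S-values of a term's ancestor closure: S(term) = 1 and, walking upward,
## S(t) = max over child edges (child in the closure) of weight * S(child).
.wangSValues <- function(dag, term) {
    ed <- dag@edges
    ## ancestor closure by BFS on child -> parent edges
    anc <- term
    frontier <- term
    while (length(frontier)) {
        parents <- unique(ed$parent[ed$child %in% frontier])
        frontier <- setdiff(parents, anc)
        anc <- c(anc, frontier)
    }
    s <- setNames(numeric(length(anc)), anc)
    s[term] <- 1
    sub <- ed[ed$child %in% anc & ed$parent %in% anc, , drop = FALSE]
    w <- unname(dag@weights[sub$relation])
    ## relaxation to fixed point (the closure is a DAG, so this terminates
    ## after at most |closure| sweeps)
    repeat {
        changed <- FALSE
        if (nrow(sub)) {
            cand <- w * s[sub$child]
            for (i in seq_len(nrow(sub))) {
                p <- sub$parent[i]
                if (cand[i] > s[p]) { s[p] <- cand[i]; changed <- TRUE }
            }
        }
        if (!changed) break
    }
    s
}

#' Wang semantic similarity of two ontology terms
#'
#' S-values are propagated upward from each term through its ancestor
#' closure with relation-specific weights; the similarity is the summed
#' S-value mass on the shared ancestors (terms included) over the total
#' semantic value of both terms. Identical terms score 1.
#'
#' @param dag An [OntologyDag-class].
#' @param termA,termB term identifiers, same namespace.
#' @return value in (0, 1\].
#' @export
wangTermSim <- function(dag, termA, termB) {
    tm <- dag@terms
    if (!termA %in% tm$id || !termB %in% tm$id)
        stop("term not in the ontology")
    nsA <- tm$namespace[tm$id == termA]
    nsB <- tm$namespace[tm$id == termB]
    if (nsA != nsB)
        stop("cross-namespace similarity is undefined (", nsA, " vs ",
             nsB, ")")
    sA <- .wangSValues(dag, termA)
    sB <- .wangSValues(dag, termB)
    shared <- intersect(names(sA), names(sB))
    sum(sA[shared] + sB[shared]) / (sum(sA) + sum(sB))
}

#' Semantic similarity of two term sets (one gene, two annotations)
#'
#' Best-match average: every term of one set is matched to its most
#' similar term in the other set, and the two directional means are
#' averaged.
#'
#' @param dag An [OntologyDag-class].
#' @param termsA,termsB non-empty character vectors of same-namespace term
#'   ids.
#' @return value in \[0, 1\].
#' @export
geneSemanticSim <- function(dag, termsA, termsB) {
    termsA <- unique(termsA); termsB <- unique(termsB)
    if (!length(termsA) || !length(termsB))
        stop("both term sets must be non-empty")
    sim <- matrix(0, length(termsA), length(termsB))
    for (i in seq_along(termsA))
        for (j in seq_along(termsB))
            sim[i, j] <- wangTermSim(dag, termsA[i], termsB[j])
    (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
}

#' Compare two annotation sets
#'
#' Three indices: Jaccard on the namespace-restricted gene-term pair sets
#' (structure free), Jaccard on the annotated gene sets (structure free),
#' and the mean gene-wise Wang semantic similarity over genes annotated by
#' both sets (structure based). Genes with an empty term set after the
#' namespace restriction are skipped and reported.
#'
#' @param annA,annB [AnnotationSet-class] objects.
#' @param dag An [OntologyDag-class].
#' @param namespace optional namespace to restrict terms to (e.g. `"MF"`);
#'   `NULL` keeps all terms.
#' @return list with `jaccard_pairs`, `jaccard_genes`, `semantic_mean`
#'   (`NA` when no gene is shared), `per_gene` (named numeric vector) and
#'   `skipped_genes`.
#' @export
pipelineSimilarity <- function(annA, annB, dag, namespace = NULL) {
    restrict <- function(ann) {
        p <- annPairs(ann)
        if (!is.null(namespace)) {
            keep <- dag@terms$id[dag@terms$namespace == namespace]
            p <- p[p$term %in% keep, , drop = FALSE]
        }
        p
    }
    pA <- restrict(annA); pB <- restrict(annB)
    jp <- jaccardIndex(paste(pA$gene, pA$term, sep = "\r"),
                       paste(pB$gene, pB$term, sep = "\r"))
    jg <- jaccardIndex(annGenes(annA), annGenes(annB))
    shared <- intersect(unique(pA$gene), unique(pB$gene))
    per <- numeric(0); skipped <- character(0)
    for (g in shared) {
        tA <- pA$term[pA$gene == g]; tB <- pB$term[pB$gene == g]
        if (!length(tA) || !length(tB)) { skipped <- c(skipped, g); next }
        per[g] <- geneSemanticSim(dag, tA, tB)
    }
    list(jaccard_pairs = jp, jaccard_genes = jg,
         semantic_mean = if (length(per)) mean(per) else NA_real_,
         per_gene = per, skipped_genes = skipped)
}

#' Pairwise similarity matrix across several annotation sets
#'
#' @param annList named list of [AnnotationSet-class] objects.
#' @param dag An [OntologyDag-class].
#' @param namespace optional namespace restriction.
#' @param index which index to tabulate (`"semantic_mean"`,
#'   `"jaccard_pairs"` or `"jaccard_genes"`).
#' @return symmetric numeric matrix.
#' @export
similarityMatrix <- function(annList, dag, namespace = NULL,
                             index = c("semantic_mean", "jaccard_pairs",
                                       "jaccard_genes")) {
    index <- match.arg(index)
    n <- length(annList)
    m <- matrix(NA_real_, n, n, dimnames = list(names(annList),
                                                names(annList)))
    for (i in seq_len(n)) {
        m[i, i] <- 1
        for (j in seq_len(i - 1L)) {
            v <- pipelineSimilarity(annList[[i]], annList[[j]], dag,
                                    namespace)[[index]]
            m[i, j] <- m[j, i] <- v
        }
    }
    m
}
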