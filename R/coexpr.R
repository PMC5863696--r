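## Pearson correlations for a set of gene pairs, via row-standardised
## profiles: r(i, j) = sum(z_i * z_j).
.standardiseRows <- function(X) {
    mu <- rowMeans(X)
    ctr <- X - mu
    ss <- sqrt(rowSums(ctr^2))
    ctr / ss
}

#' Co-expression test for one term's gene set
#'
#' The observed scores are the Pearson correlations of all within-term gene
#' pairs over the expression profiles; each repeat draws random gene pairs
#' from the matrix (zero-variance genes excluded on both sides), and a
#' one-sided two-sample Kolmogorov-Smirnov test asks whether the observed
#' correlations are stochastically greater than the random ones. The mean
#' p-value over the repeats is the term's final p-value.
#'
#' The null sample per repeat holds `max(100, n_pairs)` random pairs: at
#' the equal-n prescribed by the observed side the one-sided KS p is
#' noticeably conservative for small terms (the KS statistic is discrete in
#' steps of 1/n), and a larger null restores the nominal level.
#'
#' @param termGenes character vector of the term's genes.
#' @param X numeric expression matrix, genes x tissues (rownames = genes).
#' @param repeats number of null redraws averaged (default 100).
#' @param seed optional integer seed; fixing it makes the result exactly
#'   reproducible.
#' @param alpha significance level for the `significant` flag.
#' @param twoSided use the two-sided KS test instead of the one-sided
#'   "observed greater" default.
#' @param logTransform apply log2(x + 1) to the matrix before correlating.
#' @param term label used in messages.
#' @return list with `term`, `n_genes_in_matrix`, `n_pairs`, `mean_p`,
#'   `p_per_repeat`, `significant`.
#' @export
termCoexpressionTest <- function(termGenes, X, repeats = 100L, seed = NULL,
                                 alpha = 0.001, twoSided = FALSE,
                                 logTransform = FALSE, term = "term") {
    if (!is.null(seed)) set.seed(seed)
    if (logTransform) X <- log2(X + 1)
    usable <- rownames(X)[apply(X, 1L, stats::var) > 0]
    genes <- intersect(unique(termGenes), usable)
    if (length(genes) < 2L)
        stop("term '", term, "': fewer than 2 usable genes in the matrix")
    Z <- .standardiseRows(X[usable, , drop = FALSE])
    gi <- match(genes, usable)
    cm <- tcrossprod(Z[gi, , drop = FALSE])
    obs <- cm[upper.tri(cm)]
    nPairs <- length(obs)
    nNull <- max(100L, nPairs)
    nGenes <- length(usable)
    alt <- if (twoSided) "two.sided" else "less"
    ps <- vapply(seq_len(repeats), function(r) {
        ## sample distinct unordered pairs without replacement
        ii <- sample.int(nGenes, 2L * nNull, replace = TRUE)
        p1 <- ii[seq_len(nNull)]
        p2 <- ii[nNull + seq_len(nNull)]
        bad <- p1 == p2
        while (any(bad)) {
            p2[bad] <- sample.int(nGenes, sum(bad), replace = TRUE)
            bad <- p1 == p2
        }
        key <- paste(pmin(p1, p2), pmax(p1, p2))
        dup <- duplicated(key)
        while (any(dup)) {
            p2[dup] <- sample.int(nGenes, sum(dup), replace = TRUE)
            bad <- p1 == p2
            while (any(bad)) {
                p2[bad] <- sample.int(nGenes, sum(bad), replace = TRUE)
                bad <- p1 == p2
            }
            key <- paste(pmin(p1, p2), pmax(p1, p2))
            dup <- duplicated(key)
        }
        nul <- rowSums(Z[p1, , drop = FALSE] * Z[p2, , drop = FALSE])
        suppressWarnings(stats::ks.test(obs, nul,
                                        alternative = alt)$p.value)
    }, 0)
    meanP <- mean(ps)
    list(term = term, n_genes_in_matrix = length(genes), n_pairs = nPairs,
         mean_p = meanP, p_per_repeat = ps, significant = meanP < alpha)
}

#' Co-expression validation of an annotation set
#'
#' Terms are filtered by their gene count among matrix-present genes
#' (default 5..300), each surviving term is tested with
#' [termCoexpressionTest()], and the fraction of terms significant at
#' `alpha` is reported per ontology namespace and overall.
#'
#' @param annset An [AnnotationSet-class].
#' @param X expression matrix (genes x tissues).
#' @param dag An [OntologyDag-class] supplying term namespaces.
#' @param alpha significance level (default 0.001).
#' @param termSizeLimits inclusive (min, max) on per-term matrix-present
#'   gene counts.
#' @param repeats,seed forwarded to [termCoexpressionTest()]; per-term
#'   seeds are derived from `seed` so terms are independent but the whole
#'   summary is reproducible.
#' @return list with `terms` (per-term data.frame: `term`, `namespace`,
#'   `n_genes`, `mean_p`, `significant`) and `summary` (per-namespace
#'   data.frame `namespace`, `n_terms_tested`, `n_significant`, `ratio`;
#'   the `ratio` is `NA` where nothing was testable, and an `overall` row
#'   is appended).
#' @export
validationSummary <- function(annset, X, dag, alpha = 0.001,
                              termSizeLimits = c(5L, 300L),
                              repeats = 100L, seed = NULL) {
    p <- annPairs(annset)
    present <- p[p$gene %in% rownames(X), , drop = FALSE]
    sizes <- vapply(split(present$gene, present$term),
                    function(g) length(unique(g)), 0L)
    testable <- names(sizes)[sizes >= termSizeLimits[1L] &
                             sizes <= termSizeLimits[2L]]
    nsOf <- setNames(dag@terms$namespace, dag@terms$id)
    rows <- list()
    for (i in seq_along(testable)) {
        t <- testable[i]
        genes <- unique(present$gene[present$term == t])
        res <- termCoexpressionTest(
            genes, X, repeats = repeats,
            seed = if (is.null(seed)) NULL else seed + i,
            alpha = alpha, term = t)
        rows[[i]] <- data.frame(
            term = t,
            namespace = if (t %in% names(nsOf)) unname(nsOf[t])
                        else "unknown",
            n_genes = res$n_genes_in_matrix, mean_p = res$mean_p,
            significant = res$significant)
    }
    terms <- if (length(rows)) do.call(rbind, rows)
             else data.frame(term = character(0), namespace = character(0),
                             n_genes = integer(0), mean_p = numeric(0),
                             significant = logical(0))
    tally <- function(df, label) data.frame(
        namespace = label, n_terms_tested = nrow(df),
        n_significant = sum(df$significant),
        ratio = if (nrow(df)) sum(df$significant) / nrow(df) else NA_real_)
    parts <- lapply(sort(unique(terms$namespace)), function(ns)
        tally(terms[terms$namespace == ns, , drop = FALSE], ns))
    summary <- do.call(rbind, c(parts, list(tally(terms, "overall"))))
    rownames(summary) <- NULL
    list(terms = terms, summary = summary)
}
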