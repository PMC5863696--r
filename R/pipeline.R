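.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full annotation pipeline on a directory of inputs
#'
#' Stages, in order: anchor extraction from the MAF, collinearity detection
#' with MAA markers (default gap_size 30) and with gene markers (default
#' gap_size 10), level classification, ortholog-pair inference with OPSS
#' scoring, annotation transfer with the term-size filter, optional
#' comparison against supplied reference annotation sets, and optional
#' co-expression validation. Every stage writes its outputs under
#' `outDir`; a JSON manifest records per-stage outputs with md5 checksums,
#' so identical inputs, parameters and seed reproduce identical manifests.
#'
#' The input directory follows the [writeWorld()] layout:
#' `alignments.maf`, `genes_<species>.gff3`, `hits.tsv`, `ontology.obo`,
#' `annotations_<species>.tsv`, `expression.tsv`, `species_order.txt`.
#'
#' @param inputDir directory of pipeline inputs.
#' @param outDir output directory (created).
#' @param maaParams,geneParams [detectionParams()] for the two marker
#'   types.
#' @param minOverlap,evalueMax ortholog-inference thresholds.
#' @param termSizeLimits inclusive per-term gene-count bounds for the
#'   transfer filter.
#' @param alpha,repeats co-expression validation parameters.
#' @param seed root seed for all stochastic stages.
#' @param validate run the co-expression validation stage (requires
#'   `expression.tsv`).
#' @param compareWith optional named character vector of annotation-table
#'   paths for the target species to compare the transferred annotation
#'   against.
#' @param namespace optional namespace restriction for the comparison.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(inputDir, outDir,
                        maaParams = detectionParams(3L, 30L, 0.01),
                        geneParams = detectionParams(3L, 10L, 0.01),
                        minOverlap = 0.5, evalueMax = 1e-5,
                        termSizeLimits = c(5L, 300L), alpha = 0.001,
                        repeats = 100L, seed = 1L, validate = TRUE,
                        compareWith = NULL, namespace = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stages <- list()
    outputs <- character(0)
    emit <- function(stage, counts, files) {
        stages[[length(stages) + 1L]] <<- list(
            stage = stage, counts = counts,
            outputs = data.frame(path = basename(files),
                                 md5 = unname(tools::md5sum(files))))
        outputs <<- c(outputs, files)
    }
    order <- .stage("inputs",
        readPhyloOrder(file.path(inputDir, "species_order.txt")))
    sp <- speciesOrder(order); ref <- refSpecies(order)
    blocks <- .stage("inputs", readMaf(file.path(inputDir,
                                                 "alignments.maf")))
    genes <- .stage("inputs", {
        gl <- lapply(sp, function(s) readGeneModels(
            file.path(inputDir, sprintf("genes_%s.gff3", s)),
            "gff3", species = s))
        do.call(c, gl)
    })
    hits <- .stage("inputs", readHomologyTable(file.path(inputDir,
                                                         "hits.tsv")))
    dag <- .stage("inputs", readObo(file.path(inputDir, "ontology.obo")))

    ## stage: anchors
    maas <- .stage("maa", {
        a <- extractMaas(blocks, requiredSpecies = sp,
                         referenceSpecies = ref)
        writeAnchorsBed(a, file.path(outDir, "maas.bed"))
        a
    })
    emit("maa", list(n_anchors = length(maas)),
         file.path(outDir, "maas.bed"))

    ## stage: collinearity, MAA markers
    maaMaps <- maaMarkerMaps(blocks, sp)
    maaSegs <- .stage("collinearity_maa", {
        per <- lapply(sp[-1L], function(s) detectSegments(
            maaMaps[[ref]], maaMaps[[s]],
            buildHomologyPairs(maaMaps[[ref]], maaMaps[[s]]),
            maaParams, speciesA = ref, speciesB = s))
        segs <- do.call(combineSegments, per)
        writeSegmentsTsv(segs, file.path(outDir, "segments_maa.tsv"))
        segs
    })
    emit("collinearity_maa", list(n_segments = length(maaSegs)),
         file.path(outDir, "segments_maa.tsv"))

    ## stage: collinearity, gene markers
    gm <- S4Vectors::mcols(genes)
    geneMaps <- lapply(sp, function(s) {
        g <- genes[gm$species == s]
        mm <- markerMap(g, idCol = "gene_id")
        mm
    })
    names(geneMaps) <- sp
    geneSegs <- .stage("collinearity_genes", {
        per <- lapply(sp[-1L], function(s) detectSegments(
            geneMaps[[ref]], geneMaps[[s]],
            buildHomologyPairs(geneMaps[[ref]], geneMaps[[s]], hits,
                               evalueMax),
            geneParams, speciesA = ref, speciesB = s))
        segs <- do.call(combineSegments, per)
        writeSegmentsTsv(segs, file.path(outDir, "segments_genes.tsv"))
        segs
    })
    emit("collinearity_genes", list(n_segments = length(geneSegs)),
         file.path(outDir, "segments_genes.tsv"))

    ## stage: orthology
    opps <- .stage("orthology", {
        o <- inferOpps(genes, maaSegs, geneSegs, hits, order,
                       minOverlap = minOverlap, evalueMax = evalueMax)
        utils::write.table(o, file.path(outDir, "opps.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        o
    })
    emit("orthology", list(n_opps = nrow(opps),
                           n_bbh = sum(opps$is_bbh)),
         file.path(outDir, "opps.tsv"))

    ## stage: transfer
    transferred <- .stage("transfer", {
        annFiles <- file.path(inputDir,
                              sprintf("annotations_%s.tsv", sp[-1L]))
        have <- file.exists(annFiles)
        src <- lapply(annFiles[have], readAnnotationTable, dag = dag)
        names(src) <- sp[-1L][have]
        tr <- transferAnnotations(opps, src, targetSpecies = ref)
        tr <- filterTermSizes(tr, termSizeLimits[1L], termSizeLimits[2L])
        writeAnnotationTable(tr, file.path(outDir, "annotation_ref.tsv"))
        tr
    })
    smry <- annotationSummary(transferred,
                              sum(gm$species == ref))
    emit("transfer", smry, file.path(outDir, "annotation_ref.tsv"))

    ## stage: compare (optional)
    if (!is.null(compareWith)) {
        cmp <- .stage("compare", {
            rows <- lapply(names(compareWith), function(lbl) {
                other <- readAnnotationTable(compareWith[[lbl]], dag = dag)
                r <- pipelineSimilarity(transferred, other, dag, namespace)
                data.frame(against = lbl, jaccard_pairs = r$jaccard_pairs,
                           jaccard_genes = r$jaccard_genes,
                           semantic_mean = r$semantic_mean)
            })
            tb <- do.call(rbind, rows)
            utils::write.table(tb, file.path(outDir, "comparison.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            tb
        })
        emit("compare", list(n_comparisons = nrow(cmp)),
             file.path(outDir, "comparison.tsv"))
    }

    ## stage: validate (optional)
    exprPath <- file.path(inputDir, "expression.tsv")
    if (validate && file.exists(exprPath)) {
        val <- .stage("validate", {
            X <- readExpressionMatrix(exprPath)
            v <- validationSummary(transferred, X, dag, alpha = alpha,
                                   termSizeLimits = termSizeLimits,
                                   repeats = repeats, seed = seed)
            utils::write.table(v$terms,
                               file.path(outDir, "validation_terms.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            utils::write.table(v$summary,
                               file.path(outDir, "validation_summary.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            v
        })
        emit("validate",
             list(n_terms_tested =
                      val$summary$n_terms_tested[val$summary$namespace ==
                                                 "overall"],
                  n_significant =
                      val$summary$n_significant[val$summary$namespace ==
                                                "overall"]),
             file.path(outDir, c("validation_terms.tsv",
                                 "validation_summary.tsv")))
    }

    manifest <- list(seed = seed,
                     params = list(maa = maaParams, genes = geneParams,
                                   min_overlap = minOverlap,
                                   evalue_max = evalueMax,
                                   term_size_limits = termSizeLimits,
                                   alpha = alpha, repeats = repeats),
                     stages = stages)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Run the pipeline from a YAML configuration
#'
#' Thin wrapper mapping a YAML file of [runPipeline()] arguments
#' (`input_dir`, `out_dir`, `maa_gap_size`, `gene_gap_size`,
#' `anchor_points`, `prob_cutoff`, `min_overlap`, `evalue_max`,
#' `term_size_limits`, `alpha`, `repeats`, `seed`, `validate`) onto a
#' pipeline run.
#'
#' @param configPath path to the YAML file.
#' @return the manifest, invisibly.
#' @export
runPipelineConfig <- function(configPath) {
    cfg <- yaml::read_yaml(configPath)
    ap <- cfg$anchor_points %||% 3L
    pc <- cfg$prob_cutoff %||% 0.01
    runPipeline(
        inputDir = cfg$input_dir, outDir = cfg$out_dir,
        maaParams = detectionParams(ap, cfg$maa_gap_size %||% 30L, pc),
        geneParams = detectionParams(ap, cfg$gene_gap_size %||% 10L, pc),
        minOverlap = cfg$min_overlap %||% 0.5,
        evalueMax = cfg$evalue_max %||% 1e-5,
        termSizeLimits = unlist(cfg$term_size_limits %||% c(5L, 300L)),
        alpha = cfg$alpha %||% 0.001, repeats = cfg$repeats %||% 100L,
        seed = cfg$seed %||% 1L,
        validate = cfg$validate %||% TRUE)
}
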