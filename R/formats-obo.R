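#' Read an OBO 1.2 ontology
#'
#' Minimal reader for the `[Term]` stanza dialect: `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` lines are honoured;
#' terms flagged `is_obsolete: true` are excluded together with their
#' edges. Edges point child to parent. A cycle raises an error naming one
#' offending cycle (via the class validity check).
#'
#' @param path path to the OBO file.
#' @param weights relation weights forwarded to [ontologyDag()].
#' @return An [OntologyDag-class].
#' @export
readObo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    terms <- list(); edges <- list()
    cur <- NULL
    inTerm <- FALSE
    flush <- function() {
        if (is.null(cur) || isTRUE(cur$obsolete)) return()
        terms[[length(terms) + 1L]] <<- data.frame(
            id = cur$id, name = cur$name %||% cur$id,
            namespace = cur$namespace %||% "unknown")
        for (e in cur$edges)
            edges[[length(edges) + 1L]] <<- data.frame(
                child = cur$id, parent = e[2L], relation = e[1L])
    }
    for (ln in lines) {
        ln <- sub("!.*$", "", ln)   # strip trailing comments
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush(); cur <- list(edges = list()); inTerm <- TRUE; next
        }
        if (startsWith(ln, "[")) { flush(); cur <- NULL; inTerm <- FALSE; next }
        if (!inTerm || !nzchar(ln)) next
        if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
        else if (startsWith(ln, "name:"))
            cur$name <- trimws(sub("^name:", "", ln))
        else if (startsWith(ln, "namespace:"))
            cur$namespace <- trimws(sub("^namespace:", "", ln))
        else if (startsWith(ln, "is_obsolete:"))
            cur$obsolete <- grepl("true", ln)
        else if (startsWith(ln, "is_a:")) {
            tgt <- strsplit(trimws(sub("^is_a:", "", ln)), "[ \t]+")[[1L]][1L]
            cur$edges <- c(cur$edges, list(c("is_a", tgt)))
        } else if (startsWith(ln, "relationship:")) {
            f <- strsplit(trimws(sub("^relationship:", "", ln)),
                          "[ \t]+")[[1L]]
            if (length(f) >= 2L && f[1L] == "part_of")
                cur$edges <- c(cur$edges, list(c("part_of", f[2L])))
        }
    }
    flush()
    if (!length(terms))
        return(ontologyDag(data.frame(id = character(0), name = character(0),
                                      namespace = character(0)),
                           weights = weights))
    tm <- do.call(rbind, terms)
    ed <- if (length(edges)) do.call(rbind, edges) else NULL
    ## drop edges pointing at obsolete/unknown parents
    if (!is.null(ed)) ed <- ed[ed$parent %in% tm$id, , drop = FALSE]
    ontologyDag(tm, ed, weights = weights)
}

#' Write an OntologyDag as OBO 1.2
#'
#' @param dag an [OntologyDag-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeObo <- function(dag, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("format-version: 1.2", ""), con)
    ed <- dag@edges
    for (i in seq_len(nrow(dag@terms))) {
        t <- dag@terms[i, ]
        writeLines("[Term]", con)
        writeLines(paste0("id: ", t$id), con)
        writeLines(paste0("name: ", t$name), con)
        writeLines(paste0("namespace: ", t$namespace), con)
        te <- ed[ed$child == t$id, , drop = FALSE]
        for (j in seq_len(nrow(te))) {
            if (te$relation[j] == "is_a")
                writeLines(paste0("is_a: ", te$parent[j]), con)
            else
                writeLines(paste0("relationship: ", te$relation[j], " ",
                                  te$parent[j]), con)
        }
        writeLines("", con)
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
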