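#' Read a MAF multiple-alignment file
#'
#' Parses the MULTIZ dialect of MAF: each `a` line opens an alignment block,
#' followed by one `s` line per species row. MAF `s` coordinates are 0-based
#' with a length and may be given on the minus strand of the source
#' sequence; they are converted here to forward-strand, 1-based closed
#' intervals (the strand is kept in the `strand` column).
#'
#' The `src` field is split at the first "." into species and chromosome.
#'
#' @param path path to a MAF file.
#' @return data.frame in long format, one row per species row, with columns
#'   `block` (integer block index), `species`, `chrom`, `start`, `end`
#'   (1-based closed, forward strand), `strand`, `src_size` and `text`
#'   (aligned text, possibly `NA`).
#' @seealso [writeMaf()]
#' @export
readMaf <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    block <- 0L
    rows <- vector("list", sum(startsWith(lines, "s")))
    ri <- 0L
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (startsWith(ln, "a")) {
            block <- block + 1L
        } else if (startsWith(ln, "s")) {
            f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
            if (length(f) < 6L)
                stop("malformed s-line at line ", i, ": expected >= 6 fields")
            start0 <- suppressWarnings(as.numeric(f[3L]))
            size <- suppressWarnings(as.numeric(f[4L]))
            srcSize <- suppressWarnings(as.numeric(f[6L]))
            if (anyNA(c(start0, size, srcSize)) || size < 1)
                stop("malformed s-line at line ", i,
                     ": non-numeric or non-positive coordinates")
            if (!f[5L] %in% c("+", "-"))
                stop("malformed s-line at line ", i, ": bad strand")
            if (block == 0L)
                stop("s-line at line ", i, " before any 'a' line")
            sc <- strsplit(f[2L], ".", fixed = TRUE)[[1L]]
            if (length(sc) < 2L)
                stop("malformed s-line at line ", i,
                     ": src must be species.chrom")
            species <- sc[1L]
            chrom <- paste(sc[-1L], collapse = ".")
            if (f[5L] == "-") {
                fstart0 <- srcSize - (start0 + size)
            } else {
                fstart0 <- start0
            }
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                block = block, species = species, chrom = chrom,
                start = fstart0 + 1, end = fstart0 + size,
                strand = f[5L], src_size = srcSize,
                text = if (length(f) >= 7L) f[7L] else NA_character_)
        }
    }
    if (ri == 0L)
        return(data.frame(block = integer(0), species = character(0),
                          chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          src_size = numeric(0), text = character(0)))
    do.call(rbind, rows[seq_len(ri)])
}

#' Write alignment blocks as MAF
#'
#' Inverse of [readMaf()]: forward-strand intervals are converted back to
#' MAF's strand-relative, 0-based length-encoded coordinates. Rows with no
#' aligned text are written as runs of `N` of the interval length.
#'
#' @param blocks data.frame as returned by [readMaf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(blocks, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##maf version=1", con)
    for (b in unique(blocks$block)) {
        rows <- blocks[blocks$block == b, , drop = FALSE]
        writeLines("", con)
        writeLines("a score=0", con)
        for (j in seq_len(nrow(rows))) {
            r <- rows[j, ]
            size <- r$end - r$start + 1
            fstart0 <- r$start - 1
            start0 <- if (r$strand == "-") r$src_size - (fstart0 + size)
                      else fstart0
            txt <- r$text
            if (is.na(txt)) txt <- strrep("N", size)
            writeLines(sprintf("s %s.%s %d %d %s %d %s",
                               r$species, r$chrom, as.integer(start0),
                               as.integer(size), r$strand,
                               as.integer(r$src_size), txt), con)
        }
    }
    invisible(path)
}
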