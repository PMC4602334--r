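## Matrix TSV dialect: three header rows (locus ids, gene symbols,
## cytobands) over the locus columns; the first three columns of every row
## are sample_id, group, gleason (gleason may be NA). Data cells use the
## tokens HET / HOM / GAIN / OK / NA.

#' Read an aberration-call matrix from TSV
#'
#' Parses the package's sample-by-locus TSV dialect (see
#' [writeAberrationMatrix()] for the layout). Unknown state tokens,
#' duplicated sample or locus ids, and ragged rows raise an error naming
#' the offending row and column.
#'
#' @param path path to a TSV file.
#' @return An [AberrationExperiment-class].
#' @seealso [writeAberrationMatrix()]
#' @export
readAberrationMatrix <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 4L)
        stop("matrix file needs 3 header rows and at least one sample row")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    width <- lengths(cells)
    if (any(width != width[1L]))
        stop("ragged row(s): line ",
             paste(which(width != width[1L]), collapse = ", "))
    lead <- 3L
    lociIds <- cells[[1L]][-seq_len(lead)]
    genes <- cells[[2L]][-seq_len(lead)]
    bands <- cells[[3L]][-seq_len(lead)]
    if (anyDuplicated(lociIds))
        stop("duplicate locus id(s): ",
             paste(unique(lociIds[duplicated(lociIds)]), collapse = ", "))
    body <- cells[-seq_len(3L)]
    ids <- vapply(body, `[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate sample id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    grp <- vapply(body, `[`, "", 2L)
    gleason <- suppressWarnings(as.integer(vapply(body, `[`, "", 3L)))
    tok2state <- structure(names(.STATE_TOKENS), names = .STATE_TOKENS)
    calls <- matrix(NA_character_, length(lociIds), length(body),
                    dimnames = list(lociIds, ids))
    for (j in seq_along(body)) {
        tokens <- body[[j]][-seq_len(lead)]
        st <- tok2state[tokens]
        if (anyNA(st)) {
            bad <- which(is.na(st))[1L]
            stop("unknown state token '", tokens[bad], "' at line ",
                 j + 3L, ", locus ", lociIds[bad])
        }
        calls[, j] <- st
    }
    bands[bands == "NA"] <- NA_character_
    AberrationExperiment(calls,
        lociData = S4Vectors::DataFrame(notI_site_id = lociIds,
                                        gene_symbol = genes,
                                        cytoband = bands),
        sampleData = S4Vectors::DataFrame(group = grp, gleason = gleason,
                                          row.names = ids))
}

#' Write an aberration-call matrix as TSV
#'
#' Serializes an [AberrationExperiment-class] in a layout that round-trips
#' exactly through [readAberrationMatrix()]: header rows 1-3 carry the
#' locus ids, gene symbols and cytobands; each subsequent row is one
#' sample (`sample_id`, `group`, `gleason`, then one token per locus,
#' `HET`/`HOM`/`GAIN`/`OK`/`NA`).
#'
#' @param x an [AberrationExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAberrationMatrix <- function(x, path) {
    rd <- SummarizedExperiment::rowData(x)
    calls <- assay(x, "calls")
    gleason <- if ("gleason" %in% colnames(SummarizedExperiment::colData(x)))
        x$gleason else rep(NA_integer_, ncol(x))
    hdr <- c(
        paste(c("sample_id", "group", "gleason",
                as.character(rd$notI_site_id)), collapse = "\t"),
        paste(c(".", ".", ".", as.character(rd$gene_symbol)),
              collapse = "\t"),
        paste(c(".", ".", ".",
                ifelse(is.na(rd$cytoband), "NA",
                       as.character(rd$cytoband))), collapse = "\t"))
    rows <- vapply(seq_len(ncol(x)), function(j) {
        paste(c(colnames(x)[j], as.character(x$group)[j],
                ifelse(is.na(gleason[j]), "NA", gleason[j]),
                .STATE_TOKENS[calls[, j]]), collapse = "\t")
    }, "")
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Read a bisulfite clone grid from TSV
#'
#' The first header row is `clone` followed by CpG-position labels; labels
#' suffixed with `*` mark the CpG pairs that form the NotI site. Each data
#' row is a clone id followed by 1 (methylated), 0 (unmethylated) or NA.
#'
#' @param path path to a TSV file.
#' @return A [BisulfiteCloneGrid-class].
#' @seealso [bisulfiteSiteSummary()]
#' @export
readBisulfiteGrid <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    labels <- colnames(tab)[-1L]
    noti <- grep("\\*$", labels)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    colnames(m) <- sub("\\*$", "", labels)
    BisulfiteCloneGrid(m, notiPositions = noti)
}
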