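#' Per-group methylation/deletion frequencies
#'
#' Counts aberrant calls (`HET_LOSS` or `HOM_LOSS`) per locus and group.
#' Missing calls stay in the denominator and count as non-aberrant, so
#' every denominator equals the full group size, mirroring the reference
#' study's frequency tables.
#'
#' @param x an [AberrationExperiment-class].
#' @param groups character vector of group labels to tabulate (default:
#'   all groups present, in order of first appearance).
#' @return A [S4Vectors::DataFrame] with one row per (locus, group):
#'   `notI_site_id`, `gene_symbol`, `group`, `n_aberrant`, `n_total`,
#'   `fraction`, and a formatted `cell` ("73% (11/15)").
#' @examples
#' x <- generateCohort(defaultDesign(seed = 2))
#' head(groupFrequencies(x))
#' @export
groupFrequencies <- function(x, groups = unique(as.character(x$group))) {
    if (!length(groups)) stop("at least one group label is required")
    rd <- SummarizedExperiment::rowData(x)
    loss <- isLoss(assay(x, "calls"))
    res <- lapply(groups, function(gr) {
        j <- resolveGroups(x, gr)
        k <- as.integer(rowSums(loss[, j, drop = FALSE]))
        S4Vectors::DataFrame(
            notI_site_id = as.character(rd$notI_site_id),
            gene_symbol = as.character(rd$gene_symbol),
            group = gr, n_aberrant = k, n_total = length(j),
            fraction = k / length(j),
            cell = formatFrequencyCell(k, length(j)))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Filter loci altered in more than a given fraction of tumors
#'
#' Keeps loci whose pooled frequency of any change (loss or gain) across
#' the selected tumor samples strictly exceeds `minFraction`. With the
#' default 10% cutoff this is the reference study's clone filter.
#'
#' @param x an [AberrationExperiment-class].
#' @param tumorGroups group labels pooled as "tumors" (default: every
#'   group except `normal`).
#' @param minFraction retention cutoff in `[0,1]` (strict inequality).
#' @return The `rowData` rows of the retained loci, with an extra
#'   `changed_fraction` column.
#' @examples
#' x <- generateCohort(defaultDesign(seed = 2))
#' nrow(filterAlteredLoci(x, minFraction = 0.10))
#' @export
filterAlteredLoci <- function(x,
                              tumorGroups = setdiff(
                                  unique(as.character(x$group)), "normal"),
                              minFraction = 0.10) {
    stopifnot(minFraction >= 0, minFraction <= 1)
    j <- resolveGroups(x, tumorGroups)
    calls <- assay(x, "calls")[, j, drop = FALSE]
    changed <- isLoss(calls) | calls == "GAIN"
    frac <- rowSums(changed) / length(j)
    keep <- frac > minFraction
    out <- SummarizedExperiment::rowData(x)[keep, , drop = FALSE]
    out$changed_fraction <- frac[keep]
    out
}

#' Census of alteration types over the whole matrix
#'
#' @param x an [AberrationExperiment-class].
#' @return Named integer vector with counts `het_loss`, `hom_loss`,
#'   `gain`, `unchanged`, `missing`; the counts always sum to
#'   `nrow(x) * ncol(x)`.
#' @examples
#' alterationCensus(generateCohort(defaultDesign(seed = 2)))
#' @export
alterationCensus <- function(x) {
    calls <- assay(x, "calls")
    counts <- vapply(.CALL_STATES, function(s) sum(calls == s), integer(1))
    names(counts) <- tolower(names(counts))
    counts
}

#' Rank loci by pooled methylation/deletion frequency
#'
#' Orders loci by their aberrant-call frequency pooled over the selected
#' tumor samples, descending, ties broken lexicographically by NotI-site
#' id, and emits per-group "percent (k/n)" cells in the layout of the
#' reference study's top-loci table.
#'
#' @inheritParams filterAlteredLoci
#' @param topN number of rows to return (default: all loci).
#' @return A [S4Vectors::DataFrame] ordered by `pooled_fraction`
#'   descending, with one formatted frequency column per group.
#' @examples
#' x <- generateCohort(defaultDesign(seed = 2))
#' rankLociTable(x, topN = 5)
#' @export
rankLociTable <- function(x, topN = nrow(x),
                          tumorGroups = setdiff(
                              unique(as.character(x$group)), "normal")) {
    stopifnot(topN <= nrow(x))
    rd <- SummarizedExperiment::rowData(x)
    j <- resolveGroups(x, tumorGroups)
    loss <- isLoss(assay(x, "calls"))
    pooled <- rowSums(loss[, j, drop = FALSE]) / length(j)
    out <- S4Vectors::DataFrame(
        notI_site_id = as.character(rd$notI_site_id),
        gene_symbol = as.character(rd$gene_symbol),
        cytoband = as.character(rd$cytoband),
        pooled_fraction = pooled)
    for (gr in tumorGroups) {
        jj <- resolveGroups(x, gr)
        k <- as.integer(rowSums(loss[, jj, drop = FALSE]))
        out[[gr]] <- formatFrequencyCell(k, length(jj))
    }
    ord <- order(-out$pooled_fraction, out$notI_site_id)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out[seq_len(topN), , drop = FALSE]
}

#' Summarize a bisulfite clone grid
#'
#' Computes the NotI-site methylation fraction (clones methylated at every
#' designated NotI CpG, among clones informative at all those positions)
#' and the per-clone methylation density over informative CpGs.
#'
#' @param grid a [BisulfiteCloneGrid-class].
#' @return List with `notI_fraction` (scalar in `[0,1]`, `NaN` when no
#'   clone is informative at the NotI site) and `per_clone_density`
#'   (named numeric vector).
#' @examples
#' g <- BisulfiteCloneGrid(matrix(c(1, 1, 0, 1, 1, 0, 0, 1), 2),
#'                         notiPositions = 1:2)
#' bisulfiteSiteSummary(g)
#' @export
bisulfiteSiteSummary <- function(grid) {
    validObject(grid)
    m <- grid@calls
    noti <- m[, grid@notiPositions, drop = FALSE]
    informative <- rowSums(is.na(noti)) == 0L
    methylated <- informative & rowSums(noti == 1L) == ncol(noti)
    dens <- apply(m, 1L, function(r) {
        r <- r[!is.na(r)]
        if (!length(r)) NaN else mean(r == 1L)
    })
    list(notI_fraction = sum(methylated) / sum(informative),
         per_clone_density = dens)
}

#' Relative expression from qPCR Cq values (delta-delta-Cq)
#'
#' Normalizes each sample's target Cq against the mean Cq of its
#' reference genes (the log-scale equivalent of a geometric mean of
#' linear quantities), subtracts the calibrator's normalized value, and
#' reports `fold = 2^(-ddCq)`. Fold changes of at least 2 in either
#' direction are called `up` / `down`, anything else `unchanged`.
#'
#' @param targetCq numeric vector, target-gene Cq per sample.
#' @param referenceCq numeric matrix (samples x reference genes) of
#'   reference-gene Cqs; a vector is treated as a single sample's
#'   references.
#' @param calibratorTargetCq scalar target Cq of the calibrator sample.
#' @param calibratorReferenceCq numeric vector of the calibrator's
#'   reference-gene Cqs.
#' @return A `data.frame` with `dd_cq`, `fold_change` and `call` (one of
#'   `down`, `unchanged`, `up`) per sample.
#' @examples
#' qpcrFoldChange(25, c(20, 21, 19), 23.415, c(20, 21, 19))  # ~3x down
#' @export
qpcrFoldChange <- function(targetCq, referenceCq, calibratorTargetCq,
                           calibratorReferenceCq) {
    if (is.vector(referenceCq))
        referenceCq <- matrix(referenceCq, nrow = 1L)
    if (!all(is.finite(targetCq)) || !all(is.finite(referenceCq)) ||
        !is.finite(calibratorTargetCq) ||
        !all(is.finite(calibratorReferenceCq)))
        stop("all Cq values must be finite")
    stopifnot(length(targetCq) == nrow(referenceCq))
    dCq <- targetCq - rowMeans(referenceCq)
    dCal <- calibratorTargetCq - mean(calibratorReferenceCq)
    ddCq <- dCq - dCal
    fold <- 2^(-ddCq)
    call <- ifelse(fold <= 0.5, "down", ifelse(fold >= 2, "up", "unchanged"))
    data.frame(dd_cq = ddCq, fold_change = fold, call = call,
               stringsAsFactors = FALSE)
}
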