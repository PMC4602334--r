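#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Valid per-cell states of the NotI-microarray assay. HET_LOSS and HOM_LOSS
## jointly mean "methylation and/or deletion" (the assay cannot separate the
## two mechanisms); GAIN is amplification/demethylation.
.CALL_STATES <- c("HET_LOSS", "HOM_LOSS", "GAIN", "UNCHANGED", "MISSING")

## States counted as aberrant ("methylation/deletion") downstream.
.LOSS_STATES <- c("HET_LOSS", "HOM_LOSS")

## On-disk tokens of the matrix TSV dialect.
.STATE_TOKENS <- c(HET_LOSS = "HET", HOM_LOSS = "HOM", GAIN = "GAIN",
                   UNCHANGED = "OK", MISSING = "NA")

.GROUP_LEVELS <- c("adenoma", "cancer_le7", "cancer_gt7", "normal")

#' AberrationExperiment: sample x locus NotI aberration calls
#'
#' The central container of the package: a
#' [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"calls"` is a character matrix of per-locus, per-sample aberration
#' states, one of `HET_LOSS`, `HOM_LOSS`, `GAIN`, `UNCHANGED`, `MISSING`.
#' Rows are NotI clones (loci), columns are samples. `rowData()` carries
#' the locus annotation (`notI_site_id`, `gene_symbol`, `cytoband`),
#' `colData()` the per-sample `group` (one of `adenoma`, `cancer_le7`,
#' `cancer_gt7`, `normal`) and an optional integer `gleason`.
#'
#' @aliases AberrationExperiment-class
#' @seealso [AberrationExperiment()] for the constructor,
#'   [aberrationCalls()], [sampleGroups()], [generateCohort()].
#' @export
setClass("AberrationExperiment", contains = "SummarizedExperiment")

setValidity("AberrationExperiment", function(object) {
    msg <- character()
    if (!"calls" %in% assayNames(object))
        return("assay 'calls' is required")
    calls <- assay(object, "calls")
    if (!is.character(calls))
        msg <- c(msg, "assay 'calls' must be a character matrix")
    else {
        bad <- setdiff(unique(as.vector(calls)), .CALL_STATES)
        if (length(bad))
            msg <- c(msg, paste0("unknown call state(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "locus (row) names must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample (column) names must be present and unique")
    for (fld in c("notI_site_id", "gene_symbol", "cytoband"))
        if (!fld %in% colnames(rowData(object)))
            msg <- c(msg, paste0("rowData column '", fld, "' is required"))
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'group' is required")
    else {
        grp <- as.character(object$group)
        if (!all(grp %in% .GROUP_LEVELS))
            msg <- c(msg, paste0("unknown group label(s): ",
                                 paste(setdiff(grp, .GROUP_LEVELS),
                                       collapse = ", ")))
        if ("gleason" %in% colnames(colData(object))) {
            gs <- object$gleason
            ok <- is.na(gs) |
                (grp == "cancer_le7" & gs <= 7) |
                (grp == "cancer_gt7" & gs > 7) |
                !grp %in% c("cancer_le7", "cancer_gt7")
            if (!all(ok))
                msg <- c(msg, "gleason scores inconsistent with group labels")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AberrationExperiment
#'
#' @param calls character matrix of call states, loci in rows, samples in
#'   columns; row and column names must be unique.
#' @param lociData `DataFrame`/`data.frame` with columns `notI_site_id`,
#'   `gene_symbol`, `cytoband`, one row per locus. Defaults to using the
#'   row names of `calls` as both clone id and gene symbol.
#' @param sampleData `DataFrame`/`data.frame` with a `group` column (and
#'   optionally `gleason`), one row per sample.
#' @return An [AberrationExperiment-class] object.
#' @examples
#' calls <- matrix("UNCHANGED", 2, 3,
#'                 dimnames = list(c("L1", "L2"), c("s1", "s2", "s3")))
#' ae <- AberrationExperiment(calls,
#'     sampleData = data.frame(group = c("adenoma", "adenoma", "cancer_le7")))
#' ae
#' @export
AberrationExperiment <- function(calls, lociData = NULL, sampleData) {
    if (is.null(lociData))
        lociData <- DataFrame(notI_site_id = rownames(calls),
                              gene_symbol = rownames(calls),
                              cytoband = NA_character_)
    lociData <- as(lociData, "DataFrame")
    sampleData <- as(sampleData, "DataFrame")
    if (is.null(rownames(sampleData)) ||
        all(rownames(sampleData) == as.character(seq_len(nrow(sampleData)))))
        rownames(sampleData) <- colnames(calls)
    rownames(lociData) <- rownames(calls)
    se <- SummarizedExperiment(assays = list(calls = calls),
                               rowData = lociData, colData = sampleData)
    new("AberrationExperiment", se)
}

setMethod("show", "AberrationExperiment", function(object) {
    cat("AberrationExperiment:", nrow(object), "loci x",
        ncol(object), "samples\n")
    grp <- table(as.character(object$group))
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
    cen <- alterationCensus(object)
    cat("  calls :", paste(names(cen), cen, sep = "=", collapse = ", "), "\n")
    invisible(NULL)
})

#' CohortDesign: generative model of a synthetic aberration cohort
#'
#' Describes the statistical structure of a simulated NotI-microarray
#' cohort: group sizes, locus annotations, per-(locus, group) probabilities
#' of methylation/deletion and of amplification/demethylation, the fraction
#' of losses that are homozygous, and a missing-call rate. Calls are
#' independent Bernoulli draws per cell; the marginal per-group frequencies
#' are the only distributional facts the design encodes.
#'
#' @slot groups named integer vector, samples per group (names are group
#'   labels).
#' @slot loci `DataFrame` with `notI_site_id`, `gene_symbol`, `cytoband`.
#' @slot aberrationProb numeric matrix (loci x groups) of per-cell
#'   methylation/deletion probabilities among informative calls.
#' @slot gainProb numeric matrix (loci x groups) of
#'   amplification/demethylation probabilities.
#' @slot homFraction scalar in `[0,1]`: probability a loss call is
#'   homozygous rather than heterozygous.
#' @slot missingProb scalar in `[0,1]`: per-cell missing-call rate.
#' @slot seed integer default seed used by [generateCohort()].
#' @seealso [defaultDesign()], [generateCohort()]
#' @export
setClass("CohortDesign",
    representation(groups = "integer", loci = "DataFrame",
                   aberrationProb = "matrix", gainProb = "matrix",
                   homFraction = "numeric", missingProb = "numeric",
                   seed = "integer"))

setValidity("CohortDesign", function(object) {
    msg <- character()
    if (any(object@groups <= 0L) || is.null(names(object@groups)))
        msg <- c(msg, "group sample counts must be positive and named")
    ids <- object@loci$notI_site_id
    if (anyDuplicated(ids))
        msg <- c(msg, "locus ids must be unique")
    dm <- dim(object@aberrationProb)
    if (!identical(dm, dim(object@gainProb)) ||
        dm[1L] != nrow(object@loci) || dm[2L] != length(object@groups))
        msg <- c(msg, "probability matrices must be loci x groups")
    p <- object@aberrationProb; g <- object@gainProb
    if (any(p < 0 | p > 1) || any(g < 0 | g > 1))
        msg <- c(msg, "probabilities must lie in [0,1]")
    else if (any(p + g > 1 + 1e-12))
        msg <- c(msg, "aberrationProb + gainProb must be <= 1 everywhere")
    for (nm in c("homFraction", "missingProb")) {
        v <- slot(object, nm)
        if (length(v) != 1L || v < 0 || v > 1)
            msg <- c(msg, paste0(nm, " must be a scalar in [0,1]"))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortDesign", function(object) {
    cat("CohortDesign:", nrow(object@loci), "loci;",
        paste(names(object@groups), object@groups, sep = "=",
              collapse = ", "), "\n")
    cat(sprintf("  homFraction=%.3f missingProb=%.3f seed=%d\n",
                object@homFraction, object@missingProb, object@seed))
    invisible(NULL)
})

#' FunctionalNetwork: undirected gene-gene functional-coupling network
#'
#' A simple undirected graph over gene symbols, with optional per-edge
#' confidence scores (FunCoup-style) and a provenance tag per edge
#' (`"scored"`, `"curated"`, or `"both"` where an edge occurred in both
#' sources). Backed by an [igraph::igraph] object.
#'
#' @slot graph an `igraph` undirected simple graph; edge attributes
#'   `score` (numeric, `NA` for curated-only edges) and `provenance`.
#' @seealso [loadNetwork()], [functionalNetwork()], [generateNetwork()],
#'   [countLinks()], [neaTest()]
#' @export
setClass("FunctionalNetwork", representation(graph = "ANY"))

setValidity("FunctionalNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g))
        return("graph slot must hold an igraph object")
    if (igraph::is_directed(g))
        return("network must be undirected")
    if (!igraph::is_simple(g))
        return("network must be simple (no loops or multi-edges)")
    TRUE
})

setMethod("show", "FunctionalNetwork", function(object) {
    g <- object@graph
    cat("FunctionalNetwork:", igraph::vcount(g), "genes,",
        igraph::ecount(g), "links\n")
    if ("provenance" %in% igraph::edge_attr_names(g)) {
        pv <- table(igraph::E(g)$provenance)
        cat("  provenance:", paste(names(pv), pv, sep = "=",
                                   collapse = ", "), "\n")
    }
    invisible(NULL)
})

#' MarkerPanel: a locus set with a count-threshold decision rule
#'
#' A marker panel is an ordered set of gene symbols plus a cutoff on the
#' number of panel loci showing methylation/deletion in a sample. With
#' direction `"ge"` a sample is called positive when the aberrant-marker
#' count is at least `threshold`; with `"lt"` when it is strictly below
#' `threshold` (used when the markers are enriched in the negative class).
#'
#' @slot name character panel name.
#' @slot markers character vector of gene symbols (resolved against
#'   `rowData(x)$gene_symbol`, matching any slash-joined component).
#' @slot threshold integer cutoff, `1 <= threshold <= length(markers)`.
#' @slot direction `"ge"` or `"lt"`.
#' @slot positiveClass,negativeClass character vectors of group labels.
#' @seealso [MarkerPanel()], [defaultPanels()], [classifySamples()],
#'   [evaluatePanel()]
#' @export
setClass("MarkerPanel",
    representation(name = "character", markers = "character",
                   threshold = "integer", direction = "character",
                   positiveClass = "character", negativeClass = "character"))

setValidity("MarkerPanel", function(object) {
    msg <- character()
    if (object@threshold < 1L || object@threshold > length(object@markers))
        msg <- c(msg, "threshold must lie in 1..length(markers)")
    if (!object@direction %in% c("ge", "lt"))
        msg <- c(msg, "direction must be 'ge' or 'lt'")
    if (length(intersect(object@positiveClass, object@negativeClass)))
        msg <- c(msg, "positive and negative classes must be disjoint")
    if (length(msg)) msg else TRUE
})

#' @rdname MarkerPanel-class
#' @param name,markers,threshold,direction,positiveClass,negativeClass see
#'   the corresponding slots.
#' @return A `MarkerPanel` object.
#' @export
MarkerPanel <- function(name, markers, threshold, direction = c("ge", "lt"),
                        positiveClass, negativeClass) {
    new("MarkerPanel", name = name, markers = markers,
        threshold = as.integer(threshold),
        direction = match.arg(direction),
        positiveClass = positiveClass, negativeClass = negativeClass)
}

setMethod("show", "MarkerPanel", function(object) {
    rule <- if (object@direction == "ge") ">=" else "<"
    cat(sprintf("MarkerPanel '%s': positive if aberrant-marker count %s %d\n",
                object@name, rule, object@threshold))
    cat("  markers :", paste(object@markers, collapse = ", "), "\n")
    cat("  positive:", paste(object@positiveClass, collapse = "+"),
        " negative:", paste(object@negativeClass, collapse = "+"), "\n")
    invisible(NULL)
})

#' PanelEvaluation: confusion counts, operating metrics and Gini interval
#'
#' Result of [evaluatePanel()]: confusion counts over the panel's positive
#' and negative classes, sensitivity/specificity/accuracy, the Gini
#' coefficient interval implied by score ties (worst and best tie
#' orderings), and the two corresponding cumulative-positive lift curves.
#'
#' @slot tp,fp,tn,fn integer confusion counts.
#' @slot sensitivity,specificity,accuracy numeric in `[0,1]`.
#' @slot giniLow,giniHigh numeric in `[-1,1]`, `giniLow <= giniHigh`.
#' @slot liftWorst,liftBest integer vectors: cumulative positives as
#'   samples are taken in decreasing-score order under the least / most
#'   favorable tie ordering.
#' @export
setClass("PanelEvaluation",
    representation(tp = "integer", fp = "integer", tn = "integer",
                   fn = "integer", sensitivity = "numeric",
                   specificity = "numeric", accuracy = "numeric",
                   giniLow = "numeric", giniHigh = "numeric",
                   liftWorst = "integer", liftBest = "integer"))

setValidity("PanelEvaluation", function(object) {
    msg <- character()
    if (object@giniLow > object@giniHigh + 1e-12)
        msg <- c(msg, "giniLow must not exceed giniHigh")
    for (nm in c("sensitivity", "specificity", "accuracy")) {
        v <- slot(object, nm)
        if (!is.na(v) && (v < -1e-12 || v > 1 + 1e-12))
            msg <- c(msg, paste0(nm, " must lie in [0,1]"))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PanelEvaluation", function(object) {
    cat(sprintf(
        "PanelEvaluation: TP=%d FP=%d TN=%d FN=%d\n  Sn=%.3f Sp=%.3f Ac=%.3f  Gini in [%.3f, %.3f]\n",
        object@tp, object@fp, object@tn, object@fn, object@sensitivity,
        object@specificity, object@accuracy, object@giniLow, object@giniHigh))
    invisible(NULL)
})

#' BisulfiteCloneGrid: per-clone, per-CpG methylation calls
#'
#' Bisulfite-sequencing validation data: a grid of methylation calls over
#' sequenced clones (rows) and CpG-pair positions along the amplicon
#' (columns), with a subset of positions designated as the NotI site.
#'
#' @slot calls integer matrix, clones x CpG positions; 1 = methylated,
#'   0 = unmethylated, `NA` = no data.
#' @slot notiPositions integer indices of the CpG columns that make up the
#'   NotI recognition site.
#' @seealso [bisulfiteSiteSummary()], [readBisulfiteGrid()]
#' @export
setClass("BisulfiteCloneGrid",
    representation(calls = "matrix", notiPositions = "integer"))

setValidity("BisulfiteCloneGrid", function(object) {
    msg <- character()
    if (nrow(object@calls) < 1L)
        msg <- c(msg, "at least one clone is required")
    v <- object@calls
    if (!all(v %in% c(0L, 1L, NA_integer_)))
        msg <- c(msg, "calls must be 0, 1 or NA")
    if (!all(object@notiPositions %in% seq_len(ncol(object@calls))))
        msg <- c(msg, "NotI positions must index CpG columns")
    if (length(msg)) msg else TRUE
})

#' @rdname BisulfiteCloneGrid-class
#' @param calls,notiPositions see the corresponding slots.
#' @export
BisulfiteCloneGrid <- function(calls, notiPositions) {
    mode(calls) <- "integer"
    new("BisulfiteCloneGrid", calls = calls,
        notiPositions = as.integer(notiPositions))
}
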