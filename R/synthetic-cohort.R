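#' Default synthetic cohort design emulating the reference study
#'
#' Builds a [CohortDesign-class] mirroring the reference prostate-tumor
#' cohort: 15 adenomas, 14 nonaggressive carcinomas (Gleason <= 7) and 4
#' aggressive carcinomas (Gleason > 7) over 180 chromosome-3 NotI loci.
#' The 50 loci of [referenceFrequencyTable()] and the 11 further contrast
#' loci of [referenceContrastCounts()] carry their reported per-group
#' frequencies as aberration probabilities; the remaining loci get a flat
#' background rate. Gain probabilities are capped at `1 - aberrationProb`
#' so that the two never exceed 1.
#'
#' @param backgroundRate per-group methylation/deletion probability of
#'   unannotated background loci (default 0.05).
#' @param homFraction probability a loss call is homozygous; default
#'   461/(461+1163) = 0.284, the reference cohort's homozygous share of
#'   its 1624 loss calls.
#' @param gainProb per-cell amplification/demethylation probability;
#'   default 0.001 (24 gains among roughly 33 x 180 calls).
#' @param missingProb per-cell missing-call rate (default 0.02; the
#'   reference study shows sparse missingness but reports no rate).
#' @param normalSamples optional number of tumor-free samples to append as
#'   a `normal` group with background-rate aberrations on every locus
#'   (default 0; the reference matrix contains no normal columns, its
#'   normals being a pooled hybridization reference).
#' @param seed default seed stored in the design and used by
#'   [generateCohort()].
#' @return A [CohortDesign-class] object with 180 loci.
#' @examples
#' d <- defaultDesign()
#' aberrationProb(d)["NR1-XM13C", "adenoma"]   # IQSEC1: 0.73
#' @export
defaultDesign <- function(backgroundRate = 0.05,
                          homFraction = 461 / (461 + 1163),
                          gainProb = 0.001, missingProb = 0.02,
                          normalSamples = 0L, seed = 1L) {
    top <- .topLoci
    extra <- .extraLoci
    nBg <- 180L - nrow(top) - nrow(extra)
    bg <- data.frame(
        notI_site_id = sprintf("NMA-BG%03d", seq_len(nBg)),
        gene_symbol = sprintf("BG%03d", seq_len(nBg)),
        cytoband = NA_character_, stringsAsFactors = FALSE)
    loci <- S4Vectors::DataFrame(
        notI_site_id = c(top$notI_site_id, extra$notI_site_id,
                         bg$notI_site_id),
        gene_symbol = c(top$gene_symbol, extra$gene_symbol, bg$gene_symbol),
        cytoband = c(top$cytoband, extra$cytoband, bg$cytoband))
    groups <- c(adenoma = 15L, cancer_le7 = 14L, cancer_gt7 = 4L)
    if (normalSamples > 0L)
        groups <- c(groups, normal = as.integer(normalSamples))
    p <- matrix(backgroundRate, nrow(loci), length(groups),
                dimnames = list(loci$notI_site_id, names(groups)))
    tumor <- c("adenoma", "cancer_le7", "cancer_gt7")
    p[seq_len(nrow(top)), tumor] <-
        as.matrix(top[, c("pct_adenoma", "pct_cancer_le7",
                          "pct_cancer_gt7")]) / 100
    ex <- as.matrix(extra[, c("p_adenoma", "p_cancer_le7", "p_cancer_gt7")])
    ex[is.na(ex)] <- backgroundRate
    p[nrow(top) + seq_len(nrow(extra)), tumor] <- ex
    g <- matrix(pmin(gainProb, 1 - p), nrow(p), ncol(p),
                dimnames = dimnames(p))
    new("CohortDesign", groups = groups, loci = loci, aberrationProb = p,
        gainProb = g, homFraction = homFraction, missingProb = missingProb,
        seed = as.integer(seed))
}

#' @describeIn defaultDesign accessor for the per-(locus, group)
#'   methylation/deletion probability matrix of a design.
#' @param design a [CohortDesign-class].
#' @export
aberrationProb <- function(design) design@aberrationProb

#' Simulate an aberration-call cohort from a design
#'
#' Draws one call per (locus, sample) cell, independently: `MISSING` with
#' `missingProb`; otherwise `GAIN` with the cell's gain probability;
#' otherwise a loss with the cell's aberration probability, homozygous
#' with probability `homFraction` and heterozygous otherwise; otherwise
#' `UNCHANGED`. Thus among informative (non-missing) calls the loss
#' frequency is `(1 - gainProb) * aberrationProb`. Carcinoma samples are
#' assigned a Gleason score consistent with their group (5-7 for
#' `cancer_le7`, 8-10 for `cancer_gt7`). Bit-identical output for a given
#' design and seed; the caller's RNG state is untouched.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer seed; defaults to the design's stored seed.
#' @return An [AberrationExperiment-class], loci x samples; sample names
#'   encode group and index (`A01..`, `C01..`, `G01..`, `N01..`).
#' @examples
#' x <- generateCohort(defaultDesign(seed = 7))
#' x
#' @export
generateCohort <- function(design, seed = design@seed) {
    validObject(design)
    groups <- design@groups
    nL <- nrow(design@loci)
    sizes <- as.integer(groups)
    colGroup <- rep(names(groups), sizes)
    nS <- sum(sizes)
    p <- design@aberrationProb[, colGroup, drop = FALSE]
    g <- design@gainProb[, colGroup, drop = FALSE]
    res <- withSeed(seed, {
        uMiss <- matrix(runif(nL * nS), nL, nS)
        uGain <- matrix(runif(nL * nS), nL, nS)
        uAb <- matrix(runif(nL * nS), nL, nS)
        uHom <- matrix(runif(nL * nS), nL, nS)
        calls <- matrix("UNCHANGED", nL, nS)
        calls[uAb < p] <- "HET_LOSS"
        calls[uAb < p & uHom < design@homFraction] <- "HOM_LOSS"
        calls[uGain < g] <- "GAIN"
        calls[uMiss < design@missingProb] <- "MISSING"
        gleason <- rep(NA_integer_, nS)
        gleason[colGroup == "cancer_le7"] <-
            sample(5:7, sum(colGroup == "cancer_le7"), replace = TRUE)
        gleason[colGroup == "cancer_gt7"] <-
            sample(8:10, sum(colGroup == "cancer_gt7"), replace = TRUE)
        list(calls = calls, gleason = gleason)
    })
    prefix <- c(adenoma = "A", cancer_le7 = "C", cancer_gt7 = "G",
                normal = "N")[colGroup]
    prefix[is.na(prefix)] <- toupper(substr(colGroup[is.na(prefix)], 1, 1))
    ids <- sprintf("%s%02d", prefix, unlist(lapply(sizes, seq_len)))
    calls <- res$calls
    dimnames(calls) <- list(design@loci$notI_site_id, ids)
    AberrationExperiment(calls, lociData = design@loci,
        sampleData = S4Vectors::DataFrame(group = colGroup,
                                          gleason = res$gleason,
                                          row.names = ids))
}

#' Simulate a functional network with planted modules
#'
#' Generates an undirected simple graph in which gene pairs inside each
#' planted module are joined at that module's edge probability and every
#' other pair at a flat background probability, as a fixture for network
#' enrichment analysis.
#'
#' @param nGenes number of genes; vertices are named `g001`, `g002`, ...
#'   unless `genes` is given.
#' @param backgroundEdgeProb edge probability outside planted modules.
#' @param plantedModules list of `list(genes =, prob =)` entries; `genes`
#'   may be vertex names or integer indices.
#' @param seed integer seed (draws are local; caller RNG untouched).
#' @param genes optional character vector of vertex names.
#' @return A [FunctionalNetwork-class].
#' @examples
#' net <- generateNetwork(50, 0.02,
#'     list(list(genes = 1:10, prob = 0.8)), seed = 1)
#' net
#' @export
generateNetwork <- function(nGenes, backgroundEdgeProb,
                            plantedModules = list(), seed = 1L,
                            genes = sprintf("g%03d", seq_len(nGenes))) {
    stopifnot(backgroundEdgeProb >= 0, backgroundEdgeProb <= 1,
              length(genes) == nGenes)
    idx <- which(upper.tri(matrix(0L, nGenes, nGenes)), arr.ind = TRUE)
    rate <- rep(backgroundEdgeProb, nrow(idx))
    for (m in plantedModules) {
        mi <- if (is.numeric(m$genes)) as.integer(m$genes)
              else match(m$genes, genes)
        stopifnot(!anyNA(mi), m$prob >= 0, m$prob <= 1)
        inMod <- idx[, 1L] %in% mi & idx[, 2L] %in% mi
        rate[inMod] <- m$prob
    }
    keep <- withSeed(seed, runif(nrow(idx)) < rate)
    edges <- data.frame(from = genes[idx[keep, 1L]],
                        to = genes[idx[keep, 2L]],
                        stringsAsFactors = FALSE)
    functionalNetwork(edges, genes = genes, provenance = "scored")
}
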