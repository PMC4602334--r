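#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided P value under the point-probability rule: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, of every table whose point probability does not exceed the
#' observed one (up to a relative tie tolerance of 1e-7). This is the
#' convention of mainstream statistics packages and the one that
#' reproduces the reference study's reported P values.
#'
#' @param table 2x2 matrix (or length-4 vector, filled by row) of
#'   non-negative integer counts; rows are aberrant / non-aberrant,
#'   columns the two groups.
#' @return The exact P value in `(0, 1]`.
#' @examples
#' fisherExactTwoSided(matrix(c(7, 0, 8, 14), 2))   # 0.006
#' @export
fisherExactTwoSided <- function(table) {
    if (!is.matrix(table)) table <- matrix(table, 2L, byrow = TRUE)
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    if (sum(table) == 0L)
        stop("at least one positive margin is required")
    min(1, stats::fisher.test(table)$p.value)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Advisory companion to [fisherExactTwoSided()]; never used for
#' significance flags. A table with a zero margin has no defined
#' statistic and is reported as `p = 1` with `degenerate = TRUE`.
#'
#' @inheritParams fisherExactTwoSided
#' @param yates apply the continuity correction (default `FALSE`).
#' @return List with `p_value` and logical `degenerate`.
#' @examples
#' chiSquareTest(matrix(c(10, 0, 0, 10), 2))$p_value
#' @export
chiSquareTest <- function(table, yates = FALSE) {
    if (!is.matrix(table)) table <- matrix(table, 2L, byrow = TRUE)
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    if (any(rowSums(table) == 0L) || any(colSums(table) == 0L)) {
        warning("zero margin: chi-square statistic undefined, p set to 1")
        return(list(p_value = 1, degenerate = TRUE))
    }
    p <- suppressWarnings(
        stats::chisq.test(table, correct = yates)$p.value)
    list(p_value = p, degenerate = FALSE)
}

#' Per-locus two-group contingency testing
#'
#' Builds, for every locus, the 2x2 table of aberrant (`HET_LOSS` or
#' `HOM_LOSS`) versus non-aberrant samples across two disjoint group
#' specs (each a character vector of group labels, pooled), tests it with
#' the two-sided exact test, and orders loci by ascending P value (ties
#' broken by NotI-site id). The chi-square P value and the sample odds
#' ratio are reported as secondary columns. No multiple-testing
#' correction is applied by default (`correct = "none"`); `"BH"` adds a
#' Benjamini-Hochberg `fdr` column without changing the significance
#' flag, which always reflects the raw exact P.
#'
#' @param x an [AberrationExperiment-class].
#' @param groupA,groupB character vectors of group labels; pooled, must
#'   select disjoint non-empty sample sets.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param onlySignificant if `TRUE`, return only significant rows
#'   (report mode).
#' @param correct `"none"` or `"BH"`.
#' @return A [S4Vectors::DataFrame] with one row per locus (or per
#'   significant locus): counts `k_a`, `n_a`, `k_b`, `n_b`, formatted
#'   `cell_a`/`cell_b`, `p_exact`, `p_chi2`, `odds_ratio`, `significant`,
#'   and `p_formatted` ("<0.001" below 0.0005).
#' @examples
#' x <- referenceContrastMatrix("adenoma_vs_nonaggressive")
#' compareGroups(x, "adenoma", "cancer_le7")
#' @export
compareGroups <- function(x, groupA, groupB, alpha = 0.05,
                          onlySignificant = FALSE,
                          correct = c("none", "BH")) {
    correct <- match.arg(correct)
    ja <- resolveGroups(x, groupA)
    jb <- resolveGroups(x, groupB)
    if (length(intersect(ja, jb)))
        stop("group specs must select disjoint sample sets")
    rd <- SummarizedExperiment::rowData(x)
    loss <- isLoss(assay(x, "calls"))
    ka <- as.integer(rowSums(loss[, ja, drop = FALSE]))
    kb <- as.integer(rowSums(loss[, jb, drop = FALSE]))
    na <- length(ja); nb <- length(jb)
    stats <- vapply(seq_len(nrow(x)), function(i) {
        tab <- matrix(c(ka[i], kb[i], na - ka[i], nb - kb[i]), 2L,
                      byrow = TRUE)
        pe <- fisherExactTwoSided(tab)
        pc <- suppressWarnings(chiSquareTest(tab)$p_value)
        orr <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
        c(pe, pc, orr)
    }, numeric(3))
    out <- S4Vectors::DataFrame(
        notI_site_id = as.character(rd$notI_site_id),
        gene_symbol = as.character(rd$gene_symbol),
        k_a = ka, n_a = na, k_b = kb, n_b = nb,
        cell_a = formatFrequencyCell(ka, na),
        cell_b = formatFrequencyCell(kb, nb),
        p_exact = stats[1L, ], p_chi2 = stats[2L, ],
        odds_ratio = stats[3L, ],
        significant = stats[1L, ] < alpha,
        p_formatted = formatPValue(stats[1L, ]))
    if (correct == "BH")
        out$fdr <- stats::p.adjust(out$p_exact, method = "BH")
    ord <- order(out$p_exact, out$notI_site_id)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    if (onlySignificant) out[out$significant, , drop = FALSE] else out
}
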