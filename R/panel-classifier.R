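#' The three marker panels shipped with the package
#'
#' The reference study's published count-threshold rules, frozen as
#' defaults:
#' * `detection` — BHLHE40, FOXP1, LOC285205, ITGA9, CTDSPL, FGF12; a
#'   sample is a tumor when two or more markers show methylation/deletion
#'   (negative class: tumor-free `normal` samples, available in synthetic
#'   cohorts via `defaultDesign(normalSamples =)`).
#' * `aggressiveness` — LOC440944/SETD5, VHL, CLCN2, OSBPL10/ZNF860,
#'   LMCD1; aggressive when three or more markers are aberrant.
#' * `adenoma_vs_cancer` — FAM19A4, CAND2, MAP4, KY, LRRC58; these
#'   markers are adenoma-enriched, so a sample is called cancerous when
#'   fewer than two of them are aberrant.
#'
#' @return Named list of [MarkerPanel-class] objects.
#' @examples
#' defaultPanels()$aggressiveness
#' @export
defaultPanels <- function() {
    list(
        detection = MarkerPanel(
            "detection",
            c("BHLHE40", "FOXP1", "LOC285205", "ITGA9", "CTDSPL", "FGF12"),
            threshold = 2L, direction = "ge",
            positiveClass = c("adenoma", "cancer_le7", "cancer_gt7"),
            negativeClass = "normal"),
        aggressiveness = MarkerPanel(
            "aggressiveness",
            c("LOC440944/SETD5", "VHL", "CLCN2", "OSBPL10/ZNF860", "LMCD1"),
            threshold = 3L, direction = "ge",
            positiveClass = "cancer_gt7",
            negativeClass = c("adenoma", "cancer_le7")),
        adenoma_vs_cancer = MarkerPanel(
            "adenoma_vs_cancer",
            c("FAM19A4", "CAND2", "MAP4", "KY", "LRRC58"),
            threshold = 2L, direction = "lt",
            positiveClass = "cancer_le7",
            negativeClass = "adenoma"))
}

#' Aberrant-marker count per sample
#'
#' Number of panel loci called `HET_LOSS` or `HOM_LOSS` in each sample;
#' `MISSING` counts as not aberrant.
#'
#' @param x an [AberrationExperiment-class].
#' @param panel a [MarkerPanel-class]; markers are resolved against
#'   `rowData(x)$gene_symbol` (slash-joined symbols match on either
#'   component).
#' @return Named integer vector, one count per sample (all samples, not
#'   only the panel's classes).
#' @examples
#' x <- generateCohort(defaultDesign(seed = 3))
#' head(markerCount(x, defaultPanels()$aggressiveness))
#' @export
setMethod("markerCount", signature(x = "AberrationExperiment",
                                   panel = "MarkerPanel"),
    function(x, panel) {
        idx <- resolveMarkers(x, panel@markers)
        loss <- isLoss(assay(x, "calls")[idx, , drop = FALSE])
        counts <- as.integer(colSums(loss))
        names(counts) <- colnames(x)
        counts
    })

#' Classify samples with a count-threshold rule
#'
#' @inheritParams markerCount
#' @return Named character vector, `"positive"` or `"negative"` per
#'   sample: positive when the aberrant-marker count is `>= threshold`
#'   (direction `"ge"`) or `< threshold` (direction `"lt"`).
#' @examples
#' x <- generateCohort(defaultDesign(seed = 3))
#' table(classifySamples(x, defaultPanels()$aggressiveness))
#' @export
setMethod("classifySamples", signature(x = "AberrationExperiment",
                                       panel = "MarkerPanel"),
    function(x, panel) {
        counts <- markerCount(x, panel)
        hit <- if (panel@direction == "ge") counts >= panel@threshold
               else counts < panel@threshold
        structure(ifelse(hit, "positive", "negative"), names = names(counts))
    })

#' Gini coefficient interval under score ties
#'
#' Samples are ranked by score (descending when high scores indicate the
#' positive class, ascending otherwise). Integer marker counts over a
#' handful of loci tie heavily, and every tie ordering yields a
#' different cumulative-positives lift curve; the most favorable ordering
#' places positives first within each tied block, the least favorable
#' places them last. Each ordering's Gini coefficient is `2 * AUC - 1`
#' of the ROC curve it induces; the pair (worst, best) brackets every
#' achievable value.
#'
#' @param scores numeric vector of per-sample scores (e.g. marker
#'   counts).
#' @param labels logical vector, `TRUE` for positive-class samples; at
#'   least one of each class is required.
#' @param direction `"ge"` if larger scores indicate positives, `"lt"`
#'   if smaller scores do.
#' @return Named numeric vector `c(low = , high = )`, each in `[-1, 1]`.
#' @examples
#' giniInterval(c(5, 4, 2, 1), c(TRUE, TRUE, FALSE, FALSE))  # (1, 1)
#' giniInterval(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE))      # (-1, 1)
#' @export
giniInterval <- function(scores, labels, direction = c("ge", "lt")) {
    direction <- match.arg(direction)
    labels <- as.logical(labels)
    if (!any(labels) || all(labels))
        stop("both classes must be represented")
    s <- if (direction == "ge") scores else -scores
    giniOf <- function(ord) {
        pos <- labels[ord]
        nPos <- cumsum(pos)
        auc <- sum(nPos[!pos]) / (sum(labels) * sum(!labels))
        2 * auc - 1
    }
    best <- order(-s, !labels)    # positives first within ties
    worst <- order(-s, labels)    # positives last within ties
    c(low = giniOf(worst), high = giniOf(best))
}

## Cumulative-positives lift curve for one tie ordering.
liftCurve <- function(scores, labels, direction = "ge",
                      ties = c("best", "worst")) {
    ties <- match.arg(ties)
    labels <- as.logical(labels)
    s <- if (direction == "ge") scores else -scores
    ord <- if (ties == "best") order(-s, !labels) else order(-s, labels)
    as.integer(cumsum(labels[ord]))
}

#' Evaluate a marker panel on a cohort
#'
#' Applies the panel's decision rule to the samples of its positive and
#' negative classes, accumulates the confusion counts, and derives
#' sensitivity (`TP/(TP+FN)`), specificity (`TN/(TN+FP)`), accuracy
#' (`(TP+TN)/total`) and the tie-ambiguity Gini interval of the
#' aberrant-marker count as a ranking score, together with the worst- and
#' best-case lift curves.
#'
#' @inheritParams markerCount
#' @return A [PanelEvaluation-class].
#' @examples
#' x <- generateCohort(defaultDesign(seed = 3))
#' evaluatePanel(x, defaultPanels()$aggressiveness)
#' @export
setMethod("evaluatePanel", signature(x = "AberrationExperiment",
                                     panel = "MarkerPanel"),
    function(x, panel) {
        jp <- resolveGroups(x, panel@positiveClass)
        jn <- resolveGroups(x, panel@negativeClass)
        sel <- c(jp, jn)
        labels <- c(rep(TRUE, length(jp)), rep(FALSE, length(jn)))
        counts <- markerCount(x, panel)[sel]
        pred <- if (panel@direction == "ge") counts >= panel@threshold
                else counts < panel@threshold
        .panelEvaluation(pred, labels, counts, panel@direction)
    })

.panelEvaluation <- function(pred, labels, counts, direction) {
    tp <- sum(pred & labels); fn <- sum(!pred & labels)
    tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
    gini <- giniInterval(counts, labels, direction)
    new("PanelEvaluation",
        tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
        fn = as.integer(fn),
        sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
        accuracy = (tp + tn) / length(labels),
        giniLow = unname(gini["low"]), giniHigh = unname(gini["high"]),
        liftWorst = liftCurve(counts, labels, direction, "worst"),
        liftBest = liftCurve(counts, labels, direction, "best"))
}

#' Exhaustive search over count-threshold panels
#'
#' Enumerates every size-`k` subset of the candidate loci, every
#' threshold `t` in `1..k` and every requested direction, evaluates each
#' rule on the given classes, and ranks the rules by accuracy, breaking
#' ties by worst-case Gini and then by the lexicographic marker list.
#' Deterministic and invariant to the input order of the candidates. The
#' candidate set is capped at 30 loci; pre-filter with
#' [compareGroups()] for larger screens.
#'
#' @param x an [AberrationExperiment-class].
#' @param candidates character vector of candidate gene symbols
#'   (`k <= length(candidates) <= 30`).
#' @param k panel size.
#' @param directions subset of `c("ge", "lt")` to explore.
#' @param positiveClass,negativeClass group specs, as in
#'   [MarkerPanel-class].
#' @param topN number of top-ranked rules to return (default 10).
#' @return A [S4Vectors::DataFrame] with `markers` (comma-joined, sorted
#'   enumeration order), `threshold`, `direction`, confusion counts,
#'   `sensitivity`, `specificity`, `accuracy` and `gini_worst`, best
#'   rule first.
#' @examples
#' x <- generateCohort(defaultDesign(seed = 3))
#' searchPanels(x, c("LOC440944/SETD5", "VHL", "CLCN2"), k = 2,
#'              positiveClass = "cancer_gt7",
#'              negativeClass = c("adenoma", "cancer_le7"), topN = 3)
#' @export
searchPanels <- function(x, candidates, k, directions = c("ge", "lt"),
                         positiveClass, negativeClass, topN = 10L) {
    candidates <- sort(unique(candidates))
    m <- length(candidates)
    if (m > 30L)
        stop("candidate set too large (", m, " > 30): pre-filter the loci, ",
             "e.g. with compareGroups()")
    stopifnot(k >= 1L, k <= m, all(directions %in% c("ge", "lt")))
    jp <- resolveGroups(x, positiveClass)
    jn <- resolveGroups(x, negativeClass)
    sel <- c(jp, jn)
    labels <- c(rep(TRUE, length(jp)), rep(FALSE, length(jn)))
    idx <- resolveMarkers(x, candidates)
    A <- t(isLoss(assay(x, "calls")[idx, sel, drop = FALSE])) * 1
    subs <- utils::combn(m, k)
    nSub <- ncol(subs)
    Z <- matrix(0, m, nSub)
    Z[cbind(as.vector(subs), rep(seq_len(nSub), each = k))] <- 1
    counts <- A %*% Z                       # samples x subsets
    nPos <- sum(labels); nNeg <- sum(!labels)
    markerStr <- apply(subs, 2L, function(s)
        paste(candidates[s], collapse = ","))
    ## flat grid over (subset, threshold, direction)
    grid <- expand.grid(sub = seq_len(nSub), t = seq_len(k),
                        dir = directions, stringsAsFactors = FALSE)
    tp <- fp <- integer(nrow(grid))
    for (dir in directions) for (t in seq_len(k)) {
        pred <- if (dir == "ge") counts >= t else counts < t
        rowsel <- grid$dir == dir & grid$t == t
        tp[rowsel] <- colSums(pred[labels, , drop = FALSE])
        fp[rowsel] <- colSums(pred[!labels, , drop = FALSE])
    }
    acc <- (tp + nNeg - fp) / (nPos + nNeg)
    ## worst-case Gini is only needed to order rows competing at the
    ## accuracy boundary of the top-N cut
    cutoff <- sort(acc, decreasing = TRUE)[min(topN, length(acc))]
    cand <- which(acc >= cutoff)
    need <- unique(grid[cand, c("sub", "dir")])
    gkey <- paste(grid$sub, grid$dir)
    gini <- rep(NA_real_, nrow(grid))
    gval <- vapply(seq_len(nrow(need)), function(i)
        giniInterval(counts[, need$sub[i]], labels, need$dir[i])[["low"]],
        numeric(1))
    gini[cand] <- gval[match(gkey[cand], paste(need$sub, need$dir))]
    ord <- cand[order(-acc[cand], -gini[cand], markerStr[grid$sub[cand]],
                      grid$t[cand], grid$dir[cand])]
    top <- ord[seq_len(min(topN, length(ord)))]
    S4Vectors::DataFrame(
        markers = markerStr[grid$sub[top]],
        threshold = grid$t[top], direction = grid$dir[top],
        tp = tp[top], fp = fp[top],
        tn = as.integer(nNeg - fp[top]), fn = as.integer(nPos - tp[top]),
        sensitivity = tp[top] / nPos, specificity = (nNeg - fp[top]) / nNeg,
        accuracy = acc[top], gini_worst = gini[top])
}
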