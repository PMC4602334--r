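## A 6-locus detection-style fixture: one sample aberrant at BHLHE40 and
## FOXP1 only, one clean, one with calls on all markers.
detectionFixture <- function() {
    genes <- c("BHLHE40", "FOXP1", "LOC285205", "ITGA9", "CTDSPL", "FGF12")
    calls <- matrix("UNCHANGED", 6, 3,
                    dimnames = list(genes, c("t1", "t2", "n1")))
    calls[c("BHLHE40", "FOXP1"), "t1"] <- "HET_LOSS"
    calls["ITGA9", "t1"] <- "MISSING"          # missing is not aberrant
    calls[, "t2"] <- "HOM_LOSS"
    makeAE(calls, c("adenoma", "cancer_le7", "normal"), genes = genes)
}

test_that("marker counts ignore missing calls and resolve symbols", {
    x <- detectionFixture()
    panel <- defaultPanels()$detection
    expect_identical(markerCount(x, panel),
                     c(t1 = 2L, t2 = 6L, n1 = 0L))
    bad <- MarkerPanel("bad", c("BHLHE40", "NOPE"), 1, "ge",
                       "adenoma", "normal")
    expect_error(markerCount(x, bad), "NOPE")
    ## slash-joined symbols match on either component
    calls <- matrix("HET_LOSS", 1, 2,
                    dimnames = list("L1", c("a", "b")))
    y <- makeAE(calls, c("cancer_gt7", "adenoma"),
                genes = "LOC440944/SETD5")
    p <- MarkerPanel("p", "SETD5", 1, "ge", "cancer_gt7", "adenoma")
    expect_identical(unname(markerCount(y, p)), c(1L, 1L))
})

test_that("count-threshold rules classify in both directions", {
    x <- detectionFixture()
    panels <- defaultPanels()
    ## detection rule: two or more aberrant markers -> tumor
    expect_identical(unname(classifySamples(x, panels$detection)),
                     c("positive", "positive", "negative"))
    ## aggressiveness rule needs three or more
    agg <- MarkerPanel("agg3", c("BHLHE40", "FOXP1", "LOC285205"),
                       3, "ge", "cancer_gt7", "adenoma")
    expect_identical(unname(classifySamples(x, agg)),
                     c("negative", "positive", "negative"))
    ## less-than rule: clean samples are called positive
    lt <- MarkerPanel("lt2", c("BHLHE40", "FOXP1"), 2, "lt",
                      "cancer_le7", "adenoma")
    expect_identical(unname(classifySamples(x, lt)),
                     c("negative", "negative", "positive"))
})

test_that("panel evaluation reproduces forced confusion patterns", {
    d <- plantedDesign(30, 30, pTrue = 1, pNull = 0)
    x <- generateCohort(d, 1)
    panel <- MarkerPanel("perfect", sprintf("TRUE%d", 1:5), 3, "ge",
                         "cancer_le7", "adenoma")
    ev <- evaluatePanel(x, panel)
    expect_equal(ev@sensitivity, 1)
    expect_equal(ev@specificity, 1)
    expect_equal(ev@accuracy, 1)
    expect_equal(c(ev@giniLow, ev@giniHigh), c(1, 1))
    ## an impossible threshold yields the all-negative classifier
    never <- MarkerPanel("never", sprintf("NULL%02d", 1:5), 5, "ge",
                         "cancer_le7", "adenoma")
    ev0 <- evaluatePanel(x, never)
    expect_equal(ev0@sensitivity, 0)
    expect_equal(ev0@specificity, 1)
})

test_that("Sn*P + Sp*N = TP + TN = Ac*total on every evaluation", {
    panels <- defaultPanels()
    for (s in 1:5) {
        x <- generateCohort(defaultDesign(normalSamples = 10, seed = s))
        for (panel in panels) {
            ev <- evaluatePanel(x, panel)
            P <- ev@tp + ev@fn; N <- ev@tn + ev@fp
            expect_equal(ev@sensitivity * P + ev@specificity * N,
                         ev@tp + ev@tn)
            expect_equal(ev@accuracy * (P + N), ev@tp + ev@tn)
            expect_identical(length(ev@liftBest), P + N)
            expect_identical(max(ev@liftBest), P)
        }
    }
})

test_that("gini interval brackets tie ambiguity", {
    ## perfect separation without ties
    expect_equal(giniInterval(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE)),
                 c(low = 1, high = 1))
    ## one shared score collapses to the documented extremes
    expect_equal(giniInterval(rep(3, 6), rep(c(TRUE, FALSE), 3)),
                 c(low = -1, high = 1))
    expect_error(giniInterval(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("gini interval equals the explicit-permutation oracle", {
    set.seed(7)
    for (i in 1:200) {
        n <- sample(4:12, 1)
        labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (all(labels) || !any(labels)) next
        scores <- sample(0:4, n, replace = TRUE)
        dir <- sample(c("ge", "lt"), 1)
        g <- giniInterval(scores, labels, dir)
        expect_equal(g[["low"]], oracleGini(scores, labels, dir, "worst"),
                     tolerance = 1e-12)
        expect_equal(g[["high"]], oracleGini(scores, labels, dir, "best"),
                     tolerance = 1e-12)
        expect_true(g[["low"]] <= g[["high"]])
        expect_true(g[["low"]] >= -1 && g[["high"]] <= 1)
        ## untied scores collapse the interval
        untied <- sample(seq_len(n))
        gu <- giniInterval(untied, labels)
        expect_equal(gu[["low"]], gu[["high"]])
    }
})

test_that("raising the threshold trades sensitivity for specificity", {
    for (s in 1:3) {
        x <- generateCohort(plantedDesign(40, 40, pTrue = 0.5,
                                          pNull = 0.2), seed = s)
        prev <- NULL
        for (t in 1:5) {
            panel <- MarkerPanel("p", sprintf("TRUE%d", 1:5), t, "ge",
                                 "cancer_le7", "adenoma")
            ev <- evaluatePanel(x, panel)
            if (!is.null(prev)) {
                expect_lte(ev@sensitivity, prev@sensitivity + 1e-12)
                expect_gte(ev@specificity, prev@specificity - 1e-12)
            }
            prev <- ev
        }
    }
})

test_that("operating points converge to the binomial tails", {
    ## independent markers, p = 0.4 in tumors vs 0.05 in normals,
    ## detection-style rule t = 2 over 6 markers
    d <- plantedDesign(2000, 2000, nTrue = 6, nNull = 0, pTrue = 0.4,
                       pNull = 0.05, posGroup = "adenoma",
                       negGroup = "normal")
    x <- generateCohort(d, seed = 23)
    panel <- MarkerPanel("det", sprintf("TRUE%d", 1:6), 2, "ge",
                         "adenoma", "normal")
    ev <- evaluatePanel(x, panel)
    snExp <- 1 - pbinom(1, 6, 0.4)
    spExp <- pbinom(1, 6, 0.05)
    expect_lt(abs(ev@sensitivity - snExp),
              3 * sqrt(snExp * (1 - snExp) / 2000))
    expect_lt(abs(ev@specificity - spExp),
              3 * sqrt(spExp * (1 - spExp) / 2000))
})

test_that("panel search is deterministic and order-invariant", {
    x <- generateCohort(plantedDesign(60, 60), seed = 3)
    cand <- c(sprintf("TRUE%d", 1:5), sprintf("NULL%02d", 1:5))
    a <- searchPanels(x, cand, k = 3, directions = "ge",
                      positiveClass = "cancer_le7",
                      negativeClass = "adenoma", topN = 5)
    b <- searchPanels(x, rev(cand), k = 3, directions = "ge",
                      positiveClass = "cancer_le7",
                      negativeClass = "adenoma", topN = 5)
    expect_identical(as.data.frame(a), as.data.frame(b))
    ## a single subset comes back with its best threshold
    solo <- searchPanels(x, sprintf("TRUE%d", 1:5), k = 5,
                         directions = "ge",
                         positiveClass = "cancer_le7",
                         negativeClass = "adenoma", topN = 1)
    expect_identical(solo$markers,
                     paste(sprintf("TRUE%d", 1:5), collapse = ","))
    expect_error(searchPanels(x, sprintf("X%d", 1:31), k = 2,
                              positiveClass = "cancer_le7",
                              negativeClass = "adenoma"),
                 "too large")
})
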