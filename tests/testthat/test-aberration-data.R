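test_that("the TSV dialect round-trips a synthetic cohort exactly", {
    x <- generateCohort(defaultDesign(seed = 11))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeAberrationMatrix(x, f)
    y <- readAberrationMatrix(f)
    expect_identical(aberrationCalls(y), aberrationCalls(x))
    expect_identical(sampleGroups(y), sampleGroups(x))
    expect_identical(y$gleason, x$gleason)
    expect_identical(as.data.frame(lociInfo(y)),
                     as.data.frame(lociInfo(x)))
    ## write(read(f)) is byte-stable
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeAberrationMatrix(y, f2)
    expect_identical(readLines(f2), readLines(f))
})

test_that("state tokens map to call states", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tgroup\tgleason\tL1\tL2",
                 ".\t.\t.\tG1\tG2",
                 ".\t.\t.\tNA\tNA",
                 "s1\tadenoma\tNA\tHET\tHOM",
                 "s2\tcancer_le7\t6\tGAIN\tNA"), f)
    x <- readAberrationMatrix(f)
    expect_identical(aberrationCalls(x)["L1", "s1"], "HET_LOSS")
    expect_identical(aberrationCalls(x)["L2", "s1"], "HOM_LOSS")
    expect_identical(aberrationCalls(x)["L1", "s2"], "GAIN")
    expect_identical(aberrationCalls(x)["L2", "s2"], "MISSING")
    expect_identical(x$gleason, c(NA_integer_, 6L))
})

test_that("parse errors name the offending row and column", {
    f <- withr::local_tempfile(fileext = ".tsv")
    hdr <- c("sample_id\tgroup\tgleason\tL1\tL2", ".\t.\t.\tg\tg",
             ".\t.\t.\tNA\tNA")
    writeLines(c(hdr, "s1\tadenoma\tNA\tHET\tBOGUS"), f)
    expect_error(readAberrationMatrix(f), "BOGUS.*line 4.*L2")
    writeLines(c(hdr, "s1\tadenoma\tNA\tOK\tOK",
                 "s1\tadenoma\tNA\tOK\tOK"), f)
    expect_error(readAberrationMatrix(f), "duplicate sample")
    writeLines(c("sample_id\tgroup\tgleason\tL1\tL1", hdr[2:3],
                 "s1\tadenoma\tNA\tOK\tOK"), f)
    expect_error(readAberrationMatrix(f), "duplicate locus")
    writeLines(c(hdr, "s1\tadenoma\tNA\tOK"), f)
    expect_error(readAberrationMatrix(f), "ragged")
})

test_that("group frequencies count losses over full group sizes", {
    calls <- matrix("UNCHANGED", 1, 15,
                    dimnames = list("L1", sprintf("s%02d", 1:15)))
    calls[1, 1:10] <- "HET_LOSS"
    calls[1, 11] <- "HOM_LOSS"
    calls[1, 12] <- "MISSING"       # stays in the denominator
    x <- makeAE(calls, rep("adenoma", 15))
    fr <- groupFrequencies(x, "adenoma")
    expect_identical(fr$n_aberrant, 11L)
    expect_identical(fr$n_total, 15L)
    expect_equal(fr$fraction, 11 / 15)
    expect_identical(fr$cell, "73% (11/15)")
    ## zero-aberrant locus
    x0 <- makeAE(matrix("GAIN", 1, 4, dimnames = list("L1", NULL)),
                 rep("cancer_gt7", 4))
    expect_equal(groupFrequencies(x0, "cancer_gt7")$fraction, 0)
    expect_error(groupFrequencies(x, "no_such_group"), "group label")
})

test_that("group frequencies match a brute-force recount", {
    x <- generateCohort(defaultDesign(seed = 4))
    fr <- groupFrequencies(x)
    calls <- aberrationCalls(x)
    for (r in sample(nrow(fr), 50)) {
        j <- which(sampleGroups(x) == fr$group[r])
        i <- which(rownames(x) == fr$notI_site_id[r])
        k <- 0L
        for (jj in j)
            if (calls[i, jj] %in% c("HET_LOSS", "HOM_LOSS")) k <- k + 1L
        expect_identical(fr$n_aberrant[r], k)
        expect_identical(fr$n_total[r], length(j))
    }
})

test_that("the altered-locus filter applies a strict pooled cutoff", {
    calls <- matrix("UNCHANGED", 3, 33)
    rownames(calls) <- c("keep", "dropEq", "keepGain")
    calls["keep", 1:4] <- "HET_LOSS"        # 4/33 = 0.121 > 0.10
    calls["dropEq", 1:3] <- "HOM_LOSS"      # 3/33 = 0.091 <= 0.10
    calls["keepGain", 1:4] <- "GAIN"        # gains count as changes
    x <- makeAE(calls, rep(c("adenoma", "cancer_le7", "cancer_gt7"),
                           c(15, 14, 4)))
    kept <- filterAlteredLoci(x, minFraction = 0.10)
    expect_setequal(kept$notI_site_id, c("keep", "keepGain"))
})

test_that("raising the filter cutoff never grows the locus set", {
    x <- generateCohort(defaultDesign(seed = 6))
    sizes <- vapply(seq(0, 0.9, by = 0.1), function(th)
        nrow(filterAlteredLoci(x, minFraction = th)), numeric(1))
    expect_true(all(diff(sizes) <= 0))
    ## and the kept set equals a brute-force recount at 0.10
    calls <- aberrationCalls(x)
    frac <- apply(calls, 1, function(r)
        mean(r %in% c("HET_LOSS", "HOM_LOSS", "GAIN")))
    expect_setequal(filterAlteredLoci(x, minFraction = 0.1)$notI_site_id,
                    rownames(x)[frac > 0.1])
})

test_that("alteration census is exhaustive and conserved", {
    x <- makeAE(matrix("UNCHANGED", 3, 3), rep("adenoma", 3))
    expect_identical(alterationCensus(x),
                     c(het_loss = 0L, hom_loss = 0L, gain = 0L,
                       unchanged = 9L, missing = 0L))
    y <- generateCohort(defaultDesign(seed = 10))
    cen <- alterationCensus(y)
    expect_identical(sum(cen), nrow(y) * ncol(y))
    expect_identical(cen[["het_loss"]],
                     sum(aberrationCalls(y) == "HET_LOSS"))
    ## a design forced to homozygous losses only
    d <- plantedDesign(10, 10, pTrue = 1, pNull = 1)
    d@homFraction <- 1
    z <- generateCohort(d, 1)
    expect_identical(alterationCensus(z)[["hom_loss"]],
                     nrow(z) * ncol(z))
})

test_that("locus ranking is a descending permutation with id tie-break", {
    calls <- matrix("UNCHANGED", 3, 10)
    rownames(calls) <- c("B", "A", "C")
    calls["B", 1:5] <- "HET_LOSS"
    calls["A", 1:5] <- "HOM_LOSS"    # tied with B -> A first
    calls["C", 1:8] <- "HET_LOSS"
    x <- makeAE(calls, rep("adenoma", 10))
    tab <- rankLociTable(x)
    expect_identical(tab$notI_site_id, c("C", "A", "B"))
    ## permutation of all loci, descending pooled frequency
    y <- generateCohort(defaultDesign(seed = 13))
    full <- rankLociTable(y)
    expect_setequal(full$notI_site_id, rownames(y))
    expect_true(all(diff(full$pooled_fraction) <= 1e-12))
    expect_identical(nrow(rankLociTable(y, topN = 50)), 50L)
})

test_that("bisulfite summary counts NotI-methylated clones", {
    ## 11 clones, 6 methylated at both NotI CpGs
    m <- matrix(0L, 11, 10)
    m[1:6, 3:4] <- 1L
    g <- BisulfiteCloneGrid(m, notiPositions = 3:4)
    s <- bisulfiteSiteSummary(g)
    expect_equal(s$notI_fraction, 6 / 11)
    ## all-unmethylated grid
    s0 <- bisulfiteSiteSummary(BisulfiteCloneGrid(matrix(0L, 3, 4), 1:2))
    expect_equal(s0$notI_fraction, 0)
    expect_true(all(s0$per_clone_density == 0))
})

test_that("bisulfite summary matches a hand count on a 4x5 grid", {
    m <- matrix(c(1, 1, 1, 0, 1,      # clone1: NotI (cols 1-2) methylated
                  1, 0, 0, 0, NA,     # clone2: not fully NotI-methylated
                  NA, 1, 1, 1, 1,     # clone3: no data at a NotI column
                  1, 1, 0, 1, 1),     # clone4: NotI methylated
                4, 5, byrow = TRUE)
    rownames(m) <- paste0("cl", 1:4)
    s <- bisulfiteSiteSummary(BisulfiteCloneGrid(m, notiPositions = 1:2))
    ## informative at NotI: clones 1,2,4; fully methylated there: 1,4
    expect_equal(s$notI_fraction, 2 / 3)
    expect_equal(unname(s$per_clone_density),
                 c(4 / 5, 1 / 4, 4 / 4, 4 / 5))
})

test_that("bisulfite grids read from TSV with starred NotI columns", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("clone\tCG1\tCG2*\tCG3*\tCG4",
                 "cl1\t1\t1\t1\t0",
                 "cl2\t0\tNA\t1\t1"), f)
    g <- readBisulfiteGrid(f)
    expect_identical(g@notiPositions, 2:3)
    expect_identical(dim(g@calls), c(2L, 4L))
    expect_equal(bisulfiteSiteSummary(g)$notI_fraction, 1)
})

test_that("delta-delta-Cq fold changes follow the closed form", {
    ## identical tumor and calibrator
    r <- qpcrFoldChange(20, c(18, 19, 20), 20, c(18, 19, 20))
    expect_equal(r$fold_change, 1)
    expect_identical(r$call, "unchanged")
    ## ddCq = +1.585 -> ~3-fold down
    r3 <- qpcrFoldChange(21.585, c(20, 20, 20), 20, c(20, 20, 20))
    expect_equal(r3$fold_change, 2^-1.585)
    expect_identical(r3$call, "down")
    ## random fixture vs closed form
    set.seed(30)
    tc <- runif(8, 20, 30)
    rc <- matrix(runif(24, 18, 25), 8, 3)
    out <- qpcrFoldChange(tc, rc, 22, c(19, 20, 21))
    manual <- 2^-((tc - rowMeans(rc)) - (22 - mean(c(19, 20, 21))))
    expect_equal(out$fold_change, manual, tolerance = 1e-12)
    expect_identical(out$call,
                     ifelse(manual <= 0.5, "down",
                            ifelse(manual >= 2, "up", "unchanged")))
    expect_error(qpcrFoldChange(NA, c(1, 2), 1, c(1, 2)), "finite")
})
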