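## Independent brute-force oracles: each recomputes a quantity by direct
## enumeration or explicit loops, never through the package's code path.

## Two-sided exact P by full enumeration over all tables with the observed
## margins (point-probability rule, relative tie tolerance 1e-7).
oracleFisher <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
    support <- max(0, c1 - r2):min(r1, c1)
    pt <- vapply(support, function(x)
        exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)),
        numeric(1))
    obs <- pt[match(a, support)]
    sum(pt[pt <= obs * (1 + 1e-7)])
}

## Pearson chi-square P from the textbook formula.
oracleChisq <- function(tab, yates = FALSE) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    dev <- abs(tab - E)
    if (yates) dev <- pmax(dev - 0.5, 0)
    stats::pchisq(sum(dev^2 / E), df = 1, lower.tail = FALSE)
}

## Gini of one explicit tie ordering, AUC counted by a pair double loop.
oracleGini <- function(scores, labels, direction = "ge", ties = "best") {
    s <- if (direction == "ge") scores else -scores
    ord <- if (ties == "best") order(-s, !labels) else order(-s, labels)
    lab <- labels[ord]
    pos <- which(lab); neg <- which(!lab)
    before <- 0L
    for (i in pos) for (j in neg) if (i < j) before <- before + 1L
    2 * before / (length(pos) * length(neg)) - 1
}

## Link counts by explicit loops over an edge data.frame.
oracleCountLinks <- function(edges, A, B, mode = "direct") {
    if (mode == "direct") {
        n <- 0L
        for (i in seq_len(nrow(edges))) {
            u <- edges$from[i]; v <- edges$to[i]
            if ((u %in% A && v %in% B) || (u %in% B && v %in% A))
                n <- n + 1L
        }
        return(n)
    }
    nodes <- unique(c(edges$from, edges$to))
    adj <- sapply(nodes, function(v)
        unique(c(edges$to[edges$from == v], edges$from[edges$to == v])),
        simplify = FALSE)
    seen <- character(); total <- 0L
    for (a in intersect(A, nodes)) for (b in intersect(B, nodes)) {
        if (a == b) next
        key <- paste(sort(c(a, b)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        total <- total + length(intersect(adj[[a]], adj[[b]]))
    }
    total
}

## Benjamini-Hochberg step-up by its definition.
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

## Small AberrationExperiment from a state matrix and group labels.
makeAE <- function(calls, groups, genes = rownames(calls)) {
    if (is.null(rownames(calls)))
        rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
    if (is.null(genes)) genes <- rownames(calls)
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
    AberrationExperiment(calls,
        lociData = S4Vectors::DataFrame(notI_site_id = rownames(calls),
                                        gene_symbol = genes,
                                        cytoband = NA_character_),
        sampleData = S4Vectors::DataFrame(group = groups))
}

## Two-group planted design used by the classifier tests: nTrue
## informative loci against null loci, all independent Bernoulli.
plantedDesign <- function(nPos, nNeg, nTrue = 5L, nNull = 15L,
                          pTrue = 0.9, pNull = 0.05,
                          posGroup = "cancer_le7", negGroup = "adenoma") {
    genes <- c(sprintf("TRUE%d", seq_len(nTrue)),
               sprintf("NULL%02d", seq_len(nNull)))
    loci <- S4Vectors::DataFrame(notI_site_id = genes, gene_symbol = genes,
                                 cytoband = NA_character_)
    p <- matrix(pNull, nTrue + nNull, 2,
                dimnames = list(genes, c(posGroup, negGroup)))
    p[seq_len(nTrue), posGroup] <- pTrue
    groups <- stats::setNames(c(as.integer(nPos), as.integer(nNeg)),
                              c(posGroup, negGroup))
    new("CohortDesign", groups = groups, loci = loci, aberrationProb = p,
        gainProb = p * 0, homFraction = 0.3, missingProb = 0, seed = 1L)
}
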