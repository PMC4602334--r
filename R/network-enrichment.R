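#' Build a FunctionalNetwork from an edge table
#'
#' @param edges `data.frame` with columns `from`, `to` and optionally
#'   `score`; gene symbols are uppercased, self-loops dropped and
#'   duplicate edges merged (keeping the maximum score).
#' @param genes optional vector of vertex names to include even when
#'   isolated.
#' @param provenance default provenance tag for edges lacking one.
#' @return A [FunctionalNetwork-class].
#' @examples
#' functionalNetwork(data.frame(from = c("a", "b"), to = c("b", "c")))
#' @export
functionalNetwork <- function(edges, genes = NULL, provenance = "curated") {
    edges$from <- toupper(as.character(edges$from))
    edges$to <- toupper(as.character(edges$to))
    if (is.null(edges$score))
        edges$score <- rep(NA_real_, nrow(edges))
    if (is.null(edges$provenance))
        edges$provenance <- rep(provenance, nrow(edges))
    if (!is.null(genes)) genes <- toupper(as.character(genes))
    verts <- unique(c(edges$from, edges$to, genes))
    g <- igraph::graph_from_data_frame(
        edges[, c("from", "to", "score", "provenance")],
        directed = FALSE, vertices = verts)
    g <- igraph::simplify(g, edge.attr.comb = list(
        score = function(s) if (all(is.na(s))) NA_real_ else
            max(s, na.rm = TRUE),
        provenance = function(p) if (length(unique(p)) > 1L) "both"
            else p[1L]))
    new("FunctionalNetwork", graph = g)
}

#' Load a functional network from scored and curated edge lists
#'
#' Scored files are 3-column TSVs (geneA, geneB, confidence score in
#' `[0,1]`, FunCoup-style); only edges with score strictly above
#' `scoreThreshold` are kept. Curated files are 2-column TSVs and enter
#' unconditionally. The union is deduplicated into a simple undirected
#' graph with uppercased symbols; an edge present in both sources is
#' tagged `"both"`.
#'
#' @param scoredFiles,curatedFiles character vectors of file paths.
#' @param scoreThreshold confidence cutoff for scored edges (strict;
#'   default 0.5).
#' @return A [FunctionalNetwork-class].
#' @export
loadNetwork <- function(scoredFiles = character(),
                        curatedFiles = character(), scoreThreshold = 0.5) {
    parse <- function(path, ncolReq, tag) {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(parts) < ncolReq)
        if (length(bad))
            stop("malformed line ", bad[1L], " in ", path,
                 ": expected at least ", ncolReq, " tab-separated fields")
        data.frame(
            from = vapply(parts, `[`, "", 1L),
            to = vapply(parts, `[`, "", 2L),
            score = if (ncolReq >= 3L)
                as.numeric(vapply(parts, `[`, "", 3L)) else NA_real_,
            provenance = tag, stringsAsFactors = FALSE)
    }
    scored <- lapply(scoredFiles, parse, ncolReq = 3L, tag = "scored")
    curated <- lapply(curatedFiles, parse, ncolReq = 2L, tag = "curated")
    edges <- do.call(rbind, c(scored, curated))
    if (is.null(edges) || !nrow(edges))
        stop("no edges parsed")
    if (anyNA(edges$score[edges$provenance == "scored"]))
        stop("non-numeric score in scored edge list")
    keep <- edges$provenance == "curated" | edges$score > scoreThreshold
    functionalNetwork(edges[keep, , drop = FALSE])
}

#' @describeIn functionalNetwork vertex names of a network.
#' @param network a [FunctionalNetwork-class].
#' @export
networkGenes <- function(network) igraph::V(network@graph)$name

#' @describeIn functionalNetwork edge table (`from`, `to`, `score`,
#'   `provenance`) of a network.
#' @export
networkEdges <- function(network) {
    g <- network@graph
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1L], to = el[, 2L],
               score = if ("score" %in% igraph::edge_attr_names(g))
                   igraph::E(g)$score else NA_real_,
               provenance = if ("provenance" %in%
                                igraph::edge_attr_names(g))
                   igraph::E(g)$provenance else NA_character_,
               stringsAsFactors = FALSE)
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes the network by double-edge swaps, preserving every
#' vertex's degree and the total edge count: the null model behind the
#' permutation mode of [neaTest()].
#'
#' @param network a [FunctionalNetwork-class].
#' @param seed integer seed.
#' @param swapsPerEdge number of attempted swaps per edge (default 10).
#' @return A rewired [FunctionalNetwork-class].
#' @export
rewireNetwork <- function(network, seed, swapsPerEdge = 10L) {
    g <- withSeed(seed, .rewire(network@graph, swapsPerEdge))
    new("FunctionalNetwork", graph = g)
}

.rewire <- function(g, swapsPerEdge = 10L) {
    niter <- max(100L, swapsPerEdge * igraph::ecount(g))
    igraph::rewire(g, igraph::keeping_degseq(niter = niter))
}

#' Count network links between two gene sets
#'
#' Direct mode counts edges with one endpoint in `setA` and the other in
#' `setB`, each edge once; with `setA == setB` this is the within-set
#' edge count. Shared-neighbor (indirect) mode counts, over unordered
#' pairs `(a, b)` with `a` in `setA`, `b` in `setB`, `a != b`, the total
#' number of network vertices adjacent to both. Genes absent from the
#' network are ignored; genes in both sets contribute each qualifying
#' edge or pair exactly once.
#'
#' @param network a [FunctionalNetwork-class].
#' @param setA,setB character vectors of gene symbols.
#' @param mode `"direct"` or `"shared_neighbor"`.
#' @return A non-negative integer count; symmetric in `setA`/`setB`.
#' @examples
#' net <- functionalNetwork(data.frame(from = "A", to = "B"))
#' countLinks(net, "A", "B")
#' @export
setMethod("countLinks", "FunctionalNetwork",
    function(network, setA, setB, mode = c("direct", "shared_neighbor")) {
        mode <- match.arg(mode)
        g <- network@graph
        A <- intersect(toupper(setA), networkGenes(network))
        B <- intersect(toupper(setB), networkGenes(network))
        if (!length(A) || !length(B)) return(0L)
        if (mode == "direct") {
            el <- igraph::as_edgelist(g)
            hit <- (el[, 1L] %in% A & el[, 2L] %in% B) |
                   (el[, 1L] %in% B & el[, 2L] %in% A)
            return(sum(hit))
        }
        M <- igraph::as_adjacency_matrix(g, sparse = TRUE)
        ai <- match(A, rownames(M)); bi <- match(B, rownames(M))
        S <- as.matrix(M[ai, , drop = FALSE] %*%
                       Matrix::t(M[bi, , drop = FALSE]))
        pa <- rep(ai, times = length(bi))
        pb <- rep(bi, each = length(ai))
        keep <- pa != pb & !duplicated(paste(pmin(pa, pb), pmax(pa, pb)))
        sum(S[cbind(rep(seq_along(ai), times = length(bi))[keep],
                    rep(seq_along(bi), each = length(ai))[keep])])
    })

#' Network enrichment test between two gene sets
#'
#' Tests whether the observed link count between `setA` and `setB`
#' exceeds chance. The permutation null regenerates the network by
#' degree-preserving double-edge swaps `nPerm` times and recounts;
#' `expected` is the permutation mean, `z = (obs - mean)/sd`, and the
#' one-sided P value is the add-one-smoothed upper empirical
#' probability, `(1 + #{perm >= obs}) / (nPerm + 1)`. The analytic null
#' (direct mode only) takes the expected count as
#' `D_A * D_B / (2m)` — `D` the summed degrees of each set, `m` the
#' edge total — with a Poisson upper tail. Deterministic given `seed`.
#'
#' @param network a [FunctionalNetwork-class].
#' @param setA,setB character gene sets.
#' @param mode `"direct"` or `"shared_neighbor"`.
#' @param null `"permutation"` (default) or `"analytic"`.
#' @param nPerm number of network permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param setAName,setBName labels used in the result row.
#' @return One-row [S4Vectors::DataFrame]: `set_a`, `set_b`, `mode`,
#'   `null`, `n_obs`, `expected`, `z`, `p_value`, `degenerate` (TRUE
#'   when all permuted counts were equal, in which case `p_value` rests
#'   on the empirical rank alone).
#' @examples
#' net <- generateNetwork(30, 0.05, seed = 4)
#' neaTest(net, networkGenes(net)[1:5], networkGenes(net)[6:10],
#'         nPerm = 100, seed = 1)
#' @export
setMethod("neaTest", "FunctionalNetwork",
    function(network, setA, setB, mode = c("direct", "shared_neighbor"),
             null = c("permutation", "analytic"), nPerm = 1000L,
             seed = 1L, setAName = "setA", setBName = "setB") {
        mode <- match.arg(mode)
        null <- match.arg(null)
        obs <- countLinks(network, setA, setB, mode)
        if (null == "analytic") {
            res <- .neaAnalytic(network, setA, setB, mode, obs)
        } else {
            if (nPerm < 100L) stop("nPerm must be at least 100")
            perm <- withSeed(seed, {
                g <- network@graph
                vapply(seq_len(nPerm), function(i) {
                    g <<- .rewire(g)
                    countLinks(new("FunctionalNetwork", graph = g),
                               setA, setB, mode)
                }, numeric(1))
            })
            s <- stats::sd(perm)
            res <- list(expected = mean(perm),
                        z = if (s > 0) (obs - mean(perm)) / s else NA_real_,
                        p = (1 + sum(perm >= obs)) / (nPerm + 1),
                        degenerate = s == 0)
            if (res$degenerate)
                warning("all permuted counts equal; z undefined, ",
                        "p from empirical rank only")
        }
        S4Vectors::DataFrame(set_a = setAName, set_b = setBName,
                             mode = mode, null = null,
                             n_obs = as.integer(obs),
                             expected = res$expected, z = res$z,
                             p_value = res$p, degenerate = res$degenerate)
    })

## Configuration-model expectation of the direct link count. For disjoint
## sets this is D_A * D_B / (2m); edges inside the overlap A-and-B are
## counted once, contributing D_I^2 / (4m), so the general form decomposes
## over (A minus I), (B minus I) and I.
.neaAnalytic <- function(network, setA, setB, mode, obs) {
    if (mode != "direct")
        stop("the analytic null is defined for direct mode only")
    g <- network@graph
    A <- intersect(toupper(setA), networkGenes(network))
    B <- intersect(toupper(setB), networkGenes(network))
    m <- igraph::ecount(g)
    I <- intersect(A, B)
    dI <- sum(igraph::degree(g, I))
    dA <- sum(igraph::degree(g, setdiff(A, I)))
    dB <- sum(igraph::degree(g, setdiff(B, I)))
    lambda <- (dA * dB + dA * dI + dI * dB) / (2 * m) + dI^2 / (4 * m)
    list(expected = lambda,
         z = if (lambda > 0) (obs - lambda) / sqrt(lambda) else NA_real_,
         p = stats::ppois(obs - 1L, lambda, lower.tail = FALSE),
         degenerate = FALSE)
}

#' Screen marker sets against a pathway collection
#'
#' Runs [neaTest()] for every (marker set, pathway) pair and for each
#' marker set against itself (within-set consistency, reported with
#' `set_b = "within-set"`), applies Benjamini-Hochberg FDR across the
#' whole family, and reports the relations with at least `minLinks`
#' observed links and FDR below `fdrThreshold`, sorted by FDR and then
#' by observed links (descending).
#'
#' @param network a [FunctionalNetwork-class].
#' @param markerSets,pathways named lists of character gene sets (e.g.
#'   from [readGmt()]).
#' @inheritParams neaTest
#' @param minLinks minimum observed links for a reported relation.
#' @param fdrThreshold FDR cutoff for reported relations.
#' @param all if `TRUE`, return the full tested family with a `pass`
#'   column instead of the filtered report.
#' @return A [S4Vectors::DataFrame], one row per tested pair, with an
#'   `fdr` column added to the [neaTest()] fields.
#' @export
neaScreen <- function(network, markerSets, pathways = list(),
                      mode = c("direct", "shared_neighbor"),
                      null = c("permutation", "analytic"),
                      nPerm = 1000L, seed = 1L, minLinks = 10L,
                      fdrThreshold = 0.01, all = FALSE) {
    mode <- match.arg(mode)
    null <- match.arg(null)
    if (!length(markerSets)) stop("at least one marker set is required")
    pairs <- list()
    for (ms in names(markerSets)) {
        for (pw in names(pathways))
            pairs[[length(pairs) + 1L]] <-
                list(a = ms, b = pw, A = markerSets[[ms]],
                     B = pathways[[pw]], label = pw)
        pairs[[length(pairs) + 1L]] <-
            list(a = ms, b = "within-set", A = markerSets[[ms]],
                 B = markerSets[[ms]], label = "within-set")
    }
    rows <- lapply(seq_along(pairs), function(i) {
        p <- pairs[[i]]
        neaTest(network, p$A, p$B, mode = mode, null = null,
                nPerm = nPerm, seed = seed + i - 1L,
                setAName = p$a, setBName = p$b)
    })
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p_value, method = "BH")
    out$pass <- out$n_obs >= minLinks & out$fdr < fdrThreshold
    ord <- order(out$fdr, -out$n_obs)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    if (all) out else out[out$pass, , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Line-oriented GMT: set name, description, then member genes, all
#' tab-separated. Symbols are uppercased.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors; descriptions are kept in the
#'   `"description"` attribute of each element.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1L],
             ": need name, description and at least one gene")
    sets <- lapply(parts, function(p)
        structure(toupper(p[-(1:2)]), description = p[2L]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character gene sets.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = rep("na", length(sets))) {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
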