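## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
## Every stochastic operation in the package routes through this so that no
## call mutates global RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Resolve a group spec (character vector of group labels) to sample column
## indices of an AberrationExperiment.
resolveGroups <- function(x, groups) {
    grp <- as.character(x$group)
    unknown <- setdiff(groups, unique(grp))
    if (length(unknown))
        stop("group label(s) not present in the matrix: ",
             paste(unknown, collapse = ", "))
    which(grp %in% groups)
}

## Match marker gene symbols against rowData(x)$gene_symbol, accepting any
## slash-joined component ("LOC440944/SETD5" matches either name).
resolveMarkers <- function(x, markers) {
    sym <- as.character(SummarizedExperiment::rowData(x)$gene_symbol)
    parts <- strsplit(sym, "/", fixed = TRUE)
    idx <- vapply(markers, function(m) {
        hit <- which(sym == m | vapply(parts, function(p) m %in% p, logical(1)))
        if (!length(hit))
            stop("marker symbol not found in matrix loci: ", m)
        hit[1L]
    }, integer(1))
    unname(idx)
}

## "73% (11/15)" cells mirroring the study's frequency tables.
formatFrequencyCell <- function(k, n) {
    sprintf("%d%% (%d/%d)", round(100 * k / n), k, n)
}

## P value rendering used in report tables: 3 decimals, "<0.001" for any
## value below 0.001 (the reference tables print "<0.001" for P = 0.0007).
formatPValue <- function(p) {
    ifelse(p < 1e-3, "<0.001", sprintf("%.3f", p))
}

## Logical matrix of aberrant (methylation/deletion) calls.
isLoss <- function(calls) {
    calls == "HET_LOSS" | calls == "HOM_LOSS"
}
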