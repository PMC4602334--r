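#' Accessors for AberrationExperiment
#'
#' `aberrationCalls()` returns the character call matrix (loci x
#' samples); `sampleGroups()` the per-sample group labels; `lociInfo()`
#' the locus annotation.
#'
#' @param x an [AberrationExperiment-class].
#' @return See the individual descriptions.
#' @examples
#' x <- generateCohort(defaultDesign(seed = 5))
#' aberrationCalls(x)[1:2, 1:3]
#' table(sampleGroups(x))
#' @export
aberrationCalls <- function(x) assay(x, "calls")

#' @rdname aberrationCalls
#' @export
sampleGroups <- function(x) as.character(x$group)

#' @rdname aberrationCalls
#' @export
lociInfo <- function(x) SummarizedExperiment::rowData(x)
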