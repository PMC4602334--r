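#' @rdname markerCount
#' @export
setGeneric("markerCount", function(x, panel) standardGeneric("markerCount"))

#' @rdname classifySamples
#' @export
setGeneric("classifySamples",
           function(x, panel) standardGeneric("classifySamples"))

#' @rdname evaluatePanel
#' @export
setGeneric("evaluatePanel",
           function(x, panel) standardGeneric("evaluatePanel"))

#' @rdname countLinks
#' @export
setGeneric("countLinks", function(network, setA, setB,
                                  mode = c("direct", "shared_neighbor"))
    standardGeneric("countLinks"))

#' @rdname neaTest
#' @export
setGeneric("neaTest", function(network, setA, setB,
                               mode = c("direct", "shared_neighbor"),
                               null = c("permutation", "analytic"),
                               nPerm = 1000L, seed = 1L,
                               setAName = "setA", setBName = "setB")
    standardGeneric("neaTest"))
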