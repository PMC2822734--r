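#' @rdname geneSet
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname geneSet
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname geneSetCollection
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @rdname geneSetCollection
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
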