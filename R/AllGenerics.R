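#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("relAbund", function(x, ...) standardGeneric("relAbund"))

#' @export
setGeneric("sampleDepth", function(x) standardGeneric("sampleDepth"))

#' @export
setGeneric("asvSequences", function(x) standardGeneric("asvSequences"))

#' @export
setGeneric("asvSequences<-", function(x, value) standardGeneric("asvSequences<-"))

#' @export
setGeneric("humanFraction", function(x, partition, ...)
    standardGeneric("humanFraction"))

#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @export
setGeneric("shannonDiversity", function(x, ...)
    standardGeneric("shannonDiversity"))
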