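#' @export
setGeneric("phageIds", function(x, ...) standardGeneric("phageIds"))

#' @export
setGeneric("genomeLengths", function(x, ...) standardGeneric("genomeLengths"))

#' @export
setGeneric("dbCensus", function(x, ...) standardGeneric("dbCensus"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("activeSamples", function(x, ...) standardGeneric("activeSamples"))

#' @export
setGeneric("dyadTable", function(x, ...) standardGeneric("dyadTable"))

#' @export
setGeneric("phageKeys", function(x, ...) standardGeneric("phageKeys"))

#' @export
setGeneric("calledSets", function(x, ...) standardGeneric("calledSets"))

#' @export
setGeneric("renameDatabaseSequences",
           function(x, prefix, ...) standardGeneric("renameDatabaseSequences"))
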