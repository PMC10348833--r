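#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @export
setGeneric("txNames", function(x) standardGeneric("txNames"))

#' @export
setGeneric("subexons", function(x) standardGeneric("subexons"))

#' @export
setGeneric("nSubexons", function(x) standardGeneric("nSubexons"))

#' @export
setGeneric("txSignature", function(x, tx) standardGeneric("txSignature"))

#' @export
setGeneric("donorSites", function(x) standardGeneric("donorSites"))

#' @export
setGeneric("acceptorSites", function(x) standardGeneric("acceptorSites"))

#' @export
setGeneric("intronTable", function(x) standardGeneric("intronTable"))

#' @export
setGeneric("junctionTable", function(x) standardGeneric("junctionTable"))

#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @export
setGeneric("fragmentSeqs", function(x) standardGeneric("fragmentSeqs"))

#' @export
setGeneric("sigCounts", function(x) standardGeneric("sigCounts"))

#' @export
setGeneric("mappingStats", function(x) standardGeneric("mappingStats"))
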