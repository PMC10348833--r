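# Accessors and show() methods.

#' @describeIn GeneModel-class gene identifier
#' @param x a GeneModel
#' @export
setMethod("geneID", "GeneModel", function(x) x@geneID)

#' @describeIn GeneModel-class transcript identifiers
#' @export
setMethod("txNames", "GeneModel", function(x) names(x@exonsByTx))

#' @describeIn GeneModel-class subexon partition as an IRanges
#' @export
setMethod("subexons", "GeneModel", function(x) x@subexons)

#' @describeIn GeneModel-class number of subexons
#' @export
setMethod("nSubexons", "GeneModel", function(x) length(x@subexons))

#' @describeIn GeneModel-class subexon index sequence of transcript \code{tx}
#' @param tx transcript identifier
#' @export
setMethod("txSignature", "GeneModel", function(x, tx) {
  if (!tx %in% names(x@txSignatures))
    stop("unknown transcript '", tx, "' in gene ", x@geneID)
  x@txSignatures[[tx]]
})

#' @describeIn GeneModel-class annotated donor site coordinates
#' @export
setMethod("donorSites", "GeneModel", function(x) x@donors)

#' @describeIn GeneModel-class annotated acceptor site coordinates
#' @export
setMethod("acceptorSites", "GeneModel", function(x) x@acceptors)

#' @describeIn GeneModel-class annotated introns (one row per unique intron)
#' @export
setMethod("intronTable", "GeneModel", function(x) x@introns)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s:%d-%d %s)\n", object@geneID, object@chrom,
              min(start(object@subexons)), max(end(object@subexons)),
              object@strand))
  cat(sprintf("  %d transcripts, %d subexons, %d annotated introns\n",
              length(object@exonsByTx), length(object@subexons),
              nrow(object@introns)))
  for (tx in names(object@txSignatures))
    cat(sprintf("  %s: (%s)\n", tx, sigKey(object@txSignatures[[tx]])))
})

#' @describeIn SpliceGraph-class junction edges (annotated + guessed/discovered)
#' @param x a SpliceGraph
#' @export
setMethod("junctionTable", "SpliceGraph", function(x) x@junctions)

setMethod("show", "SpliceGraph", function(object) {
  st <- table(factor(object@junctions$status,
                     levels = c("annotated", "guessed", "discovered")))
  cat(sprintf(
    "SpliceGraph of %s [mode=%s]: %d nodes, %d unspliced edges, %d junctions (%d annotated, %d guessed, %d discovered)\n",
    object@gene@geneID, object@mode, length(object@gene@subexons),
    length(object@adjacent), nrow(object@junctions),
    st[["annotated"]], st[["guessed"]], st[["discovered"]]))
})

#' @describeIn FragmentSet-class per-fragment metadata
#' @param x a FragmentSet
#' @export
setMethod("fragmentTable", "FragmentSet", function(x) x@table)

#' @describeIn FragmentSet-class fragment sequences
#' @export
setMethod("fragmentSeqs", "FragmentSet", function(x) x@seqs)

setMethod("length", "FragmentSet", function(x) nrow(x@table))

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet %s (mode=%s, l=%d): %d fragments, %d nt total\n",
              object@variant, object@mode, object@readLength,
              nrow(object@table), sum(width(object@seqs))))
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex k=%d over %d fragments (%d postings)\n",
              object@k, length(object@fragments), nrow(object@postings)))
})

#' @describeIn SignatureCounts-class counts table (gene, sig, count)
#' @param x a SignatureCounts
#' @export
setMethod("sigCounts", "SignatureCounts", function(x) x@counts)

#' @describeIn SignatureCounts-class mapped/unmapped/ambiguous read totals
#' @export
setMethod("mappingStats", "SignatureCounts", function(x) {
  c(mapped = x@mapped, unmapped = x@unmapped, ambiguous = x@ambiguous)
})

setMethod("show", "SignatureCounts", function(object) {
  cat(sprintf(
    "SignatureCounts: %d classes, %d reads mapped (%d unmapped, %d ambiguous)\n",
    nrow(object@counts), object@mapped, object@unmapped, object@ambiguous))
})
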