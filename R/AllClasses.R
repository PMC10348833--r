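#' GeneModel: one gene's transcripts, splice sites and subexon partition
#'
#' A \code{GeneModel} holds, for a single gene, the annotated transcripts
#' (exon intervals), the subexon partition (smallest exonic units bounded by
#' splice sites or transcript start/end sites, numbered 1..n in increasing
#' genomic order), the per-transcript subexon index sequences, the annotated
#' introns and the donor/acceptor site sets. All coordinates are 1-based and
#' closed, on the genomic forward strand.
#'
#' Donor and acceptor sites are stored as the genomic coordinate of the
#' exonic base adjacent to the intron on the transcription 5' (donor) or 3'
#' (acceptor) side; for a '+' gene the donor of an intron [a,b] is a-1 and
#' the acceptor b+1, mirrored on '-'.
#'
#' @slot geneID gene identifier
#' @slot chrom chromosome name
#' @slot strand "+" or "-"
#' @slot exonsByTx named list of \link[IRanges]{IRanges}, one per transcript,
#'   sorted, disjoint, abutting exons merged
#' @slot txSignatures named list of strictly increasing integer vectors: the
#'   subexon index sequence of each transcript
#' @slot subexons \link[IRanges]{IRanges} of the subexon partition
#' @slot subexonTx list of character vectors: transcripts containing each
#'   subexon
#' @slot introns data.frame of unique annotated introns with columns
#'   \code{start}, \code{end} (first/last intronic base), \code{donor},
#'   \code{acceptor}, \code{txs}
#' @slot donors,acceptors integer vectors of annotated splice-site
#'   coordinates
#' @exportClass GeneModel
setClass("GeneModel", representation(
  geneID = "character",
  chrom = "character",
  strand = "character",
  exonsByTx = "list",
  txSignatures = "list",
  subexons = "IRanges",
  subexonTx = "list",
  introns = "data.frame",
  donors = "integer",
  acceptors = "integer"
))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  se <- object@subexons
  n <- length(se)
  if (n == 0L) msg <- c(msg, "gene has no subexons")
  if (n > 1L) {
    if (is.unsorted(start(se), strictly = TRUE))
      msg <- c(msg, "subexons not sorted by start")
    if (any(start(se)[-1L] <= end(se)[-n]))
      msg <- c(msg, "subexons overlap")
  }
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@txSignatures) != length(object@exonsByTx))
    msg <- c(msg, "one signature per transcript required")
  for (tx in names(object@txSignatures)) {
    sig <- object@txSignatures[[tx]]
    if (length(sig) && is.unsorted(sig, strictly = TRUE))
      msg <- c(msg, sprintf("signature of %s not strictly increasing", tx))
    if (length(sig) &&
        sum(width(se)[sig]) != sum(width(object@exonsByTx[[tx]])))
      msg <- c(msg, sprintf("subexons of %s do not tile its exons", tx))
  }
  if (any(lengths(object@subexonTx) == 0L))
    msg <- c(msg, "every subexon must be contained in >= 1 transcript")
  if (length(msg)) msg else TRUE
})

#' SpliceGraph: subexons as nodes, unspliced adjacencies and junctions as edges
#'
#' Nodes are the subexon indices of one gene. Unspliced edges connect
#' genomically abutting subexons that occur consecutively inside one exon of
#' an annotated transcript; spliced edges are annotated, guessed
#' (mode-dependent) or discovered junctions. Every annotated transcript's
#' subexon index sequence is a path in every mode.
#'
#' @slot gene the \linkS4class{GeneModel}
#' @slot mode "annotated", "as" or "ap"
#' @slot adjacent integer vector: i present iff unspliced edge (i, i+1)
#' @slot junctions data.frame with columns \code{from}, \code{to} (subexon
#'   indices), \code{intronStart}, \code{intronEnd}, \code{status}
#'   (annotated/guessed/discovered)
#' @exportClass SpliceGraph
setClass("SpliceGraph", representation(
  gene = "GeneModel",
  mode = "character",
  adjacent = "integer",
  junctions = "data.frame"
))

setValidity("SpliceGraph", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("annotated", "as", "ap"))
    msg <- c(msg, "mode must be annotated, as or ap")
  j <- object@junctions
  if (nrow(j) && any(j$from >= j$to))
    msg <- c(msg, "junction edges must go left to right")
  n <- length(object@gene@subexons)
  if (length(object@adjacent) && any(object@adjacent >= n))
    msg <- c(msg, "adjacency index out of range")
  if (length(msg)) msg else TRUE
})

#' FragmentSet: transcript fragments over feasible signatures
#'
#' One fragment per (maximal) feasible signature, with the fragment name
#' encoding the signature and the included first/last subexon lengths
#' (grammar \code{gene|i1,i2,...|a,b}), the nucleotide sequence (genomic
#' forward strand) and the segment breakpoints used by the positional scan.
#'
#' @slot variant "F11", "Fmax" or "F"
#' @slot readLength the read length l the set was built for
#' @slot mode the splice-graph mode the signatures were enumerated under
#' @slot table data.frame with one row per fragment: \code{name},
#'   \code{gene}, \code{sigKey}, and list columns \code{sig} (integer
#'   vector; negative entries are intron pseudo-segments), \code{segStart},
#'   \code{segEnd} (genomic coordinates per segment) and \code{cum}
#'   (cumulative segment end offsets within the fragment)
#' @slot seqs \link[Biostrings]{DNAStringSet} of fragment sequences, parallel
#'   to \code{table}
#' @exportClass FragmentSet
setClass("FragmentSet", representation(
  variant = "character",
  readLength = "integer",
  mode = "character",
  table = "data.frame",
  seqs = "DNAStringSet"
))

setValidity("FragmentSet", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("F11", "Fmax", "F"))
    msg <- c(msg, "variant must be F11, Fmax or F")
  if (nrow(object@table) != length(object@seqs))
    msg <- c(msg, "table and seqs must be parallel")
  if (nrow(object@table)) {
    segLen <- mapply(function(s, e) sum(e - s + 1L),
                     object@table$segStart, object@table$segEnd)
    if (any(segLen != width(object@seqs)))
      msg <- c(msg, "sequence length must equal sum of included segment lengths")
  }
  if (length(msg)) msg else TRUE
})

#' KmerIndex: k-mer postings over a fragment set
#'
#' Maps every k-mer of every fragment to its (fragment, offset) postings;
#' the mapping engine looks up anchor k-mers of a read and votes on the
#' implied read start offset within each candidate fragment.
#'
#' @slot k k-mer size
#' @slot postings data.table keyed by \code{kmer} with columns \code{frag}
#'   (row index into the fragment table) and \code{pos} (1-based offset of
#'   the k-mer within the fragment)
#' @slot fragments the indexed \linkS4class{FragmentSet}
#' @exportClass KmerIndex
setClass("KmerIndex", representation(
  k = "integer",
  postings = "data.table",
  fragments = "FragmentSet"
))

#' SignatureCounts: reads per mapping signature per gene
#'
#' Two reads are equivalent iff their mapping signatures are identical; this
#' class stores the sizes of the resulting equivalence classes together with
#' mapping bookkeeping (mapped + unmapped + ambiguous = input reads;
#' ambiguous reads are excluded from the counts).
#'
#' @slot counts data.frame with columns \code{gene}, \code{sig} (comma-joined
#'   subexon indices) and \code{count}
#' @slot mapped,unmapped,ambiguous integer totals
#' @exportClass SignatureCounts
setClass("SignatureCounts", representation(
  counts = "data.frame",
  mapped = "integer",
  unmapped = "integer",
  ambiguous = "integer"
))

setValidity("SignatureCounts", function(object) {
  msg <- character(0)
  need <- c("gene", "sig", "count")
  if (!all(need %in% names(object@counts)))
    msg <- c(msg, "counts needs columns gene, sig, count")
  else if (nrow(object@counts) && any(object@counts$count < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})
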