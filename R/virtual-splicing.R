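# Guessing novel junctions between annotated splice sites and assembling
# the splice graph whose path language stands in for the virtual
# transcriptomes (annotated < as < ap). Virtual transcriptomes are never
# materialized during indexing; the graph makes every feasible signature a
# local, bounded walk.

# Candidate donor-acceptor pairs in transcription order with the intron in
# internal coordinates; shared by both guessing modes.
candidateJunctions <- function(gm, minIntron) {
  donors <- gm@donors; acceptors <- gm@acceptors
  if (!length(donors) || !length(acceptors)) {
    return(data.frame(intronStart = integer(0), intronEnd = integer(0),
                      donor = integer(0), acceptor = integer(0)))
  }
  grid <- expand.grid(donor = donors, acceptor = acceptors)
  if (gm@strand == "+") {
    grid$intronStart <- grid$donor + 1L
    grid$intronEnd <- grid$acceptor - 1L
  } else {
    grid$intronStart <- grid$acceptor + 1L
    grid$intronEnd <- grid$donor - 1L
  }
  grid <- grid[grid$intronEnd - grid$intronStart + 1L >= minIntron, ,
               drop = FALSE]
  if (nrow(grid) && nrow(gm@introns)) {
    key <- paste(grid$intronStart, grid$intronEnd)
    akey <- paste(gm@introns$start, gm@introns$end)
    grid <- grid[!key %in% akey, , drop = FALSE]
  }
  # both endpoints must sit on subexon boundaries (they do by construction:
  # splice sites are cut points), and splice only at exon/intron borders
  se <- gm@subexons
  grid <- grid[(grid$intronStart - 1L) %in% end(se) &
                 (grid$intronEnd + 1L) %in% start(se), , drop = FALSE]
  grid[order(grid$intronStart, grid$intronEnd), , drop = FALSE]
}

#' Guess novel junctions under the alternative-splicing virtual transcriptome
#'
#' Returns every donor-acceptor pair, both annotated in the gene and in
#' transcription order, that is not an annotated intron and whose implied
#' novel intron classifies as exon skipping, alternative donor, alternative
#' acceptor or alternative donor-acceptor pair with respect to at least one
#' annotated transcript. Intronless genes yield an empty set.
#'
#' @param gm a \linkS4class{GeneModel}
#' @param minIntron minimum guessed intron length in nt (degenerate
#'   micro-introns are rejected)
#' @param maxJunctions cap on guessed junctions per gene (warning when hit)
#' @return data.frame with columns intronStart, intronEnd, donor, acceptor,
#'   status ("guessed")
#' @export
guessJunctionsAS <- function(gm, minIntron = 20L, maxJunctions = 50000L) {
  cand <- candidateJunctions(gm, minIntron)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$intronStart[i]; b <- cand$intronEnd[i]
    for (tx in txNames(gm)) {
      ex <- gm@exonsByTx[[tx]]
      if (max(end(ex)) < a || min(start(ex)) > b) next
      type <- classifyIntron(gm, a, b, tx)$type
      if (type %in% c("ES", "AD", "AA", "AP")) { keep[i] <- TRUE; break }
    }
  }
  res <- cand[keep, , drop = FALSE]
  if (nrow(res) > maxJunctions) {
    warning("gene ", gm@geneID, ": guessed junction cap (", maxJunctions,
            ") reached; truncating")
    res <- res[seq_len(maxJunctions), , drop = FALSE]
  }
  res$status <- rep("guessed", nrow(res))
  rownames(res) <- NULL
  res
}

#' Guess novel junctions under the alternative-processing virtual
#' transcriptome
#'
#' The laxer superset of \code{\link{guessJunctionsAS}}: every non-annotated
#' donor-acceptor pair in transcription order is admitted (annotated sites
#' only; touching exons of different transcripts are still never merged,
#' which is a property of the unspliced edges, not of junctions).
#'
#' @inheritParams guessJunctionsAS
#' @export
guessJunctionsAP <- function(gm, minIntron = 20L, maxJunctions = 50000L) {
  res <- candidateJunctions(gm, minIntron)
  if (nrow(res) > maxJunctions) {
    warning("gene ", gm@geneID, ": guessed junction cap (", maxJunctions,
            ") reached; truncating")
    res <- res[seq_len(maxJunctions), , drop = FALSE]
  }
  res$status <- rep("guessed", nrow(res))
  rownames(res) <- NULL
  res
}

#' Build the splice graph of a gene
#'
#' Nodes are subexon indices. Unspliced edges connect genomically abutting
#' subexons that lie consecutively inside one exon of an annotated
#' transcript (touching exons of different transcripts are never merged).
#' Spliced edges are the annotated introns plus, depending on the mode, the
#' guessed junction set; discovered junctions (refine phase) can be added
#' explicitly. Every annotated transcript's subexon index sequence is a
#' path in every mode.
#'
#' @param gm a \linkS4class{GeneModel}
#' @param mode "annotated", "as" or "ap"
#' @param minIntron,maxJunctions see \code{\link{guessJunctionsAS}}
#' @param extraJunctions optional data.frame of discovered junctions
#'   (columns intronStart, intronEnd) added as spliced edges with status
#'   "discovered"
#' @return a \linkS4class{SpliceGraph}
#' @export
buildSpliceGraph <- function(gm, mode = c("annotated", "as", "ap"),
                             minIntron = 20L, maxJunctions = 50000L,
                             extraJunctions = NULL) {
  mode <- match.arg(mode)
  se <- gm@subexons
  n <- length(se)

  adjacent <- integer(0)
  for (tx in txNames(gm)) {
    ex <- gm@exonsByTx[[tx]]
    sig <- txSignature(gm, tx)
    for (p in seq_len(max(0L, length(sig) - 1L))) {
      i <- sig[p]; j <- sig[p + 1L]
      if (j == i + 1L && start(se)[j] == end(se)[i] + 1L &&
          any(start(ex) <= end(se)[i] & end(ex) >= start(se)[j]))
        adjacent <- c(adjacent, i)
    }
  }
  adjacent <- sort(unique(adjacent))

  jn <- gm@introns
  junctions <- data.frame(
    from = match(jn$start - 1L, end(se)),
    to = match(jn$end + 1L, start(se)),
    intronStart = jn$start, intronEnd = jn$end,
    status = rep("annotated", nrow(jn)))
  guessed <- switch(mode,
    annotated = NULL,
    as = guessJunctionsAS(gm, minIntron, maxJunctions),
    ap = guessJunctionsAP(gm, minIntron, maxJunctions))
  if (!is.null(guessed) && nrow(guessed)) {
    junctions <- rbind(junctions, data.frame(
      from = match(guessed$intronStart - 1L, end(se)),
      to = match(guessed$intronEnd + 1L, start(se)),
      intronStart = guessed$intronStart, intronEnd = guessed$intronEnd,
      status = guessed$status))
  }
  if (!is.null(extraJunctions) && nrow(extraJunctions)) {
    from <- match(extraJunctions$intronStart - 1L, end(se))
    to <- match(extraJunctions$intronEnd + 1L, start(se))
    ok <- !is.na(from) & !is.na(to)
    if (any(ok)) {
      junctions <- rbind(junctions, data.frame(
        from = from[ok], to = to[ok],
        intronStart = extraJunctions$intronStart[ok],
        intronEnd = extraJunctions$intronEnd[ok],
        status = rep("discovered", sum(ok))))
    }
  }
  if (nrow(junctions)) {
    if (anyNA(junctions$from) || anyNA(junctions$to))
      stop("internal error: junction endpoint not on a subexon boundary")
    key <- paste(junctions$intronStart, junctions$intronEnd)
    junctions <- junctions[!duplicated(key), , drop = FALSE]
    junctions <- junctions[order(junctions$from, junctions$to), , drop = FALSE]
    rownames(junctions) <- NULL
  }
  new("SpliceGraph", gene = gm, mode = mode, adjacent = adjacent,
      junctions = junctions)
}

# Successor/predecessor lists of a splice graph.
graphEdges <- function(graph) {
  n <- length(graph@gene@subexons)
  out <- vector("list", n); inc <- vector("list", n)
  for (i in graph@adjacent) {
    out[[i]] <- c(out[[i]], i + 1L)
    inc[[i + 1L]] <- c(inc[[i + 1L]], i)
  }
  j <- graph@junctions
  for (r in seq_len(nrow(j))) {
    out[[j$from[r]]] <- c(out[[j$from[r]]], j$to[r])
    inc[[j$to[r]]] <- c(inc[[j$to[r]]], j$from[r])
  }
  list(out = lapply(out, function(x) sort(unique(x))),
       inc = lapply(inc, function(x) sort(unique(x))))
}

# Anchoring data for as-mode signatures: for each annotated transcript t,
# the nodes inside t's genomic span, and which of them are reachable from a
# transcript-start node / can reach a transcript-end node without leaving
# the span. A signature is as-anchored iff for some t all its nodes lie in
# the span, its first node is start-reachable and its last node is
# end-reachable: it is then a window of an explicit virtual transcript.
anchorSets <- function(graph) {
  gm <- graph@gene
  se <- gm@subexons
  n <- length(se)
  edges <- graphEdges(graph)
  starts <- vapply(gm@txSignatures, function(s) s[1L], integer(1))
  ends <- vapply(gm@txSignatures, function(s) s[length(s)], integer(1))
  res <- list()
  for (tx in txNames(gm)) {
    ex <- gm@exonsByTx[[tx]]
    lo <- min(start(ex)); hi <- max(end(ex))
    ok <- start(se) >= lo & end(se) <= hi
    fwd <- logical(n); fwd[starts[ok[starts]]] <- TRUE
    for (i in seq_len(n)) {
      if (!ok[i] || fwd[i]) next
      pre <- edges$inc[[i]]
      if (length(pre) && any(fwd[pre] & ok[pre])) fwd[i] <- TRUE
    }
    bwd <- logical(n); bwd[ends[ok[ends]]] <- TRUE
    for (i in rev(seq_len(n))) {
      if (!ok[i] || bwd[i]) next
      suc <- edges$out[[i]]
      if (length(suc) && any(bwd[suc] & ok[suc])) bwd[i] <- TRUE
    }
    res[[tx]] <- list(ok = ok, fwd = fwd & ok, bwd = bwd & ok)
  }
  res
}

# Does the mode's transcriptome contain a transcript with sig as a
# contiguous window? annotated: contiguous subsequence of some annotated
# signature; as: anchoring test above; ap: always (any walk extends to a
# source-to-sink path).
sigAnchored <- function(sig, graph, anchors, mode = graph@mode) {
  switch(mode,
    annotated = any(vapply(graph@gene@txSignatures, function(t)
      isContiguousSub(sig, t), logical(1))),
    as = any(vapply(anchors, function(a)
      all(a$ok[sig]) && a$fwd[sig[1L]] && a$bwd[sig[length(sig)]],
      logical(1))),
    ap = TRUE)
}

#' Write a junction table for inspection
#' @param graph a \linkS4class{SpliceGraph}
#' @param path output TSV path
#' @export
writeJunctions <- function(graph, path) {
  gm <- graph@gene
  j <- graph@junctions
  plus <- gm@strand == "+"
  out <- data.frame(
    gene = rep(gm@geneID, nrow(j)), chrom = rep(gm@chrom, nrow(j)),
    donor = if (plus) j$intronStart - 1L else j$intronEnd + 1L,
    acceptor = if (plus) j$intronEnd + 1L else j$intronStart - 1L,
    strand = rep(gm@strand, nrow(j)), status = j$status)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
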