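# Classification of novel introns into alternative-splicing event types.
#
# Every novel intron implied by a mapping signature is compared pairwise to
# every annotated transcript of its gene; the same intron can imply
# different event types with respect to different transcripts. Types:
#   IE  novel intron strictly inside one exon (exitron)
#   ES  (multi-)exon skipping: >= 1 complete exon strictly inside the
#       intron; classical iff the intron spans exactly from the end of the
#       preceding kept exon to the start of the following kept exon
#   AD  alternative donor: acceptor matches an intron of t, donor does not
#   AA  alternative acceptor: donor matches, acceptor does not
#   AP  alternative donor-acceptor pair: neither matches, but the intron
#       overlaps an intron of t
#   UNK none of the above (would require read assembly to classify)
# Precedence is IE, ES, AD, AA, AP, UNK.

#' Classify a novel intron against one annotated transcript
#'
#' @param gm the \linkS4class{GeneModel}
#' @param intronStart,intronEnd first and last intronic base of the novel
#'   intron (1-based, genomic)
#' @param tx transcript identifier to compare against
#' @return list with elements \code{type} (one of ES, AD, AA, AP, IE, UNK),
#'   \code{classical} (logical; ES only, NA otherwise) and
#'   \code{skippedExons} (integer; ES only, 0 otherwise)
#' @export
classifyIntron <- function(gm, intronStart, intronEnd, tx) {
  a <- as.integer(intronStart); b <- as.integer(intronEnd)
  if (a > b) stop("empty intron")
  ex <- gm@exonsByTx[[tx]]
  if (is.null(ex)) stop("unknown transcript '", tx, "'")
  itab <- gm@introns
  if (nrow(itab)) {
    hit <- itab$start == a & itab$end == b
    if (any(hit) && tx %in% strsplit(itab$txs[hit], ",")[[1]])
      stop("intron ", a, "-", b, " is annotated in transcript ", tx,
           " (not novel)")
  }
  plus <- gm@strand == "+"
  donorPos <- if (plus) a - 1L else b + 1L
  acceptorPos <- if (plus) b + 1L else a - 1L

  # IE: strictly inside one exon
  if (any(start(ex) < a & b < end(ex)))
    return(list(type = "IE", classical = NA, skippedExons = 0L))

  # ES: >= 1 complete exon of tx inside the intron
  inside <- start(ex) >= a & end(ex) <= b
  if (any(inside)) {
    classical <- any(end(ex) == a - 1L) && any(start(ex) == b + 1L)
    return(list(type = "ES", classical = classical,
                skippedExons = sum(inside)))
  }

  if (length(ex) >= 2L) {
    txIntronStart <- end(ex)[-length(ex)] + 1L
    txIntronEnd <- start(ex)[-1L] - 1L
    txDonors <- if (plus) txIntronStart - 1L else txIntronEnd + 1L
    txAcceptors <- if (plus) txIntronEnd + 1L else txIntronStart - 1L
    donorMatch <- donorPos %in% txDonors
    acceptorMatch <- acceptorPos %in% txAcceptors
    if (acceptorMatch && !donorMatch)
      return(list(type = "AD", classical = NA, skippedExons = 0L))
    if (donorMatch && !acceptorMatch)
      return(list(type = "AA", classical = NA, skippedExons = 0L))
    if (!donorMatch && !acceptorMatch &&
        any(txIntronStart <= b & txIntronEnd >= a))
      return(list(type = "AP", classical = NA, skippedExons = 0L))
  }
  list(type = "UNK", classical = NA, skippedExons = 0L)
}

# Junction occurrences in a signature: consecutive positive entries (i, j)
# whose genomic gap is spliced over. Adjacent abutting subexons are
# unspliced coverage, not junctions; pairs flanking an intron pseudo-entry
# (negative) are retention coverage, not junctions.
sigJunctions <- function(gm, sig) {
  res <- list()
  if (length(sig) < 2L) return(res)
  se <- gm@subexons
  for (p in seq_len(length(sig) - 1L)) {
    i <- sig[p]; j <- sig[p + 1L]
    if (i < 0L || j < 0L) next
    if (j == i + 1L && start(se)[j] == end(se)[i] + 1L) next
    res[[length(res) + 1L]] <- c(from = i, to = j,
                                 intronStart = end(se)[i] + 1L,
                                 intronEnd = start(se)[j] - 1L)
  }
  res
}

isAnnotatedIntron <- function(gm, intronStart, intronEnd) {
  nrow(gm@introns) > 0L &&
    any(gm@introns$start == intronStart & gm@introns$end == intronEnd)
}

#' Annotate all novel splicing events implied by signature counts
#'
#' Every signature containing at least one novel junction contributes its
#' count to that junction; each novel junction is classified against every
#' annotated transcript of its gene that overlaps the junction span,
#' producing one record per (junction, transcript) pair.
#'
#' @param counts a \linkS4class{SignatureCounts}
#' @param models named list of \linkS4class{GeneModel}
#' @return data.frame with columns gene, chrom, strand, donor, acceptor,
#'   intronStart, intronEnd, transcript, type, classical, skippedExons,
#'   supportingCount
#' @export
annotateEvents <- function(counts, models) {
  tab <- sigCounts(counts)
  out <- list()
  for (g in unique(tab$gene)) {
    gm <- models[[g]]
    if (is.null(gm)) stop("no gene model for gene ", g)
    sub <- tab[tab$gene == g, , drop = FALSE]
    # supporting count per novel junction
    support <- list()
    for (r in seq_len(nrow(sub))) {
      sig <- sigParse(sub$sig[r])
      for (jn in sigJunctions(gm, sig)) {
        if (isAnnotatedIntron(gm, jn[["intronStart"]], jn[["intronEnd"]]))
          next
        key <- paste(jn[["intronStart"]], jn[["intronEnd"]])
        if (is.null(support[[key]])) support[[key]] <- c(jn, count = 0)
        support[[key]]["count"] <- support[[key]]["count"] + sub$count[r]
      }
    }
    plus <- gm@strand == "+"
    for (key in names(support)) {
      jn <- support[[key]]
      a <- jn[["intronStart"]]; b <- jn[["intronEnd"]]
      donorPos <- if (plus) a - 1L else b + 1L
      acceptorPos <- if (plus) b + 1L else a - 1L
      for (tx in txNames(gm)) {
        ex <- gm@exonsByTx[[tx]]
        if (max(end(ex)) < a || min(start(ex)) > b) next
        cls <- classifyIntron(gm, a, b, tx)
        out[[length(out) + 1L]] <- data.frame(
          gene = g, chrom = gm@chrom, strand = gm@strand,
          donor = donorPos, acceptor = acceptorPos,
          intronStart = a, intronEnd = b, transcript = tx,
          type = cls$type, classical = cls$classical,
          skippedExons = cls$skippedExons,
          supportingCount = as.integer(jn[["count"]]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      strand = character(0), donor = integer(0),
                      acceptor = integer(0), intronStart = integer(0),
                      intronEnd = integer(0), transcript = character(0),
                      type = character(0), classical = logical(0),
                      skippedExons = integer(0),
                      supportingCount = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$intronStart, res$intronEnd, res$transcript), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect intron retention from signature counts
#'
#' Conservative rule: a retained intron is reported for an intronic gap I
#' (a region between consecutive subexons that is exonic in no transcript)
#' iff at least one read maps contiguously across an exon-intron boundary
#' of I or within I, and no junction with an intron boundary strictly
#' inside I has nonzero count. Reads across/within I are observed through
#' intron-inclusion fragments (see \code{withIntrons} in
#' \code{\link{buildFragments}}).
#'
#' @param counts a \linkS4class{SignatureCounts}
#' @param models named list of \linkS4class{GeneModel}
#' @param extraJunctions optional data.frame of additional observed
#'   junctions (columns chrom, intronStart, intronEnd, count), e.g. from a
#'   spliced-aligner junction file, applied to condition (c)
#' @return data.frame with one row per retained intron: gene, chrom,
#'   strand, leftSubexon, intronStart, intronEnd, type ("IR"),
#'   supportingCount
#' @export
detectIntronRetention <- function(counts, models, extraJunctions = NULL) {
  tab <- sigCounts(counts)
  out <- list()
  for (g in unique(tab$gene)) {
    gm <- models[[g]]
    if (is.null(gm)) stop("no gene model for gene ", g)
    sub <- tab[tab$gene == g, , drop = FALSE]
    gaps <- intronicGaps(gm)
    if (!nrow(gaps)) next
    # observed junction intron boundaries with nonzero count
    jStarts <- integer(0); jEnds <- integer(0)
    for (r in seq_len(nrow(sub))) {
      if (sub$count[r] <= 0) next
      for (jn in sigJunctions(gm, sigParse(sub$sig[r]))) {
        jStarts <- c(jStarts, jn[["intronStart"]])
        jEnds <- c(jEnds, jn[["intronEnd"]])
      }
    }
    if (!is.null(extraJunctions) && nrow(extraJunctions)) {
      ej <- extraJunctions[extraJunctions$chrom == gm@chrom &
                             extraJunctions$count > 0, , drop = FALSE]
      jStarts <- c(jStarts, ej$intronStart)
      jEnds <- c(jEnds, ej$intronEnd)
    }
    for (i in seq_len(nrow(gaps))) {
      k <- gaps$leftSubexon[i]
      gs <- gaps$start[i]; ge <- gaps$end[i]
      supp <- 0L
      for (r in seq_len(nrow(sub))) {
        if (-k %in% sigParse(sub$sig[r])) supp <- supp + sub$count[r]
      }
      if (supp == 0L) next
      spliceInside <- any(jStarts > gs & jStarts <= ge) ||
        any(jEnds >= gs & jEnds < ge)
      if (spliceInside) next
      out[[length(out) + 1L]] <- data.frame(
        gene = g, chrom = gm@chrom, strand = gm@strand, leftSubexon = k,
        intronStart = gs, intronEnd = ge, type = "IR",
        supportingCount = as.integer(supp))
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      strand = character(0), leftSubexon = integer(0),
                      intronStart = integer(0), intronEnd = integer(0),
                      type = character(0), supportingCount = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
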