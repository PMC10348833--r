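# Gene model construction: subexon partition, transcript signatures,
# splice-site bookkeeping, GTF/FASTA parsing.

#' Subexon partition of a set of transcripts
#'
#' Cuts the exonic union of all transcripts of one gene at every exon start
#' and end (splice sites and transcript start/end sites), yielding the
#' smallest exonic units -- subexons -- numbered left to right starting at 1.
#' Abutting exons within one transcript must be merged beforehand (the
#' GeneModel constructor does); boundaries between touching exons of
#' different transcripts are kept.
#'
#' @param exonsByTx list of \link[IRanges]{IRanges}, one element per
#'   transcript
#' @param extraBreaks integer vector of additional cut positions: a value c
#'   cuts between c and c+1 (used when incorporating discovered splice
#'   sites)
#' @return \link[IRanges]{IRanges} of subexons, sorted by start
#' @export
subexonPartition <- function(exonsByTx, extraBreaks = integer(0)) {
  if (length(exonsByTx) == 0L) stop("empty transcript set")
  all <- do.call(c, unname(exonsByTx))
  se <- sort(disjoin(all))
  if (length(extraBreaks)) {
    extraBreaks <- sort(unique(as.integer(extraBreaks)))
    starts <- integer(0); ends <- integer(0)
    for (i in seq_along(se)) {
      s <- start(se)[i]; e <- end(se)[i]
      cuts <- extraBreaks[extraBreaks >= s & extraBreaks < e]
      bs <- c(s, cuts + 1L)
      be <- c(cuts, e)
      starts <- c(starts, bs); ends <- c(ends, be)
    }
    se <- IRanges(start = starts, end = ends)
  }
  se
}

# Subexon index sequence of one transcript over a given partition; checks
# that the subexons tile the transcript's exons exactly.
transcriptSignatureFor <- function(exons, subexonRanges) {
  ov <- findOverlaps(subexonRanges, exons)
  idx <- sort(unique(queryHits(ov)))
  if (sum(width(subexonRanges)[idx]) != sum(width(exons)) ||
      any(start(subexonRanges)[idx] < min(start(exons))) ||
      any(end(subexonRanges)[idx] > max(end(exons))))
    stop("subexon set inconsistent with transcript (invariant breach)")
  idx
}

#' Build a GeneModel from per-transcript exon intervals
#'
#' @param geneID,chrom,strand gene metadata; strand "*" is treated as "+"
#'   with a warning
#' @param exonsByTx named list of \link[IRanges]{IRanges} (one per
#'   transcript); abutting exons within a transcript are merged
#' @param extraBreaks additional cut positions (see
#'   \code{\link{subexonPartition}})
#' @return a \linkS4class{GeneModel}
#' @export
geneModelFromExons <- function(geneID, chrom, strand, exonsByTx,
                               extraBreaks = integer(0)) {
  if (length(exonsByTx) == 0L) stop("gene ", geneID, " has no transcripts")
  if (is.null(names(exonsByTx)) || any(!nzchar(names(exonsByTx))))
    stop("exonsByTx must be a named list")
  if (identical(strand, "*") || is.na(strand)) {
    warning("gene ", geneID, " is unstranded; treating as '+'")
    strand <- "+"
  }
  exonsByTx <- lapply(exonsByTx, function(x) reduce(sort(x)))
  se <- subexonPartition(exonsByTx, extraBreaks)
  txSigs <- lapply(exonsByTx, transcriptSignatureFor, subexonRanges = se)
  subexonTx <- lapply(seq_along(se), function(i) {
    names(exonsByTx)[vapply(txSigs, function(s) i %in% s, logical(1))]
  })

  introns <- data.frame(start = integer(0), end = integer(0),
                        donor = integer(0), acceptor = integer(0),
                        txs = character(0))
  for (tx in names(exonsByTx)) {
    ex <- exonsByTx[[tx]]
    if (length(ex) < 2L) next
    a <- end(ex)[-length(ex)] + 1L
    b <- start(ex)[-1L] - 1L
    d <- if (strand == "+") a - 1L else b + 1L
    ac <- if (strand == "+") b + 1L else a - 1L
    introns <- rbind(introns, data.frame(start = a, end = b, donor = d,
                                         acceptor = ac, txs = tx))
  }
  if (nrow(introns)) {
    key <- paste(introns$start, introns$end)
    agg <- tapply(introns$txs, key, function(x) paste(sort(x), collapse = ","))
    introns <- introns[!duplicated(key), , drop = FALSE]
    introns$txs <- as.character(agg[paste(introns$start, introns$end)])
    introns <- introns[order(introns$start, introns$end), , drop = FALSE]
    rownames(introns) <- NULL
  }

  new("GeneModel", geneID = geneID, chrom = chrom, strand = strand,
      exonsByTx = exonsByTx, txSignatures = txSigs, subexons = se,
      subexonTx = subexonTx, introns = introns,
      donors = sort(unique(introns$donor)),
      acceptors = sort(unique(introns$acceptor)))
}

#' Parse a GTF annotation and genome FASTA into gene models
#'
#' Requires exon feature rows with \code{gene_id} and \code{transcript_id}
#' attributes (Ensembl/RefSeq dialects); gene/transcript rows are optional.
#' Transcripts of one gene on different chromosomes are rejected, and a
#' chromosome referenced by the GTF but missing from the FASTA is a hard
#' error naming the chromosome.
#'
#' @param gtfPath path to the GTF file
#' @param fastaPath path to the genome FASTA
#' @return list with elements \code{models} (named list of
#'   \linkS4class{GeneModel}) and \code{genome}
#'   (\link[Biostrings]{DNAStringSet}, names trimmed to the first word)
#' @export
parseAnnotation <- function(gtfPath, fastaPath) {
  lines <- readLines(gtfPath)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", gtfPath,
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", gtfPath)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("GTF exon records must carry gene_id and transcript_id attributes")

  genome <- readGenome(fastaPath)

  models <- list()
  for (g in unique(gr$gene_id)) {
    sub <- gr[gr$gene_id == g]
    chroms <- unique(as.character(seqnames(sub)))
    if (length(chroms) > 1L)
      stop("gene ", g, " has transcripts on multiple chromosomes: ",
           paste(chroms, collapse = ", "))
    if (!chroms %in% names(genome))
      stop("no sequence available for chromosome '", chroms, "'")
    strands <- unique(as.character(BiocGenerics::strand(sub)))
    strand <- if (length(strands) == 1L) strands else "*"
    exonsByTx <- lapply(split(ranges(sub), sub$transcript_id), identity)
    models[[g]] <- geneModelFromExons(g, chroms, strand, exonsByTx)
  }
  list(models = models, genome = genome)
}

#' Read a genome FASTA, trimming sequence names to their first word
#' @param fastaPath path to FASTA (plain or gzipped)
#' @export
readGenome <- function(fastaPath) {
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Serialize gene models to a TSV (stable, byte-identical across runs)
#'
#' One row per transcript with its exon chain and subexon signature; a
#' paired reader reconstructs identical models.
#'
#' @param models named list of \linkS4class{GeneModel}
#' @param path output TSV path
#' @export
writeGeneModels <- function(models, path) {
  rows <- list()
  for (g in names(models)) {
    gm <- models[[g]]
    for (tx in txNames(gm)) {
      ex <- gm@exonsByTx[[tx]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, chrom = gm@chrom, strand = gm@strand, tx = tx,
        exons = paste(sprintf("%d-%d", start(ex), end(ex)), collapse = ";"),
        signature = sigKey(txSignature(gm, tx)))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$tx), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models serialized by \code{\link{writeGeneModels}}
#' @param path TSV path
#' @export
readGeneModels <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  models <- list()
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    exonsByTx <- list()
    for (i in seq_len(nrow(sub))) {
      parts <- strsplit(strsplit(sub$exons[i], ";", fixed = TRUE)[[1]],
                        "-", fixed = TRUE)
      exonsByTx[[sub$tx[i]]] <- IRanges(
        start = as.integer(vapply(parts, `[`, "", 1L)),
        end = as.integer(vapply(parts, `[`, "", 2L)))
    }
    models[[g]] <- geneModelFromExons(g, sub$chrom[1L], sub$strand[1L],
                                      exonsByTx)
  }
  models
}

# Intronic gaps of a gene: maximal regions between consecutive subexons that
# are exonic in no transcript. Returns a data.frame with the left subexon
# index and the gap coordinates.
intronicGaps <- function(gm) {
  se <- gm@subexons
  n <- length(se)
  if (n < 2L) {
    return(data.frame(leftSubexon = integer(0), start = integer(0),
                      end = integer(0)))
  }
  gap <- which(start(se)[-1L] > end(se)[-n] + 1L)
  data.frame(leftSubexon = gap, start = end(se)[gap] + 1L,
             end = start(se)[gap + 1L] - 1L)
}
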