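# Refinement: incorporate novel splice sites reported by an external
# spliced aligner (junction-file dialect of STAR's SJ.out.tab) for reads
# the pseudoaligner left unmapped. Discovered sites interior to existing
# subexons split them; subexon indices are reassigned left to right and
# existing signature counts are rewritten through the remap table (a
# split index expands to all its successor indices, so totals are
# conserved); fragments are rebuilt for affected genes only and the
# previously unmapped reads are requantified.

#' Parse a spliced-aligner junction file (SJ.out.tab dialect)
#'
#' Nine tab-separated columns: chrom, intron start, intron end (1-based,
#' inclusive), strand code (0 undefined, 1 '+', 2 '-'), motif code,
#' annotated flag, unique-read count, multi-read count, max overhang.
#'
#' @param path junction file path
#' @return data.frame with typed columns (strand decoded to "+", "-", "*")
#' @export
parseSJ <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed junction file ", path, ": line ", bad[1L], " has ",
         lengths(fields)[bad[1L]], " columns (expected 9)")
  m <- do.call(rbind, fields)
  data.frame(
    chrom = m[, 1L],
    intronStart = as.integer(m[, 2L]),
    intronEnd = as.integer(m[, 3L]),
    strand = c("*", "+", "-")[as.integer(m[, 4L]) + 1L],
    motif = as.integer(m[, 5L]),
    annotated = as.integer(m[, 6L]),
    uniqueReads = as.integer(m[, 7L]),
    multiReads = as.integer(m[, 8L]),
    maxOverhang = as.integer(m[, 9L]))
}

#' Write junction records in the same 9-column dialect
#' @param records data.frame as returned by \code{\link{parseSJ}}
#' @param path output path
#' @export
writeSJ <- function(records, path) {
  m <- cbind(records$chrom, records$intronStart, records$intronEnd,
             match(records$strand, c("*", "+", "-")) - 1L, records$motif,
             records$annotated, records$uniqueReads, records$multiReads,
             records$maxOverhang)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Incorporate discovered splice sites into gene models
#'
#' Filters junction records (minimum unique reads and overhang), assigns
#' each record to the gene whose subexon span contains it, splits subexons
#' at discovered sites interior to them, reindexes subexons left to right
#' and rewrites signature counts through the old-to-new remap table.
#' Records outside any gene are skipped (novel exons are not assembled) and
#' reported.
#'
#' @param models named list of \linkS4class{GeneModel}
#' @param records data.frame from \code{\link{parseSJ}}
#' @param counts optional \linkS4class{SignatureCounts} to rewrite
#' @param minUnique,minOverhang record filters (defaults 3 and 10)
#' @return list with \code{models} (updated), \code{remap} (per gene: list
#'   old index -> integer vector of new indices), \code{discovered}
#'   (data.frame of discovered junctions per gene), \code{skipped}
#'   (records not inside any gene), \code{affected} (gene ids whose model
#'   changed or that gained a discovered junction) and \code{counts}
#'   (rewritten, if supplied)
#' @export
incorporateNovelSites <- function(models, records, counts = NULL,
                                  minUnique = 3L, minOverhang = 10L) {
  keep <- records$uniqueReads >= minUnique &
    records$maxOverhang >= minOverhang
  records <- records[keep, , drop = FALSE]

  spans <- lapply(models, function(gm)
    c(min(start(gm@subexons)), max(end(gm@subexons))))
  chroms <- vapply(models, function(gm) gm@chrom, character(1))

  skipped <- records[0, , drop = FALSE]
  byGene <- setNames(vector("list", length(models)), names(models))
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    g <- names(models)[chroms == rec$chrom &
                         vapply(spans, function(sp)
                           rec$intronStart > sp[1L] &&
                             rec$intronEnd < sp[2L], logical(1))]
    if (!length(g)) { skipped <- rbind(skipped, rec); next }
    g <- g[1L]
    byGene[[g]] <- rbind(byGene[[g]], rec)
  }

  newModels <- models
  remaps <- list()
  discovered <- list()
  affected <- character(0)
  for (g in names(models)) {
    recs <- byGene[[g]]
    if (is.null(recs) || !nrow(recs)) next
    gm <- models[[g]]
    se <- gm@subexons
    # candidate cut positions: boundary between c and c+1 for each site
    cuts <- sort(unique(c(recs$intronStart - 1L, recs$intronEnd)))
    inner <- cuts[vapply(cuts, function(c)
      any(start(se) <= c & c < end(se)), logical(1))]
    gm2 <- if (length(inner)) {
      geneModelFromExons(gm@geneID, gm@chrom, gm@strand, gm@exonsByTx,
                         extraBreaks = inner)
    } else gm
    se2 <- gm2@subexons
    remap <- lapply(seq_along(se), function(i)
      which(start(se2) >= start(se)[i] & end(se2) <= end(se)[i]))
    newModels[[g]] <- gm2
    remaps[[g]] <- remap
    akey <- paste(gm@introns$start, gm@introns$end)
    novel <- !paste(recs$intronStart, recs$intronEnd) %in% akey
    # only junctions whose both flanks are exonic become usable edges
    flankOK <- (recs$intronStart - 1L) %in% end(se2) &
      (recs$intronEnd + 1L) %in% start(se2)
    dj <- recs[novel & flankOK, , drop = FALSE]
    if (nrow(dj)) {
      discovered[[g]] <- data.frame(
        gene = g, chrom = gm@chrom,
        intronStart = dj$intronStart, intronEnd = dj$intronEnd,
        status = "discovered")
    }
    skipped <- rbind(skipped, recs[novel & !flankOK, , drop = FALSE])
    if (length(inner) || nrow(dj)) affected <- c(affected, g)
  }

  if (!is.null(counts)) counts <- remapSignatureCounts(counts, remaps)
  list(models = newModels, remap = remaps,
       discovered = if (length(discovered))
         do.call(rbind, unname(discovered))
       else data.frame(gene = character(0), chrom = character(0),
                       intronStart = integer(0), intronEnd = integer(0),
                       status = character(0)),
       skipped = skipped, affected = affected, counts = counts)
}

#' Rewrite signature counts through a subexon index remap
#'
#' A signature entry whose subexon was split expands to all successor
#' indices (splits occur at discovered sites interior to previously
#' unspliced segments, so a read overlapping the old subexon overlaps all
#' its pieces within fragments that keep the segment contiguous); counts
#' are preserved.
#'
#' @param counts a \linkS4class{SignatureCounts}
#' @param remaps per-gene remap tables (see
#'   \code{\link{incorporateNovelSites}})
#' @export
remapSignatureCounts <- function(counts, remaps) {
  tab <- sigCounts(counts)
  for (r in seq_len(nrow(tab))) {
    remap <- remaps[[tab$gene[r]]]
    if (is.null(remap)) next
    sig <- sigParse(tab$sig[r])
    new <- unlist(lapply(sig, function(i) {
      if (i > 0L) remap[[i]]
      else -max(remap[[-i]])         # gap after old k follows its last piece
    }))
    tab$sig[r] <- sigKey(new)
  }
  signatureCounts(tab, mapped = counts@mapped, unmapped = counts@unmapped,
                  ambiguous = counts@ambiguous)
}

#' Requantify previously unmapped reads after site incorporation
#'
#' Rebuilds splice graphs and fragments only for genes whose model changed
#' (including the discovered junctions as spliced edges), maps the
#' unmapped reads against the new index and returns the resulting delta
#' counts; merging into the main table is additive, so phase-1 counts are
#' never decreased.
#'
#' @param reads character vector, DNAStringSet or FASTQ path(s) of the
#'   unmapped reads
#' @param refined result of \code{\link{incorporateNovelSites}}
#' @param genome chromosome sequences
#' @param l read length
#' @param mode splice-graph mode for the rebuilt fragments
#' @param k k-mer size (default min(31, l-1))
#' @param withIntrons emit intron-inclusion fragments too
#' @return a \linkS4class{SignatureCounts} delta (empty when no gene was
#'   affected)
#' @export
requantUnmapped <- function(reads, refined, genome, l,
                            mode = c("as", "annotated", "ap"), k = NULL,
                            withIntrons = FALSE) {
  mode <- match.arg(mode)
  affected <- refined$affected
  if (!length(affected)) {
    return(signatureCounts(data.frame(gene = character(0),
                                      sig = character(0),
                                      count = integer(0))))
  }
  graphs <- lapply(affected, function(g) {
    dj <- refined$discovered
    dj <- dj[dj$gene == g, , drop = FALSE]
    buildSpliceGraph(refined$models[[g]], mode, extraJunctions = dj)
  })
  frags <- buildFragments(graphs, genome, l, variant = "F",
                          withIntrons = withIntrons)
  idx <- buildKmerIndex(frags, k)
  countReads(reads, idx)
}
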