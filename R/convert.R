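# Conversion of signature counts to other counting schemes. Signature
# counts are the finest transcriptomic counting unit: every conversion here
# is many-to-one and needs no re-processing of reads.

#' Convert signature counts to transcript compatibility counts (TCCs)
#'
#' The compatible transcript set of a signature i is the intersection of
#' t(s) over its subexons minus the union of t(s) over the gap subexons
#' (those lying between its first and last subexon but not in it), where
#' t(s) is the set of transcripts containing subexon s. Signatures whose
#' resulting set is empty arise from novel splicing patterns and are kept
#' under the reserved key \code{NOVEL}, so that total counts are conserved.
#'
#' @param counts a \linkS4class{SignatureCounts}
#' @param models named list of \linkS4class{GeneModel}
#' @return data.frame with columns gene, transcripts (comma-joined, sorted;
#'   \code{NOVEL} for the empty set) and count
#' @export
toTCC <- function(counts, models) {
  tab <- sigCounts(counts)
  keys <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    gm <- models[[tab$gene[r]]]
    if (is.null(gm)) stop("no gene model for gene ", tab$gene[r])
    keys[r] <- tccKey(gm, sigParse(tab$sig[r]))
  }
  agg <- aggregate(count ~ gene + transcripts,
                   data = data.frame(gene = tab$gene, transcripts = keys,
                                     count = tab$count),
                   FUN = sum)
  agg <- agg[order(agg$gene, agg$transcripts), c("gene", "transcripts",
                                                 "count")]
  rownames(agg) <- NULL
  agg
}

# TCC key of one signature: comma-joined sorted transcript ids, or NOVEL.
tccKey <- function(gm, sig) {
  pos <- sig[sig > 0L]
  if (length(pos) < length(sig)) return("NOVEL")   # intron-retention reads
  if (any(pos > length(gm@subexonTx))) stop("unknown subexon index")
  txSets <- gm@subexonTx[pos]
  compat <- Reduce(intersect, txSets)
  gapIdx <- setdiff(seq(min(pos), max(pos)), pos)
  if (length(gapIdx))
    compat <- setdiff(compat, unique(unlist(gm@subexonTx[gapIdx])))
  if (!length(compat)) "NOVEL" else paste(sort(compat), collapse = ",")
}

#' Convert signature counts to per-subexon counts
#'
#' For every subexon s, sums the counts of all signatures containing s
#' (a read overlapping several subexons contributes to each of them).
#'
#' @inheritParams toTCC
#' @return data.frame with columns gene, subexon, count
#' @export
toSubexonCounts <- function(counts) {
  tab <- sigCounts(counts)
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    sig <- sigParse(tab$sig[r])
    pos <- sig[sig > 0L]
    if (!length(pos)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = tab$gene[r], subexon = pos, count = tab$count[r])
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), subexon = integer(0),
                      count = integer(0)))
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(count ~ gene + subexon, data = df, FUN = sum)
  agg <- agg[order(agg$gene, agg$subexon), c("gene", "subexon", "count")]
  rownames(agg) <- NULL
  agg
}

#' Merge signatures into counting bins
#'
#' Merges signatures whose genomic spans overlap and whose compatible
#' (annotated) transcript sets are equal, by transitive closure; the bin
#' count is the sum over member signatures. This reproduces segment-library
#' style counting bins from signature counts.
#'
#' @inheritParams toTCC
#' @return data.frame with columns gene, bin (semicolon-joined member
#'   signatures), transcripts, count
#' @export
toMergedBins <- function(counts, models) {
  tab <- sigCounts(counts)
  out <- list()
  for (g in unique(tab$gene)) {
    gm <- models[[g]]
    if (is.null(gm)) stop("no gene model for gene ", g)
    sub <- tab[tab$gene == g, , drop = FALSE]
    n <- nrow(sub)
    sigs <- lapply(sub$sig, sigParse)
    keys <- vapply(sigs, tccKey, character(1), gm = gm)
    se <- gm@subexons
    spanStart <- vapply(sigs, function(s) {
      p <- abs(s); start(se)[min(p)]
    }, integer(1))
    spanEnd <- vapply(sigs, function(s) {
      p <- abs(s); end(se)[max(p)]
    }, integer(1))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (keys[i] == keys[j] && spanStart[i] <= spanEnd[j] &&
          spanStart[j] <= spanEnd[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    for (rt in sort(unique(root))) {
      members <- which(root == rt)
      out[[length(out) + 1L]] <- data.frame(
        gene = g,
        bin = paste(sub$sig[members][sigOrder(sub$sig[members])],
                    collapse = ";"),
        transcripts = keys[rt], count = sum(sub$count[members]))
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), bin = character(0),
                      transcripts = character(0), count = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$gene, df$bin), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert signature counts to splicing-graph node and edge counts
#'
#' Node counts are per-subexon counts; edge counts sum, for every junction
#' or unspliced adjacency, the counts of signatures in which its two
#' subexons appear consecutively (a signature spanning two junctions
#' increments both edges).
#'
#' @inheritParams toTCC
#' @return list with data.frames \code{nodes} (gene, subexon, count) and
#'   \code{edges} (gene, from, to, type spliced/adjacent, count)
#' @export
toGraphCounts <- function(counts, models) {
  tab <- sigCounts(counts)
  nodes <- toSubexonCounts(counts)
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    gm <- models[[tab$gene[r]]]
    if (is.null(gm)) stop("no gene model for gene ", tab$gene[r])
    sig <- sigParse(tab$sig[r])
    pos <- sig[sig > 0L]
    if (length(pos) < 2L) next
    se <- gm@subexons
    for (p in seq_len(length(pos) - 1L)) {
      i <- pos[p]; j <- pos[p + 1L]
      if (any(sig < 0L)) {
        # retention coverage between i and j is not an edge traversal
        k <- which(sig == i)
        if (sig[k + 1L] < 0L) next
      }
      type <- if (j == i + 1L && start(se)[j] == end(se)[i] + 1L)
        "adjacent" else "spliced"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = tab$gene[r], from = i, to = j, type = type,
        count = tab$count[r])
    }
  }
  edges <- if (length(rows)) {
    df <- do.call(rbind, rows)
    agg <- aggregate(count ~ gene + from + to + type, data = df, FUN = sum)
    agg <- agg[order(agg$gene, agg$from, agg$to), ]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(gene = character(0), from = integer(0), to = integer(0),
               type = character(0), count = integer(0))
  }
  list(nodes = nodes, edges = edges)
}

#' Write per-subexon counts in flattened exon-bin format
#'
#' Emits one row per subexon with a flattened bin id
#' (\code{gene:E<index>}), the layout used by exon-level differential-usage
#' tools.
#'
#' @param counts a \linkS4class{SignatureCounts}
#' @param models named list of \linkS4class{GeneModel}
#' @param path output TSV
#' @export
writeDexseqCounts <- function(counts, models, path) {
  sub <- toSubexonCounts(counts)
  full <- list()
  for (g in names(models)) {
    n <- nSubexons(models[[g]])
    cnt <- integer(n)
    here <- sub[sub$gene == g, , drop = FALSE]
    cnt[here$subexon] <- here$count
    full[[length(full) + 1L]] <- data.frame(
      bin = sprintf("%s:E%03d", g, seq_len(n)), count = cnt)
  }
  out <- do.call(rbind, full)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
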