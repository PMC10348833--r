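# Feasible-signature enumeration and fragment construction.
#
# A signature i = (i1,...,im) is feasible for read length l iff
#   f1: it is a contiguous window of a transcript of the (virtual)
#       transcriptome (a contiguous walk in the splice graph passing the
#       mode's anchoring test),
#   f2: sum of its subexon lengths >= l, and
#   f3: for m >= 3, the internal subexon lengths sum to <= l-2
# (a read must fully cover all internal subexons and still reach >= 1 nt
# into each boundary subexon). f3 bounds every walk, so enumeration is
# local. The fragment of a feasible signature is the minimal genomic
# concatenation that contains every read with that signature: with
# L_int the internal length and b = l - L_int - 1, the last min(|s_i1|, b)
# bases of the first subexon, all internal subexons, and the first
# min(|s_im|, b) bases of the last.

#' Enumerate feasible signatures over a splice graph
#'
#' @param graph a \linkS4class{SpliceGraph}
#' @param l read length (>= 2)
#' @return list with components \code{sigs} (list of integer vectors) and
#'   \code{maximal} (logical vector: no feasible signature strictly
#'   contains the signature as a contiguous subsequence)
#' @export
enumerateFeasibleSignatures <- function(graph, l) {
  l <- as.integer(l)
  if (l < 2L) stop("read length l must be >= 2")
  gm <- graph@gene
  lens <- width(gm@subexons)
  n <- length(lens)
  edges <- graphEdges(graph)
  anchors <- if (graph@mode == "as") anchorSets(graph) else NULL

  # prunable relaxation of the anchoring test: extensions only add nodes
  couldAnchor <- function(sig) {
    switch(graph@mode,
      annotated = any(vapply(gm@txSignatures, function(t)
        isContiguousSub(sig, t), logical(1))),
      as = any(vapply(anchors, function(a) all(a$ok[sig]), logical(1))),
      ap = TRUE)
  }

  sigs <- list()
  walk <- function(sig, internalSum) {
    # internalSum = sum of lengths of sig[-1][- last]; maintained by caller
    if (sum(lens[sig]) >= l && sigAnchored(sig, graph, anchors))
      sigs[[length(sigs) + 1L]] <<- sig
    last <- sig[length(sig)]
    for (nxt in edges$out[[last]]) {
      newInternal <- internalSum + lens[last] * (length(sig) > 1L)
      if (newInternal > l - 2L) next
      ext <- c(sig, nxt)
      if (!couldAnchor(ext)) next
      walk(ext, newInternal)
    }
  }
  for (i1 in seq_len(n)) {
    if (!couldAnchor(i1)) next
    walk(i1, 0L)
  }

  feasSet <- new.env(hash = TRUE)
  for (s in sigs) assign(sigKey(s), TRUE, envir = feasSet)
  isFeasibleExt <- function(ext) {
    m <- length(ext)
    if (m >= 3L && sum(lens[ext[2:(m - 1L)]]) > l - 2L) return(FALSE)
    # f2 holds a fortiori; anchoring must be re-checked
    sigAnchored(ext, graph, anchors)
  }
  maximal <- vapply(sigs, function(sig) {
    first <- sig[1L]; last <- sig[length(sig)]
    for (p in edges$inc[[first]]) if (isFeasibleExt(c(p, sig))) return(FALSE)
    for (s in edges$out[[last]]) if (isFeasibleExt(c(sig, s))) return(FALSE)
    TRUE
  }, logical(1))

  ord <- sigOrder(vapply(sigs, sigKey, character(1)))
  list(sigs = sigs[ord], maximal = maximal[ord])
}

# Included first/last lengths of the minimal (F11) fragment of a feasible
# signature.
eq1Lengths <- function(sig, lens, l) {
  m <- length(sig)
  if (m == 1L) return(c(lens[sig], lens[sig]))
  Lint <- if (m > 2L) sum(lens[sig[2:(m - 1L)]]) else 0L
  b <- l - Lint - 1L
  c(min(lens[sig[1L]], b), min(lens[sig[m]], b))
}

# Assemble fragment rows (metadata + sequence) for signatures with given
# included boundary lengths. sig entries may include negative intron
# pseudo-segments (whose coordinates are supplied via segment overrides in
# buildFragments' intron branch).
fragmentRows <- function(gm, chromSeq, sigs, firstLens, lastLens) {
  se <- gm@subexons
  name <- character(length(sigs))
  segStart <- vector("list", length(sigs))
  segEnd <- vector("list", length(sigs))
  cum <- vector("list", length(sigs))
  seqs <- character(length(sigs))
  for (i in seq_along(sigs)) {
    sig <- sigs[[i]]
    m <- length(sig)
    ss <- start(se)[sig]; ee <- end(se)[sig]
    ss[1L] <- ee[1L] - firstLens[i] + 1L
    ee[m] <- start(se)[sig[m]] + lastLens[i] - 1L
    if (m == 1L) { ss <- start(se)[sig]; ee <- end(se)[sig] }
    segStart[[i]] <- ss; segEnd[[i]] <- ee
    cum[[i]] <- cumsum(ee - ss + 1L)
    name[i] <- sprintf("%s|%s|%d,%d", gm@geneID, sigKey(sig),
                       ee[1L] - ss[1L] + 1L, ee[m] - ss[m] + 1L)
    seqs[i] <- paste(vapply(seq_len(m), function(q)
      as.character(subseq(chromSeq, ss[q], ee[q])), character(1)),
      collapse = "")
  }
  data.frame(name = name, gene = rep(gm@geneID, length(sigs)),
             sigKey = vapply(sigs, sigKey, character(1)),
             sig = I(sigs), segStart = I(segStart), segEnd = I(segEnd),
             cum = I(cum), seq = seqs)
}

#' Build a fragment set for one or more genes
#'
#' Variants: \code{F11} has one minimally trimmed fragment per feasible
#' signature; \code{Fmax} keeps only maximal signatures with first/last
#' subexons included in full; \code{F} (the default, used for mapping)
#' takes the maximal signatures, additionally emits every subexon of length
#' >= l as a singleton fragment, and trims the first/last subexon
#' contribution of the remaining fragments to at most l-1 nt, so that every
#' mapping overlapping a trimmed boundary subexon also overlaps the next
#' internal one. Signature counts obtained by mapping a read set against
#' any of the three variants are identical.
#'
#' @param graphs a \linkS4class{SpliceGraph} or list of them
#' @param genome \link[Biostrings]{DNAStringSet} of chromosome sequences
#' @param l read length
#' @param variant "F", "Fmax" or "F11"
#' @param withIntrons also emit one intron-inclusion fragment per intronic
#'   gap (at most l-1 nt of each flanking subexon plus the full intron);
#'   the intron is a pseudo-segment written as a negative signature entry
#'   and excluded from the subexon index space
#' @return a \linkS4class{FragmentSet}
#' @export
buildFragments <- function(graphs, genome, l, variant = c("F", "Fmax", "F11"),
                           withIntrons = FALSE) {
  variant <- match.arg(variant)
  if (is(graphs, "SpliceGraph")) graphs <- list(graphs)
  l <- as.integer(l)
  rows <- list()
  for (graph in graphs) {
    gm <- graph@gene
    cs <- chromSeq(genome, gm@chrom)
    enum <- enumerateFeasibleSignatures(graph, l)
    lens <- width(gm@subexons)
    if (variant == "F11") {
      sigs <- enum$sigs
      fl <- t(vapply(sigs, eq1Lengths, numeric(2), lens = lens, l = l))
      tab <- fragmentRows(gm, cs, sigs, as.integer(fl[, 1L]),
                          as.integer(fl[, 2L]))
    } else if (variant == "Fmax") {
      sigs <- enum$sigs[enum$maximal]
      first <- vapply(sigs, function(s) lens[s[1L]], integer(1))
      last <- vapply(sigs, function(s) lens[s[length(s)]], integer(1))
      tab <- fragmentRows(gm, cs, sigs, first, last)
    } else {
      sigs <- enum$sigs[enum$maximal]
      multi <- sigs[lengths(sigs) >= 2L]
      first <- vapply(multi, function(s) min(lens[s[1L]], l - 1L), integer(1))
      last <- vapply(multi, function(s) min(lens[s[length(s)]], l - 1L),
                     integer(1))
      singles <- as.list(which(lens >= l))
      tab <- rbind(
        fragmentRows(gm, cs, singles, lens[unlist(singles)],
                     lens[unlist(singles)]),
        fragmentRows(gm, cs, multi, first, last))
    }
    if (withIntrons) {
      gaps <- intronicGaps(gm)
      if (nrow(gaps)) {
        se <- gm@subexons
        irows <- lapply(seq_len(nrow(gaps)), function(i) {
          k <- gaps$leftSubexon[i]
          lflank <- min(lens[k], l - 1L)
          rflank <- min(lens[k + 1L], l - 1L)
          ss <- c(end(se)[k] - lflank + 1L, gaps$start[i], start(se)[k + 1L])
          ee <- c(end(se)[k], gaps$end[i], start(se)[k + 1L] + rflank - 1L)
          sig <- c(k, -k, k + 1L)
          data.frame(
            name = sprintf("%s|%s|%d,%d", gm@geneID, sigKey(sig), lflank,
                           rflank),
            gene = gm@geneID, sigKey = sigKey(sig), sig = I(list(sig)),
            segStart = I(list(ss)), segEnd = I(list(ee)),
            cum = I(list(cumsum(ee - ss + 1L))),
            seq = paste(vapply(seq_len(3L), function(q)
              as.character(subseq(cs, ss[q], ee[q])), character(1)),
              collapse = ""))
        })
        tab <- rbind(tab, do.call(rbind, irows))
      }
    }
    rows[[length(rows) + 1L]] <- tab
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab$name), , drop = FALSE]
  tab <- tab[order(tab$gene, sigSortKey(tab$sigKey)), , drop = FALSE]
  rownames(tab) <- NULL
  seqs <- DNAStringSet(tab$seq)
  names(seqs) <- tab$name
  tab$seq <- NULL
  mode <- if (length(graphs)) graphs[[1L]]@mode else "annotated"
  new("FragmentSet", variant = variant, readLength = l, mode = mode,
      table = tab, seqs = seqs)
}

#' Parse a fragment name back into its signature and boundary lengths
#'
#' Fragment names follow the grammar \code{gene|i1,i2,...,im|a,b} and can
#' be decoded without the gene model.
#'
#' @param name fragment name(s)
#' @return list (one element per name) with gene, sig, firstLen, lastLen
#' @export
parseFragmentName <- function(name) {
  lapply(name, function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(parts) != 3L) stop("malformed fragment name: ", nm)
    ab <- as.integer(strsplit(parts[3L], ",", fixed = TRUE)[[1]])
    list(gene = parts[1L], sig = sigParse(parts[2L]), firstLen = ab[1L],
         lastLen = ab[2L])
  })
}

# Positional scan: the signature of a read occupying [offset, offset+len-1]
# within fragment row `row` of the fragment table.
scanSignature <- function(tabRow, offset, len) {
  cum <- tabRow$cum[[1L]]
  sig <- tabRow$sig[[1L]]
  from <- findInterval(offset - 1L, cum) + 1L
  to <- findInterval(offset + len - 1L - 1L, cum) + 1L
  sig[from:to]
}

#' Write a fragment set as FASTA plus a sidecar TSV
#' @param fragset a \linkS4class{FragmentSet}
#' @param fastaPath output FASTA; the sidecar TSV (same path with
#'   \code{.tsv} appended) maps fragment name to gene, signature and
#'   breakpoints
#' @export
writeFragments <- function(fragset, fastaPath) {
  writeXStringSet(fragmentSeqs(fragset), fastaPath, width = 80L)
  tab <- fragmentTable(fragset)
  side <- data.frame(
    name = tab$name, gene = tab$gene, signature = tab$sigKey,
    breakpoints = vapply(tab$cum, function(x) paste(x, collapse = ","),
                         character(1)),
    segStarts = vapply(tab$segStart, function(x) paste(x, collapse = ","),
                       character(1)),
    segEnds = vapply(tab$segEnd, function(x) paste(x, collapse = ","),
                     character(1)))
  write.table(side, paste0(fastaPath, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fastaPath)
}

#' Enumerate the explicit virtual transcripts of a splice graph
#'
#' Materializes the mode's transcriptome for small genes (test/verification
#' use): annotated mode returns the annotated signatures; as mode all paths
#' from a transcript-start subexon to a transcript-end subexon whose span
#' stays within the span of at least one annotated transcript; ap mode all
#' maximal paths (no incoming edge to extend left, none outgoing right).
#'
#' @param graph a \linkS4class{SpliceGraph}
#' @param maxPaths safety cap (error when exceeded)
#' @return list of integer vectors (subexon index sequences)
#' @export
enumerateVirtualTranscripts <- function(graph, maxPaths = 100000L) {
  gm <- graph@gene
  if (graph@mode == "annotated")
    return(unname(gm@txSignatures[order(names(gm@txSignatures))]))
  edges <- graphEdges(graph)
  n <- length(gm@subexons)
  se <- gm@subexons
  if (graph@mode == "as") {
    spans <- lapply(gm@exonsByTx, function(ex)
      c(min(start(ex)), max(end(ex))))
    nodeOK <- lapply(spans, function(sp)
      start(se) >= sp[1L] & end(se) <= sp[2L])
    sources <- sort(unique(vapply(gm@txSignatures, `[`, integer(1), 1L)))
    sinks <- sort(unique(vapply(gm@txSignatures, function(s)
      s[length(s)], integer(1))))
    paths <- list()
    walk <- function(path, okTx) {
      if (length(paths) > maxPaths) stop("virtual transcript cap exceeded")
      if (path[length(path)] %in% sinks)
        paths[[length(paths) + 1L]] <<- path
      for (nxt in edges$out[[path[length(path)]]]) {
        ok2 <- okTx[vapply(okTx, function(t) nodeOK[[t]][nxt], logical(1))]
        if (length(ok2)) walk(c(path, nxt), ok2)
      }
    }
    for (s in sources) {
      okTx <- names(nodeOK)[vapply(nodeOK, function(v) v[s], logical(1))]
      if (length(okTx)) walk(s, okTx)
    }
  } else {
    hasIn <- vapply(edges$inc, length, integer(1)) > 0L
    paths <- list()
    walk <- function(path) {
      if (length(paths) > maxPaths) stop("virtual transcript cap exceeded")
      suc <- edges$out[[path[length(path)]]]
      if (!length(suc)) {
        paths[[length(paths) + 1L]] <<- path
        return()
      }
      for (nxt in suc) walk(c(path, nxt))
    }
    for (s in which(!hasIn)) walk(s)
  }
  keys <- vapply(paths, sigKey, character(1))
  paths <- paths[!duplicated(keys)]
  paths[sigOrder(vapply(paths, sigKey, character(1)))]
}

#' Verify correctness and completeness of a fragment set
#'
#' Exhaustive check against the explicit virtual transcriptome of the
#' graph: (correctness) every fragment's signature is a contiguous window
#' of some explicit virtual transcript; (completeness) every read-length
#' window over every explicit virtual transcript occurs as a substring of
#' some fragment whose positional scan at that occurrence returns the
#' window's true signature. Intended for small genes (test use).
#'
#' @param fragset a \linkS4class{FragmentSet}
#' @param graph the \linkS4class{SpliceGraph} the set was built from
#' @param genome chromosome sequences
#' @param l read length
#' @return list with \code{correctViolations} and
#'   \code{completeViolations} (data.frames, empty when the set is correct
#'   and complete), \code{nWindows} and \code{nFragments}
#' @export
verifyFragmentSet <- function(fragset, graph, genome, l) {
  gm <- graph@gene
  l <- as.integer(l)
  virt <- enumerateVirtualTranscripts(graph)
  tab <- fragmentTable(fragset)
  mine <- tab$gene == gm@geneID
  tab <- tab[mine, , drop = FALSE]
  seqs <- fragmentSeqs(fragset)[mine]
  exonic <- !vapply(tab$sig, function(s) any(s < 0L), logical(1))

  correct <- list()
  for (i in which(exonic)) {
    sig <- tab$sig[[i]]
    if (!any(vapply(virt, isContiguousSub, logical(1), x = sig)))
      correct[[length(correct) + 1L]] <- data.frame(fragment = tab$name[i])
  }

  # map contiguous-window signature -> candidate fragments
  cand <- new.env(hash = TRUE)
  for (i in which(exonic)) {
    sig <- tab$sig[[i]]
    m <- length(sig)
    for (aa in seq_len(m)) for (bb in aa:m) {
      key <- sigKey(sig[aa:bb])
      assign(key, c(if (exists(key, cand, inherits = FALSE))
        get(key, cand), i), cand)
    }
  }

  cs <- chromSeq(genome, gm@chrom)
  se <- gm@subexons
  fragChar <- as.character(seqs)
  complete <- list()
  nWindows <- 0L
  seen <- new.env(hash = TRUE)
  for (v in virt) {
    lens <- width(se)[v]
    cum <- cumsum(lens)
    total <- cum[length(cum)]
    if (total < l) next
    vseq <- paste(vapply(seq_along(v), function(q) as.character(
      subseq(cs, start(se)[v[q]], end(se)[v[q]])), character(1)),
      collapse = "")
    for (off in seq_len(total - l + 1L)) {
      from <- findInterval(off - 1L, cum) + 1L
      to <- findInterval(off + l - 2L, cum) + 1L
      wsig <- v[from:to]
      inFirst <- off - c(0L, cum)[from]   # 1-based start within first subexon
      dkey <- paste(sigKey(wsig), inFirst)
      if (exists(dkey, seen, inherits = FALSE)) next
      assign(dkey, TRUE, seen)
      nWindows <- nWindows + 1L
      wseq <- substr(vseq, off, off + l - 1L)
      key <- sigKey(wsig)
      hit <- FALSE
      if (exists(key, cand, inherits = FALSE)) {
        for (i in get(key, cand)) {
          starts <- gregexpr(wseq, fragChar[i], fixed = TRUE)[[1]]
          if (starts[1L] == -1L) next
          for (st in starts) {
            if (identical(scanSignature(tab[i, ], st, l), wsig)) {
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
      }
      if (!hit)
        complete[[length(complete) + 1L]] <- data.frame(
          virtual = sigKey(v), offset = off, signature = key)
    }
  }
  list(
    correctViolations = if (length(correct)) do.call(rbind, correct)
      else data.frame(fragment = character(0)),
    completeViolations = if (length(complete)) do.call(rbind, complete)
      else data.frame(virtual = character(0), offset = integer(0),
                      signature = character(0)),
    nWindows = nWindows, nFragments = nrow(tab))
}
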