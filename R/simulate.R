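# Deterministic synthetic-data generator: random multi-transcript genes,
# genome and annotation writers, truth-labelled read libraries (optionally
# with held-out novel junctions and a hidden novel splice site), and the
# brute-force oracles used to verify the pipeline. Everything is a pure
# function of the seed.

#' Fixture specification
#'
#' Bundles all generator parameters. Defaults describe a desk-scale
#' short-read library: 75 bp reads, uniform sampling over transcript
#' windows, substitution errors only, one tenth of reads drawn across
#' held-out (novel) junctions when hold-out mode is on.
#'
#' @param seed integer seed driving all randomness
#' @param nGenes number of genes (one chromosome each)
#' @param exonsPerGene,exonLen,intronLen,txPerGene inclusive ranges
#' @param readLength read length l in nt
#' @param nReads number of reads
#' @param errorRate per-base substitution probability in [0, 1)
#' @param novelFrac fraction of reads sampled across held-out junctions
#'   (used when \code{holdOut} is TRUE)
#' @param holdOut remove one skipped-exon transcript per gene from the
#'   annotation so its junction becomes novel (but remains in the virtual
#'   transcriptome)
#' @param novelSiteFrac fraction of reads drawn across a hidden novel
#'   acceptor site (not annotated and not guessable; recovered only by the
#'   refine phase); applies to the first gene
#' @param paired generate paired-end mates from fragments of
#'   \code{insertRange}
#' @param insertRange fragment insert size range for paired mode
#' @param minIntron minimal intron length used throughout
#' @return a list of class "FixtureSpec"
#' @export
fixtureSpec <- function(seed, nGenes = 2L, exonsPerGene = c(3L, 8L),
                        exonLen = c(40L, 120L), intronLen = c(40L, 200L),
                        txPerGene = c(1L, 3L), readLength = 75L,
                        nReads = 10000L, errorRate = 0,
                        novelFrac = 0.1, holdOut = FALSE,
                        novelSiteFrac = 0, paired = FALSE,
                        insertRange = c(150L, 300L), minIntron = 20L) {
  stopifnot(nGenes >= 1L, exonsPerGene[1L] >= 1L,
            exonLen[1L] >= 2L, intronLen[1L] >= 1L, txPerGene[1L] >= 1L,
            readLength >= 2L, nReads >= 0L,
            errorRate >= 0, errorRate < 1,
            novelFrac >= 0, novelFrac <= 1, novelSiteFrac >= 0)
  if (intronLen[1L] < minIntron)
    stop("infeasible spec: intron length range below minIntron")
  spec <- list(seed = seed, nGenes = as.integer(nGenes),
               exonsPerGene = as.integer(exonsPerGene),
               exonLen = as.integer(exonLen),
               intronLen = as.integer(intronLen),
               txPerGene = as.integer(txPerGene),
               readLength = as.integer(readLength),
               nReads = as.integer(nReads), errorRate = errorRate,
               novelFrac = novelFrac, holdOut = isTRUE(holdOut),
               novelSiteFrac = novelSiteFrac, paired = isTRUE(paired),
               insertRange = as.integer(insertRange),
               minIntron = as.integer(minIntron))
  class(spec) <- "FixtureSpec"
  spec
}

rint <- function(range, n = 1L) {
  if (range[1L] >= range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# sample() treats a scalar first argument as 1:x; never do that
pickOne <- function(v) if (length(v) == 1L) v else sample(v, 1L)
shuffle <- function(v) if (length(v) == 1L) v else sample(v)

# Random gene structure: master exon chain plus derived transcript
# variants (internal exon skipping, alternative donors/acceptors, 5'
# truncation).
randomGeneSpec <- function(geneID, chrom, spec) {
  n <- rint(spec$exonsPerGene)
  lens <- rint(spec$exonLen, n)
  gaps <- rint(spec$intronLen, max(0L, n - 1L))
  starts <- 101L + cumsum(c(0L, head(lens, -1L) + gaps))
  master <- IRanges(start = starts, end = starts + lens - 1L)
  strand <- sample(c("+", "-"), 1L)
  exonsByTx <- list(master)
  names(exonsByTx) <- paste0(geneID, ".t1")
  nTx <- rint(spec$txPerGene)
  t <- 2L
  tries <- 0L
  while (length(exonsByTx) < nTx && tries < 20L) {
    tries <- tries + 1L
    kind <- sample(c("skip", "altdonor", "altacceptor", "truncate"), 1L)
    ex <- master
    if (kind == "skip" && n >= 3L) {
      drop <- pickOne(2:(n - 1L))
      ex <- master[-drop]
    } else if (kind == "altdonor" && n >= 2L) {
      i <- pickOne(seq_len(n - 1L))
      d <- sample(5:15, 1L)
      if (width(master)[i] - d < 10L) next
      end(ex)[i] <- end(ex)[i] - d
    } else if (kind == "altacceptor" && n >= 2L) {
      i <- pickOne(2:n)
      d <- sample(5:15, 1L)
      if (width(master)[i] - d < 10L) next
      start(ex)[i] <- start(ex)[i] + d
    } else if (kind == "truncate" && n >= 3L) {
      ex <- master[-seq_len(pickOne(seq_len(n - 2L)))]
    } else next
    dup <- any(vapply(exonsByTx, function(e)
      length(e) == length(ex) && all(start(e) == start(ex)) &&
        all(end(e) == end(ex)), logical(1)))
    if (dup) next
    exonsByTx[[paste0(geneID, ".t", t)]] <- ex
    t <- t + 1L
  }

  heldOut <- NULL
  if (spec$holdOut && n >= 3L) {
    for (drop in shuffle(2:(n - 1L))) {
      ex <- master[-drop]
      jStart <- end(master)[drop - 1L] + 1L
      jEnd <- start(master)[drop + 1L] - 1L
      annotatedJ <- any(vapply(exonsByTx, function(e) {
        length(e) >= 2L &&
          any(end(e)[-length(e)] + 1L == jStart & start(e)[-1L] - 1L == jEnd)
      }, logical(1)))
      dup <- any(vapply(exonsByTx, function(e)
        length(e) == length(ex) && all(start(e) == start(ex)) &&
          all(end(e) == end(ex)), logical(1)))
      if (!annotatedJ && !dup) {
        heldOut <- list(tx = paste0(geneID, ".held"), exons = ex,
                        intronStart = jStart, intronEnd = jEnd)
        break
      }
    }
  }
  list(geneID = geneID, chrom = chrom, strand = strand,
       exonsByTx = exonsByTx, heldOut = heldOut)
}

# Transcript sequence and per-base genomic coordinates in transcription
# order.
txLayout <- function(exons, strand, chromSeq) {
  gpos <- unlist(lapply(seq_along(exons), function(i)
    seq.int(start(exons)[i], end(exons)[i])))
  s <- paste(vapply(seq_along(exons), function(i)
    as.character(subseq(chromSeq, start(exons)[i], end(exons)[i])),
    character(1)), collapse = "")
  if (strand == "-") {
    s <- as.character(reverseComplement(DNAString(s)))
    gpos <- rev(gpos)
  }
  list(seq = s, gpos = gpos)
}

# Genomic footprint (IRanges of blocks) of transcript window [w, w+len-1].
windowBlocks <- function(layout, w, len) {
  p <- sort(layout$gpos[w:(w + len - 1L)])
  brk <- which(diff(p) > 1L)
  IRanges(start = p[c(1L, brk + 1L)], end = p[c(brk, length(p))])
}

#' True mapping signature of a read from its genomic footprint
#'
#' @param gm a \linkS4class{GeneModel}
#' @param blocks \link[IRanges]{IRanges} of the read's genomic blocks
#' @return increasing integer vector of overlapped subexon indices
#' @export
oracleSignature <- function(gm, blocks) {
  sort(unique(queryHits(findOverlaps(gm@subexons, blocks))))
}

#' Brute-force transcript compatibility of a read
#'
#' A read is compatible with a transcript iff its genomic footprint maps
#' to a contiguous run of transcript coordinates (all bases exonic in the
#' transcript, no skipped transcript base).
#'
#' @param gm a \linkS4class{GeneModel}
#' @param blocks \link[IRanges]{IRanges} of the read's genomic blocks
#' @return character vector of compatible transcript ids
#' @export
oracleCompatibility <- function(gm, blocks) {
  pos <- unlist(lapply(seq_along(blocks), function(i)
    seq.int(start(blocks)[i], end(blocks)[i])))
  ok <- vapply(txNames(gm), function(tx) {
    ex <- gm@exonsByTx[[tx]]
    gpos <- unlist(lapply(seq_along(ex), function(i)
      seq.int(start(ex)[i], end(ex)[i])))
    idx <- match(pos, gpos)
    !anyNA(idx) && (length(idx) == 1L || all(diff(sort(idx)) == 1L))
  }, logical(1))
  txNames(gm)[ok]
}

#' Generate a complete synthetic fixture
#'
#' Produces genome, annotation, truth-labelled reads, the explicit
#' as-mode virtual transcript list, and (when requested) files on disk.
#' Fully deterministic given the spec's seed.
#'
#' @param spec a \code{\link{fixtureSpec}}
#' @param dir if non-NULL, write genome.fa, annotation.gtf, reads.fastq
#'   (reads_1/2.fastq when paired), truth.tsv, virtual.tsv and novel.sj
#'   into this directory
#' @param virtual enumerate the explicit as-mode virtual transcripts per
#'   gene (skipped for genes where the enumeration exceeds the cap)
#' @return list with models, genome, reads (named character vector),
#'   truth (data.frame), geneSpecs, heldOut (data.frame of held-out
#'   junctions), novelSite (NULL or list), virtual (per-gene list of
#'   signatures), and paths (when \code{dir} was given)
#' @export
makeFixture <- function(spec, dir = NULL, virtual = TRUE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  l <- spec$readLength
  withSeed(spec$seed, {
    geneSpecs <- lapply(seq_len(spec$nGenes), function(g)
      randomGeneSpec(sprintf("G%03d", g), sprintf("chr%d", g), spec))

    # hidden novel acceptor on the first gene with >= 2 exons
    novelSite <- NULL
    if (spec$novelSiteFrac > 0) {
      for (gs in geneSpecs) {
        master <- gs$exonsByTx[[1L]]
        if (length(master) < 2L) next
        j <- 2L
        delta <- 15L
        if (width(master)[j] - delta < 10L) next
        ex <- master
        start(ex)[j] <- start(ex)[j] + delta
        novelSite <- list(gene = gs$geneID, chrom = gs$chrom,
                          strand = gs$strand,
                          tx = paste0(gs$geneID, ".site"), exons = ex,
                          intronStart = end(master)[j - 1L] + 1L,
                          intronEnd = start(master)[j] + delta - 1L)
        break
      }
    }

    models <- list()
    for (gs in geneSpecs)
      models[[gs$geneID]] <- geneModelFromExons(gs$geneID, gs$chrom,
                                                gs$strand, gs$exonsByTx)
    genome <- DNAStringSet(vapply(geneSpecs, function(gs)
      randomDNA(max(end(gs$exonsByTx[[1L]])) + 100L), character(1)))
    names(genome) <- vapply(geneSpecs, `[[`, "", "chrom")

    # read sources: (gene, tx, layout, window weights)
    sources <- list()
    for (gs in geneSpecs) {
      cs <- genome[[gs$chrom]]
      for (tx in names(gs$exonsByTx)) {
        lay <- txLayout(gs$exonsByTx[[tx]], gs$strand, cs)
        if (nchar(lay$seq) < l) next
        sources[[length(sources) + 1L]] <- list(
          gene = gs$geneID, tx = tx, lay = lay, novel = FALSE)
      }
    }
    heldSources <- list()
    heldRows <- list()
    for (gs in geneSpecs) {
      if (is.null(gs$heldOut)) next
      lay <- txLayout(gs$heldOut$exons, gs$strand, genome[[gs$chrom]])
      if (nchar(lay$seq) < l) next
      heldSources[[length(heldSources) + 1L]] <- list(
        gene = gs$geneID, tx = gs$heldOut$tx, lay = lay, novel = TRUE,
        jn = c(gs$heldOut$intronStart, gs$heldOut$intronEnd))
      heldRows[[length(heldRows) + 1L]] <- data.frame(
        gene = gs$geneID, chrom = gs$chrom, strand = gs$strand,
        tx = gs$heldOut$tx, intronStart = gs$heldOut$intronStart,
        intronEnd = gs$heldOut$intronEnd)
    }
    heldOut <- if (length(heldRows)) do.call(rbind, heldRows)
      else data.frame(gene = character(0), chrom = character(0),
                      strand = character(0), tx = character(0),
                      intronStart = integer(0), intronEnd = integer(0))

    nNovel <- if (length(heldSources)) round(spec$nReads * spec$novelFrac)
      else 0L
    nSite <- if (!is.null(novelSite)) round(spec$nReads * spec$novelSiteFrac)
      else 0L
    nAnn <- spec$nReads - nNovel - nSite
    if (!length(sources) && nAnn > 0L) stop("no transcript long enough to sample reads")

    # windows spanning a junction: read must cover both flanking bases
    junctionWindows <- function(lay, intronStart, intronEnd) {
      left <- which(lay$gpos == intronStart - 1L)
      right <- which(lay$gpos == intronEnd + 1L)
      cj <- min(left, right)      # junction lies between cj and cj+1
      lo <- max(1L, cj - l + 2L)
      hi <- min(cj, nchar(lay$seq) - l + 1L)
      if (lo > hi) integer(0) else seq.int(lo, hi)
    }

    origins <- list()
    if (nAnn > 0L) {
      wTotals <- vapply(sources, function(s)
        nchar(s$lay$seq) - l + 1L, integer(1))
      pick <- sample.int(length(sources), nAnn, replace = TRUE,
                     prob = wTotals / sum(wTotals))
      for (q in seq_len(nAnn)) {
        s <- sources[[pick[q]]]
        w <- sample.int(nchar(s$lay$seq) - l + 1L, 1L)
        origins[[length(origins) + 1L]] <- list(s = s, w = w,
                                                class = "annotated")
      }
    }
    if (nNovel > 0L) {
      for (q in seq_len(nNovel)) {
        s <- heldSources[[1L + (q - 1L) %% length(heldSources)]]
        ws <- junctionWindows(s$lay, s$jn[1L], s$jn[2L])
        w <- ws[sample.int(length(ws), 1L)]
        origins[[length(origins) + 1L]] <- list(s = s, w = w,
                                                class = "novel_junction")
      }
    }
    if (nSite > 0L) {
      gsChrom <- genome[[novelSite$chrom]]
      lay <- txLayout(novelSite$exons, novelSite$strand, gsChrom)
      s <- list(gene = novelSite$gene, tx = novelSite$tx, lay = lay,
                novel = TRUE)
      # keep >= 15 nt on both sides of the novel junction
      ws <- junctionWindows(lay, novelSite$intronStart, novelSite$intronEnd)
      ws <- ws[ws >= 1L]
      left <- which(lay$gpos == novelSite$intronStart - 1L)
      right <- which(lay$gpos == novelSite$intronEnd + 1L)
      cj <- min(left, right)
      ws <- ws[cj - ws + 1L >= 15L & ws + l - 1L - cj >= 15L]
      if (!length(ws)) stop("novel-site junction not coverable at this l")
      for (q in seq_len(nSite)) {
        w <- ws[sample.int(length(ws), 1L)]
        origins[[length(origins) + 1L]] <- list(s = s, w = w,
                                                class = "novel_site")
      }
    }

    bases <- c("A", "C", "G", "T")
    addErrors <- function(sq) {
      errPos <- which(runif(nchar(sq)) < spec$errorRate)
      if (length(errPos)) {
        ch <- strsplit(sq, "")[[1]]
        for (p in errPos) ch[p] <- pickOne(setdiff(bases, ch[p]))
        sq <- paste(ch, collapse = "")
      }
      list(seq = sq, errPos = errPos)
    }
    truthRow <- function(id, o, w, sq, errPos) {
      blocks <- windowBlocks(o$s$lay, w, l)
      data.frame(
        readID = id, gene = o$s$gene, tx = o$s$tx, class = o$class,
        txStart = w,
        blocks = paste(sprintf("%d-%d", start(blocks), end(blocks)),
                       collapse = ";"),
        trueSig = sigKey(oracleSignature(models[[o$s$gene]], blocks)),
        errorPos = paste(errPos, collapse = ","))
    }
    reads <- character(0); reads2 <- NULL
    truthRows <- list()
    if (!spec$paired) {
      reads <- character(length(origins))
      for (q in seq_along(origins)) {
        o <- origins[[q]]
        e <- addErrors(substr(o$s$lay$seq, o$w, o$w + l - 1L))
        reads[q] <- e$seq
        truthRows[[q]] <- truthRow(sprintf("r%06d", q), o, o$w, e$seq,
                                   e$errPos)
      }
    } else {
      reads <- character(length(origins))
      reads2 <- character(length(origins))
      for (q in seq_along(origins)) {
        o <- origins[[q]]
        txLen <- nchar(o$s$lay$seq)
        ins <- min(rint(spec$insertRange), txLen - o$w + 1L)
        ins <- max(ins, l)
        w2 <- o$w + ins - l
        e1 <- addErrors(substr(o$s$lay$seq, o$w, o$w + l - 1L))
        sq2 <- as.character(reverseComplement(DNAString(
          substr(o$s$lay$seq, w2, w2 + l - 1L))))
        e2 <- addErrors(sq2)
        reads[q] <- e1$seq; reads2[q] <- e2$seq
        truthRows[[length(truthRows) + 1L]] <-
          truthRow(sprintf("r%06d/1", q), o, o$w, e1$seq, e1$errPos)
        truthRows[[length(truthRows) + 1L]] <-
          truthRow(sprintf("r%06d/2", q), o, w2, e2$seq, e2$errPos)
      }
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
      else data.frame(readID = character(0), gene = character(0),
                      tx = character(0), class = character(0),
                      txStart = integer(0), blocks = character(0),
                      trueSig = character(0), errorPos = character(0))
    names(reads) <- if (spec$paired) sprintf("r%06d/1", seq_along(reads))
      else truth$readID
    if (spec$paired) names(reads2) <- sprintf("r%06d/2", seq_along(reads2))

    virt <- NULL
    if (virtual) {
      virt <- lapply(models, function(gm) {
        tryCatch(
          enumerateVirtualTranscripts(
            buildSpliceGraph(gm, "as", minIntron = spec$minIntron),
            maxPaths = 20000L),
          error = function(e) NULL)
      })
      truth$identifiable <- flagIdentifiable(truth, reads2all(reads, reads2),
                                             models, genome, virt, l)
    }

    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        gtf = file.path(dir, "annotation.gtf"),
        fastq = if (spec$paired) file.path(dir, "reads_1.fastq")
          else file.path(dir, "reads.fastq"),
        truth = file.path(dir, "truth.tsv"),
        virtual = file.path(dir, "virtual.tsv"))
      writeXStringSet(genome, paths$genome, width = 80L)
      writeFixtureGTF(models, paths$gtf, seed = spec$seed)
      writeLines(as.vector(rbind(paste0("@", names(reads)), reads, "+",
                                 strrep("I", nchar(reads)))), paths$fastq)
      if (spec$paired) {
        paths$fastq2 <- file.path(dir, "reads_2.fastq")
        writeLines(as.vector(rbind(paste0("@", names(reads2)), reads2, "+",
                                   strrep("I", nchar(reads2)))),
                   paths$fastq2)
      }
      write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (!is.null(virt)) {
        vt <- do.call(rbind, lapply(names(virt), function(g) {
          if (is.null(virt[[g]])) return(NULL)
          data.frame(gene = g,
                     signature = vapply(virt[[g]], sigKey, character(1)))
        }))
        write.table(vt, paths$virtual, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      if (!is.null(novelSite) && nSite > 0L) {
        paths$sj <- file.path(dir, "novel.sj")
        writeSJ(data.frame(chrom = novelSite$chrom,
                           intronStart = novelSite$intronStart,
                           intronEnd = novelSite$intronEnd,
                           strand = novelSite$strand, motif = 0L,
                           annotated = 0L, uniqueReads = nSite,
                           multiReads = 0L, maxOverhang = l - 15L),
                paths$sj)
      }
    }
    list(spec = spec, models = models, genome = genome, reads = reads,
         reads2 = reads2, truth = truth, geneSpecs = geneSpecs,
         heldOut = heldOut, novelSite = novelSite, virtual = virt,
         paths = paths)
  })
}

reads2all <- function(reads, reads2) {
  if (is.null(reads2)) return(reads)
  out <- character(2L * length(reads))
  out[seq(1L, length(out), 2L)] <- reads
  out[seq(2L, length(out), 2L)] <- reads2
  names(out) <- as.vector(rbind(names(reads), names(reads2)))
  out
}

#' Oracle identifiability of reads against a virtual transcriptome
#'
#' A read is identifiable iff no placement of its sequence (either
#' orientation) over any explicit virtual transcript implies a different
#' (gene, signature) than its true origin; unidentifiable reads (typically
#' 1-5 nt junction overhangs whose alternative splicing continuation starts
#' with the same bases) cannot be assigned by any mapper and are exactly
#' the reads the engine drops as ambiguous. Reads whose first/last subexon
#' overlap is >= 16 nt cannot collide within a desk-scale random genome and
#' are accepted directly; shorter junction overhangs are brute-forced by
#' occurrence search. Reads of classes not in \code{classes} get NA
#' (novel-site reads are only meaningful against a refined transcriptome).
#'
#' @param truth fixture truth table (readID, gene, class, blocks, ...)
#' @param reads named read sequences
#' @param models named list of \linkS4class{GeneModel} (refined models when
#'   scoring novel-site reads)
#' @param genome chromosome sequences
#' @param virt per-gene list of explicit virtual transcript signatures
#' @param l read length
#' @param classes truth classes to score
#' @return logical vector parallel to \code{truth} rows (NA = not scored)
#' @export
flagIdentifiable <- function(truth, reads, models, genome, virt, l,
                             classes = c("annotated", "novel_junction")) {
  vseqs <- list()
  for (g in names(models)) {
    if (is.null(virt[[g]])) { vseqs[g] <- list(NULL); next }
    gm <- models[[g]]
    cs <- genome[[gm@chrom]]
    se <- gm@subexons
    vseqs[[g]] <- lapply(virt[[g]], function(v) {
      sq <- paste(vapply(v, function(i)
        as.character(subseq(cs, start(se)[i], end(se)[i])), character(1)),
        collapse = "")
      list(sig = v, seq = sq, cum = cumsum(width(se)[v]))
    })
  }
  out <- rep(NA, nrow(truth))
  for (r in seq_len(nrow(truth))) {
    if (!truth$class[r] %in% classes) next
    g <- truth$gene[r]
    if (is.null(vseqs[[g]])) next
    gm <- models[[g]]
    parts <- strsplit(strsplit(truth$blocks[r], ";")[[1]], "-")
    blocks <- IRanges(
      start = as.integer(vapply(parts, `[`, "", 1L)),
      end = as.integer(vapply(parts, `[`, "", 2L)))
    sig <- oracleSignature(gm, blocks)
    if (length(sig) >= 2L) {
      covFirst <- min(end(blocks)[1L], end(gm@subexons)[sig[1L]]) -
        start(blocks)[1L] + 1L
      nb <- length(blocks)
      covLast <- end(blocks)[nb] -
        max(start(blocks)[nb], start(gm@subexons)[sig[length(sig)]]) + 1L
      minOver <- min(covFirst, covLast)
    } else minOver <- Inf
    if (minOver >= 16L) { out[r] <- TRUE; next }
    rd <- reads[[truth$readID[r]]]
    rdrc <- as.character(reverseComplement(DNAString(rd)))
    ident <- TRUE
    for (g2 in names(vseqs)) {
      if (is.null(vseqs[[g2]])) next
      for (v in vseqs[[g2]]) {
        for (sq in unique(c(rd, rdrc))) {
          occ <- gregexpr(sq, v$seq, fixed = TRUE)[[1]]
          if (occ[1L] == -1L) next
          for (o in occ) {
            from <- findInterval(o - 1L, v$cum) + 1L
            to <- findInterval(o + l - 2L, v$cum) + 1L
            osig <- v$sig[from:to]
            if (g2 != g || !identical(osig, sig)) ident <- FALSE
          }
        }
        if (!ident) break
      }
      if (!ident) break
    }
    out[r] <- ident
  }
  out
}

# GTF writer for fixture annotations (gene/transcript/exon rows with
# gene_id and transcript_id attributes).
writeFixtureGTF <- function(models, path, seed = NA) {
  lines <- c(sprintf("#!fixture generator seed %s", seed))
  for (g in names(models)) {
    gm <- models[[g]]
    gs <- min(start(gm@subexons)); ge <- max(end(gm@subexons))
    lines <- c(lines, sprintf(
      "%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      gm@chrom, gs, ge, gm@strand, g))
    for (tx in txNames(gm)) {
      ex <- gm@exonsByTx[[tx]]
      lines <- c(lines, sprintf(
        "%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        gm@chrom, min(start(ex)), max(end(ex)), gm@strand, g, tx))
      lines <- c(lines, sprintf(
        "%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        gm@chrom, start(ex), end(ex), gm@strand, g, tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' The two-transcript demonstration gene (five subexons)
#'
#' A '+'-strand gene whose two annotated transcripts partition the exonic
#' sequence into five subexons: FIXA covers (1,2,5) with exons
#' 101-200, 301-400, 781-900, FIXB covers (1,2,3,4,5) with exons 101-200,
#' 301-480, 581-680, 781-900. Two novel splicing patterns live in its
#' virtual transcriptome: skipping FIXB's two middle exons (signature
#' (1,5)) and the junction chain of a transcript with signature (2,4,5)
#' that combines FIXA's donor at 400 with FIXB's acceptor at 581.
#'
#' @return list with gm (\linkS4class{GeneModel}) and genome
#'   (\link[Biostrings]{DNAStringSet})
#' @export
fig2Gene <- function() {
  exonsByTx <- list(
    FIXA = IRanges(start = c(101L, 301L, 781L), end = c(200L, 400L, 900L)),
    FIXB = IRanges(start = c(101L, 301L, 581L, 781L),
                   end = c(200L, 480L, 680L, 900L)))
  gm <- geneModelFromExons("FIXG1", "chrF", "+", exonsByTx)
  genome <- withSeed(1021L, DNAStringSet(setNames(randomDNA(1000L), "chrF")))
  list(gm = gm, genome = genome)
}

#' The three-transcript event-taxonomy gene (eight subexons)
#'
#' A '+'-strand gene with transcripts EVT1 (3,8), EVT2 (1..8) and EVT3
#' (1,5,7,8) over eight subexons, built so that the canonical novel
#' introns exhibit every event type: (1,7) is a classical exon skipping
#' wrt EVT3 and nonclassical wrt EVT2, (3,5) an alternative donor wrt
#' EVT2, (4,6) an alternative acceptor wrt EVT2, (5,8) an alternative
#' donor-acceptor pair wrt EVT2 and an alternative acceptor wrt EVT3,
#' (1,3) a novel intron in exon wrt EVT2, and the gap between subexons 6
#' and 7 is intronic in every transcript (intron-retention territory).
#'
#' @return list with gm and genome as in \code{\link{fig2Gene}}
#' @export
fig3Gene <- function() {
  exonsByTx <- list(
    EVT1 = IRanges(start = c(261L, 861L), end = c(340L, 940L)),
    EVT2 = IRanges(start = c(101L, 521L, 781L), end = c(420L, 680L, 940L)),
    EVT3 = IRanges(start = c(101L, 521L, 781L), end = c(180L, 600L, 940L)))
  gm <- geneModelFromExons("FIXE1", "chrE", "+", exonsByTx)
  genome <- withSeed(1022L, DNAStringSet(setNames(randomDNA(1100L), "chrE")))
  list(gm = gm, genome = genome)
}
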