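# Lightweight k-mer pseudoalignment of reads to fragments.
#
# Anchor k-mers of a read (a stride-k set plus the final position, so that
# any single mismatch leaves at least one intact anchor on each side once
# the mismatch is >= k from both read ends) are looked up in the postings
# table; each posting votes for the read start offset it implies within a
# fragment. The winning (fragment, offset) determines the mapping signature
# by a linear scan through the fragment's subexon breakpoints. Reads whose
# tied best hits imply different signatures are ambiguous and excluded from
# the counts.

#' Build a k-mer index over a fragment set
#'
#' @param fragset a \linkS4class{FragmentSet}
#' @param k k-mer size; defaults to min(31, l-1); must be < the indexed
#'   read length
#' @return a \linkS4class{KmerIndex}
#' @export
buildKmerIndex <- function(fragset, k = NULL) {
  l <- fragset@readLength
  if (is.null(k)) k <- min(31L, l - 1L)
  k <- as.integer(k)
  if (k >= l) stop("k (", k, ") must be smaller than the read length (", l, ")")
  if (k < 1L) stop("k must be positive")
  seqs <- as.character(fragmentSeqs(fragset))
  posts <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table(kmer = substring(seqs[i], pos, pos + k - 1L),
               frag = i, pos = pos)
  })
  postings <- rbindlist(posts)
  if (nrow(postings) == 0L)
    postings <- data.table(kmer = character(0), frag = integer(0),
                           pos = integer(0))
  setkey(postings, kmer)
  new("KmerIndex", k = k, postings = postings, fragments = fragset)
}

anchorPositions <- function(readLen, k) {
  unique(c(seq.int(1L, readLen - k + 1L, by = k), readLen - k + 1L))
}

# Candidate (fragment, offset, orientation) votes for a batch of reads.
# Returns a data.table: read, frag, offset, rc, support.
candidateHits <- function(reads, index) {
  k <- index@k
  rl <- nchar(reads)
  rc <- as.character(reverseComplement(DNAStringSet(reads)))
  pieces <- list()
  for (L in sort(unique(rl))) {
    if (L < k) next
    sel <- which(rl == L)
    ap <- anchorPositions(L, k)
    for (orient in c(FALSE, TRUE)) {
      src <- if (orient) rc[sel] else reads[sel]
      pieces[[length(pieces) + 1L]] <- data.table(
        read = rep(sel, each = length(ap)),
        rpos = rep(ap, times = length(sel)),
        rc = orient,
        kmer = unlist(lapply(src, function(s)
          substring(s, ap, ap + k - 1L)), use.names = FALSE))
    }
  }
  if (!length(pieces)) {
    return(data.table(read = integer(0), frag = integer(0),
                      offset = integer(0), rc = logical(0),
                      support = integer(0)))
  }
  q <- rbindlist(pieces)
  hits <- index@postings[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) {
    return(data.table(read = integer(0), frag = integer(0),
                      offset = integer(0), rc = logical(0),
                      support = integer(0)))
  }
  hits[, offset := pos - rpos + 1L]
  fragLen <- width(fragmentSeqs(index@fragments))
  hits[, rl := nchar(reads)[read]]
  hits <- hits[offset >= 1L & offset + rl - 1L <= fragLen[frag]]
  hits[, .(support = .N), by = .(read, frag, offset, rc)]
}

# Resolve candidate hits of one read set into signatures.
# Returns a data.table: read, status (mapped/unmapped/ambiguous), frag,
# offset, gene, sig.
resolveHits <- function(reads, hits, index, verifyHamming = Inf,
                        maxNFrac = 0.1) {
  tab <- fragmentTable(index@fragments)
  seqs <- as.character(fragmentSeqs(index@fragments))
  rcReads <- as.character(reverseComplement(DNAStringSet(reads)))
  n <- length(reads)
  status <- rep("unmapped", n)
  frag <- rep(NA_integer_, n); offset <- rep(NA_integer_, n)
  gene <- rep(NA_character_, n); sig <- rep(NA_character_, n)

  badN <- vapply(reads, function(s) {
    mean(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T")) > maxNFrac
  }, logical(1))

  if (nrow(hits)) {
    hits <- hits[!badN[read]]
  }
  if (nrow(hits)) {
    best <- hits[hits[, .I[support == max(support)], by = read]$V1]
    # exact-match length as secondary criterion among tied-support hits
    best[, mlen := mapply(function(r, f, o, isrc) {
      s <- if (isrc) rcReads[r] else reads[r]
      matchingBases(s, substr(seqs[f], o, o + nchar(s) - 1L))
    }, read, frag, offset, rc)]
    best <- best[best[, .I[mlen == max(mlen)], by = read]$V1]
    if (is.finite(verifyHamming)) {
      best <- best[nchar(reads)[read] - mlen <= verifyHamming]
    }
    if (nrow(best)) {
      cums <- tab$cum
      sigl <- tab$sig
      best[, sigc := mapply(function(f, o, len) {
        cum <- cums[[f]]
        from <- findInterval(o - 1L, cum) + 1L
        to <- findInterval(o + len - 2L, cum) + 1L
        sigKey(sigl[[f]][from:to])
      }, frag, offset, nchar(reads)[read])]
      best[, genec := tab$gene[frag]]
      res <- best[, {
        u <- unique(paste(genec, sigc))
        if (length(u) == 1L) {
          pick <- which.min(frag)
          list(status = "mapped", frag = frag[pick], offset = offset[pick],
               gene = genec[pick], sig = sigc[pick])
        } else {
          list(status = "ambiguous", frag = NA_integer_,
               offset = NA_integer_, gene = NA_character_,
               sig = NA_character_)
        }
      }, by = read]
      status[res$read] <- res$status
      frag[res$read] <- res$frag; offset[res$read] <- res$offset
      gene[res$read] <- res$gene; sig[res$read] <- res$sig
    }
  }
  data.table(read = seq_len(n), status = status, frag = frag,
             offset = offset, gene = gene, sig = sig)
}

#' Map reads to fragments and resolve their mapping signatures
#'
#' @param reads character vector or \link[Biostrings]{DNAStringSet}
#' @param index a \linkS4class{KmerIndex}
#' @param verifyHamming if finite, reject winning hits with more than this
#'   many mismatches against the fragment sequence
#' @param maxNFrac reads with a larger fraction of non-ACGT bases are
#'   unmapped
#' @return data.table with one row per read: read, status
#'   (mapped/unmapped/ambiguous), frag, offset, gene, sig
#' @export
mapReads <- function(reads, index, verifyHamming = Inf, maxNFrac = 0.1) {
  reads <- as.character(reads)
  l <- index@fragments@readLength
  if (any(nchar(reads) > l))
    stop("reads longer than the indexed read length (", l,
         "); rebuild the index with a larger l")
  hits <- candidateHits(reads, index)
  resolveHits(reads, hits, index, verifyHamming, maxNFrac)
}

#' Map a single read
#'
#' @inheritParams mapReads
#' @param read a single nucleotide string
#' @return the signature as an integer vector, or the string "unmapped" /
#'   "ambiguous"
#' @export
mapRead <- function(read, index, verifyHamming = Inf, maxNFrac = 0.1) {
  res <- mapReads(read, index, verifyHamming, maxNFrac)
  if (res$status[1L] != "mapped") return(res$status[1L])
  sigParse(res$sig[1L])
}

#' Select the primary hit among candidate hits of one read
#'
#' Maximal k-mer support, ties broken by maximal verified exact-match
#' length, remaining ties by lowest fragment id (deterministic).
#'
#' @param hits data.table with columns frag, offset, rc, support (as
#'   produced by the candidate stage)
#' @param read the read sequence
#' @param index the \linkS4class{KmerIndex}
#' @return single-row data.table
#' @export
selectPrimary <- function(hits, read, index) {
  if (nrow(hits) == 0L) stop("selectPrimary requires >= 1 hit")
  seqs <- as.character(fragmentSeqs(index@fragments))
  fwdStr <- as.character(read)[1L]
  rcStr <- as.character(reverseComplement(DNAStringSet(fwdStr)))
  cand <- hits[support == max(support)]
  cand[, mlen := mapply(function(f, o, isrc) {
    s <- if (isrc) rcStr else fwdStr
    matchingBases(s, substr(seqs[f], o, o + nchar(s) - 1L))
  }, frag, offset, rc)]
  cand <- cand[mlen == max(mlen)]
  cand[order(frag, offset)][1L]
}

#' Read a FASTQ file (optionally gzipped) into a named character vector
#'
#' Validates record structure and reports the number of the first
#' incomplete record.
#'
#' @param path FASTQ path
#' @return named character vector of read sequences
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ ", path, ": record ", length(lines) %/% 4L + 1L,
         " is incomplete")
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  seqs <- toupper(lines[seq(2L, length(lines), 4L)])
  setNames(seqs, ids)
}

#' Count reads by mapping signature
#'
#' Maps each read independently and accumulates one count per mapped read
#' under its (gene, signature) class. For paired-end libraries each mate is
#' mapped independently and the counts of both ends are summed (default);
#' with \code{pairSignatures = TRUE} counts are instead keyed by the
#' ordered signature pair of each read pair.
#'
#' @param fastq path(s) to FASTQ file(s), or a character vector /
#'   DNAStringSet of read sequences
#' @param index a \linkS4class{KmerIndex}
#' @param mate2 optional path(s) or sequences for the second mates
#' @param pairSignatures key counts by the ordered pair of mate signatures
#' @param verifyHamming,maxNFrac see \code{\link{mapReads}}
#' @return a \linkS4class{SignatureCounts}
#' @export
countReads <- function(fastq, index, mate2 = NULL, pairSignatures = FALSE,
                       verifyHamming = Inf, maxNFrac = 0.1) {
  getSeqs <- function(x) {
    if (is(x, "DNAStringSet")) return(as.character(x))
    if (is.character(x) && length(x) && all(file.exists(x)))
      return(unlist(lapply(x, readFastq)))
    as.character(x)
  }
  r1 <- getSeqs(fastq)
  r2 <- if (!is.null(mate2)) getSeqs(mate2) else NULL
  if (pairSignatures && is.null(r2))
    stop("pairSignatures requires second mates")
  if (!is.null(r2) && pairSignatures && length(r1) != length(r2))
    stop("mates not synchronized: ", length(r1), " vs ", length(r2), " reads")

  if (pairSignatures) {
    m1 <- mapReads(r1, index, verifyHamming, maxNFrac)
    m2 <- mapReads(r2, index, verifyHamming, maxNFrac)
    ok <- m1$status == "mapped" & m2$status == "mapped" & m1$gene == m2$gene
    dt <- data.table(gene = m1$gene[ok],
                     sig = paste(m1$sig[ok], m2$sig[ok], sep = "|"))
    counts <- dt[, .(count = .N), by = .(gene, sig)]
    mapped <- sum(ok)
    unmapped <- sum(m1$status == "unmapped" | m2$status == "unmapped" |
                      (!ok & m1$status == "mapped" & m2$status == "mapped"))
    ambiguous <- length(r1) - mapped - unmapped
  } else {
    all <- c(r1, r2)
    m <- mapReads(all, index, verifyHamming, maxNFrac)
    ok <- m$status == "mapped"
    dt <- data.table(gene = m$gene[ok], sig = m$sig[ok])
    counts <- if (nrow(dt)) dt[, .(count = .N), by = .(gene, sig)]
      else data.table(gene = character(0), sig = character(0),
                      count = integer(0))
    mapped <- sum(ok)
    unmapped <- sum(m$status == "unmapped")
    ambiguous <- sum(m$status == "ambiguous")
  }
  counts <- as.data.frame(counts)
  counts <- counts[order(counts$gene, sigSortKey(counts$sig)), , drop = FALSE]
  rownames(counts) <- NULL
  new("SignatureCounts", counts = counts, mapped = as.integer(mapped),
      unmapped = as.integer(unmapped), ambiguous = as.integer(ambiguous))
}

#' Construct a SignatureCounts object from a plain table
#' @param df data.frame with columns gene, sig, count
#' @param mapped,unmapped,ambiguous totals (default: sum of counts, 0, 0)
#' @export
signatureCounts <- function(df, mapped = sum(df$count), unmapped = 0L,
                            ambiguous = 0L) {
  df <- as.data.frame(df)[, c("gene", "sig", "count")]
  df <- df[order(df$gene, sigSortKey(df$sig)), , drop = FALSE]
  rownames(df) <- NULL
  new("SignatureCounts", counts = df, mapped = as.integer(mapped),
      unmapped = as.integer(unmapped), ambiguous = as.integer(ambiguous))
}

#' Additively merge two signature-count tables
#' @param a,b \linkS4class{SignatureCounts}
#' @export
mergeCounts <- function(a, b) {
  dt <- rbind(as.data.table(sigCounts(a)), as.data.table(sigCounts(b)))
  merged <- dt[, .(count = sum(count)), by = .(gene, sig)]
  signatureCounts(as.data.frame(merged),
                  mapped = a@mapped + b@mapped,
                  unmapped = a@unmapped + b@unmapped,
                  ambiguous = a@ambiguous + b@ambiguous)
}

#' Write signature counts as TSV (plus a run-summary JSON sidecar)
#' @param counts a \linkS4class{SignatureCounts}
#' @param path output TSV
#' @export
writeSignatureCounts <- function(counts, path) {
  write.table(sigCounts(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  st <- mappingStats(counts)
  jsonlite::write_json(as.list(st), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read signature counts written by \code{\link{writeSignatureCounts}}
#' @param path TSV path
#' @export
readSignatureCounts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer"))
  js <- paste0(path, ".json")
  if (file.exists(js)) {
    st <- jsonlite::read_json(js)
    signatureCounts(df, st$mapped, st$unmapped, st$ambiguous)
  } else signatureCounts(df)
}
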