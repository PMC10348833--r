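test_that("the k-mer index contains every fragment k-mer", {
  g <- simpleGene(101, 180)
  fr <- buildFragments(buildSpliceGraph(g$gm, "annotated"), g$genome, 20L)
  idx <- buildKmerIndex(fr, 5L)
  L <- IRanges::width(fragmentSeqs(fr))[1]
  expect_equal(nrow(idx@postings), L - 5L + 1L)

  # two fragments sharing sequence carry both postings
  g2 <- simpleGene(c(101, 301), c(200, 400),
                   extra = list(t2 = IRanges::IRanges(c(101, 301),
                                                      c(150, 400))))
  fr2 <- buildFragments(buildSpliceGraph(g2$gm, "as"), g2$genome, 20L,
                        variant = "F11")
  idx2 <- buildKmerIndex(fr2, 7L)
  seqs <- as.character(fragmentSeqs(fr2))
  for (i in seq_along(seqs)) {
    for (p in unique(c(1L, nchar(seqs[i]) - 6L))) {
      hit <- idx2@postings[list(substr(seqs[i], p, p + 6L)), on = "kmer",
                           nomatch = NULL]
      expect_true(i %in% hit$frag)
    }
  }

  expect_error(buildKmerIndex(fr, 20L), "smaller than the read length")
  expect_error(buildKmerIndex(fr, 25L), "smaller than the read length")
})

test_that("error-free reads map to their true signature", {
  fx <- smallFixture(40L, nGenes = 2L, nReads = 300L)
  cnt <- pipelineCounts(fx)
  expect_same_counts(cnt, truthHistogram(fx$truth))
  st <- mappingStats(cnt)
  expect_equal(st[["mapped"]] + st[["unmapped"]] + st[["ambiguous"]],
               length(fx$reads))
  expect_equal(st[["ambiguous"]],
               sum(!fx$truth$identifiable, na.rm = TRUE))
})

test_that("a central mismatch leaves the mapping signature unchanged", {
  fx <- smallFixture(41L, nGenes = 1L, nReads = 60L, readLength = 100L)
  graphs <- lapply(fx$models, buildSpliceGraph, mode = "as")
  idx <- buildKmerIndex(buildFragments(graphs, fx$genome, 100L), 31L)
  base <- mapReads(fx$reads, idx)
  r <- which(base$status == "mapped")[1]
  ch <- strsplit(fx$reads[[r]], "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  res <- mapReads(paste(ch, collapse = ""), idx)
  expect_equal(res$status[1], "mapped")
  expect_equal(res$sig[1], base$sig[r])
})

test_that("reads inside a trimmed boundary subexon map to its singleton", {
  fx <- smallFixture(42L, nGenes = 1L, nReads = 0L)
  gm <- fx$models[[1]]
  l <- fx$spec$readLength
  lens <- IRanges::width(subexons(gm))
  i <- which(lens >= l)[1]
  expect_false(is.na(i))
  fr <- buildFragments(buildSpliceGraph(gm, "as"), fx$genome, l)
  idx <- buildKmerIndex(fr)
  cs <- fx$genome[[gm@chrom]]
  se <- subexons(gm)
  read <- as.character(Biostrings::subseq(cs, IRanges::start(se)[i],
                                          IRanges::start(se)[i] + l - 1L))
  res <- mapReads(read, idx)
  expect_equal(res$status[1], "mapped")
  expect_equal(res$sig[1], as.character(i))
  # trimming soundness: a mapped read overlapping the first subexon of a
  # multi-subexon fragment always reaches the second
  tab <- fragmentTable(idx@fragments)
  f <- res$frag[1]
  expect_equal(length(tab$sig[[f]]), 1L)
})

test_that("signature counts mirror equivalence classes of identical reads", {
  fxg <- fig2()
  fr <- buildFragments(buildSpliceGraph(fxg$gm, "as"), fxg$genome, 20L)
  idx <- buildKmerIndex(fr)
  cs <- fxg$genome[["chrF"]]
  read <- as.character(Biostrings::subseq(cs, 121L, 140L))  # inside s1
  cnt <- countReads(rep(read, 7L), idx)
  tab <- sigCounts(cnt)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sig, "1")
  expect_equal(tab$count, 7L)

  empty <- countReads(character(0), idx)
  expect_equal(nrow(sigCounts(empty)), 0L)
  expect_equal(mappingStats(empty)[["mapped"]], 0L)
})

test_that("primary-hit selection is deterministic under ties", {
  fxg <- fig2()
  fr <- buildFragments(buildSpliceGraph(fxg$gm, "as"), fxg$genome, 20L)
  idx <- buildKmerIndex(fr)
  cs <- fxg$genome[["chrF"]]
  read <- as.character(Biostrings::subseq(cs, 121L, 140L))
  hits <- SpliceFrags:::candidateHits(read, idx)
  expect_gte(nrow(hits), 1L)
  prim <- selectPrimary(hits, read, idx)
  top <- hits[hits$support == max(hits$support), ]
  expect_equal(prim$frag, min(top$frag))
  expect_identical(selectPrimary(hits, read, idx)$frag, prim$frag)
  expect_error(selectPrimary(hits[0], read, idx), ">= 1 hit")

  # single hit returns itself; higher support wins
  one <- hits[1]
  expect_equal(selectPrimary(one, read, idx)$frag, one$frag)
})

test_that("short reads map from k nt up; over-long reads are rejected", {
  fx <- smallFixture(40L, nGenes = 2L, nReads = 300L)
  graphs <- lapply(fx$models, buildSpliceGraph, mode = "as")
  idx <- buildKmerIndex(buildFragments(graphs, fx$genome,
                                       fx$spec$readLength))
  short <- substr(fx$reads[[1]], 1L, idx@k + 4L)
  res <- mapReads(short, idx)
  expect_equal(res$status[1], "mapped")
  long <- strrep("A", fx$spec$readLength + 1L)
  expect_error(mapReads(long, idx), "longer than the indexed")
  # mostly-N reads are unmapped
  nn <- paste(rep("N", fx$spec$readLength), collapse = "")
  expect_equal(mapReads(nn, idx)$status[1], "unmapped")
})

test_that("FASTQ input is validated and paired ends sum mate counts", {
  d <- withr::local_tempdir()
  spec <- fixtureSpec(seed = 43L, nGenes = 1L, nReads = 150L, paired = TRUE)
  fx <- makeFixture(spec, dir = d)
  graphs <- lapply(fx$models, buildSpliceGraph, mode = "as")
  idx <- buildKmerIndex(buildFragments(graphs, fx$genome,
                                       spec$readLength))
  cnt <- countReads(fx$paths$fastq, idx, mate2 = fx$paths$fastq2)
  expect_same_counts(cnt, truthHistogram(fx$truth))

  pairc <- countReads(fx$reads, idx, mate2 = fx$reads2,
                      pairSignatures = TRUE)
  expect_equal(sum(sigCounts(pairc)$count), mappingStats(pairc)[["mapped"]])
  expect_true(all(grepl("|", sigCounts(pairc)$sig, fixed = TRUE)))

  trunc <- file.path(d, "trunc.fastq")
  writeLines(head(readLines(fx$paths$fastq), 7L), trunc)
  expect_error(countReads(trunc, idx), "record 2")
})

test_that("cross-gene sequence duplications are dropped as ambiguous", {
  ex <- IRanges::IRanges(c(101, 301), c(200, 400))
  gmA <- geneModelFromExons("DUPA", "cA", "+", list(a1 = ex))
  gmB <- geneModelFromExons("DUPB", "cB", "+", list(b1 = ex))
  seq <- withr::with_seed(7L, paste(sample(c("A", "C", "G", "T"), 500L,
                                           replace = TRUE), collapse = ""))
  genome <- Biostrings::DNAStringSet(c(cA = seq, cB = seq))
  graphs <- list(buildSpliceGraph(gmA, "annotated"),
                 buildSpliceGraph(gmB, "annotated"))
  idx <- buildKmerIndex(buildFragments(graphs, genome, 20L))
  read <- substr(seq, 121, 140)
  res <- mapReads(read, idx)
  expect_equal(res$status[1], "ambiguous")
  cnt <- countReads(read, idx)
  expect_equal(mappingStats(cnt)[["ambiguous"]], 1L)
  expect_equal(nrow(sigCounts(cnt)), 0L)
})

test_that("grouping by signature refines the transcript-compatibility classes", {
  fx <- smallFixture(40L, nGenes = 2L, nReads = 300L)
  cnt <- pipelineCounts(fx)
  tab <- sigCounts(cnt)
  key <- vapply(seq_len(nrow(tab)), function(r)
    SpliceFrags:::tccKey(fx$models[[tab$gene[r]]],
                         SpliceFrags:::sigParse(tab$sig[r])), character(1))
  expect_equal(length(key), nrow(tab))   # exactly one TCC class per signature
})
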