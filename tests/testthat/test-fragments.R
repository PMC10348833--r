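test_that("feasibility boundary: internal subexons must fit in l-2", {
  # three-exon transcript whose middle subexon has length 8
  mk <- function(midLen) simpleGene(c(101, 301, 401), c(200, 300 + midLen,
                                                        500))
  g <- mk(8L)
  graph <- buildSpliceGraph(g$gm, "annotated")
  keys10 <- vapply(enumerateFeasibleSignatures(graph, 10L)$sigs,
                   SpliceFrags:::sigKey, character(1))
  expect_true("1,2,3" %in% keys10)          # 8 == l - 2
  keys9 <- vapply(enumerateFeasibleSignatures(graph, 9L)$sigs,
                  SpliceFrags:::sigKey, character(1))
  expect_false("1,2,3" %in% keys9)          # 8 > l - 2

  # a single subexon is feasible iff it can hold a whole read
  g2 <- simpleGene(101, 108)
  keys <- vapply(enumerateFeasibleSignatures(
    buildSpliceGraph(g2$gm, "annotated"), 8L)$sigs,
    SpliceFrags:::sigKey, character(1))
  expect_equal(keys, "1")
  expect_equal(length(enumerateFeasibleSignatures(
    buildSpliceGraph(g2$gm, "annotated"), 9L)$sigs), 0L)

  expect_error(enumerateFeasibleSignatures(buildSpliceGraph(g2$gm,
                                                            "annotated"), 1L),
               ">= 2")
})

test_that("enumeration equals the sliding-window oracle", {
  for (seed in c(30L, 31L)) {
    fx <- smallFixture(seed, nGenes = 1L, nReads = 0L, readLength = 10L)
    for (gm in fx$models) {
      graph <- buildSpliceGraph(gm, "as")
      l <- 10L
      enum <- vapply(enumerateFeasibleSignatures(graph, l)$sigs,
                     SpliceFrags:::sigKey, character(1))
      # oracle: slide every length-l window over every explicit virtual
      # transcript and record the overlapped index sequence
      virt <- enumerateVirtualTranscripts(graph)
      se <- subexons(gm)
      oracle <- character(0)
      for (v in virt) {
        cum <- cumsum(IRanges::width(se)[v])
        if (cum[length(cum)] < l) next
        for (off in seq_len(cum[length(cum)] - l + 1L)) {
          from <- findInterval(off - 1L, cum) + 1L
          to <- findInterval(off + l - 2L, cum) + 1L
          oracle <- c(oracle, SpliceFrags:::sigKey(v[from:to]))
        }
      }
      expect_setequal(enum, unique(oracle))
    }
  }
})

test_that("fragment sequences follow the minimal-trim arithmetic", {
  # m = 2: last l-1 of the first and first l-1 of the second subexon
  g <- simpleGene(c(101, 301), c(150, 350))
  graph <- buildSpliceGraph(g$gm, "annotated")
  f11 <- buildFragments(graph, g$genome, 10L, variant = "F11")
  tab <- fragmentTable(f11)
  r <- which(tab$sigKey == "1,2")
  expect_equal(IRanges::width(fragmentSeqs(f11))[r], 18L)
  expect_equal(tab$segStart[[r]], c(142L, 301L))
  expect_equal(tab$segEnd[[r]], c(150L, 309L))
  # every junction-spanning read occurs in the fragment
  cs <- g$genome[["chrS"]]
  txSeq <- paste0(as.character(Biostrings::subseq(cs, 101, 150)),
                  as.character(Biostrings::subseq(cs, 301, 350)))
  frag <- as.character(fragmentSeqs(f11)[[r]])
  for (w in 42:50) {   # all windows covering the junction between 50|51
    expect_true(grepl(substr(txSeq, w, w + 9L), frag, fixed = TRUE))
  }

  # m = 3 with a 4 nt middle subexon at l = 10: b = 5, total 14
  g3 <- simpleGene(c(101, 301, 401), c(200, 304, 500))
  f311 <- buildFragments(buildSpliceGraph(g3$gm, "annotated"), g3$genome,
                         10L, variant = "F11")
  t3 <- fragmentTable(f311)
  r3 <- which(t3$sigKey == "1,2,3")
  expect_equal(IRanges::width(fragmentSeqs(f311))[r3], 14L)
  nm <- parseFragmentName(t3$name[r3])[[1]]
  expect_equal(nm$sig, 1:3)
  expect_equal(nm$firstLen, 5L)
  expect_equal(nm$lastLen, 5L)

  # m = 1: the whole subexon
  r1 <- which(t3$sigKey == "1")
  expect_equal(IRanges::width(fragmentSeqs(f311))[r1], 100L)
})

test_that("long subexons become singletons and other fragments are trimmed", {
  fx <- smallFixture(32L, nGenes = 1L, nReads = 0L)
  gm <- fx$models[[1]]
  l <- fx$spec$readLength
  graph <- buildSpliceGraph(gm, "as")
  fr <- buildFragments(graph, fx$genome, l, variant = "F")
  tab <- fragmentTable(fr)
  lens <- IRanges::width(subexons(gm))
  for (i in which(lens >= l)) {
    # the subexon appears as its own fragment
    expect_true(any(tab$sigKey == as.character(i)))
    # and no other fragment contains more than l-1 of its bases
    for (r in seq_len(nrow(tab))) {
      if (tab$sigKey[r] == as.character(i)) next
      seg <- which(tab$sig[[r]] == i)
      if (length(seg))
        expect_lte(tab$segEnd[[r]][seg] - tab$segStart[[r]][seg] + 1L,
                   l - 1L)
    }
  }
})

test_that("fragment sets are correct and complete on the demo genes", {
  for (fxg in list(fig2(), fig3())) {
    for (l in c(8L, 10L, 15L)) {
      graph <- buildSpliceGraph(fxg$gm, "as")
      fr <- buildFragments(graph, fxg$genome, l, variant = "F")
      v <- verifyFragmentSet(fr, graph, fxg$genome, l)
      expect_equal(nrow(v$correctViolations), 0L)
      expect_equal(nrow(v$completeViolations), 0L)
      expect_gt(v$nWindows, 0L)
    }
  }
})

test_that("a 1 nt subexon between junctions does not break completeness", {
  g <- simpleGene(c(101, 301, 501), c(200, 400, 600),
                  extra = list(t2 = IRanges::IRanges(c(101, 301, 501),
                                                     c(200, 301, 600))))
  # t2's alternative donor at 301 creates the 1 nt subexon [301,301]
  expect_true(1L %in% IRanges::width(subexons(g$gm)))
  for (l in c(8L, 10L, 15L)) {
    graph <- buildSpliceGraph(g$gm, "as")
    fr <- buildFragments(graph, g$genome, l, variant = "F")
    v <- verifyFragmentSet(fr, graph, g$genome, l)
    expect_equal(nrow(v$correctViolations), 0L)
    expect_equal(nrow(v$completeViolations), 0L)
  }
})

test_that("maximal signatures are fewer and named round-trip", {
  fx <- smallFixture(33L, nGenes = 2L, nReads = 0L)
  graphs <- lapply(fx$models, buildSpliceGraph, mode = "as")
  l <- fx$spec$readLength
  f11 <- buildFragments(graphs, fx$genome, l, variant = "F11")
  fmax <- buildFragments(graphs, fx$genome, l, variant = "Fmax")
  expect_lte(length(fmax), length(f11))
  tab <- fragmentTable(fmax)
  parsed <- parseFragmentName(tab$name)
  for (r in seq_len(nrow(tab))) {
    expect_equal(parsed[[r]]$gene, tab$gene[r])
    expect_equal(parsed[[r]]$sig, tab$sig[[r]])
  }
})

test_that("fragment FASTA output is byte-identical across runs", {
  d <- withr::local_tempdir()
  fx <- smallFixture(34L, nGenes = 1L, nReads = 0L)
  graph <- buildSpliceGraph(fx$models[[1]], "as")
  p1 <- file.path(d, "a.fa"); p2 <- file.path(d, "b.fa")
  writeFragments(buildFragments(graph, fx$genome, 75L, variant = "F"), p1)
  writeFragments(buildFragments(graph, fx$genome, 75L, variant = "F"), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(paste0(p1, ".tsv")),
                   readLines(paste0(p2, ".tsv")))
})

test_that("intron-inclusion fragments carry the intron as a pseudo-segment", {
  fxg <- fig3()
  graph <- buildSpliceGraph(fxg$gm, "as")
  fr <- buildFragments(graph, fxg$genome, 10L, variant = "F",
                       withIntrons = TRUE)
  tab <- fragmentTable(fr)
  ir <- which(vapply(tab$sig, function(s) any(s < 0L), logical(1)))
  expect_true(length(ir) > 0L)
  r <- ir[vapply(tab$sig[ir], function(s) identical(s, c(6L, -6L, 7L)),
                 logical(1))]
  expect_equal(length(r), 1L)
  # flank at most l-1, intron in full (gap 681..780)
  expect_equal(tab$segStart[[r]][2], 681L)
  expect_equal(tab$segEnd[[r]][2], 780L)
  expect_lte(tab$segEnd[[r]][1] - tab$segStart[[r]][1] + 1L, 9L)
})
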