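test_that("the canonical novel introns classify into every event type", {
  gm <- fig3()$gm
  # exon skipping: classical wrt EVT3, nonclassical wrt EVT2
  es3 <- classifyIntron(gm, 181, 780, "EVT3")
  expect_equal(es3$type, "ES")
  expect_true(es3$classical)
  expect_equal(es3$skippedExons, 1L)
  es2 <- classifyIntron(gm, 181, 780, "EVT2")
  expect_equal(es2$type, "ES")
  expect_false(es2$classical)
  # alternative donor / acceptor / donor-acceptor pair / exitron
  expect_equal(classifyIntron(gm, 341, 520, "EVT2")$type, "AD")
  expect_equal(classifyIntron(gm, 421, 600, "EVT2")$type, "AA")
  expect_equal(classifyIntron(gm, 601, 860, "EVT2")$type, "AP")
  expect_equal(classifyIntron(gm, 601, 860, "EVT3")$type, "AA")
  expect_equal(classifyIntron(gm, 181, 260, "EVT2")$type, "IE")
  # classifying an annotated intron of the same transcript is an error
  expect_error(classifyIntron(gm, 421, 520, "EVT2"), "not novel")
})

test_that("multi-exon skipping reports the number of skipped exons", {
  gm <- fig2()$gm
  cls <- classifyIntron(gm, 201, 780, "FIXB")
  expect_equal(cls$type, "ES")
  expect_true(cls$classical)
  expect_equal(cls$skippedExons, 2L)
})

test_that("classification is total over candidate junctions", {
  for (seed in c(60L, 61L)) {
    fx <- smallFixture(seed, nGenes = 2L, nReads = 0L)
    for (gm in fx$models) {
      cand <- SpliceFrags:::candidateJunctions(gm, 20L)
      for (r in seq_len(nrow(cand))) {
        for (tx in txNames(gm)) {
          ex <- gm@exonsByTx[[tx]]
          if (max(IRanges::end(ex)) < cand$intronStart[r] ||
              min(IRanges::start(ex)) > cand$intronEnd[r]) next
          cls <- classifyIntron(gm, cand$intronStart[r], cand$intronEnd[r],
                                tx)
          expect_true(cls$type %in% c("ES", "AD", "AA", "AP", "IE", "UNK"))
        }
      }
    }
  }
})

test_that("as-guessed junctions always classify as ES/AD/AA/AP", {
  for (seed in c(60L, 61L)) {
    fx <- smallFixture(seed, nGenes = 2L, nReads = 0L)
    for (gm in fx$models) {
      gj <- guessJunctionsAS(gm)
      for (r in seq_len(nrow(gj))) {
        types <- vapply(txNames(gm), function(tx) {
          ex <- gm@exonsByTx[[tx]]
          if (max(IRanges::end(ex)) < gj$intronStart[r] ||
              min(IRanges::start(ex)) > gj$intronEnd[r]) return("none")
          classifyIntron(gm, gj$intronStart[r], gj$intronEnd[r], tx)$type
        }, character(1))
        expect_true(any(types %in% c("ES", "AD", "AA", "AP")))
      }
    }
  }
})

test_that("classification is invariant under strand mirroring", {
  gm <- fig3()$gm
  L <- 1101L
  flip <- function(x) L - x + 1L
  gmM <- geneModelFromExons("MIR", "chrM", "-", lapply(gm@exonsByTx,
    function(ex) IRanges::IRanges(start = flip(IRanges::end(ex)),
                                  end = flip(IRanges::start(ex)))))
  cases <- list(c(181, 780), c(341, 520), c(421, 600), c(601, 860),
                c(181, 260))
  for (cs in cases) {
    for (tx in txNames(gm)) {
      ex <- gm@exonsByTx[[tx]]
      if (max(IRanges::end(ex)) < cs[1] || min(IRanges::start(ex)) > cs[2])
        next
      a <- classifyIntron(gm, cs[1], cs[2], tx)
      b <- classifyIntron(gmM, flip(cs[2]), flip(cs[1]),
                          sub(gm@geneID, "MIR", tx, fixed = TRUE))
      expect_equal(b$type, a$type)
      expect_equal(b$classical, a$classical)
    }
  }
})

test_that("annotateEvents records one row per junction and transcript", {
  gm <- fig3()$gm
  models <- list(FIXE1 = gm)
  # no novel junctions: empty table
  annOnly <- signatureCounts(data.frame(gene = "FIXE1", sig = c("1", "7,8"),
                                        count = c(5L, 5L)))
  expect_equal(nrow(annotateEvents(annOnly, models)), 0L)

  cnt <- signatureCounts(data.frame(gene = "FIXE1",
                                    sig = c("5,8", "4,5,8"),
                                    count = c(12L, 8L)))
  ev <- annotateEvents(cnt, models)
  # junction (5,8) is supported by both signatures; one record per
  # overlapping transcript, with distinct types
  j <- ev[ev$intronStart == 601L & ev$intronEnd == 860L, ]
  expect_setequal(j$transcript, c("EVT1", "EVT2", "EVT3"))
  expect_equal(unique(j$supportingCount), 20L)
  expect_equal(j$type[j$transcript == "EVT2"], "AP")
  expect_equal(j$type[j$transcript == "EVT3"], "AA")
  expect_equal(ev$donor[1], 600L)
  expect_equal(ev$acceptor[1], 861L)
})

test_that("events on a held-out fixture recover the skipping junction", {
  fx <- smallFixture(62L, nGenes = 1L, nReads = 500L, holdOut = TRUE)
  expect_equal(nrow(fx$heldOut), 1L)
  cnt <- pipelineCounts(fx)
  ev <- annotateEvents(cnt, fx$models)
  j <- ev[ev$intronStart == fx$heldOut$intronStart &
            ev$intronEnd == fx$heldOut$intronEnd, ]
  expect_gt(nrow(j), 0L)
  expect_true("ES" %in% j$type)
  novel <- sum(fx$truth$class == "novel_junction" & fx$truth$identifiable)
  expect_gte(j$supportingCount[1], novel)
})

test_that("intron retention needs coverage and no splicing inside", {
  gm <- fig3()$gm
  models <- list(FIXE1 = gm)
  # unspliced coverage across the s6|s7 gap, no internal splicing: IR
  cnt <- signatureCounts(data.frame(gene = "FIXE1", sig = "6,-6,7",
                                    count = 5L))
  ir <- detectIntronRetention(cnt, models)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$intronStart, 681L)
  expect_equal(ir$intronEnd, 780L)
  expect_equal(ir$supportingCount, 5L)

  # an observed junction with a boundary strictly inside the gap kills IR
  ej <- data.frame(chrom = "chrE", intronStart = 700L, intronEnd = 780L,
                   count = 3L)
  expect_equal(nrow(detectIntronRetention(cnt, models,
                                          extraJunctions = ej)), 0L)

  # no coverage: no IR
  none <- signatureCounts(data.frame(gene = "FIXE1", sig = "6,7",
                                     count = 5L))
  expect_equal(nrow(detectIntronRetention(none, models)), 0L)

  # a region that is exonic in another transcript is never an IR candidate:
  # EVT3's intron 181..520 is exonic in EVT2, so it is not an intronic gap
  gaps <- SpliceFrags:::intronicGaps(gm)
  expect_false(any(gaps$start <= 200 & gaps$end >= 200))
})

test_that("retained introns are observable through intron fragments", {
  fxg <- fig3()
  graph <- buildSpliceGraph(fxg$gm, "as")
  fr <- buildFragments(graph, fxg$genome, 20L, withIntrons = TRUE)
  idx <- buildKmerIndex(fr)
  cs <- fxg$genome[["chrE"]]
  # a read across the exon-intron boundary at 680|681
  read <- as.character(Biostrings::subseq(cs, 671L, 690L))
  res <- mapReads(read, idx)
  expect_equal(res$status[1], "mapped")
  expect_equal(res$sig[1], "6,-6")
  cnt <- countReads(rep(read, 4L), idx)
  ir <- detectIntronRetention(cnt, list(FIXE1 = fxg$gm))
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$supportingCount, 4L)
})
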