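fig2Counts <- function() {
  signatureCounts(data.frame(
    gene = "FIXG1",
    sig = c("1", "1,2", "2,4,5", "1,5"),
    count = c(4L, 3L, 2L, 3L)))
}

test_that("transcript compatibility follows the signature set expression", {
  models <- list(FIXG1 = fig2()$gm)
  tcc <- toTCC(fig2Counts(), models)
  # reads with signatures (1) and (1,2) are compatible with both
  # transcripts; (2,4,5) subtracts t(s3) and becomes novel mass, as does
  # the exon-skipping signature (1,5)
  expect_equal(tcc$count[tcc$transcripts == "FIXA,FIXB"], 7L)
  expect_equal(tcc$count[tcc$transcripts == "NOVEL"], 5L)
  expect_equal(sum(tcc$count), 12L)

  # single-transcript gene: everything goes to that transcript
  g <- simpleGene(c(101, 301), c(200, 400))
  single <- signatureCounts(data.frame(gene = "S1",
                                       sig = c("1", "1,2", "2"),
                                       count = c(1L, 2L, 3L)))
  t1 <- toTCC(single, list(S1 = g$gm))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$transcripts, "t1")
  expect_equal(t1$count, 6L)

  expect_error(toTCC(signatureCounts(data.frame(gene = "S1", sig = "9",
                                                count = 1L)),
                     list(S1 = g$gm)), "unknown subexon")
})

test_that("the set expression agrees with the per-read compatibility oracle", {
  for (seed in c(50L, 51L)) {
    fx <- smallFixture(seed, nGenes = 2L, nReads = 400L, holdOut = TRUE)
    tr <- fx$truth
    for (r in seq_len(nrow(tr))) {
      gm <- fx$models[[tr$gene[r]]]
      blocks <- truthBlocks(tr, r)
      expected <- oracleCompatibility(gm, blocks)
      key <- SpliceFrags:::tccKey(gm, SpliceFrags:::sigParse(tr$trueSig[r]))
      if (!length(expected)) {
        expect_equal(key, "NOVEL")
      } else {
        expect_equal(key, paste(sort(expected), collapse = ","))
      }
    }
  }
})

test_that("subexon counts add signature counts per contained subexon", {
  sub <- toSubexonCounts(fig2Counts())
  # three reads with signature (1,5) contribute 3 to s1 and 3 to s5
  expect_equal(sub$count[sub$subexon == 5L], 2L + 3L)
  expect_equal(sub$count[sub$subexon == 1L], 4L + 3L + 3L)
  expect_equal(sub$count[sub$subexon == 4L], 2L)

  empty <- signatureCounts(data.frame(gene = character(0),
                                      sig = character(0),
                                      count = integer(0)))
  expect_equal(nrow(toSubexonCounts(empty)), 0L)

  # overlap-counting oracle on a fixture
  fx <- smallFixture(50L, nGenes = 2L, nReads = 400L, holdOut = TRUE)
  cnt <- signatureCounts(truthHistogram(fx$truth))
  sub <- toSubexonCounts(cnt)
  tr <- fx$truth[fx$truth$identifiable, ]
  for (g in names(fx$models)) {
    gm <- fx$models[[g]]
    here <- tr[tr$gene == g, , drop = FALSE]
    for (i in seq_len(nSubexons(gm))) {
      n <- sum(vapply(seq_len(nrow(here)), function(r)
        i %in% SpliceFrags:::sigParse(here$trueSig[r]), logical(1)))
      got <- sub$count[sub$gene == g & sub$subexon == i]
      expect_equal(if (length(got)) got else 0L, n)
    }
  }
})

test_that("bins merge overlapping signatures with equal transcript sets", {
  models <- list(FIXG1 = fig2()$gm)
  bins <- toMergedBins(fig2Counts(), models)
  # (1) and (1,2) overlap and share the annotated compatibility set
  b <- bins[bins$transcripts == "FIXA,FIXB", ]
  expect_equal(b$bin, "1;1,2")
  expect_equal(b$count, 7L)
  expect_equal(sum(bins$count), 12L)

  # disjoint spans stay separate even with equal transcript sets
  far <- signatureCounts(data.frame(gene = "FIXG1", sig = c("1", "5"),
                                    count = c(2L, 2L)))
  bins2 <- toMergedBins(far, models)
  expect_equal(nrow(bins2), 2L)

  # transitive-closure oracle on a fixture
  fx <- smallFixture(50L, nGenes = 2L, nReads = 400L, holdOut = TRUE)
  cnt <- signatureCounts(truthHistogram(fx$truth))
  got <- toMergedBins(cnt, fx$models)
  tab <- sigCounts(cnt)
  for (g in unique(tab$gene)) {
    gm <- fx$models[[g]]
    sub <- tab[tab$gene == g, ]
    sigs <- lapply(sub$sig, SpliceFrags:::sigParse)
    keys <- vapply(sigs, SpliceFrags:::tccKey, character(1), gm = gm)
    se <- subexons(gm)
    sp <- t(vapply(sigs, function(s)
      c(IRanges::start(se)[min(abs(s))], IRanges::end(se)[max(abs(s))]),
      integer(2)))
    grp <- seq_len(nrow(sub))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
        if (grp[i] != grp[j] && keys[i] == keys[j] &&
            sp[i, 1] <= sp[j, 2] && sp[j, 1] <= sp[i, 2]) {
          grp[grp == max(grp[c(i, j)])] <- min(grp[c(i, j)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    oracleBins <- sort(vapply(split(sub$count, grp), sum, numeric(1)))
    gotBins <- sort(got$count[got$gene == g])
    expect_equal(as.integer(gotBins), as.integer(oracleBins))
    expect_equal(length(gotBins), length(unique(grp)))
  }
})

test_that("graph counts quantify nodes and traversed edges", {
  g <- fig3()$gm
  cnt <- signatureCounts(data.frame(gene = "FIXE1",
                                    sig = c("1,3", "1,3,5"),
                                    count = c(5L, 2L)))
  gc <- toGraphCounts(cnt, list(FIXE1 = g))
  e13 <- gc$edges[gc$edges$from == 1L & gc$edges$to == 3L, ]
  expect_equal(e13$count, 7L)       # both signatures traverse (1,3)
  expect_equal(e13$type, "spliced")
  e35 <- gc$edges[gc$edges$from == 3L & gc$edges$to == 5L, ]
  expect_equal(e35$count, 2L)       # the two-junction signature adds both
  expect_equal(gc$nodes$count[gc$nodes$subexon == 3L], 7L)

  # adjacency vs spliced: (1,2) in the demo gene spans a real intron
  gc2 <- toGraphCounts(fig2Counts(), list(FIXG1 = fig2()$gm))
  expect_true(all(gc2$edges$type == "spliced"))
  # unspliced coverage of genomically abutting subexons is an adjacency
  gm3 <- fig3()$gm
  adj <- toGraphCounts(signatureCounts(data.frame(
    gene = "FIXE1", sig = "1,2", count = 4L)), list(FIXE1 = gm3))
  expect_equal(adj$edges$type, "adjacent")

  # per-read junction-crossing oracle
  fx <- smallFixture(50L, nGenes = 2L, nReads = 400L, holdOut = TRUE)
  cntf <- signatureCounts(truthHistogram(fx$truth))
  gcf <- toGraphCounts(cntf, fx$models)
  tr <- fx$truth[fx$truth$identifiable, ]
  for (r in seq_len(nrow(gcf$edges))) {
    e <- gcf$edges[r, ]
    n <- 0L
    here <- tr[tr$gene == e$gene, , drop = FALSE]
    for (q in seq_len(nrow(here))) {
      s <- SpliceFrags:::sigParse(here$trueSig[q])
      pos <- which(s == e$from)
      if (length(pos) && pos < length(s) && s[pos + 1L] == e$to)
        n <- n + 1L
    }
    expect_equal(as.integer(e$count), n)
  }
})

test_that("conversions conserve totals and are pure", {
  fx <- smallFixture(50L, nGenes = 2L, nReads = 400L, holdOut = TRUE)
  cnt <- signatureCounts(truthHistogram(fx$truth))
  total <- sum(sigCounts(cnt)$count)
  tcc <- toTCC(cnt, fx$models)
  expect_equal(sum(tcc$count), total)
  bins <- toMergedBins(cnt, fx$models)
  expect_equal(sum(bins$count), total)
  expect_identical(toTCC(cnt, fx$models), tcc)
  expect_identical(toMergedBins(cnt, fx$models), bins)
  expect_identical(toSubexonCounts(cnt), toSubexonCounts(cnt))
})

test_that("flattened exon-bin output covers every subexon once", {
  d <- withr::local_tempdir()
  models <- list(FIXG1 = fig2()$gm)
  p <- file.path(d, "dex.tsv")
  writeDexseqCounts(fig2Counts(), models, p)
  tab <- read.table(p, sep = "\t")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$V1, sprintf("FIXG1:E%03d", 1:5))
  expect_equal(tab$V2, c(10L, 5L, 0L, 2L, 5L))
})
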