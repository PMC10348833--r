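# Shared fixtures and small utilities for the test suite. Fixtures are
# generated in code (no data files) and cached per test run.

.fixCache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixCache, inherits = FALSE))
    assign(key, maker(), envir = .fixCache)
  get(key, envir = .fixCache, inherits = FALSE)
}

fig2 <- function() cached("fig2", fig2Gene)
fig3 <- function() cached("fig3", fig3Gene)

smallFixture <- function(seed, ...) {
  args <- list(...)
  key <- paste0("fx_", seed, "_", paste(names(args), unlist(args),
                                        sep = "=", collapse = "_"))
  cached(key, function() makeFixture(do.call(
    fixtureSpec, c(list(seed = seed), args))))
}

# truth histogram over identifiable reads, as a (gene, sig, count) frame
truthHistogram <- function(truth, classes = NULL) {
  keep <- !is.na(truth$identifiable) & truth$identifiable
  if (!is.null(classes)) keep <- keep & truth$class %in% classes
  tr <- truth[keep, , drop = FALSE]
  if (!nrow(tr)) {
    return(data.frame(gene = character(0), sig = character(0),
                      count = integer(0)))
  }
  agg <- aggregate(list(count = rep(1L, nrow(tr))),
                   by = list(gene = tr$gene, sig = tr$trueSig), FUN = sum)
  agg[order(agg$gene, agg$sig), ]
}

# run the standard pipeline (graphs -> fragments -> index -> counts)
pipelineCounts <- function(fx, mode = "as", variant = "F", k = NULL,
                           verifyHamming = Inf, withIntrons = FALSE) {
  l <- fx$spec$readLength
  graphs <- lapply(fx$models, buildSpliceGraph, mode = mode)
  frags <- buildFragments(graphs, fx$genome, l, variant = variant,
                          withIntrons = withIntrons)
  idx <- buildKmerIndex(frags, k)
  countReads(fx$reads, idx, verifyHamming = verifyHamming)
}

expect_same_counts <- function(counts, expected) {
  got <- sigCounts(counts)
  got <- got[order(got$gene, got$sig), c("gene", "sig", "count")]
  expected <- expected[order(expected$gene, expected$sig),
                       c("gene", "sig", "count")]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got$gene, expected$gene)
  expect_equal(got$sig, expected$sig)
  expect_equal(as.integer(got$count), as.integer(expected$count))
}

# genomic blocks recorded in a truth row
truthBlocks <- function(truth, r) {
  parts <- strsplit(strsplit(truth$blocks[r], ";")[[1]], "-")
  IRanges::IRanges(start = as.integer(vapply(parts, `[`, "", 1L)),
                   end = as.integer(vapply(parts, `[`, "", 2L)))
}

# identifiability of novel-site reads against the refined transcriptome
refinedIdent <- function(fx, ref) {
  virt <- setNames(lapply(names(ref$models), function(g) {
    dj <- ref$discovered[ref$discovered$gene == g, , drop = FALSE]
    tryCatch(enumerateVirtualTranscripts(
      buildSpliceGraph(ref$models[[g]], "as", extraJunctions = dj),
      maxPaths = 20000L), error = function(e) NULL)
  }), names(ref$models))
  flagIdentifiable(fx$truth, fx$reads, ref$models, fx$genome, virt,
                   fx$spec$readLength, classes = "novel_site")
}

# one-transcript gene model over given exon coordinates on a random genome
simpleGene <- function(exonStarts, exonEnds, strand = "+", seed = 99L,
                       id = "S1", chrom = "chrS", extra = list()) {
  exonsByTx <- c(list(t1 = IRanges::IRanges(exonStarts, exonEnds)), extra)
  gm <- geneModelFromExons(id, chrom, strand, exonsByTx)
  genome <- withr::with_seed(seed, Biostrings::DNAStringSet(
    setNames(paste(sample(c("A", "C", "G", "T"),
                          max(exonEnds) + 100L, replace = TRUE),
                   collapse = ""), chrom)))
  list(gm = gm, genome = genome)
}
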