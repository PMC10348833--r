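# SpliceFrags

Quantifying alternative splicing — including *novel* splicing — from short
RNA-seq reads usually forces a choice: fast pseudoalignment against known
transcripts (which misses unannotated junctions), or a full genomic spliced
alignment followed by feature counting (which is slow). SpliceFrags takes a
third route: it **guesses** novel junctions by recombining annotated donor
and acceptor sites, builds a compact set of **transcript fragments**
guaranteed to contain every read of a fixed length, pseudoaligns reads to
those fragments with a light k-mer engine, and counts reads by their
**mapping signature**. It is aimed at transcriptomics analysts who want
event-level novel-splicing evidence from bulk or single-cell short-read
libraries without running a genomic aligner on the whole dataset.

## The method in brief

A gene's transcripts partition its exonic sequence into *subexons*
s<sub>1</sub>…s<sub>n</sub>, the smallest segments bounded by splice sites
or transcript start/end sites. The mapping signature of a read is the
increasing index sequence ı = (i<sub>1</sub>, i<sub>2</sub>, …) of subexons
it overlaps; reads are equivalent iff their signatures match, and signature
counts are the class sizes. Signature counts convert, without touching
reads again, to:

* transcript compatibility counts via
  ∩<sub>i∈ı</sub> t(s<sub>i</sub>) ∖ ∪<sub>i∈ı̄</sub> t(s<sub>i</sub>)
  (empty set ⇒ novel pattern, kept under a reserved `NOVEL` key),
* per-subexon (flattened exon-bin) counts,
* merged counting bins (overlapping signatures with equal transcript sets),
* splicing-graph node and edge counts.

For read length *l*, a signature is *feasible* iff it is a window of some
(virtual) transcript, its subexons can hold a read (Σ|s<sub>i</sub>| ≥ l),
and its internal subexons fit under the read
(Σ<sub>internal</sub>|s<sub>i</sub>| ≤ l−2). The fragment of a feasible
signature is the minimal genomic concatenation containing every read with
that signature; the shipped fragment set trims boundary subexons to l−1 nt
and emits long subexons as singletons, so fragments barely overlap. Novel
introns implied by counted signatures are classified per comparison
transcript into exon skipping (classical/nonclassical, with skipped-exon
count), alternative donor / acceptor / donor–acceptor pair, novel intron in
exon (exitron), intron retention (conservative rule), or unknown. A refine
phase ingests a spliced-aligner junction file, splits subexons at
discovered sites, remaps existing counts losslessly and requantifies
previously unmapped reads.

## Worked example

The bundled demonstration gene has two transcripts over five subexons
(FIXA = (1,2,5), FIXB = (1,2,3,4,5)). We map ten reads: four inside
subexon 1, three across the annotated junction (1,2), and three across the
*novel* exon-skipping junction (1,5) that only exists in the guessed
virtual transcriptome:

```r
library(SpliceFrags); library(Biostrings)
demo  <- fig2Gene()
graph <- buildSpliceGraph(demo$gm, mode = "as")
frags <- buildFragments(graph, demo$genome, l = 20, variant = "F")
idx   <- buildKmerIndex(frags)
cs    <- demo$genome[["chrF"]]
reads <- c(rep(as.character(subseq(cs, 121, 140)), 4),
           rep(paste0(subseq(cs, 191, 200), subseq(cs, 301, 310)), 3),
           rep(paste0(subseq(cs, 191, 200), subseq(cs, 781, 790)), 3))
counts <- countReads(reads, idx)
counts
#> SignatureCounts: 3 classes, 10 reads mapped (0 unmapped, 0 ambiguous)
sigCounts(counts)
#>    gene sig count
#> 1 FIXG1   1     4
#> 2 FIXG1 1,2     3
#> 3 FIXG1 1,5     3
```

All ten reads map, including the novel-junction reads — no aligner was
involved. The conversions show why signatures are the finest unit: the
first seven reads are compatible with both transcripts and collapse into
one compatibility class of size 7, while the skipping reads form novel
mass; per-subexon counts credit the three (1,5) reads to both s1 and s5:

```r
toTCC(counts, list(FIXG1 = demo$gm))
#>    gene transcripts count
#> 1 FIXG1   FIXA,FIXB     7
#> 2 FIXG1       NOVEL     3
toSubexonCounts(counts)
#>    gene subexon count
#> 1 FIXG1       1    10
#> 2 FIXG1       2     3
#> 3 FIXG1       5     3
annotateEvents(counts, list(FIXG1 = demo$gm))[,
  c("transcript", "donor", "acceptor", "type", "classical",
    "skippedExons", "supportingCount")]
#>   transcript donor acceptor type classical skippedExons supportingCount
#> 1       FIXA   200      781   ES      TRUE            1               3
#> 2       FIXB   200      781   ES      TRUE            2               3
```

The novel intron (donor 200, acceptor 781) is a classical exon skipping —
of one exon relative to FIXA, of two relative to FIXB — supported by three
reads.

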