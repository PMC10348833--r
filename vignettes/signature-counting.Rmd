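---
title: "Counting novel splicing with subexon signatures and transcript fragments"
author: "SpliceFrags maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting novel splicing with subexon signatures and transcript fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceFrags)
```

## The model

Short RNA-seq reads carry local splicing information: which exonic segments
a read touches and which it splices over. SpliceFrags quantifies exactly
that. A gene's transcripts partition its exonic sequence into *subexons* —
the smallest segments bounded by splice sites or transcript start/end sites
— numbered $s_1, \dots, s_n$ left to right along the genome. The *mapping
signature* of a read is the increasing sequence $\imath = (i_1, i_2, \dots)$
of subexon indices it overlaps; two reads are equivalent iff their
signatures are identical, and the *signature count* is the size of such an
equivalence class. Signatures are the finest transcriptomic counting unit:
transcript compatibility classes, per-subexon (exon-bin) counts, merged
counting bins and splicing-graph node/edge counts are all many-to-one
functions of the signature table and are recomputed here without revisiting
reads. The compatible transcript set of a signature is
$\bigcap_{i \in \imath} t(s_i) \setminus \bigcup_{i \in \bar\imath} t(s_i)$,
where $t(s)$ is the set of transcripts containing $s$ and $\bar\imath$ are
the skipped indices between the first and last entry; an empty result marks
a novel splicing pattern and is kept under a reserved `NOVEL` key so totals
are conserved.

Novel junctions are *guessed* before any read is seen: every annotated
donor–acceptor pair in transcription order whose implied intron is not
annotated and classifies as exon skipping (ES), alternative donor (AD),
alternative acceptor (AA) or alternative donor–acceptor pair (AP) with
respect to at least one annotated transcript becomes a spliced edge of the
gene's splice graph. The graph's path language plays the role of a virtual
transcriptome: `annotated` restricts paths to the annotated transcripts,
`as` admits guessed junctions anchored within the span of at least one
annotated transcript (transcript start/end sites are never invented), and
`ap` drops the span constraint, mimicking more general alternative
processing. Junction sets and path languages nest accordingly. The `as`
membership test is intentionally local — a junction is admitted by its
event classification, a signature by span anchoring — which makes
membership decidable per walk; the explicit virtual-transcript enumerator
(`enumerateVirtualTranscripts`) materializes the same language by
depth-first path enumeration and is what the verification and simulation
tools slide read windows over.

## Feasible signatures and fragments

Given read length $l$, a signature $\imath = (i_1,\dots,i_m)$ is *feasible*
iff (f1) it is a contiguous window of some (virtual) transcript, (f2)
$\sum_{i \in \imath} |s_i| \ge l$, and (f3) for $m \ge 3$ the internal
subexons satisfy $\sum_{j=2}^{m-1} |s_{i_j}| \le l - 2$, because a read
must cover all internal subexons and still reach at least one base into
each boundary subexon. Condition f3 bounds every enumeration walk, so the
index never materializes whole virtual transcripts. The minimal fragment of
a feasible signature concatenates, with $b = l - L_\text{int} - 1$, the
last $\min(|s_{i_1}|, b)$ bases of the first subexon, all internal
subexons, and the first $\min(|s_{i_m}|, b)$ bases of the last; every
error-free read with that signature is a substring of it. Three fragment
sets are built from this:

* **F11** — one minimally trimmed fragment per feasible signature;
* **Fmax** — only *maximal* signatures (not contained contiguously in any
  other feasible signature), with boundary subexons included in full;
* **F** (default) — Fmax plus every subexon of length $\ge l$ as a
  singleton fragment, with the boundary contribution of the remaining
  fragments trimmed to at most $l-1$ nt, so that any mapping overlapping a
  trimmed boundary subexon also reaches the adjacent internal one and
  cannot conflict with the singleton.

All three induce identical signature counts; `verifyFragmentSet` checks,
exhaustively for small genes, that every fragment derives from a virtual
transcript and that every read-length window over every virtual transcript
occurs in some fragment whose positional scan returns the window's true
signature. A caveat worth knowing: the *number* of fragments in Fmax never
exceeds F11, but total sequence volume need not decrease along F11 → Fmax
→ F at toy scale. Fmax duplicates long boundary subexons across the
fragments sharing them, and F's singleton for a subexon $d$ pays $|d|$
while trimming saves $n_d(|d| - l + 1)$ over its $n_d$ boundary
occurrences; with few transcripts per gene (small $n_d$) and subexons
shorter than about $2(l-1)$, F can exceed Fmax by a few tens of bases. The
volume savings of F are a genome-scale phenomenon, where junction-rich loci
give large $n_d$; the package keeps the three definitions exact rather than
optimizing the toy-scale ordering.

## The mapping engine

Fragments are indexed by their $k$-mers ($k = \min(31, l-1)$ by default).
For each read, anchor $k$-mers at stride $k$ plus the final position are
looked up in both orientations; each posting votes for the read-start
offset it implies within a fragment. The winner is the candidate with
maximal support, ties broken by exact-match length and then by lowest
fragment id. The anchor layout guarantees that a single substitution at
least $k$ nt from both read ends leaves one intact anchor on each side, so
such reads keep their signature. The winning offset determines the
signature by a linear scan through the fragment's breakpoints. When tied
best candidates imply *different* (gene, signature) pairs the read is
counted as `ambiguous` and excluded: such ties at 0% error are
information-theoretic (a 1–5 nt junction overhang whose alternative
continuation starts with the same bases), and the fixture truth tables
carry an oracle-computed `identifiable` flag that marks exactly these
reads. Paired-end mates are mapped independently and their counts summed;
`pairSignatures = TRUE` keys counts by the ordered signature pair instead.
Optional Hamming verification (`verifyHamming`) rejects winners whose best
placement still mismatches too many bases — useful before refinement, so
reads across unannotated splice sites are reported unmapped rather than
force-fitted.

## Event annotation and refinement

Every novel intron implied by a counted signature is compared against each
annotated transcript of its gene: strictly inside one exon → IE (exitron);
at least one complete exon strictly inside the intron → ES, *classical* iff
the intron spans exactly from the end of the preceding kept exon to the
start of the following one, with the number of skipped exons attached;
otherwise a matching acceptor with a novel donor → AD, matching donor → AA,
neither matching but overlapping an intron → AP; everything else → UNK.
Precedence is IE, ES, AD, AA, AP, UNK, and the same intron may imply
different types against different transcripts. Intron retention is called
conservatively: only for regions that are intronic in every transcript,
covered by unspliced reads (observed through optional intron-inclusion
fragments, whose intron is a pseudo-segment excluded from the signature
index space), and containing no splicing with nonzero count.

The refine phase ingests a 9-column spliced-aligner junction file
(records filtered at $\ge 3$ unique reads and $\ge 10$ nt overhang by
default — conventional junction-confidence filters, configurable). Sites
interior to a subexon split it; indices are renumbered and existing counts
are rewritten through the old→new remap, expanding a split index to all its
successors, which conserves totals. Fragments are rebuilt only for affected
genes, with discovered junctions as additional spliced edges, and the
previously unmapped reads are requantified; merging is additive.

## The synthetic-data generator

`makeFixture` emulates a desk-scale sequencing study: random multi-exon
genes (3–8 exons of 40–120 nt, introns 40–200 nt, 1–3 isoforms per gene
derived by internal exon skipping, alternative donors/acceptors and 5'
truncation), one chromosome per gene, uniform position sampling over
transcript windows, uniform substitution errors (no indels, since the
mapper has no gapped model), and 75 nt single- or paired-end reads —
10,000 by default. Optional modes hold out a skipped-exon transcript so its
junction is only reachable by guessing (`holdOut`), or hide a novel
acceptor 15 nt inside an exon that only the refine phase can recover
(`novelSiteFrac`), with the matching junction file written alongside.
Every read carries a truth record (origin, genomic blocks, true signature,
error positions, identifiability). What the generator does *not* emulate —
realistic error profiles, expression gradients (weights default to
uniform), overlapping genes on one chromosome, intron-retention reads —
bounds what passing tests show about real libraries; the fixed demo genes
(`fig2Gene`, `fig3Gene`) pin the worked splicing-pattern and
event-taxonomy examples instead.

Verification problem sizes used by the test-suite and `scripts/acceptance.R`
are deliberate choices: exhaustive window verification over 50 single-gene
fixtures at $l \in \{8, 10, 15, 50\}$, 10,000-read libraries for truth
recovery, systematic single-substitution scans at $l = 100$, $k = 31$, and
20 fixtures for the conversion oracles — small enough to enumerate
exhaustively, large enough to exercise every rule.

## Numerical and design choices

* Coordinates are 1-based, closed, genomic-forward throughout (the
  IRanges convention); GTF and junction files need no conversion. Donor and
  acceptor positions are the exonic bases adjacent to an intron on its
  transcription 5'/3' side.
* Guessed introns shorter than 20 nt are rejected (`minIntron`), and
  guessed junctions per gene are capped at 50,000 with a warning;
  degenerate micro-introns otherwise explode the graph.
* Unspliced graph edges exist only where a single annotated exon covers the
  boundary of two abutting subexons — touching exons of *different*
  transcripts are never merged.
* Ties anywhere (fragment ordering, primary hits, bin membership) are
  broken lexicographically or by lowest index, so all outputs are
  byte-identical across runs; the implementation is single-threaded and the
  command-line `--threads` option deliberately changes nothing.
* The ES rule keys on a complete skipped exon only; requiring both splice
  sites to be used by the same comparison transcript would leave
  cross-isoform skipping events unclassifiable that the taxonomy clearly
  intends as (nonclassical) ES.
* Genes without introns have no splice sites, hence nothing to guess; they
  still produce singleton fragments and signature counts.

## Limitations

Novel exons and novel transcript ends are out of scope: discovered splice
sites are used only inside existing genes, and intergenic junction records
are reported, not assembled. Transcript abundance estimation (EM over
compatibility classes) is not implemented — signature counts are the
product, and conversions feed downstream tools. The `ap` mode implements
the documented nesting and span relaxation only. At most one hidden novel
site per fixture is simulated, and paired-end signatures are counted but
not used to constrain mapping.
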