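---
title: "Gene-space assembly and copy-number estimation in polyploid genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-space assembly and copy-number estimation in polyploid genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polygenespace)
```

# The problem

An allo-hexaploid genome such as bread wheat carries three homeologous
copies of most genes, diverged by only a few percent in coding
sequence, embedded in a genome that is mostly repetitive. Shotgun
survey reads cannot be assembled genome-wide, and a naive assembly
either collapses homeologs into chimeric consensus sequences or
fragments them. `polygenespace` sidesteps whole-genome assembly: reads
are partitioned into small per-gene bins anchored on orthologous group
representative (OGR) proteins from related diploid reference genomes,
each bin is assembled under a stringent minimum overlap identity, and
the gene copy number is read off the coverage structure of the
resulting sub-assemblies along the template protein.

# The copy-number model

For one OGR of length $L$ amino acids, let $S$ be the set of
sub-assemblies (contigs $\ge$ 100 bp and singleton reads) whose
spliced, chained translated alignment to the template survives the
binning filters ($\ge$ 30 aa per HSP, per-species identity minimum).
The hit-count profile is

$$ n(i) = \#\{ s \in S : \text{chain of } s \text{ covers position } i \},
   \qquad i = 1 \dots L , $$

each sub-assembly counting at most once per position. Over the covered
positions $P = \{ i : n(i) \ge 1 \}$ the cumulative coverage
distribution is $F(h) = |\{ i \in P : n(i) \ge h \}| / |P|$, which
starts at $F(1) = 1$ and is non-increasing. The copy-number call is

$$ \hat c = \max \{ h : F(h) \ge C \} , $$

with $C \in (0, 1]$ the minimum fraction of the covered template that
every counted copy must span (default $C = 0.9$; uncovered templates
report 0, covered ones always report $\ge 1$). The estimate is
non-increasing in $C$ and non-decreasing in the assembly stringency
*mi*: both monotonicities are property-tested.

The logic of the surrounding pipeline is that $n(i)$ approximates the
local number of distinguishable gene copies: if homeolog copies
assemble separately, each contributes one sub-assembly across most of
the template; if they collapse, they contribute one jointly; if
sequencing errors fragment one copy into several overlapping
sub-assemblies, the inflation is local and is filtered by the $C$
fraction unless it is pervasive.

# The mi parameter and consensus-gated merging

*mi* (minimum overlap identity, percent) is the single most important
dial. Reads differing by sequencing error alone (0.5% per read, so
about 1% between two raw reads) must merge; homeolog copies (about 2%
apart in coding sequence at the simulated SNV rates) must not. The
workable window is narrow, and the calibration experiments below exist
to locate it (mi = 99 for these error/divergence levels).

The assembler is greedy best-overlap-first over a banded ends-free
overlap graph (candidate pairs and diagonals proposed by shared
canonical 16-mers; identity counted over aligned columns including
indel columns; tie-breaks: longer overlap, then higher identity, then
lexicographic read-id pair — fully deterministic). Three details
matter and were genuinely open design choices:

* **Merges are gated on consensus identity, not raw read identity.**
  An edge proposes a merge; the merge is accepted only if the two
  layout *consensi* agree at $\ge$ mi over the full overlap their
  placement implies. A raw-read gate at mi = 99 would permanently
  exclude the upper Poisson tail of reads (a 400 bp read with 4
  errors can never show 99% to anything), while the consensus of a
  layout has errors voted out. Candidate edges are therefore admitted
  down to mi − 3 raw identity and retried to a fixpoint, so a read
  rejected while both sides were raw singletons can join once a clean
  layout exists. Conversely a single clean 40 bp overlap between two
  homeolog layouts cannot glue them: the gate sees the full implied
  overlap, where the divergence is visible.
* **Leftover singletons are absorbed, not recounted.** After layout
  construction, a singleton aligning to an existing multi-read layout
  at $\ge$ mi − 5 joins it as a member. This is the complement of the
  outlier-exclusion rule (reads below mi − 5 against their own layout
  consensus are excluded and reported with the ultra-short and
  over-represented reads). Absorption never merges two layouts and
  never creates a contig, so it cannot change contig counts — it only
  stops high-error reads from masquerading as extra gene copies.
* **Excluded-read categories are operational definitions**: ultra-short
  (< 50 bp), over-represented (median canonical-k-mer depth above 10×
  the bin median — a repeat signature), and containment outliers
  (< mi − 5 to their layout consensus).

An exhaustive merge-order oracle (memoised search over every order of
edge application under the same acceptance contract) verifies on
hundreds of random small bins that the greedy order reproduces the
enumeration exactly wherever the outcome is order-invariant — the
overwhelming majority of bins — and always produces a layout reachable
by some valid order. Because merges are gated on consensi, the outcome
is not perfectly confluent: on bins containing an overlap sitting
exactly at the mi boundary, different merge orders can legitimately
end in different (all valid) layouts, and the greedy tie-breaks pick
one deterministically.

# Simulators: what they emulate, and what they do not

All generators are byte-deterministic under a seed.

* `generate_gene_space()` builds genes with UTRs (5′ 50–150 bp,
  3′ 100–250 bp), 0–3 introns of 80–300 bp with GT..AG ends, proteins
  of 120–300 aa back-translated through random synonymous codons, and
  gene families whose extra copies diverge by 3% per coding base
  (ORF-preserving) and 6% elsewhere — values chosen once as typical of
  recently duplicated cereal paralogs. Intergenic spacers carry exact
  copies of an emitted repeat library filling a configurable fraction
  of intergenic space.
* `simulate_reads()` draws 454-like reads: lengths Normal(400, 100)
  truncated at [50, template] (the read-length distribution was an
  open choice; this matches typical 454 FLX output), both strands,
  per-base substitution at the configured uniform rate (0.5% default),
  total bases within 2% of the requested coverage. Homopolymer indels
  — the signature 454 error mode — are deliberately *not* modeled; the
  error model is substitution-only. Read ids carry provenance for
  truth tracking; no package function reads it (tests only).
* `make_polyploid_catalogue()` replicates each transcript
  `ploidy_factor` times (default 3) and substitutes every coding base
  with probability 0.01 and every non-coding base with probability
  0.04, uniformly over the three alternatives, stops included — the
  replication protocol of the polyploid calibration. Truth counting
  collapses copies at the assembler's mi level first
  (`collapse_redundancy()`, greedy longest-first global-identity
  clustering), so copies an assembler could never separate are not
  counted as distinct truth; at these rates the collapse is almost
  always a no-op.

Passing calibrations on these simulations therefore demonstrate
recovery under substitution-type divergence and error with uniform
coverage. They do not demonstrate robustness to homopolymer indels,
coverage biases, chimeric reads, or repeat families inside genes —
real-data effects outside the generator's scope.

# Calibration experiments

* **Diploid WGS** (`calibrate_diploid()`): 200 genes, 20% of the gene
  space in two-copy families at 3% coding divergence, 40% of the
  intergenic space repeat-filled; 5× reads at 0.5% error; repeat
  filter, binning to one OGR per family, assembly at mi = 99,
  estimation at C = 0.9. Expected modal estimated:true ratio 1.
* **Polyploid catalogue** (`calibrate_polyploid()`): 200 transcripts
  triplicated with the stated SNV rates, 5× reads, same pipeline.
  Expected modal ratio 3 against the pre-replication count, with the
  directional behaviour at the flanks: mi = 97 collapses copies
  (smaller median estimate) and mi = 100 inflates them.

At 5× coverage a genuine failure mode remains visible: a single copy
whose reads happen to leave more than 10% of the covered template
unspanned drops the call by one (the C fraction is doing exactly its
job on thin data). This produces a 2-heavy shoulder next to the modal
3 in the polyploid run; raising coverage sharpens the mode but 5× is
the study condition.

# Numerical and algorithmic choices

* Alignment kernels (Rcpp): linear gap penalties (BLOSUM62 with gap 8
  for protein/translated alignment; +1/−2 with gap 3 and neutral N for
  nucleotide; gap 2 for global identity in redundancy collapsing).
  Percent identity is matches over aligned columns, gap columns
  counting against, ×100. Coordinates are 0-based half-open
  internally, 1-based inclusive on disk; the converters are inverse
  bijections (property-tested).
* Thresholds are inclusive (“minimum of 30 aa” keeps 30; identity at
  the threshold passes), with a 1e-9 guard against floating-point
  droop.
* Translated binning seeds candidate OGRs with shared amino-acid
  5-mers (≥ 2 shared, top 4 candidates) before Smith–Waterman; frames
  are broken at stop codons, no read-through.
* First-best-hit ties: score, then alignment length, then
  lexicographic subject id. Marker anchoring requires bidirectional
  best hits; non-reciprocal pairs stay unanchored.
* HSP chaining maximises summed HSP score subject to template
  co-linearity with ≤ 5 aa overlap and query co-linearity with ≤ 15 nt
  overlap, same strand throughout; gaps between chained HSPs are
  unconstrained (introns may be long). Verified against brute-force
  subset enumeration on toy HSP sets.
* MCL: self-loops of weight 1, column normalisation, expansion then
  inflation (default 1.5) to a 1e-8 fixpoint, pruning below 1e-12;
  clusters read off by attractor (column argmax). Edge weights are
  local-alignment scores normalised by the self-score of the shorter
  sequence, edge cutoff 0.3 — the inflation default follows the
  clustering tool convention, the cutoff was chosen once against
  shuffled-sequence nulls.
* Zipper: the identity threshold defaults to 75% for the top-ranked
  (evolutionarily closest) reference and 70% for the remaining ranks,
  both configurable per reference. Synteny windows default to 5 genes
  with ≥ 3 hit, fixed once as a density that tolerates one or two
  missed genes without bridging unrelated regions. Inverted marker
  intervals keep genetic-map order, insert the reference genes in
  reverse, and set an `inverted` flag.
* Sub-genome features: 6 columns (best-hit percent identity +
  normalised score per progenitor set), nucleotide-level alignment;
  the classifier is an RBF SVM with probability estimates and a
  rejection threshold of 0.6 by default (comfortably above the 1/3
  that a three-way tie produces, below what a confidently separated
  sequence reaches), with logistic regression, naive Bayes and a
  decision tree available for comparison by macro F1.
* Degenerate inputs: empty bins, all-zero profiles, empty marker maps
  and hitless markers all return typed empty results; C outside
  (0, 1], k-fold k exceeding the smallest class, missing coding
  annotation and unknown species keys are errors.

# Problem sizes

The test suite runs the module checks on toy constructions (seconds)
and the end-to-end checks at desk scale chosen by this package:
calibrations at 200 genes, mi-monotonicity at 25 genes on one fixed
binned read set, the assembler oracle on 500 random bins of 3–8 reads
drawn from 750 bp templates, the zipper on 60 genes with a 20-marker
map, and the classifier on triplicated pools of 60 genes. The
acceptance script re-runs both calibrations at 200 genes from a single
seed.

# Known limitations

* The assembler is a per-bin OLC with substitution-oriented banded
  overlaps; it is not a general-purpose assembler (no scaffolding, no
  flowgram model, indel-dense data will degrade the banded overlap
  detection).
* Copy-number calls saturate at the local sub-assembly count: very
  large gene families with copies below the mi separation threshold
  are undercounted — intrinsic to the identity-threshold approach.
* The similarity search is seeded Smith–Waterman, adequate for
  desk-scale reference sets; it does not attempt heuristic database
  search performance.
* Reference ranking in the zipper is user-supplied; evolutionary
  distances are not estimated.
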