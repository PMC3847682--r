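# polygenespace

Gene-space assembly and copy-number estimation for large, repeat-rich
(allo)polyploid genomes from shotgun survey reads — without a contiguous
genome assembly.

Large cereal genomes (bread wheat, barley) resist whole-genome assembly:
they are mostly repeats, and in an allo-hexaploid like wheat each gene is
present as up to three highly similar homeologous copies that short-read
assemblers either collapse or shatter. `polygenespace` implements a
gene-centric alternative for researchers working on such genomes:

1. **Ortholog-anchored binning.** A set of orthologous group
   representative (OGR) proteins is built from related, finished
   reference genomes (similarity graph + Markov clustering,
   `all_vs_all_protein_similarity()` / `markov_cluster()` /
   `select_ogr()`). Repeat-filtered shotgun reads are allocated to OGRs
   by six-frame translated alignment (first-best hit, ≥ 30 aa,
   per-species identity thresholds) — `mask_repeats()`, `bin_reads()`.
2. **Stringent per-bin sub-assembly.** Each read bin is assembled
   independently by a greedy overlap-layout-consensus assembler whose
   central dial is the minimum overlap identity *mi*: too low and
   homeologs collapse, too high and sequencing errors inflate copies —
   `assemble_bin()`, `assembly_sweep()`. The sub-assembly set is the
   contigs (≥ 100 bp) plus unmerged singleton reads.
3. **Copy-number estimation.** Sub-assemblies are re-aligned to their
   template protein with spliced (intron-aware) HSP chaining, turned
   into a position-specific hit-count profile
   `n(i) = #{distinct sub-assemblies covering amino acid i}`, and the
   copy number is called from the cumulative coverage distribution as

   ```
   copy number = max { h : |{i covered : n(i) >= h}| / |{i covered}| >= C }
   ```

   with C the minimum covered-template fraction (default 0.9) —
   `spliced_realign()`, `build_profile()`, `estimate_copy_number()`.
4. **Calibration by simulation.** Two seeded simulators reproduce the
   experiments used to pick *mi*: a diploid whole-genome shotgun run
   over a synthetic repeat-containing gene space
   (`calibrate_diploid()`) and an in-silico polyploid catalogue in
   which every transcript is triplicated and mutated at p = 0.01 per
   coding and p = 0.04 per non-coding base before 5× read simulation at
   0.5% uniform error (`calibrate_polyploid()`). At mi = 99 the first
   recovers family sizes 1:1 and the second the 1:3 replication.
5. **Sub-genome classification.** Sub-assemblies are classified into
   A/B/D-like sub-genomes from best-hit similarities to three
   progenitor sequence sets with a probability-calibrated SVM and a
   rejection threshold for sequences matching all progenitors equally
   well — `extract_features()`, `train_and_validate()`, `classify()`.
6. **GenomeZipper.** A virtual linear gene order for a chromosome is
   built by integrating a genetic marker backbone (bidirectional best
   hits), synteny blocks detected against ranked reference genomes
   (sliding-window density of translated first-best hits), and NGS
   sequences anchored by first-best hits — `detect_synteny()`,
   `anchor_markers()`, `build_zipper()`, `genome_zipper()`.

## Worked example

Two homeologous copies of one gene (~2% coding divergence), 5× reads at
0.5% error, binned to the family's OGR protein and assembled at
mi = 99:

```r
library(polygenespace)
gs <- generate_gene_space(2, family_sizes = 2L, seed = 7)
reads <- simulate_reads(seq_records(gs$genes$gene_id, gs$genes$seq),
                        sim_config(coverage = 5, error_rate = 0.005, seed = 7))
ogr <- seq_records(gs$genes$gene_id[1], gs$genes$protein[1])
pipe <- run_gene_pipeline(reads, ogr,
                         binning_config(repeat_filter = FALSE),
                         assembly_config(mi = 99), C = 0.9)
pipe$assembly_stats
#>                     bin n_assembled n_singleton n_excluded n_contigs
#> gene0001_c1 gene0001_c1          23           0          0         2
pipe$copy_numbers
#>        ogr_id copy_number covered_fraction max_hit_count n_subassemblies
#> 1 gene0001_c1           2        0.9565217             2               2
```

All 23 binned reads assemble into exactly two contigs — one per
homeolog — and the hit-count profile calls copy number 2: at least 90%
of the covered template positions are covered by 2 distinct
sub-assemblies (`covered_fraction` is the covered share of the
template). At mi = 97 the same reads collapse into one contig and the
call drops to 1.

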