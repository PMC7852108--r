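---
title: "Detecting viral contigs and proviruses with group-specific classifiers"
author: "viroscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting viral contigs and proviruses with group-specific classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Viral sequences in metagenomic assemblies lack universal marker genes, and
no single statistical profile covers the virosphere: tailed dsDNA phages,
giant eukaryotic viruses (NCLDV), RNA viruses, ssDNA viruses and virophages
differ radically in genome size, gene density and gene content. viroscan
therefore trains **one random-forest classifier per viral group** rather
than a single virus-vs-host model. Each classifier consumes the same
27-dimensional summary of a gene interval and returns a "viralness"
probability for its group; a contig is handled by whichever classifiers
find it convincing.

The 27 features (see `feature_names()`) are computed from gene calls and
profile-search annotations only — no k-mer or codon statistics:

* **hallmark gene count** — genes whose best profile hit is diagnostic of
  the group (capsid proteins, terminase, RdRP, ...); the only
  group-specific feature;
* **six annotation-category percentages** — viral, archaeal, bacterial,
  eukaryotic, mixed (families shared by viruses and cells), and unaligned
  (no retained hit). Viral regions are rich in viral and unaligned genes;
  cellular regions in cellular and mixed genes;
* **gene architecture** — average gene size, same-strand overlap
  frequency, gene density (genes per kb over the region span), and strand
  switching frequency. Phage genomes are dense, co-oriented and overlap-
  prone; cellular genomes switch strand far more often;
* **start-codon usage** (percent ATG, GTG, TTG) and **GC statistics**
  (mean and population SD of per-gene GC);
* **eleven RBS-motif bin percentages** — Shine–Dalgarno variants,
  `TATATA_3-6`, A/T-rich patterns, `Other`, and `None`. Many viral genes
  carry no detectable ribosome-binding motif, while most bacterial genes
  carry a canonical Shine–Dalgarno motif, making this block highly
  informative.

Per-gene categories come from a profile-hit table: hits below a bit score
of 30 are discarded (inclusive cutoff: a hit at exactly 30 is retained);
the single best retained hit sets the gene's category, with score ties
broken by a fixed category priority (viral > archaeal > bacterial >
eukaryotic > mixed) and then profile id, so results never depend on input
order. The profile-search engine itself is pluggable: the pipeline
consumes a precomputed tabular hit file plus a catalog mapping profile ids
to categories and hallmark flags.

## Training

`build_training_sets()` follows a fragment-based protocol. Genomes — not
fragments — are split 9:1 into training and test so that no genome leaks
across the split. From each genome, five fragments are drawn starting at a
uniform random position with length uniform between 1 kb and the distance
to the 3' end; each fragment is snapped to the genes whose midpoints fall
inside it (re-calling genes per fragment would drag a gene caller into the
training loop; midpoint snapping is deterministic and equivalent at the
feature level). The three negative sources (prokaryotes, eukaryotes,
plasmids) are subsampled to equal fragment counts, and per group the viral
and negative classes are balanced to the smaller size.

Features are min-max scaled with statistics fitted on the training rows
only; scaled values are deliberately **not clipped** at prediction time —
forests are insensitive to monotone range excess and clipping would hide
covariate shift. Constant features scale to 0.

`train_group_classifier()` selects hyperparameters by 5-fold
cross-validated grid search over a 10-cell grid: tree counts
{20, 50, 100, 150, 200} crossed with two split rules. The split-rule pair
is gini impurity and extremely randomized ("extratrees") splits; no R
random-forest implementation offers an information-gain (entropy)
criterion, and extratrees is the natural second rule in `ranger`, which we
use for its probability forests, per-fit seeds and single-thread
determinism. Ties in CV accuracy resolve to the earlier grid cell (fewer
trees, gini first). The winning pair is refitted on the full training
table and stored together with the scaler, the feature order and the
training metadata.

Each model also carries a sliding-window width: **the minimal genome size
observed among its training genomes**. Giant viruses never occupy 3 kb
windows and RNA viruses never need 100 kb ones, so the window is a
group property learned from the data. `default_group_specs()` retains
static fall-back widths for use without training data.

## Detection

`classify_contig()` applies all included models to the full contig.

1. **Fully viral contigs.** If any model's score reaches the cutoff
   (default 0.5, inclusive — significance is `score >= cutoff`
   everywhere), the contig is treated as (near-)entirely viral. To shave
   residual host edges, all trims of 0..t genes from either end are
   rescored, where `t = max(5, ceiling(0.1 n))`; the full Cartesian
   product of 5'/3' trims is searched (at most `(t+1)^2` cheap candidate
   scorings) and the best candidate is kept, flagged `trimmed` only if it
   strictly beats the untrimmed score. The 10% rule uses `ceiling`.
2. **Proviruses.** If no full-sequence score is significant, each model
   slides its window — the shortest gene run spanning at least the model's
   window width — one gene at a time from the 5' edge. The first
   significant window is extended gene-by-gene in 3' while the score stays
   significant; the maximal extension is emitted as a `partial`
   prediction and scanning resumes after its 3' end, so one contig can
   yield several proviruses but never overlapping ones from one model.
   Trimming is not applied to partials.
3. **Cross-classifier resolution.** Predictions from different models that
   overlap by at least one bp are clustered transitively; each cluster
   keeps its longest prediction (ties: higher score, then a fixed group
   order). The final set is pairwise non-overlapping.

Contigs with no genes are never fed to a classifier: they score 0 for
every group and produce a defined all-zero score record.

Outputs follow the conventional trio: a FASTA of predicted viral
(sub)sequences with coordinate-suffixed ids, a per-contig score table (all
per-group scores, the maximum and its group, length, hallmark count and
viral/cellular gene percentages of the winning region — "cellular" sums
the archaeal, bacterial and eukaryotic percentages, excluding mixed and
unaligned), and a boundary table. A cached annotation table is written
alongside so `rerun_detection()` can regenerate outputs under a different
cutoff or group subset without re-parsing gene calls or hits.

## The synthetic-data generator

Because the real profile databases and reference genome collections are
far beyond desk scale, the package ships a seeded generator
(`simulate_contig()`, `simulate_provirus()`, `simulate_benchmark()`) that
emulates the *statistical* structure detection relies on: per-group gene
lengths, gene density, strand switching and overlap probabilities,
annotation-category distributions, hallmark rates, start-codon and
RBS-bin usage, GC, and hit bit scores (truncated normal at the retention
cutoff, plus a 5% rate of spurious sub-cutoff hits so the bit-score
filter is exercised). Three presets ship as editable YAML: `easy`
(well-separated viral and host statistics), `hard` (overlapping
distributions), and `provirus`. Preset values reproduce the qualitative
contrasts of real data — viral: many viral-annotated and unaligned genes,
few strand switches, mostly motif-less RBS; cellular: many
cellular-annotated genes, frequent switching, Shine–Dalgarno-rich — but
are this package's own choices, not measurements.

What the generator does **not** emulate: codon structure and any
nucleotide-composition signal (sequence is produced only so FASTA/GFF
round trips are honest), assembly artifacts, chimeras, annotation noise
beyond the category distributions, or genuinely novel viral groups absent
from training. Passing tests on synthetic data therefore demonstrate that
the machinery is correct and that the method separates classes *whose
differences resemble the presets*; they do not certify real-data accuracy.

## Problem sizes and numerical choices

Benchmarks in the test suite and acceptance script use 50 genomes per
viral group and per negative source for training (splitting 9:1, five
fragments each, ~450 balanced training rows per group; ~15 s to train all
five classifiers on one core) and 5 replicate benchmark sets of 50 viral
plus 50 non-viral fragments at 5, 10 and 20 kb. Fifty genomes was chosen
as the smallest collection at which benchmark false-positive rates
stabilized; training-set size trades directly against runtime.

Numerical conventions, fixed for reproducibility: strand-switch and
overlap frequencies use the `n - 1` adjacent pairs as denominator (single
gene: 0); gene overlap means same-strand neighbors with the next start at
or before the previous end; `gc_sd` is the population (ddof 0) standard
deviation; percent features live on the 0–100 scale before scaling; all
cutoff comparisons are inclusive; simulation and training accept integer
seeds and `ranger` runs single-threaded so identical seeds give
byte-identical output tables.

## Known limitations

* **Provirus boundary precision.** Sliding-window detection reliably
  *finds* integrated proviruses (in the 20-provirus recovery experiment
  every provirus is recovered at well over the 50% rule) but boundary
  placement is coarse. Classifiers trained on pure viral versus pure host
  fragments put their decision surface midway between the classes, so a
  region that is mostly viral keeps scoring above 0.5 while host genes
  are appended: the 3' extension overshoots, and the first significant
  window fires before the true 5' edge — errors of ten or more genes are
  routine. Gene-exact boundaries would need boundary-aware training
  (mixed-composition fragments) or a post-hoc change-point refinement,
  both outside the present scan design. Downstream users should treat
  partial-prediction boundaries as approximate.
* **Thin sliding windows on cellular contigs** are the dominant
  false-positive source: 2–4-gene windows on eukaryote and plasmid
  fragments occasionally mimic small-genome viral groups (RNA, ssDNA),
  and false positives therefore grow with contig length. This mirrors the
  behavior of gene-content approaches on real data; restricting
  `include_groups` to the groups of interest suppresses most of it. In
  the shipped benchmark this makes the 20 kb cells marginal: the minimum
  F1 over (length, replicate) cells fluctuates around 0.8 with the seed
  (roughly 0.76–0.84 in our runs), while 5 and 10 kb cells sit safely at
  0.88–0.98.
* Short contigs (under ~3 kb) carry few genes, so every feature is
  noisy; accuracy degrades accordingly.
* Forest probabilities are used raw; no calibration is attempted, so the
  0.5 cutoff is a ranking convention, not a calibrated posterior.
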