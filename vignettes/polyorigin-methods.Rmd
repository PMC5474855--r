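---
title: "Subgenome classification of an allotetraploid assembly: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome classification of an allotetraploid assembly: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyorigin)
```

## The problem

An allotetraploid such as cultivated tobacco carries two complete diploid
genomes, inherited from a maternal donor (the S genome) and a paternal donor
(the T genome). Because both progenitor species still exist, their reads can
be mapped onto the tetraploid assembly: sequence that only maternal reads
reach is S-subgenome, sequence only paternal reads reach is T-subgenome,
sequence reached by both is *collapsed* (either a genuine assembly collapse
of near-identical homeologs or the loss of one parental copy, leaving a
single surviving locus that attracts both read sets), and sequence reached
by neither is *unmapped* (diverged beyond the mapper's mismatch tolerance,
or introgressed from a third species during breeding).

`polyorigin` implements that classification and the computations downstream
of it. This vignette explains the models, the tunable parameters, and the
design decisions where the procedure was genuinely open.

## Read mapping model

Classification inherits its resolution from the mapping rule: reads are
aligned end-to-end and kept only when they place with **at most 5
mismatches** (`max_mismatches`). With 100 bp reads this tolerates up to 5%
local divergence; homeologous sequence at the typical 8% divergence between
the S and T genomes is therefore invisible to the other ancestor's reads,
which is exactly what makes the partition informative.

The built-in mapper (`map_reads()`) is a k-mer seed-and-extend search:
non-overlapping seeds of length `floor(read_length / (max_mismatches + 1))`
guarantee, by the pigeonhole principle, that every placement within the
mismatch budget is anchored by at least one exact seed; candidates are then
verified by full-length Hamming comparison on both strands. A read with
several equally good placements — common inside collapsed regions, where
both homeologous copies are nearly identical — is reported at a single
locus chosen uniformly under a fixed seed, emulating the single-best-hit
behaviour of production mappers while staying exactly reproducible. The
mapper is substitution-only by construction; the simulator's divergence
model is substitution-only for the same reason, so the mapper is exact and
can be validated against an all-position Hamming scan (the test suite does
this with an independent Biostrings-based oracle).

## Base, scaffold and gene classification

A base counts as *mapped* by an ancestor when its depth is at least
`min_depth` (default 1). No published depth cutoff exists for this rule; the
default reads "covered by at least one read" literally and the parameter is
exposed. Per base: both ancestors mapped ⇒ `COLLAPSED`, neither ⇒
`UNMAPPED`, otherwise the mapping ancestor's label. Class fractions are
reported over all assembly bases (assembly Ns count in the denominator;
restricting to defined bases is a one-line filter upstream).

A scaffold is assigned to an ancestor when that ancestor maps **more than
50%** of its bases and the other **less than 10%** (both strict).

Gene calls use the gene span (exon-only measurement is available via
`gene_call_params(window = "exon")`) and apply, in fixed precedence:

1. **Assigned** (`S`/`T`): covered fraction ≥ 0.5 by one ancestor *and* its
   mean depth at least double the other's. "Coverage depth" is read as the
   mean per-base depth over the span — the most literal arithmetic reading;
   median is not used because at 10× coverage the mean is stabler over
   1–2 kb spans.
2. **Putative** (`PUTATIVE_S`/`PUTATIVE_T`): higher covered fraction and a
   mean-depth difference of at least 10 reads.
3. **Collapsed**: both covered fractions ≥ 0.5.
4. **Unmapped**: both covered fractions < 0.1.
5. Anything left is **collapsed**.

The precedence order (assigned > putative > collapsed > unmapped) is implied
but not dictated by the verbal rules; it is fixed here so every gene gets
exactly one call, and the evidence (covered fractions, mean depths) is
returned alongside.

## Rescuing collapsed genes from diagnostic polymorphisms

When one parental gene copy has been lost, the surviving copy shows
balanced coverage from both ancestors — but the *sequence* of the survivor
still betrays its parent. A position is a **diagnostic site** when each
ancestor's pileup reaches `site_min_depth = 5`, at least `site_purity = 0.9`
of each pileup agrees on one allele, and the two consensus alleles differ.
A collapsed gene is putatively assigned to the ancestor whose allele the
assembly consensus matches at `majority_fraction = 0.8` of its in-gene
sites, with at least `min_sites = 3` matches.

These four thresholds are not published anywhere; they were chosen once for
robustness at 10× per-ancestor depth (depth 5 keeps binomial sampling noise
in the pileup consensus below the purity bar; three sites at 80% majority
make a wrong rescue require at least three coincident errors) and are all
exposed as arguments. A consequence worth knowing: a collapsed gene that
happens to carry fewer than three polymorphisms between the parents cannot
be rescued and stays `COLLAPSED`. At the simulator's collapsed-region
divergence (0.005/site over a 1,250 bp gene span, ~6 sites expected) a few
percent of loss genes fall under that floor in any given run — visible as
occasional sub-100% rescue rates.

## The enrichment test

Whether a class (say, unmapped sequence) avoids or seeks gene space is
tested with a chi-squared goodness-of-fit: observed category counts against
expected counts `E = N × fraction` from the genome-wide composition,
`X² = Σ(O−E)²/E`, `df = k − 1`, upper-tail p-value, no continuity
correction (counts here are genomic base tallies, far from the small-sample
regime where Yates' correction matters). Categories with `E = 0` are
refused with advice to merge categories. `genic_overlap()` produces the
exon/intron/non-genic partition feeding it, via interval arithmetic
(IRanges) with exon taking precedence over intron and overlapping genes
resolved by union.

## The synthetic allotetraploid

The simulator is first-class, tested code; its defaults *are* the study
conditions used throughout the test suite and the acceptance script:

| parameter | default | what it emulates |
|---|---|---|
| `n_scaffolds_per_ancestor` × `scaffold_length` | 2 × 200 kb | desk-scale stand-in for a multi-Gb assembly |
| `ancestor_divergence` | 0.08 | S/T homeolog divergence, safely above the 5%/read mapping tolerance |
| `collapsed_divergence` | 0.005 | near-identical homeologs inside collapsed regions, safely below it |
| `collapsed_fraction` | 0.05 | low-divergence (collapsed) segments |
| `homeolog_loss_rate` | 0.10 | genes with one parental copy deleted |
| `introgression_fraction` | 0.05 | foreign sequence mapping to neither ancestor |
| `depth`, `read_length`, `error_rate` | 10×, 100 bp, 0 | per-ancestor sequencing |
| `gene_density`, `exons_per_gene` | 0.2/kb, 4 × 200 bp exons, 150 bp introns | regular gene models |

Construction order matters and encodes three deliberate choices:

* **Homeolog-loss genes are made low-divergence before one copy is
  deleted.** A survivor at full 8% divergence would only attract its own
  parent's reads and be (correctly, but uninformatively) classified to one
  ancestor. Real collapsed-and-rescuable genes are precisely those whose
  homeologs were similar enough for the assembly to keep a single copy that
  both read sets reach; setting the span to `collapsed_divergence` before
  deletion reproduces that situation while leaving enough fixed
  polymorphisms for the rescue to act on.
* **Collapsed and introgressed segments are placed in intergenic space**, so
  every gene has an unambiguous truth origin and gene-level accuracy can be
  scored exactly.
* **Introgression replaces equal-length spans** (no coordinate shifts);
  homeolog-loss deletions do shift coordinates and are applied right-to-left
  with gene models updated.

Reads are single-end (`round(length × depth / read_length)` per sequence,
uniform positions, reverse-complemented from the minus strand): paired-end
information matters for scaffolding, which is out of scope, not for
coverage classification. There are no simulated indels, no quality scores
and no repeat families — so passing tests demonstrate correctness of the
*rules* under a clean substitution model, not robustness to the repeat
content, indel polymorphism or base-quality structure of real data.
Determinism is a contract: one seed fixes every byte of every output
(internal RNG streams are derived from `seed` at fixed offsets per stage).

What the truth-recovery numbers mean: bases within one read length of a
truth-label boundary are excluded (coverage decays linearly across any
boundary, so labels there are genuinely undecidable at read resolution),
and `INTROGRESSED` truth maps to an expected `UNMAPPED` call. Inside
collapsed regions, a base immediately adjacent to a divergent site gets
cross-ancestor coverage only from the few reads that span no divergent
site, so a small fraction of collapsed bases drops to single-ancestor
labels; with the default geometry the genome-wide recovery sits around
98–99%, comfortably above the 90% the test suite requires.

## Assembly integration

**WGP merge.** Local whole-genome-profiling contigs are aligned to the
assembly by BLAST; per contig and target the HSPs are reduced to a
collinear chain (weighted longest-increasing-subsequence over target order,
strand-aware) and scored by query-coverage. The best target must dominate
every alternative: `alt_coverage / best_coverage < 0.6`, an interpretation
of an ambiguously worded published ratio rule, logged per decision so it
can be audited (`best_ratio` column). A chain flanking an N-run with both
flanking HSPs at ≥ 95% identity fills the gap with the contig's own
sequence when the gap is < 10 bp or < 10% of the contig length; the length
rule is measured on the N-run by default (`length_measure = "gap"`), with
the replacement-sequence reading available as an option since the
measurement target is not specified anywhere. Terminal overhangs extend
sequence ends under the same rule. Competing contigs resolve by (coverage,
shortest overhang, id) — fully deterministic. One decision row is emitted
per input contig (`FILL_GAP` / `EXTEND` / `APPEND` / `REJECT`); contigs
with no accepted edit are appended to the assembly as new sequences, so no
sequence is ever discarded and the defined-base count never decreases. Of
note, the identity floor used for *target selection* defaults to 80%, below
the 95% merge floor: a near-miss match should be selected and then visibly
rejected by the identity rule, not silently fail to select a target.

**Consensus correction.** Variant records (VCF; depth from `INFO/DP`,
alternate fraction from `INFO/AF`) with depth ≥ 10 and alternate fraction
≥ 0.9 are applied — the published procedure says only "filtered on read
coverage and allele frequency", so both thresholds are explicit parameters.
SNPs substitute in place; indels (including homopolymer corrections) are
applied right-to-left per sequence so earlier coordinates stay valid.
Multi-allelic records are skipped with a warning; overlapping accepted
indels keep the first by position and log a conflict; every reference
allele is verified against the assembly before any edit.

**Pseudomolecules.** Anchored scaffolds are concatenated per linkage group
in map order, minus-orientation scaffolds reverse-complemented, unknown
orientations treated as forward (orientation is genuinely undeterminable
from a genetic map alone), joined by exactly 100 Ns. The AGP v2.1 output
uses W component lines and spacer gap lines typed `U` with gap type
"scaffold", linkage "yes", evidence "map"; `apply_agp()` reconstructs the
pseudomolecules byte-identically from the AGP plus components, which the
tests assert.

## Numerical and coordinate conventions

Coordinates are 1-based inclusive in R structures (and GFF3/SAM/VCF/AGP
output); BED and bedGraph output is 0-based half-open per those formats.
Density tracks use consecutive 50 kb windows by default (the conventional
scale for whole-genome ideogram tracks); the final partial window is
normalised by its true width rather than dropped, so constant signal stays
constant. Ties in the mapper are broken by seeded uniform choice; ties in
merge conflicts by the documented sort; pileup consensus ties at 50/50
cannot pass the 0.9 purity bar and so never produce a diagnostic site.

## Problem sizes

The test suite and `scripts/acceptance.R` run the full study condition
(2 × 200 kb per ancestor, ~80,000 mapped reads), 50 random mapper-oracle
instances (two sequences of 0.8–3 kb, 20 reads each against a brute-force
all-position scan), 50 random merge-oracle instances (up to 10 gaps and 20
contigs against exhaustive rule application), 20 random chi-squared tables
against the reference implementation, and a byte-identity determinism
re-run — a couple of minutes end to end on one CPU. These sizes were chosen
as the smallest at which every rule is exercised with non-trivial
multiplicity (160 gene copies including 8 homeolog losses, and thousands of
truth-label boundaries).

## Known limitations

* Substitution-only models throughout the simulator and mapper; indels
  enter only through VCF correction.
* The rescue procedure reconstructs an unpublished algorithm; its
  thresholds are reasonable defaults, not published values.
* Gene-space percentages and class fractions from the simulator are
  properties of the synthetic genome, not predictions of any real genome's
  values.
* The classifier structure supports two ancestors; three-way comparisons
  (e.g. against a second candidate paternal donor) would need an additional
  track and rule set.
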