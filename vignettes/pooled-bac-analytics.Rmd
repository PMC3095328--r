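---
title: "Post-assembly analytics for pooled-BAC sequencing: models and methods"
author: "bacpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-assembly analytics for pooled-BAC sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacpool)
```

## The problem

Sequencing a pool of BAC clones and assembling the mixed reads is a
cost-efficient way to obtain targeted genomic regions of a genome that
is too large or too repetitive to finish outright. The assembler,
however, returns anonymous contigs and scaffolds. Three questions then
dominate the downstream analysis, and this package answers them:

1. **Which scaffold belongs to which clone, and is it complete?**
   Evidence comes from genetic markers anchored to clones, BAC-end
   Sanger reads, and the cloning-vector sequence flanking the BamHI
   restriction site (`GGATCC`): 30 bp of vector on either side of the
   cloning site is deliberately left untrimmed, so its appearance at a
   scaffold extreme marks a BAC border.
2. **How accurate is the consensus?** Pyrosequencing miscalls
   homopolymer run lengths; comparing an assembly against a finished
   reference of the same locus yields a census of homopolymer and
   dinucleotide tandem-repeat discrepancies and a per-10-kb error rate.
3. **What does the sequence contain, and how does it compare to a
   related genome?** Gene-model statistics, microsatellite (SSR) and
   transposon censuses, and a relative microsynteny quality score.

Every stage can be exercised on synthetic data with ground truth; the
generators live in the same package and are first-class, tested code.

## Coordinate and report conventions

All internal coordinates are 1-based closed intervals, the native
convention of R and of the Bioconductor ranges infrastructure; GFF3
input and output therefore needs no coordinate shifting. BED output is
converted to 0-based half-open on write.

Report tables use two deliberate rounding conventions, chosen so that
the package's report arithmetic is internally consistent:

* assembly report means and N-fraction percentages **truncate** to the
  printed precision (`report_mean()`, `gap_stats()`), as does the TE
  percentage column (`te_percent()`);
* gene-level percentages, densities and rates **round half-up**
  (`gene_density()`, `est_support_pct()`, `discrepancy_rate()`), since
  R's own `round()` rounds half-to-even.

Full-precision values are always retained in the returned objects; only
report views truncate.

## Scaffold-to-clone assignment

`find_marker_hits()` and the BAC-end mode of `find_borders()` share a
seed-and-extend search: exact 31-mers of the query are located with
Boyer–Moore matching and extended by affine-gap alignment of the query
against a local window (match +1, mismatch −2, gap opening −4,
extension −1). Hits below 95% identity or 50 bp aligned length are
suppressed. The floors are deliberate: loose enough to tolerate the
consensus-level errors the simulator injects, tight enough to exclude
paralogous placements. The 30 bp junction search (border mode 1) scans
a 500 bp window at each scaffold extreme on both strands, allowing two
mismatches; "at their extremes" is windowed rather than anchored at
position 0 because a scaffold may retain a short untrimmed residue.

Two tie-breaks matter in pools, where clone inserts overlap:

* a BAC end marks a *border*, so among near-equal end-sequence hits the
  one nearest a scaffold extreme wins;
* when a marker has near-equal hits on several scaffolds (its locus is
  covered by more than one clone), the clone's end-sequence evidence
  arbitrates. This mirrors manual practice, where markers, end reads
  and physical-map information are weighed together.

Completeness is a total function of the evidence: `complete` with both
ends found; `likely_complete` with one end and > 100 kb of scaffold;
`partial` with one end and 60–100 kb; `fragmentary` with no end but a
marker hit; `unassigned` otherwise. Note the literal reading: one end
on a scaffold below 60 kb classifies as `unassigned` — the scaffold is
too short for its border to certify a meaningful fraction of the
insert.

`superscaffold()` joins same-clone scaffolds with one N gap per
junction sized so the result reaches the library's mean insert length,
with a floor of 100 N per junction (the common convention for a gap of
unknown size) and a warning when the floor binds.

## The discrepancy census

`align_locus()` compares two versions of the same locus. Dynamic
programming over two ~100 kb sequences is neither necessary nor
numerically stable in memory, so the aligner chains exact shared
31-mers that are unique in both sequences, emits the identical runs
directly, and aligns only the short regions between anchor runs
(Biostrings' affine-gap aligner with the scoring above; a gap of
length L costs 4 + L). Columns where either sequence carries `N` are
excluded from comparison, so assembly gaps are never counted as
errors. If no anchors exist the sequences are rejected as unrelated,
with a crude shared-11-mer identity estimate in the message. On
sequences small enough for full dynamic programming the anchored score
is identical to the unanchored optimum; the test suite asserts this
against an independent pure-R Gotoh implementation and against the
unanchored C aligner at 2 kb.

`classify_discrepancies()` walks the difference blocks:

* an indel block inside or adjacent to a maximal single-base reference
  run of length ≥ 2 is a **homopolymer** record (one per run, signed
  length change; ambiguous placement resolves leftmost);
* length changes inside or at the edge of a perfect dinucleotide
  tandem array of ≥ 6 units in the reference are one
  **dinucleotide_repeat** record per array — the 6-unit floor admits
  the long microsatellites where such slippage is observed while
  keeping incidental two-unit repeats out;
* remaining mismatches are **substitutions**, remaining indels
  **other_indel**, and each N-masked interval is an
  **n_gap_excluded** record carrying the interval.

`run_census()` joins homopolymer records to the reference run-length
distribution per base class (A/T vs C/G, runs ≥ 5 by default), and
`discrepancy_rate()` reports `10^4 × (homopolymer + dinucleotide
records) / reference length`, half-up to one decimal.

## SSR, gene and transposon censuses

`find_ssrs()` reports maximal perfect tandem arrays with unit lengths
1–6 bp whose whole-unit length reaches the class minimum: 10 bp for
mononucleotides, 12 bp for di- and trinucleotides, 16/20/24 bp for
tetra-/penta-/hexanucleotides. Only perfect arrays count; `N` breaks
arrays; a region qualifying at several unit lengths reports at the
smallest (a poly-A is a mononucleotide array, not a dinucleotide one),
and larger-unit reports overlapping an accepted array are suppressed.
Motifs are canonicalised to the lexicographically smallest rotation
over both strands, so `CT`, `TC`, `GA`, `AG` all report as `AG`.

Denominators are fixed by the report arithmetic: SSR percentage and
kb-per-SSR use the N-free length; gene density and TE percentages use
the total length including Ns.

## Microsynteny

Orthologues are paired reciprocal-best by e-value (default cut 1e-46,
the order of magnitude below which cross-species protein hits in this
setting are unambiguous), TEs excluded. Tandem arrays — maximal runs of
adjacent same-region genes with a pairwise homology hit — collapse to
one representative, preferring a member with a cross-region pair.
Blocks are maximal runs of pairs in which consecutive paired genes are
separated by at most `max_gap = 3` unpaired genes on both sides,
irrespective of orientation and local order; TE entries neither pair
nor interrupt. Reciprocal-best was chosen over one-way best because it
is the deterministic reading of "tentatively selected, then
confirmed"; the gap tolerance makes "contiguous" precise and is a
config knob. The relative syntenic quality of a block is

$$ Q = 100 \cdot \frac{c_A + c_B}{n_A + n_B} $$

with totals and conserved counts taken after TE exclusion and tandem
collapsing. `ratio_stats()` reports means of per-pair protein-length,
exon-count and mean-intron-length ratios. Pseudogenes are not modelled;
any input gene model counts as a gene.

## The synthetic-data generators

`make_genome()` draws i.i.d. sequence at the requested GC content
(default 0.33, a typical AT-rich plant composition) and simulates gene
models with geometric exon counts (mean 4.9, which also yields ~20%
intronless genes) and log-normal exon/intron lengths (means 238 and
393 bp), gene density 9.9 per 100 kb, TE fraction 8% with superfamily
labels drawn roughly in proportion to a gene-rich plant region
(Unclassified and Gypsy/Copia dominating). Random sequence is nearly
free of long homopolymers, so the generator plants ~26 runs of ≥ 11 nt
per 100 kb (A/T-biased) and ~2 long dinucleotide arrays per 100 kb —
the substrate densities at which a pyrosequencing accuracy census is
informative. Exact distribution shapes are free parameters of the
generator, not claims about any genome.

`make_bac_pool()` draws insert sizes around a 139 kb library mean
(SD 10 kb), snaps insert boundaries to an existing `GGATCC` within
200 bp or plants one (recorded), extracts 500 bp end sequences (the
right one reverse-complemented, as BAC-end reads are), and picks one
300 bp marker per clone from a window covered by no other clone when
such a window exists (warning otherwise). The default vector junctions
are fixed synthetic 30 bp stand-ins free of `GGATCC`.

`fragment_and_scaffold()` replaces disjoint internal segments with
equal-length N runs — gaps never touch the ends, so borders survive;
`inject_errors()` contracts homopolymer runs ≥ 11 nt by 1–3 bases with
probability 0.6 (matching an observed 15-of-26 contraction rate, with
shortening the dominant direction) and removes 1–3 units from long
dinucleotide arrays with probability 0.6. Runs below the threshold are
never touched, which is what makes the "no discrepancies below 11 nt"
census check meaningful. `make_synteny_pair()` expands a copy of the
genome by scaling introns (default ×1.3), inserting TEs (default 15,
~5 kb each; on a 100 kb template this lands near a 1.8× region-size
ratio), and applying point substitutions (default 0.13/site, i.e. ~87%
identity), returning the orthologue truth table.

What the generators do *not* emulate: read-level errors and coverage
(errors are injected at the consensus level), chimeric clones, cloning
bias, segmental duplication, and real repeat landscapes. Passing tests
therefore demonstrate the correctness of the analytics under the
stated error model, not performance on arbitrary real assemblies.

## Problem sizes and determinism

Every generator takes an explicit seed and restores the caller's RNG
state; identical seeds give byte-identical outputs, and
`run_pipeline()` reruns reproduce identical report files. The test
suite and the acceptance script run the recovery checks at desk scale:
pools of 12–20 clones of ~139 kb on 4–6 Mb toy genomes, accuracy
censuses on 100 kb loci, synteny on 100 kb templates — sizes chosen so
the whole battery completes in minutes while leaving each statistic
enough events to be non-trivial.

## Worked example

```{r example, eval = FALSE}
g <- make_genome(5e5, gene_density = 9.9, gc = 0.33, seed = 1)
pool <- make_bac_pool(g, n_clones = 3, insert_mean = 100000,
                      insert_sd = 8000, seed = 2)
scf <- lapply(pool$clones, function(cl)
  simulate_clone_scaffold(pool, cl$id, n_gaps = 7, seed = 3))
scf_df <- data.frame(id = vapply(scf, `[[`, "", "id"),
                     sequence = vapply(scf, `[[`, "", "sequence"))
assign_clones(scf_df, pool$clones, pool$markers, pool$junctions)
```

## Known limitations

* `align_locus()` assumes the two sequences are versions of the same
  locus; highly diverged pairs are rejected rather than aligned.
* Difference blocks that mix an N stretch with flanking non-N
  insertions are classified from their non-N columns; pathological
  arrangements could leave a stray `other_indel` at an N boundary.
* The completeness rules deliberately leave the one-end/short-scaffold
  combination `unassigned`; projects wanting a softer rule can
  post-process the evidence attached to the assignment table.
* Orientation of superscaffold parts is taken from the caller (or from
  end-hit strands upstream); conflicting evidence is not resolved
  silently — parts default to `+` and the evidence stays attached.
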