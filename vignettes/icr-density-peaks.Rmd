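---
title: "Locating candidate imprinting control regions from composite-motif density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating candidate imprinting control regions from composite-motif density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrscan)
```

## The biological problem

Imprinting Control Regions (ICRs) and germline differentially methylated
regions (gDMRs) direct parent-of-origin-specific expression of imprinted
genes. Two sequence features co-occur in many characterized ICRs: the
hexameric recognition site of ZFP57 — the KRAB zinc-finger protein that
maintains methylation imprints — and CpG-rich MLL1 morphemes. Composite
elements in which a ZFP57 site overlaps an MLL morpheme ("ZFBS-morph
overlaps") cluster in ICRs but occur only sporadically elsewhere. That
difference in local density is the signal this package exploits: genomic
intervals where two or more composite elements fall close together are
candidate ICRs, while isolated occurrences are treated as background.

`icrscan` implements the complete prediction workflow: exact-match scanning
of chromosome sequences for both motif classes, a sliding-window density
computation over the composite-motif positions, suppression of isolated
hits, tiered peak calling, and export of UCSC genome browser custom tracks.
A seeded synthetic-genome generator and a reference-panel benchmark make
the whole pipeline testable without downloading any genome.

## The density model

Let $s_1 < s_2 < \dots < s_n$ be the start coordinates (0-based) of all
composite-motif hits on one chromosome. For a window of width $W$ anchored
at position $p$, the density signal is the count

$$ d(p) = \#\{\, i : p \le s_i < p + W \,\}. $$

Two hits can appear in a common window if and only if their starts differ
by at most $W - 1$. The package therefore defines peaks through the
**co-window relation**: consecutive sorted starts are linked when
$s_{i+1} - s_i \le W - 1$, and peaks are the connected components
(single-linkage closure) of that relation. This is equivalent to marking
every window position with $d(p) \ge 2$ and merging marked windows that
share hits — the per-base formulation is used as the brute-force oracle in
the test suite — but runs in $O(n)$ on the sparse hit list rather than
$O(L)$ on the chromosome length.

Components with fewer than `min_hits` members (default 2) are discarded:
a single composite element in isolation is indistinguishable from
background and calling it would flood the output with false positives.
Each surviving component becomes one peak with footprint
$[\min_i s_i,\ \max_i e_i)$ — the member hits themselves, not the enclosing
windows, because ICR peaks align to compact CpG islands and the window
margins carry no evidence.

### Peak scores and tiers

Published density plots describe peaks by the number of overlaps they
"cover". A chained component can be wider than one window, so the package
reports two scores per peak:

* `n_hits` — the component size; used for tier assignment;
* `max_window_count` — the largest number of member starts inside any
  single $W$-base window, i.e. the maximum of $d(p)$ restricted to the
  component.

They coincide for compact clusters and differ only when a cluster chains
across more than $W$ bases; emitting both makes either reading of a
"peak covering $k$ overlaps" reproducible.

Confidence tiers follow the empirical reliability scale: peaks covering
**2** overlaps can be true or false positives (`candidate`), peaks covering
**3** are more reliable (`robust`), and `very_robust` marks anything at or
above a configurable boundary, 4 by default. The boundary must exceed 3
because "very robust" is used for clearly stronger peaks (known ICR peaks
reach 7 overlaps); it is a label threshold only and changing it never
changes which peaks exist.

## Parameters that matter

* **`window_w` = 850 bases.** The window size of the original analysis,
  selected there by trial and error: larger windows merge unrelated hits
  into false peaks, smaller windows fragment real clusters into spiky
  singletons that the isolation filter then deletes. It is a plain
  parameter (`--window` on the command line) for sensitivity analyses.
* **`min_hits` = 2.** The isolation threshold. Raising it monotonically
  removes peaks (never creates or grows one; this is a tested invariant).
* **`tier_thresholds`** = candidate 2 / robust 3 / very robust 4, the
  scale above.
* **`strands`** = `both`. Which strand the original scans used is not
  documented; the composite elements are strand-agnostic CpG-rich motifs,
  so both strands are scanned by default and `forward_only` reproduces any
  single-strand convention. A motif equal to its own reverse complement is
  reported once, on `+`.

Motif catalogs are configuration, not code: the ZFP57 hexamer ships as
`extdata/zfp57.txt` (TGCCGC), while the shipped composite-element file
`extdata/zfbs_morph_overlaps_synthetic.txt` is an explicitly synthetic
stand-in — the published composite list is not redistributed here and
users performing real analyses must supply their own transcription of it.
Every test in the package builds its own synthetic catalogs and depends on
neither file.

## Coordinates and formats

All internal coordinates are 0-based half-open; conversion happens nowhere
because BED and bedGraph use the same convention. Sequences are normalized
on input: lowercase (soft-masked) bases are uppercased and scanned
normally — there is no evidence repeat-masked regions were excluded — and
IUPAC ambiguity codes become `N`, which matches no motif, so assembly gaps
are scanned through without ever producing a hit. Exact matching uses
`Biostrings::matchPattern`; its equivalence to a naive all-substrings
oracle is asserted over randomized catalogs in the test suite.

Track output reproduces the three-track browser display: ZFP57 hits as a
`dense` BED6 track, composite-motif hits as a `pack` BED6 track, and the
peak density as a `full` bedGraph plus a BED5 peak track. bedGraph was
chosen over fixed-step wiggle because the signal is sparse and integral;
both load identically in the browser. Output bytes are deterministic:
fixed sort order, integer formatting, `\n` endings.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` produces an i.i.d. background with configurable GC
fraction, then plants compact clusters of 2–8 catalog motifs (each inside
a span no wider than `window_w` minus the longest motif) and isolated
single motifs, all separated by more than one window width. Background
positions that happen to spell a catalog motif are locally resampled until
the background is motif-free, and the planted sequence is re-scanned to
catch junction artifacts, so the returned truth table is exact: under the
default geometry, scanning plus clustering provably recovers every planted
cluster with the planted count and suppresses every isolated plant —
precision, recall and count-exactness are all 1.0 by construction, for
every seed. A `scrub = FALSE` mode keeps accidental occurrences for stress
testing.

The default configuration — 100 kb, GC 0.5, 5 clusters of 2–7 motifs in
600-base spans, 10 isolated motifs, 2,000-base separations — is the
condition used throughout the tests and the acceptance script. The sizes
keep a full multi-seed study in seconds on one core while leaving each
geometric regime (compact cluster, chained pair, isolated hit) represented
many times over.

What the generator does **not** emulate: real CpG-island composition
(clustered CpGs against a CpG-depleted genome), repeat structure,
chromosome-scale length, or the empirical spacing statistics of composite
elements in real ICRs. Perfect recovery on synthetic genomes therefore
validates the *algorithm* — linkage, suppression, counting, coordinates —
not the *biological discriminative power* of the motif catalog, which is
exactly the part the original genome-wide analyses established and which
requires real genome builds and the published catalog to reproduce.

## Benchmarking against reference panels

`evaluate_against_panel()` scores called peaks against a curated panel of
reference ICR/gDMR intervals: a locus counts as found when any peak of at
least a chosen tier overlaps it by at least 1 bp. The permissive overlap
rule is deliberate — published correspondence between peaks and ICRs was
judged visually on the genome browser, and any containment or
majority-overlap rule would be stricter than that evidence supports; the
minimum overlap is nevertheless a parameter. Panels are user-supplied
(BED4 or headered TSV): locus coordinates for specific genome builds are
not shipped. The package's tests exercise the harness with constructed
panels, including a 20-interval panel with peaks overlapping exactly 18 —
sensitivity 0.90, the analogue of the best published panel score.

## Numerical and degenerate-input choices

* Ties and determinism: hits sort by (start, end, motif id, strand with
  `+` first); identical inputs give byte-identical outputs everywhere.
* A motif longer than its chromosome yields zero hits, not an error; an
  empty catalog is an error.
* `cluster_hits()` refuses unsorted or multi-chromosome input rather than
  silently resorting, because silently accepted misordered input usually
  signals an upstream bug.
* Overlapping hits from different catalog motifs are counted separately by
  default (the original analyses kept independent position lists per motif
  file); `collapse_cofootprint_hits()` offers the one-count-per-footprint
  alternative, keeping the earliest-starting (then longest, then
  lexicographically first) hit of each overlap component.
* The generator's rejection resampling aborts with advice after 1,000
  rounds — reachable only with catalogs so dense that a motif-free
  background of the requested composition effectively does not exist.

## Known limitations

* Exact matching only: no PWM or mismatch tolerance, and no
  methylation-state modelling even though ZFP57 binds its site methylated —
  scanning is sequence-only by design.
* Peaks carry no significance estimate; the tier scale is an empirical
  reliability label, not a p-value.
* The shipped composite-motif file is a synthetic placeholder (above);
  results on real genomes are only meaningful with the published catalog.
* Single-process scanning; genome-scale runs are minutes per chromosome,
  not seconds.

## A worked example

```{r example}
morph <- motif_catalog(c("ACGCGTCG", "TCGCGACG", "GGCGCAAT"), "ZFBS_MORPH")
sim <- simulate_genome(sim_config(seed = 7), morph)
res <- icr_scan(sim$genome, zfp57 = NULL, morph = morph)
res
evaluate_recovery(res$peaks, sim$truth)
```

```{r tracks}
out <- file.path(tempdir(), "tracks")
export_bundle(res$hits, res$peaks, out)
readLines(file.path(out, "density.bedgraph"), n = 3)
```

The same workflow is available from a shell via the wrapper script in
`system.file("scripts", "icrscan", package = "icrscan")` with subcommands
`scan`, `density`, `tracks`, `simulate` and `benchmark`.
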