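---
title: "Reconstructing viral integration events from fragment coordinates"
author: "eveTrace maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing viral integration events from fragment coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eveTrace)
```

## The model

An endogenous viral element (EVE) is a germline-fixed fragment of a
viral genome. Most EVEs are old: after insertion, the viral sequence
accumulates host-neutral substitutions, is cut apart by internal
deletions (often transposon-mediated), and may be copied to nearby loci
by segmental duplication. The observable today is a set of local
alignment fragments, each with dual coordinates — an interval on the
extant related virus and an interval on the host genome — and the
inference problem is to partition those fragments into the historical
*integration events* they descend from.

`eveTrace` treats three signals as evidence that two fragments share an
event:

1. **Collinearity with matched gaps.** If a contiguous insert decayed
   in place, consecutive surviving fragments appear in the same order
   and orientation on both genomes, and the gap between them measured
   on the virus (`g_v`) nearly equals the gap measured on the host
   (`g_h`): the intervening sequence diverged past recognition but was
   not lost. Deletions break the equality only mildly, because the
   deleted host sequence is mostly the decayed viral sequence itself.
2. **Viral-interval overlap within one locus.** Two fragments at one
   genomic region that cover the *same* part of the virus cannot be
   sequential remnants; at high identity they are copies within one
   event (duplication or tandem rearrangement).
3. **Viral adjacency across loci plus piRNA orientation.** When the
   viral span of one event ends where another's begins, the two host
   regions may descend from one insertion split by a large host
   rearrangement. Because EVE-containing piRNA clusters produce piRNAs
   predominantly antisense to the EVEs, both blocks showing the
   anti-EVE bias supports the single-origin hypothesis.

The pipeline applies them in order: single-linkage merging of host
footprints into regions, chaining by gap consistency within regions,
union–find clustering by viral overlap (optionally gated on sequence
identity), duplicate flagging, and evidence-gated adjacency merging.
Each stage only coarsens the partition, so every fragment belongs to
exactly one event at every stage.

## Parameters and why they have their values

* `maxEvalue = 0.001`, query genomes >= 10 kbp, `minSupportAccessions
  = 2`: the filter cascade keeps loci hit independently by two or more
  distinct (near-complete) viral genomes. A single-accession hit in a
  repetitive genome is weak evidence; co-located hits from related
  viruses are how real EVE loci announce themselves.
* `regionMergeDist = 100 kbp`: must bridge the ~56 kbp separation of
  two curated fragments that share one region in the worked example,
  while keeping loci megabases apart distinct. Regions are the scope
  of chaining and overlap clustering; only adjacency merging may cross
  them.
* Gap rule `|g_v - g_h| <= max(300, 0.5 * max(g_v, g_h))`, both gaps
  in `(0, 5000]`: calibrated on the curated *Ae. aegypti* table, whose
  chained pairs show discrepancies of 12–243 nt, while the host-side
  distances that must *not* chain (56 kbp, 122 Mbp) are excluded by
  the 5 kbp ceiling alone.
* `minOverlap = 50` bp and `minIdentity = 94%`: the clustering
  thresholds. When no sequence is available the overlap criterion
  alone is applied, justified by the empirical bimodality of pairwise
  identities — proximal overlapping fragments sit above 94% while
  unrelated ones sit below 85% — which is what makes the worked
  example reproducible from printed coordinates.
* `dupIdentity = 99%`, `dupCoverage = 100%`: the duplicate signature.
  Coverage is rounded to the nearest percent before comparison because
  optimal local alignments shave terminally mismatched bases, so a
  biological full-length copy can align at 99.5% coverage; without
  rounding the criterion would be unsatisfiable in practice.
* `adjacencyTol = 50` nt: generous relative to the 31-nt adjacency it
  must accept, small relative to the hundreds-of-nt gaps that should
  not merge events.
* Conservation: presence = breadth >= 0.99 at depth >= 5 (the breadth
  tolerance absorbs edge effects at fragment boundaries); sample QC
  passes organelle 1x breadth >= 0.90, separating failed libraries
  (~35%) from sound ones (>96%) with margin on both sides.
* Variation: variants are counted **unfiltered** — deliberately, since
  the densities are meant to reflect raw segregating variation; apply
  quality filters upstream if wanted. Cells with 1x breadth < 85% are
  masked rather than reported, because uncovered bases cannot yield
  calls and would bias density downward. Two published phrasings of
  this mask (< 85% covered; < 25% uncovered) conflict; the 85% figure
  is the default and both are configurable.
* piRNA tracks: 500-bp windows, reads assigned by 5' coordinate,
  dominance threshold 0.8 on the aggregate forward ratio. No published
  windowing exists for this analysis; these values are stable at the
  read densities the simulator produces and are all configurable.

## The simulator, and what passing tests do not show

`simulationConfig()` defaults encode the study conditions: host GC
0.38 versus virus GC 0.49, a full-length ~11 kbp contiguous insert per
event, deletions of 200–1500 bp with gap jitter SD 50 nt, decay to 70%
identity, optional nearby duplication with 0.5% extra divergence (kept
above the 99% duplicate-recognition threshold on purpose), negative
binomial depth with mean 20, and a piRNA antisense bias of 0.8. Two
cohort presets contrast a conserved cohort (per-EVE dropout 0.02,
mirroring a core set carried by essentially all samples) with a patchy
one (dropout 0.45).

The simulator is deliberately idealized: substitution-only decay (no
indels inside fragments, so coordinate truth stays exact), hit
emission directly from truth rather than from a real aligner,
independent per-base depth, uniformly placed variants. Tests that pass
on it validate the *logic* of chaining, clustering, filtering, QC,
presence, density and strand-ratio computation — they do not show that
a real BLASTN hit table is noise-free, that real coverage is
independent across bases, or that real piRNA tracks are as clean as
the simulated ones.

Problem sizes used by the test suite are the package's own choice: the
recovery property runs 100 seeded integrations on 2-Mbp hosts with
1–6 events each; cohort properties use 600-kbp hosts, 4-kbp viruses
and 6–8 samples over 100 seeds; density unbiasedness uses 200 seeded
2-kbp regions.

## Numerical and design choices

* **Coordinates.** All inputs are 1-based inclusive; BED output is
  0-based half-open. Curated tables encode strand by printed
  coordinate order (`h_start > h_end` = minus), normalized to an
  explicit flag plus min/max at parse time. The curated *length*
  convention is the coordinate difference, not the inclusive span, and
  readers preserve printed values (with a warning) rather than
  "repairing" them; the bundled table is shipped exactly as printed
  even where its host span disagrees slightly with independently
  derived region bounds.
* **Determinism.** Union–find uses index-ordered union; events are
  numbered by (chromosome, leftmost host coordinate); all readers are
  order-stable; every stochastic routine takes a seed and restores the
  RNG state afterwards.
* **Ties and degenerate inputs.** Representative-accession ties break
  lexicographically. Empty hit files are empty tables, not errors.
  Zero-depth positions may be omitted from depth tables and are
  treated as depth 0. Windows at interval ends are truncated rather
  than dropped. A zero-density or masked baseline makes a density
  ratio an error, not an `NA`.
* **Embedding.** No t-SNE implementation ships with the installed
  dependency stack, so `embedCoverage()` carries a compact exact
  O(n^2) t-SNE (perplexity calibration by bisection, early
  exaggeration, momentum gradient descent). That is adequate for the
  tens of rows this package embeds and keeps the result deterministic
  under a seed. Exactly identical rows are embedded once and share
  coordinates, since stochastic neighbor embeddings do not otherwise
  guarantee that identical inputs coincide; the mean silhouette width
  of event labels is reported alongside the coordinates so the visual
  claim "coverage clusters by event" has a number.
* **Alignment.** Pairwise identity uses Smith–Waterman with
  megablast-like scoring (+2/−3, gap open 5, extend 2) via Biostrings;
  identity is matches over alignment columns.
* **Interface.** The package deliberately exposes R functions plus the
  one-call `runEvePipeline()` (which writes a manifest JSON capturing
  inputs, parameters, version and seed) instead of a shell entry
  point; scripted use is a two-line Rscript.

## Known limitations

* Coordinate-only clustering (no sequences) cannot distinguish a
  high-identity duplicate from an independent insertion of a close
  strain; `flagDuplicates()` reports the signature and leaves the
  interpretation to the user.
* Adjacency merging considers event pairs on a shared donor virus
  only, and its orientation gate consumes *verdicts*; computing those
  verdicts well requires adequate small-RNA coverage over both blocks.
* The filter cascade implements the two published stages (e-value,
  multi-virus support); published hit-count reductions that depended
  on additional unpublished screening stages are not reproduced, only
  the retention principle.
* Cohort-scale published figures (e.g. the fraction of samples
  carrying every EVE) require the original sequencing cohorts; the
  package reproduces the *computations* and validates them on
  simulated cohorts instead.
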