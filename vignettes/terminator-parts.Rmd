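---
title: "Terminator parts in Chlamydomonas: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminator parts in Chlamydomonas: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termpart)
```

## The problem

Nuclear transgene expression in *Chlamydomonas reinhardtii* is erratic:
integration is random, most transformants express poorly, and expression
decays over serial subcultures. Screens that compare standardized genetic
parts — here transcriptional terminators, proxied by annotated 3′ UTRs —
need three computational layers: mining the genome annotation for
candidate parts, preparing those parts for modular cloning, and analysing
the plate-based screen that measures each part's effect on transformation
efficiency, transgene stability and reporter expression. `termpart`
implements all three, plus generators that produce statistically faithful
synthetic inputs so the whole pipeline can be exercised and tested without
any external download.

## Annotation statistics

`parse_gff3()` reads generic GFF3 (gene/mRNA/CDS/UTR records linked by
`Parent`, Phytozome-style extras tolerated) through `rtracklayer` after a
light syntactic pre-check that reports the first malformed line by number.
All coordinates are 1-based inclusive throughout the package, matching the
GFF3 convention; a feature's length is `end − start + 1` summed over its
intervals, which avoids any off-by-one against the source format.

Conventions worth stating explicitly, since each was a genuine choice:

* **Representative transcript.** Default `"longest"` (largest exonic
  length; ties broken by smallest transcript id). Filtered gene-model
  annotations typically carry one transcript per gene, so the policy only
  matters for richer annotations; `"primary"` (lexicographically first id,
  the `.1` model) is available.
* **Genes without an annotated 3′ UTR** are excluded from UTR statistics
  and counted (`n_excluded`), never treated as length 0, which would drag
  medians down artificially.
* **Size classes.** Short is strictly < 100 bp, medium 100–600 bp
  inclusive at both ends, long strictly > 600 bp; the classes partition
  the positive integers, and the test suite pins the boundary cases (99,
  100, 600, 601).
* **Histograms** use half-open 100-bp bins `[i·100, (i+1)·100)` by
  default, so bin sums below 100 bp equal the short-class count exactly.
* **Median.** For even *n* the lower-middle element is reported: it is
  always an observed, integer-valued length and reproducible across
  platforms. Interpolation is a documented option.
* **Intergenic distance.** Genes are ordered by span start per chromosome,
  strand ignored; the distance between an adjacent pair is
  `downstream_start − upstream_end − 1` (bases strictly between the two
  boundaries), measured either UTR-boundary to UTR-boundary (default,
  with a documented fallback to the span for genes lacking UTR
  annotation) or span to span. Overlapping annotations give negative
  distances, which are retained — dropping them silently would bias the
  distribution, and a caller can filter reversibly.

## Expression ranking

`rank_expression()` takes the unweighted arithmetic mean of FPKM over all
supplied timepoint columns (replicate columns enter individually — there
is no hidden pre-averaging) and assigns rank 1 to the highest mean. Tied
means receive the minimum rank of their block: the conservative choice for
downstream rank filtering, since a tie at the cutoff admits all members
rather than an arbitrary subset. "Among the top *k*" is therefore
`rank ≤ k`. `rank_filter()` additionally accepts explicit exceptions for
genes kept on biological grounds despite poor rank under the assay
conditions — the motivating case being a nitrate-reductase terminator from
a gene ranked in the tens of thousands in ammonium-grown cultures but
strongly induced under nitrogen depletion.

## Part engineering

**Motif scanning is sense-strand only.** Polyadenylation signals act on
the transcript, so the extracted, strand-oriented part (minus-strand genes
reverse-complemented) is scanned for `TGTAA`, the DNA form of UGUAA. All
overlapping occurrences are reported at 1-based positions.

**Selection rules** (`select_candidates()`): the source gene passes the
rank filter, its annotated 3′ UTR is at most `max_len` (default 1000 bp —
longer parts complicate modular cloning), and the extracted sequence
carries at least one motif. An `extend_3prime` option appends genomic
sequence past the annotated UTR end, for parts historically cloned longer
than the gene model.

**Domestication** (`domesticate()`) removes BsaI (`GGTCTC`) and BpiI
(`GAAGAC`) recognition sites on both strands. Each site is fixed by a
single substitution at the leftmost footprint position not covered by a
protected interval (all motif occurrences are protected by default),
preferring a transversion; an edit is accepted only if it destroys the
site without creating a new site of any configured enzyme, re-checked
after every edit. Terminators are non-coding, so no codon constraint
applies; synonymous-only CDS domestication is deliberately out of scope.
The procedure is idempotent and the mutation log records every edit.

**Assembly simulation** (`simulate_assembly()`) checks the 4-nt fusion
site chain (consecutive parts share an overhang; the chain closes through
the backbone) and rejects any overhang used at two junctions, which would
make a one-pot ligation ambiguous. Fusion sites are part of the input
parts and never hard-coded — published kits differ, so defaults must be
overridable. Each shared overhang is counted once in the circular product,
and `digest_assembly()` inverts the construction exactly, which the test
suite uses as a round-trip property.

**Linearization** (`linearization_flank()`) treats the plasmid as
circular (positions modulo length, sites spanning the origin found once).
If the enzyme cuts uniquely outside the cassette, the flank is the shorter
circular arc from the cut to the nearest cassette boundary — the vector
DNA protecting that cassette end during electroporation-mediated
integration. Multiple sites or in-cassette cuts are flagged rather than
thrown, since both are ordinary screening outcomes for candidate enzymes.

## Screen analytics

The screen's unit of observation is one transformant line in a microtitre
plate, followed over subculture rounds (default 3) under selection, with
a GFP call on the lines still viable at the end.

* **Transformation efficiency**: per-plate rate `colonies / dna_ug`;
  technical replicates are averaged within an experiment first, then mean
  and `SEM = sd/√n` are taken over independent experiments. A single
  experiment yields `sem = 0` with `sem_defined = FALSE` rather than `NA`
  arithmetic downstream.
* **Stability**: fraction of *initially picked* lines viable at each
  round; monotone by definition, and non-monotone input (a line that
  "revives") is rejected with the offending line named, since it
  indicates a recording error.
* **GFP fraction**: denominator is the *final-round survivors*, not the
  initially picked lines — the screen only images viable lines, so any
  other denominator would conflate stability with expression. Unassessed
  survivors are excluded and counted.
* **Mann–Whitney U**: implemented from scratch so both paths are
  oracle-testable. The exact path enumerates all labelings via the
  midrank identity `U = W − n_x(n_x+1)/2` and reports
  `P(|U − μ| ≥ |U_obs − μ|)`; with no ties this equals the classical
  doubled one-tail exact p (the tests cross-check against both a
  brute-force pairwise-counting oracle and `stats::wilcox.test`). The
  approximate path uses the tie-corrected normal approximation with a 0.5
  continuity correction. `auto` mode enumerates when there are no ties
  and at most `2e5` labelings (exhaustive yet instant at screen-typical
  group sizes), otherwise approximates. Significance is strict
  (`p < α`, default 0.05), and no multiplicity adjustment is applied by
  default — construct screens conventionally report raw p-values — with
  Bonferroni/BH behind an explicit flag.

A practical consequence pinned by the tests: with three experiments per
group the exact two-tailed p cannot fall below `2/C(6,3) = 0.1`, even
under complete separation.

## What the synthetic generators emulate — and what they do not

`gen_genome()` plants genes with a three-component 3′ UTR length mixture
whose default weights (≈ 0.036 / 0.388 / 0.576 for short/medium/long)
mirror the approximate class abundances of the real annotation, GC-biased
random sequence (default 0.64, the nuclear genome's average), and a motif
whose end sits 10–20 nt upstream of the annotated UTR end, echoing the
typical distance of poly(A) signals from the cleavage site. Every planted
length, class and motif position is echoed in a truth table; chromosome
sizes adapt to their gene content unless a fixed `chrom_size` is given, in
which case infeasible packing is an error.

`gen_fpkm()` draws log-normal baseline means (spanning orders of
magnitude, as expression does), adds a per-gene sinusoidal diurnal
component with random amplitude and phase over 24 h (default 12
timepoints), and multiplicative Gaussian noise (default CV 0.1),
truncating at zero.

`gen_screen()` draws colony counts as Poisson around
`efficiency_mean × dna_ug` per technical replicate (negative-binomial
overdispersion is not modelled; published summaries give means ± SEM
only), line survival as independent per-round Bernoulli events
conditional on prior survival (viability monotone by construction), and
GFP as Bernoulli conditional on final-round survival.
`published_screen_preset()` carries per-construct parameters transcribed from
the published screen: where only a marginal round-3 viability is printed,
it is split into equal per-round survival probabilities (a geometric
split — the least-committal choice that reproduces the printed marginal
without inventing per-round claims), and quantities published only as
figures or ranges are fixed once at values inside the stated ranges. The
deferred-selection preset uses five rounds: three non-selective rounds
over which 95/96 of lines persist, then two selective rounds bringing the
overall marginal to 49%.

What the generators deliberately do **not** model: transgene-integration
genetics, silencing mechanisms, line-to-line autocorrelation of survival
beyond the monotone constraint (unobservable from printed summaries),
fluorescence physics, or real genome sequence composition beyond GC
content. Passing tests therefore demonstrate that the *analytics* are
correct and that parameter recovery works at realistic sample sizes — not
that real screens will match the preset percentages.

## Problem sizes and tolerances

The test suite and the acceptance script run entirely on synthetic data at
the screen's own scale: three independent experiments of 96 lines per
construct (288 lines), six technical replicate plates per experiment.
Recovery checks accept estimates within the analytical binomial or
Poisson 95% confidence interval implied by those sizes — e.g.
`±1.96·√(p(1−p)/288)` for a viability percentage — so they test
calibration, not luck. Genome fixtures use 12–60 genes where exact
round-trips are asserted, and 6000 length draws for the
mixture-proportion goodness-of-fit check (chi-square, not rejected at
α = 0.01). Exact-vs-approximate Mann–Whitney agreement is checked at ten
observations per group, where full enumeration (184 756 labelings) is
still fast.

## Known limitations

* GFP enters as a boolean call; the package does not model fluorescence
  intensity, and no image processing is included.
* Domestication edits only recognition-site footprints; it will not
  resolve pathological cases where every footprint position is protected
  (reported as an error naming the site).
* The GFF3 reader targets the gene/mRNA/CDS/UTR hierarchy; genes without
  an mRNA child (e.g. tRNA-only records) are skipped and counted.
* Intergenic distances assume the annotation's gene set is complete on
  each scaffold; unannotated genes inflate apparent distances.
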