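---
title: "Methods: IBD tracing, sweep scanning and QTL mapping in a biparental breeding panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD tracing, sweep scanning and QTL mapping in a biparental breeding panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pedsweep` analyses how pedigree breeding from a single biparental cross
reshapes a crop genome. Its subject matter is a panel of elite inbred lines
bred from two inbred parents (think of an elite maize heterotic group derived
from one hybrid), plus a doubled-haploid (DH) mapping population from the
same cross. The package answers three questions and then connects the
answers:

1. **Where does each descendant's genome come from?** Parent-of-origin IBD
   tracing and IBD-conserved-region (ICR) calling.
2. **Where did selection act?** Sliding-window diversity statistics (π,
   Watterson's θ, Tajima's D) and a composite-likelihood-ratio (CLR) sweep
   scan, aggregated and thresholded into selective-sweep regions (SSWs).
3. **Which loci move the traits?** Inclusive composite interval mapping
   (ICIM) of additive QTLs in the DH population, with stable-QTL and
   QTL-cluster calling and per-line cumulative additive effects (CAE).

A forward simulator with recorded ground truth makes the whole pipeline
testable end to end without any external data.

## The simulated world

`sim_config()` describes the generative model. Two fully inbred parents
differ at a fraction `divergence` (default 0.6) of `markers_per_chrom`
markers per chromosome; marker bp positions are uniform and cM positions
proportional to bp. Meiosis places `Poisson(length_cM / 100)` crossovers
uniformly on the cM scale — a Haldane (no-interference) process. Downstream
*mapping* deliberately uses the Kosambi function instead: map functions are
analysis conventions, not generative truth, and at the marker densities used
here the numerical difference is far below the Monte-Carlo noise of any
test.

Descendant lines are bred as repeated DH generation plus truncation
selection: each cycle doubles `n_candidates` gametes (cycle 1 from the
founder F1; later cycles from crosses of two selected lines) and keeps the
`n_descendants` lines with the highest weighted score at the selected loci.
Defaults — 15 lines kept of 60 candidates over 3 cycles — reproduce the
structure of an elite panel: long complementary parental blocks, strong
drift, loci under selection fixed for the favoured parent. The DH population
(default 240 lines) is one doubled gamete of the F1 per line, so every
informative marker segregates ~1:1.

Phenotypes follow `y_ijk = g_i + E_j + e_ijk`, with `g_i` the sum of signed
additive QTL effects (`x = +1` for the parent-1 allele), a common
environment shift (sd = half the genetic sd by default) and residual noise
whose variance is set so the *line-mean* heritability over
`n_env × n_rep` observations matches `h2` (default 0.7, typical of
multi-environment yield trials). QTL effects attach to the nearest
*segregating* marker — an effect placed where the parents are identical
would otherwise silently vanish. Genotyping error is a symmetric allele
flip (default 1e-3) applied after line construction; missingness (default
2%) is independent. Parents are emitted clean, mimicking deeply sequenced
founders.

What the generator does **not** emulate: residual heterozygosity, epistasis,
genotype-by-environment interaction at QTLs, mutation, and realistic
ascertainment of markers. A green recovery test therefore establishes that
the estimators work under clean Mendelian inheritance with realistic error
rates — not that they are robust to structural model violations.

## Parent-of-origin IBD and ICRs

Because both parents are known homozygous lines, origin tracing reduces to
allele matching at the informative markers (where the parents differ).
Isolated discordant runs shorter than `min_markers` (default 5) flanked by
agreeing labels are smoothed — under an allele error rate of 1e-4 a run of
even two coordinated errors is essentially impossible, while true double
crossovers spanning fewer than 5 informative markers are rare and
unrecoverable anyway.

Maximal same-parent runs are scored with a segment LOD,
`Σ log10[P(allele | IBD, ε) / P(allele | panel frequency)]`, with ε = 1e-4,
a detection threshold of 3 and end trimming at 2.5. The trimming rule had to
be reconstructed: we trim an end through the last minimum of its inward
cumulative LOD whenever that minimum dips below −(`min_lod` − `trim_lod`),
which leaves clean ends untouched (required for breakpoint-accuracy
guarantees) while cutting error-laden tails.

One subtlety matters a lot: the frequency-based LOD is *zero* precisely
where the panel is fixed — which is exactly where ICRs live. Reported IBD
segments keep the LOD ≥ 3 filter, but the per-line chromosome tiling also
anchors on sub-threshold maximal runs, because an allele match against a
known inbred parent determines origin regardless of what the panel
frequency can certify. Without this, gap attribution back-fills swept
chromosomes with whichever parent happens to survive the filter elsewhere.

Gaps are attributed by minimum recombination: same-parent flanks absorb the
gap; different-parent flanks get a single breakpoint at the gap midpoint
(the principle determines the count, not the position; the midpoint is the
symmetric choice); terminal gaps take the nearest segment's parent. This is
provably minimal and verified against exhaustive enumeration in the tests.

ICRs are called on `icr_window_bp` bins (default 100 kb): a line's bin label
is the parent covering the majority of the bin, bin retention is the
fraction of labelled lines sharing a parent, and maximal runs of bins with
retention ≥ τ (default 0.9, our reading of "almost all" of 15 lines:
at least 14) merge into ICRs. Neither the bin size nor τ is stated by the
source study; both are parameters. Per-line retention ratios are emitted in
two variants — over ICRs only and over all assigned IBD — because the
published ratio does not say which it used.

## Sweep scanning

Inbred lines contribute one haplotype each; the derived allele is the VCF
ALT allele (parent 2's allele in simulations). Windows are non-overlapping
10-kb tiles ("sliding" with no stated step is read as step = width).
Per window, `pi = Σ 2j(n−j)/(n(n−1))` (a per-window total; ranking within
equal-length windows is scale-invariant), `theta_w = Σ 1/a1(n_site)`
(reducing to `S/a1` on complete data) and Tajima's D with the standard
constants; with missing data the constants use the window's maximum
per-site `n`. Windows with `S = 0` have undefined D and are excluded from
ranking.

The CLR scan follows the SweepFinder/SweeD logic. The background SFS φ is
the genome-wide distribution of derived counts at complete-data sites. A
sweep at `x0` with intensity α lets each lineage escape with probability
`p_e(d) = 1 − exp(−α d)`; the `k` escapees plus the single swept haplotype
are `k + 1` draws *without replacement* from the background configuration,
the swept draw copied to all non-escaped lineages, and the result is
renormalized over polymorphic outcomes. We use the exact hypergeometric
draw rather than a binomial approximation: the binomial smears φ so badly
at `p_e → 1` (≈ 0.2 log-units per site on drift-shaped backgrounds) that
the background model stops being nested and the CLR collapses to zero
genome-wide. With the hypergeometric, `α → ∞` reproduces φ exactly and
`CLR = 2[max_α Σ log P(j|α,d) − Σ log φ(j)] ≥ 0` holds by construction.
`p_e` is floored at 1e-8 (the fully swept limit conditioned on polymorphism
is otherwise degenerate) and renormalized classes at 1e-12 before logs.
The composite likelihood uses **all** sites of the chromosome by default
(`radius_bp = Inf`): a fully swept core contains no polymorphism, and only
flanking sites can localize its centre. α is maximized over 20 log-spaced
values in [1e-8, 1e-2] per bp; site distributions are cached on 64
log-spaced distance bins.

All three statistics are averaged into 100-kb tiles, ranked in the
*sweep-evidence* direction — lowest π, lowest Tajima's D, highest CLR —
and the smallest top set reaching 10% of the defined genome length
(ties included) is merged by adjacency into SSWs. The source text says the
"highest" values of all three statistics were used, which contradicts sweep
theory and its own discussion of negative Tajima's D; the direction is
configurable per statistic and the sweep-direction default is used.

## QTL mapping

Phenotypes of weight-type traits can be standardized to 13% water content
with `adjust_moisture()` (`value·(1−wc)/(1−0.13)`). Replicates within an
environment are averaged to line means and environments are scanned
separately.

ICIM is implemented in its regression form, which is equivalent to the EM
mixture form for additive DH models: stepwise marker selection (entry and
stay at P = 0.001, partial-F tests, ties broken by map order) picks
cofactors; at each 0.5-cM grid position the phenotype is pre-adjusted by
the fitted contributions of all cofactors except those within `win_cM` of
the position, and regressed on the expected QTL code computed from the
flanking markers via Kosambi recombination fractions under DH class
probabilities. `LOD = (n/2)·log10(RSS0/RSS1)`; peaks ≥ 2.5 are QTLs with
additive effect `a` (half the difference of expected-code class means),
PVE, and a 1-LOD support interval. Two peaks on a chromosome stay separate
only if ≥ 20 cM apart or separated by a ≥ 1-LOD valley (a convention, not
from the source).

Two defaults were calibrated on simulations and deserve a note. First,
markers with minor-allele frequency below `maf_min = 0.05` are dropped from
the scan map: in a 1:1-segregating DH population such columns are
genotyping-error artifacts, and as flanking markers they collapse the
expected code. Second, the cofactor exclusion window `win_cM` defaults to
20 cM: at 10 cM the QTL's own cofactor re-enters the adjustment at the edge
of its support region and truncates 1-LOD intervals (single-QTL interval
coverage 72% at 10 cM versus 82% at 20 cM in the recovery experiment). The
actual exclusion rule of the referenced software is undocumented; ours is
an explicit reconstruction.

Stable QTLs are groups of same-trait, same-chromosome QTLs with overlapping
support intervals in ≥ 2 environments. Clusters chain QTL physical
intervals (support intervals interpolated to bp through the map) with gaps
≤ 2 Mb and report chains of ≥ 4 members — the smallest published cluster
size. `cae()` sums signed effects of the alleles a line carries at the QTL
peaks.

## Co-localization

Interval algebra (normalize/union/intersect/length, backed by IRanges
behind the package's own API, 0-based half-open internally, 1-based in
reports) connects the layers. ICR×SSW overlap is reported both by count
(≥ 1 bp) and by length, overall, per parent, and per statistic, against the
union of the three SSW sets — the published overlap percentage does not say
which basis or combination it used, so all are emitted with length-based
versus the union as the headline. QTLs are flagged "in or near" a region
set within `near_dist` (default 1 Mb, with a sensitivity sweep at 0/0.5/1/2
Mb). Gene lists require ≥ 1 bp of overlap with ICR∩SSW.

## Numerical and degenerate-input conventions

* Panel frequencies of 0 or 1 contribute exactly 0 to segment LODs (never
  ±∞); all-missing lines yield empty segment lists; chromosomes without
  segments are tiled `NA` and flagged.
* Tajima's D is `NA` when `S = 0` or its variance term is non-positive.
* CLR grid points with no usable site score 0; `clr_scan` uses only
  complete-data sites because the model is defined at fixed `n`.
* `cm_to_bp`/`bp_to_cm` clamp out-of-span positions to the map ends and
  flag them; flat cM stretches interpolate with tie-averaging.
* Retention ratios with zero denominators are `NA` with an `undefined`
  flag, not errors.
* All randomness flows from a single seed; `run_all()` is byte-reproducible
  for a fixed seed.

## Recovery experiments: what the configurations mean

The acceptance suite runs fixed, documented experiments rather than
re-deriving the source study's numbers (those depend on its unpublished
resequencing and field data):

* **CLR localization** uses a recombination-dense miniature genome (one
  2-Mb chromosome of 200 cM, i.e. 10 kb/cM, 2000 markers) and a 40-line
  panel bred 3 cycles under one selected locus. Two choices matter. The
  bp/cM scale is set so the expected hitchhiking footprint (tens of cM
  after three cycles) corresponds to one or two hundred kb, mirroring the
  footprint-to-criterion proportions of a real genome; on a 50-kb/cM
  genome the footprint is measured in Mb and no method can localize a
  centre to 200 kb. The panel is larger than the 15-line study panel
  because the CLR's background model assumes a mostly-neutral genome-wide
  SFS; a 15-line panel after three bottleneck cycles is swept nearly
  everywhere, which is a genuine limitation of CLR scans on tiny pedigree
  panels and is why the ICR experiment, not the CLR experiment, uses the
  15-line panel.
* **ICR recovery** uses the study-sized 15-line panel (45 candidates,
  3 cycles, one selected locus) and asks for a favoured-parent ICR covering
  the locus.
* **QTL recovery** uses the study-sized 240-line DH population, one QTL
  explaining 10% of line-mean variance, 50 seeds, plus a 100-permutation
  null.

## Known limitations

* The breeding simplification (repeated DH + truncation selection) produces
  stronger per-cycle drift than multi-generation selfing programs; panel
  statistics are correspondingly more extreme.
* The CLR model ignores recombination-rate variation and uses a single
  background SFS; no B-value-style correction is attempted.
* ICIM here is the additive DH regression form: no dominance, no epistasis,
  no multi-environment joint model.
* IBD tracing requires known inbred parents; it is not a general-purpose
  IBD detector for unrelated samples.
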