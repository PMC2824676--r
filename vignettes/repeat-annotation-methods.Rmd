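---
title: "Competitive repeat annotation and junction markers: methods and design"
author: "RepeatJunctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive repeat annotation and junction markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatJunctions)
```

## The problem

Repeat-rich regions such as plant centromeres are dominated by tandem
satellite arrays (e.g. the maize CentC repeat) and families of
centromeric LTR retrotransposons (CRM1, CRM2, CRM3, CentA) that insert
into each other and into the satellite arrays. Stacked genome-browser
annotation is unreadable here: every locus matches many entries of
several repeat databases at once. What an analyst needs is the *single
best-fitting* repeat class per locus, plus the boundaries between
classes. Those boundaries — **repeat junctions** — are created by
element insertions, which are not sequence-specific, so a junction is
potentially unique in the genome even when both flanking repeats are
present in hundreds of copies. Two junctions close enough for one PCR
amplicon to span them form a **single-copy junction marker**, the tool
that lets highly repetitive loci (and hence whole centromeres) be
placed on a genetic map.

This package ingests homology evidence in standard aligner formats
(BLAST 12-column tabular, cross_match alignment lines, MUMmer
`show-coords`-style tables), competes overlapping annotations, detects
junctions, proposes marker candidates, identifies and dates paired
LTRs, and renders a per-query figure (SVG and PostScript). A
synthetic-centromere simulator with complete ground truth makes every
stage testable with no external binaries.

## The competition rule

All evidence for one query is reduced by a greedy ranked sweep.
Features are ranked by length (descending), then score, then database
priority, then start coordinate — only "longer wins" is inherent to
the method; the remaining keys exist to make ties deterministic. A
candidate is kept if and only if its overlap with every already-kept
*competing* feature is at most the **overlap allowance** (nt, default
0). Who competes depends on the evidence mode:

* **blast mode** — only features from *different* databases compete.
  Same-database HSPs stack freely, which is what keeps tandem repeats
  visible: consecutive satellite HSPs overlap without eliminating one
  another.
* **crossmatch mode** — every pair competes; longer contiguously
  masked segments displace shorter ones.

Elimination removes the whole shorter feature; nothing is trimmed. The
eliminated set is retained, each entry pointing at its eliminator, and
is written to a TSV/JSON-lines audit.

One property worth stating because it is *not* true: raising the
allowance does not monotonically increase the number of kept features.
A larger allowance can admit a mid-ranked feature that then eliminates
several smaller features it overlaps, lowering the total. The
properties that do hold, and are machine-checked in the test suite,
are (i) the output invariant — no kept competing pair overlaps beyond
the allowance, (ii) idempotence — re-competing the kept set changes
nothing, (iii) equivalence with an independent brute-force ranked
sweep, and (iv) full retention once the allowance reaches the longest
feature length.

Classification attaches a repeat class (family plus part, e.g.
`CRM2/LTR`) to each kept feature, by default from RepeatMasker-style
`Family#Part` subject names, optionally refined by per-subject-subrange
rules (the mechanism used to tell LTR from internal regions of a
full-element reference sequence). Unknown subjects become `other`.

## Junctions and markers

A junction is recorded between two adjacent kept features of different
repeat classes separated by at most `junction_gap_tolerance_nt`
(default 50 nt) of unannotated sequence. The default tolerance is
nonzero because untranslated element regions are deliberately not
annotated (they are low-complexity and unreliable to detect), leaving
short unannotated stubs at real element boundaries. Classes are
compared at the *family* level by default: the internal LTR/CDS
anatomy of a single element is not an insertion boundary, and treating
it as one would double-count every element. With abutting features the
junction position is the last base of the left feature; with a gap it
is the gap midpoint.

Marker candidates are all junction pairs at most
`max_marker_span_nt = 2500` nt apart, each reported once with its two
flanking class pairs, sorted by span. Primer design itself is out of
scope.

## LTR identification and K2P dating

A retroelement's two LTRs are identical at insertion and diverge
afterwards, so a young element appears as one long direct exact match
whose intervals flank an element-sized internal span. Candidate LTR
pairs are direct matches of at least `min_ltr_len = 300` nt with an
internal span of 1–25 kb (bracketing common LTR element geometries),
optionally required to overlap a CDS-classified segment. Because a
maximal match may extend a base or two into coincidentally identical
flanking context, downstream checks treat the match as *containing*
the LTR pair rather than equalling it.

Dating aligns the two LTR intervals globally (match +1, mismatch −1,
gap open −5, gap extend −1) and computes the Kimura two-parameter
distance over ungapped, unambiguous columns:

$$\kappa = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q),$$

with transition proportion $P$ and transversion proportion $Q$. Gap
columns are excluded from the denominator, so padding an alignment
with gaps leaves $\kappa$ unchanged; the distance is undefined (an
error) when $2P + Q \ge 1$ or $Q \ge 0.5$. Elements are age-ordered
by ascending $\kappa$, ties broken by the longer exact match first
(longer match lines correlate with younger elements). Converting
$\kappa$ to years needs a mutation rate the package deliberately does
not assume.

## Gaps, rulers, tiling

Runs of at least `gap_run_threshold_nt = 100` consecutive Ns are
assembly gaps, drawn as grey vertical bars — one bar per complete
100-N block, i.e. `floor(run/100)`: a 1,000-N gap yields a stack of
10 bars and a 100-N gap yields one. This generalization was chosen
because it reproduces both documented cases; the alternative (one bar
per gap) fits only the second. Ruler ticks sit at exact 1 kb
multiples, each with an absolute label and a secondary label counting
nucleotides from the end of the nearest gap at or before the tick
(positions inside a gap report 0 — ticks are never meaningful there).

Long queries are tiled into `tile_window_nt = 210000` nt windows
overlapping by `tile_overlap_nt = 10000` nt. Windows advance by
window − overlap and generation stops at the first window that reaches
the region end, so a 410 kb region yields exactly two windows. Any
feature no longer than the overlap is rendered whole in at least one
window.

## Charts

Read placements arrive as a six-column TSV (`read_id, query_id, start,
end, hits_in_query, hits_in_genome`; coordinates 1-based inclusive).
Coverage charts count, per nucleotide, the placements passing a
multiplicity filter; the three standard filters — unique
(`hits_in_query == 1`, `hits_in_genome <= 2`), multi-in-target
(`hits_in_genome <= 2`), unrestricted — are nested, so their values
are pointwise monotone. They generalize both published chart
configurations (BAC sets and whole-chromosome mode) as thresholds on
the two multiplicity columns. Charts belong to a foreground or a
background set; each set gets its own y-axis maximum (the largest
value over its member charts) and the background set is drawn first,
underneath. Mapping itself is not performed here; placements come from
an external mapper or the simulator.

## Exact matches and level layout

The built-in maximal exact match finder reports every maximal repeated
substring pair of length ≥ `min_exact_match_nt = 100`, direct and
inverted. It seeds on exact k-mers (k = the minimum length), extends
each seed pair to maximality, and keeps per-diagonal skip lists so
every maximal pair is extended exactly once; N matches nothing,
including other Ns, so matches never span assembly gaps. The test
suite proves it equal to an independent brute-force enumeration (full
pairwise comparison matrix, run-length scan of every diagonal) across
hundreds of random sequences.

For drawing, matches are processed longest first on
`max_match_levels = 30` levels: each match takes the topmost level
where its full horizontal extent (both intervals plus connector)
collides with nothing already placed; matches that fit nowhere are
dropped and counted in the audit. Direct matches are drawn red,
inverted blue; solid segments are the matching intervals, joined by a
dashed connector.

## The simulator: what it emulates and what it does not

`simulateCentromere()` builds, deterministically from one seed: random
single-copy flanks, a central tandem satellite array (monomer 156 nt
by default — a typical centromeric-satellite scale, configurable; each
copy independently mutated at the array divergence), and nested
LTR–internal–LTR insertions. Each insertion picks an annotated host
segment, a position strictly inside it, and a family different from
the host's, so every insertion creates exactly two detectable
junctions; the right LTR is mutated at the per-insertion divergence
(uniform random substitutions, giving $E[\kappa] \approx d$ to first
order). All previously logged coordinates are shifted, the host
segment is split, and the complete segment/junction/insertion log is
maintained in final coordinates. `emitEvidence()` writes the genome,
per-family BLAST tabular files (one HSP per visible segment, exact at
noise 0), a cross_match mask file, decoy HSPs on request, ChIP-like
read placements restricted to an enrichment interval, and the truth as
GFF3.

Deliberate simplifications: no target-site duplications, no
recombinant subfamily mosaics, no indel mutations, uniform
substitution (transitions not favored), insertions never target
unannotated flanks, and same-family nesting is excluded. Passing the
recovery tests therefore shows the pipeline is exact on clean,
well-separated evidence; it does not show robustness to diverged or
fragmented real-world alignments, which is what the allowance, gap
tolerance and score-equivalence parameters exist to absorb.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere (the Bioconductor
  convention); parsers normalize aligner output on input.
* Reversed subject coordinates in BLAST rows, and `C` lines in
  cross_match output, mark minus-strand features.
* The WU-BLAST-style score-equivalence filter is re-expressed as a
  post-parse filter: keep HSPs scoring at least `fraction` × (subject
  length × match reward), e.g. 0.9 for "within 10% of a perfect
  complete match" — the setting that separates closely related
  subfamily LTRs.
* Renderers are deterministic (fixed number formatting, no
  timestamps); re-rendering a model is byte-identical. SVG elements
  carry `class` and `data-*` attributes so structure is assertable;
  the PostScript mirrors the same geometry and is not asserted on
  byte-wise beyond determinism.
* The parameters file is a sectioned plain-text dialect
  (`[section]` headers, `key = value`, `#` comments) with six
  sections; `writeParamsTemplate()` emits a fully commented template
  that re-parses to the documented defaults. The dialect itself is
  this package's choice; only the six-section structure and the
  parameter meanings are inherited from the method.

## Problem sizes used by the test suite

The documented worked examples run at their natural sizes. The
property suites use: 1,000 random competition instances of up to 50
features; 200 random sequences of up to 2 kb against the brute-force
exact-match oracle at minimum lengths 8, 20 and 100; one ~520 kb
simulated centromere with 25 nested insertions for exact junction and
marker recovery; a four-epoch age ladder (divergences 0.040 / 0.025 /
0.012 / 0.002, 3 kb LTRs so estimator noise stays well under the
epoch spacing); and full-display renders of a ~60 kb simulated query.

## Known limitations

Aligners are not executed; the package consumes their output formats
(or its own exact matcher and simulator). FPC project handling, GUI
interaction, primer design, protein alignments and XML BLAST parsing
are out of scope. K2P ages are relative, not calendar dates. The
greedy competition is order-deterministic but, like the rule it
implements, not globally optimal in any objective — it is the
documented "longer eliminates shorter" sweep.
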