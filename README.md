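# RepeatJunctions

Competitive repeat annotation and repeat-junction marker discovery for
repeat-rich genomic sequence, with an R/Bioconductor-style API.

## The problem

Centromeres and similar regions are mosaics of tandem satellite arrays
and closely related retrotransposon families nested inside one
another. Conventional stacked annotation drowns such loci in
overlapping hits. Two things are needed instead:

1. **One best-fitting repeat class per locus.** Homology evidence from
   several subject databases (BLAST tabular, cross_match, MUMmer-style
   exact matches) is *competed*: ranking by length (then score,
   database priority, position), a feature is kept only if its overlap
   with every kept feature from a *different* database stays within a
   configured allowance; same-database hits stack so tandem repeats
   remain visible. In cross_match (masking) mode all features compete.
2. **Repeat junctions.** Each element insertion creates two junctions
   — boundaries between different repeat classes — which can be unique
   in the genome even when both flanking repeats are high-copy. Pairs
   of junctions no more than 2.5 kb apart are reported as single-copy
   PCR marker candidates.

Around that core the package provides assembly-gap detection (one grey
bar per complete 100-N block), gap-relative ruler coordinates, 210
kb/10 kb overlapped tiling of long queries, per-nucleotide read
coverage charts on two independent y-axes, a built-in maximal exact
match finder (direct and inverted, Rcpp), LTR-pair identification from
exact-match structure with Kimura two-parameter insertion dating

κ = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q)

(P transitions, Q transversions over ungapped columns), and a
deterministic SVG/PostScript renderer. A synthetic-centromere
simulator with complete ground truth (nested insertions, junction log,
evidence files, read placements) makes the whole pipeline testable
offline.

## Worked example

```r
library(RepeatJunctions)

sim <- simulateCentromere(seed = 11, nInsertions = 6,
                          flankLength = 10000, satelliteCopies = 80)
sim
#> CentromereSim: 80480 nt (seed 11)
#>   insertions: 6  junctions: 12  annotated segments: 25

ev <- emitEvidence(sim, "demo_out")
feats <- do.call(c, unname(lapply(names(ev$blast), function(f)
    readBlastTabular(ev$blast[[f]], f))))
track <- classifyFeatures(competeFeatures(feats, allowance = 0,
                                          mode = "blast"))
track
#> CompetedTrack for query 'simQuery' (mode: blast, allowance: 0 nt)
#>   kept: 25  eliminated: 0

j <- detectJunctions(track, gapTolerance = 50)
head(j[, c("position", "leftClass", "rightClass", "gap")], 4)
#>   position leftClass rightClass gap
#> 1    10098 CentC/SAT   CRM1/LTR   0
#> 2    18098  CRM1/LTR  CentC/SAT   0
#> 3    18166 CentC/SAT   CRM2/LTR   0
#> 4    22815  CRM2/CDS   CRM1/LTR   0

findMarkerCandidates(j, maxSpan = 2500)[, c("positionA", "positionB", "span")]
#>   positionA positionB span
#> 1     18098     18166   68
#> 2     34166     34728  562
#> 3     57821     58728  907
```

The 25 kept features are the 25 ground-truth segments (satellite
pieces plus LTR/CDS/LTR of each nested element); the 12 detected
junctions are exactly the 2 × 6 logged insertion boundaries, and three
junction pairs lie within the 2,500 nt marker span. Dating the
youngest element's LTR pair:

```r
m <- findExactMatches(simGenome(sim), minLength = 100, query = "simQuery")
m
#> ExactMatchSet for query 'simQuery' with 31 match pair(s)
#>   direct: 31  inverted: 0  length range: [593, 8001]

pairs <- identifyLtrPairs(m, minLtrLength = 300, internalRange = c(1000, 25000))
dateLtrPair(simGenome(sim), pairs[1, ])$kappa
#> [1] 0
```

(κ = 0: the simulated LTRs here were inserted with zero divergence.)
Rendering writes one SVG/PostScript pair per 210 kb tile plus GFF3,
BED, marker TSV and a JSON-lines audit:

```r
annotateQuery("simQuery", Biostrings::readDNAStringSet(ev$genome)[[1]],
              blastFeatures = feats, outDir = "demo_out")
```

A thin command-line front end with `template`, `simulate` and
`annotate` subcommands is installed at `inst/scripts/repeatjunctions`.

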