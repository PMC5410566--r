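---
title: "Methods: surveying a DnaJ/Hsp40 gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying a DnaJ/Hsp40 gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnajfam)
```

## The analysis

J-proteins (DnaJ/Hsp40) are co-chaperones defined by a ~70-residue
J-domain whose invariant His-Pro-Asp (HPD) tripeptide stimulates Hsp70
ATPase activity. A genome survey of this family proceeds from profile
search hits to a named, classified catalog: candidates are screened by
E-value, filtered on J-domain completeness, classified by domain
architecture, named along the chromosomes, characterised
physicochemically, and examined for duplication history, promoter
cis-elements and expression behaviour. `dnajfam` implements each step as
a tested function and ties them together in `run_survey()`.

This vignette records the models, conventions and design decisions
behind each stage — in particular every point where the conventional
survey workflow leaves a rule unstated and this package had to fix one.

## Domain evidence and the completeness filter

Domain evidence enters either as an external per-domain hit table (the
usual route for real data: any profile-search tool that reports target,
domain, E-value, profile span, alignment span and profile length) or
from the bundled internal scanner. The internal `profile_model()` is an
*ungapped* position-specific score model: each column emits its
consensus residue with probability 0.6 and the other 19 residues
uniformly, scored as log2-odds against a uniform background. This is
deliberately simpler than a profile HMM with insert/delete states; it
exists so the pipeline and its tests are self-contained, and real-data
users are expected to bypass it with an external hit table. Its score
threshold defaults to half the consensus score: on random background the
expected per-column score is about −1 while the consensus scores +3.6,
so a ~70-column model separates planted domains from background by a
very wide margin (no false placement was observed in 200 × 200-residue
background simulations; the planted-consensus recovery tests in
`test-domain-annotation.R` exercise both sides).

Architecture assembly (`assemble_architecture()`) applies four rules:

* **J-domain hits** must pass the E-value screen (default `1e-5`, the
  conventional threshold for this family's profile searches).
* **Completeness**: at least one J hit must cover ≥ 80% of the profile
  (`cov_complete = 0.8`). Surveys of this family routinely drop
  candidates "without a complete J-domain" without stating a criterion;
  profile coverage is the natural operationalisation because it
  separates truncated hits without inventing sequence-level rules, and
  it is configurable.
* **HPD** counts only when the tripeptide lies *inside* a J-domain span
  — an HPD in an unrelated region says nothing about J-domain function.
* **Zinc finger**: ≥ 2 CxxCxGxG repeats (`zf_min_repeats = 2`). Type-I
  DnaJ proteins carry a central zinc-binding domain built from four
  repeats, usually described as "two zinc fingers"; requiring two
  repeats is the permissive reading and is configurable.
* **C-terminal extent**: ≥ 40 residues downstream of the last annotated
  domain (`cterm_min = 40`). This is an explicit artifact convention —
  no published rule defines when a C-terminal region "is present" — and
  it is surfaced as a parameter rather than buried in code.

## Five-group classification

`classify_protein()` maps (HPD, zinc finger, C-terminal) to groups A–E
in a fixed decision order: **no HPD → E** first, then zinc finger +
C-terminal → A, zinc finger alone → D, C-terminal alone → B, bare
J-domain → C. The HPD test must come first: J-like proteins (group E)
may well carry zinc fingers or long tails, and the published pepper
catalog places such proteins in E. Enumerating the 8-point architecture
cube shows the scheme is total and a partition (4 points map to E, one
each to A/B/C/D); this is a unit test. The G/F-rich region sometimes
used in older three-group schemes is deliberately not detected: the
five-group scheme never consults it.

## Naming

Members are named `prefix` + zero-padded rank after sorting by
(numeric chromosome, start coordinate); unplaced members (chromosome
"00") follow all placed ones, ordered by locus id — this lexicographic
rule is the package's own choice (published catalogs are silent on it)
and reproduces the published pepper ordering. Padding width is 2,
growing as ⌈log10(n)⌉ for larger families. Naming is a bijection and
order-independent; both are property-tested.

## Protein properties

Molecular weight is the sum of average (not monoisotopic) residue
masses plus one water, ProtParam convention; ambiguous residues (X, B,
Z, U) are rejected rather than approximated. Theoretical pI uses the
Bjellqvist pKa set behind the ProtParam lineage, with the net charge as
the Henderson–Hasselbalch sum over side chains and termini. The charge
is strictly decreasing in pH, so the pI is the unique root, found by
bisection to 1e-3 and cross-checked against a 1e-4-step grid scan in the
tests. Both tables ship as editable TSVs under `extdata`, so an EMBOSS
pKa set is a drop-in replacement. Numeric agreement with any particular
published catalog's MW/pI columns is *not* asserted anywhere: the
underlying sequences are not part of such tables and published tables
of this size routinely contain copy errors (the bundled pepper catalog
demonstrably does — see below).

## The bundled pepper catalog

`load_catalog()` returns the 76-member pepper CaDnaJ catalog typed
verbatim from the published survey, including its internal
inconsistencies (two members share an MW/pI pair that cannot belong to
both, and the running text contradicts the table in several extrema).
The fixture is data, not a correction: derived statistics are computed
from the table as printed, and `verify_against_catalog()` only checks
statistics whose published values are internally consistent — the group
census, intron histogram, chromosome distribution, the single 100-kb
tandem candidate pair, minimum length and minimum pI.

## Tandem duplication

The three-part rule: same chromosome within 100 kb, alignment coverage
of the longer gene **strictly greater than** 70%, identity of the
aligned region **strictly greater than** 70%. Conventions fixed here:

* **Distance** is the gap between gene intervals (end of the upstream
  gene to start of the downstream one, 0 if they overlap), not
  start-to-start — robust to long genes; both readings reproduce the
  published pepper call.
* **"Inserted by less than one gene"** is operationalised as at most
  one *family member* between the pair (non-family genes are invisible
  to the pipeline); configurable or disabled with `NA`.
* **Alignment** is Needleman–Wunsch with a linear gap penalty
  (match +1 / mismatch −1 / gap −2 by default; a substitution matrix
  can be supplied), run on protein sequences by default — whether
  published 70% criteria refer to nucleotide or protein alignment is
  typically unstated. Identity is exact residue equality either way.
* **Coverage** is the fraction of the longer sequence's residues that
  sit in alignment columns paired with a residue of the other sequence;
  "coverage rate of the longer gene" names no formula, so this package
  defines one.

The row-vectorised DP is verified against a memoized exhaustive
recursion on all pairs up to length 12.

## Promoters

Windows are the 1.5 kb upstream of the transcription start (excluding
the start base itself), reverse-complemented for minus-strand genes and
truncated at contig edges. The bundled motif table carries the
heat-shock element core `AAAAAATTTC` plus canonical published consensi
for TC-rich, MBS, LTR, ABRE, TCA, TGA, GARE, CGTCA and ERE elements.
Published surveys use discovery services with unpublished internal
motif libraries, so *reproducing any particular paper's element counts
is explicitly not claimed*: the motif table is user-replaceable data,
and counts are meaningful only relative to the library in use.
Overlapping matches are counted (element tallies count occurrences),
and both strands are scanned by default, with minus-strand hits
reported in forward coordinates. The IUPAC matcher
(Biostrings-based) is cross-checked against a naive
position-by-position oracle over all 15 ambiguity codes.

## Expression patterns

The matrix is treated as a generic per-gene abundance (RPKM and FPKM
inputs are handled identically; no conversion is attempted). Transform:
`log2(x + 1)`. Pattern classes use two conventions the published
workflow leaves unstated: a tissue counts as expressing at
`expr_min = 1` RPKM, and "tissue-specific" allows at most
`specific_max = 2` expressing tissues; both are documented parameters,
not published rules, and the classes partition the gene set by
construction. Clustering is average linkage on Euclidean distance —
the common default of the heat-map tools these surveys cite — with rows
sorted by gene name beforehand so tie-breaking is deterministic; merge
heights and cophenetic distances are verified against a brute-force
agglomeration on small matrices. The dendrogram exports as Newick; the
heat map (SVG/PNG) is purely presentational and byte-deterministic.

## qPCR

2^−ΔΔCt with amplification efficiency fixed at 2 and replicates
aggregated by arithmetic mean of Ct before ΔCt (a per-replicate ΔΔCt
mode is a flag; on balanced designs the two agree exactly). Plate
offsets cancel by construction — adding a constant to every well of one
condition leaves the fold unchanged — and this is property-tested. The
up/down call thresholds (2-fold, 0.5-fold) and the 3-fold "strong
induction" flag are reporting conventions. With 0.2-cycle replicate
noise and n = 3, the estimator's median absolute log2-fold error over
500 simulated genes is below 0.25 when each gene is measured against
its own reference wells; a shared single reference adds a common bias
term to all genes (the realistic single-experiment layout the generator
emulates), which leaves rankings and correlations intact but can shift
all folds together.

## The synthetic-data generator

`simulate_family()` emulates the statistical structure the analysis
assumes, with defaults set to the published pepper study conditions: 76
family genes in groups 9/8/53/1/5, nine decoys whose J-domain hits
cover 30–70% of the profile (passing the E-value screen but failing
completeness, mirroring the published 85 → 76 filter), one tandem pair
within 100 kb at ~85% protein identity, promoter motif rates echoing
the published per-gene element tallies (e.g. ~1.4 TC-rich and ~1.85
CGTCA copies per promoter), expression archetypes in the published
29/10/3/34 proportions, and qPCR log2 folds uniform on [−3, 3] with
0.2-cycle noise.

Construction details that matter for interpreting the tests:

* Planted J-domains are the internal profile's consensus with 5%
  per-position substitution (scores stay far above threshold). Proteins
  get a long variable N-terminal region (40–200 residues) ahead of the
  J-domain: real J-proteins place the domain N-proximally but not
  terminally, and this keeps the shared consensus a minority of each
  protein so *unrelated* members stay well below the 70% duplication
  identity rule.
* Each protein is validated at construction (HPD containment,
  zinc-finger repeat count, C-terminal extent) and resampled until its
  architecture matches its group exactly — recovery tests on these
  plants are therefore exact, not approximate.
* Promoter truth is the occurrence count actually present in the
  emitted window (planted copies plus incidental background matches),
  counted by a naive matcher independent of the pipeline's scanner; the
  recovery test is a genuine dual-route check.
* Background sequence is uniform over nucleotides/residues, intergenic
  gaps default to 30–60 kb (tandem pairs 3.2–6 kb), gene structures get
  1–6 exons with GT..AG introns, and all randomness flows from the
  single design seed; bundles are byte-identical for a fixed seed.

What the generator does **not** emulate: indel evolution, realistic
codon usage or intron-length distributions, compositional bias,
overlapping gene models, and profile-search score noise. Passing
recovery tests on these plants therefore demonstrates that the pipeline
implements its stated rules exactly — not that those rules are robust
to the full messiness of real genomes.

## Problem sizes and orchestration

The test suite and the acceptance script run the full default design
(85 genes on 12 chromosomes, ~4 Mb genome) once and smaller designs
(13 family genes, 2 chromosomes) for the per-module recovery suites;
oracle-equivalence properties use sequences ≤ 12 residues (alignment),
≤ 500 residues (profile scan) and 500 simulated genes (qPCR). These
sizes were chosen so each property is measured with comfortable margins
while the whole suite stays quick to iterate on.

`run_survey()` is pure orchestration: every number it writes equals the
corresponding module function's return on the same inputs (tested), it
logs a MANIFEST of completed/skipped stages, and reruns with the same
configuration are deterministic. `verify_against_catalog()` plus the
perturbation sensitivity check close the loop on the bundled catalog.

## Known limitations

* The internal profile scanner is ungapped and uncalibrated (no
  E-value theory); it is a testing device, not a replacement for a real
  profile search.
* Promoter element counts depend entirely on the motif library; the
  bundled table is small and documented, not exhaustive.
* Segmental duplications are ingested, never discovered; no synteny or
  Ka/Ks machinery is included.
* MW/pI reproduce the ProtParam conventions, not any specific published
  table's values.
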