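---
title: "Antisense degradation-signal encoding in coding sequences: models and methods"
author: "antisenseMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antisense degradation-signal encoding in coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisenseMotifs)
options(antisenseMotifs.verbose = FALSE)
```

## The biological question

In *Saccharomyces cerevisiae* the RNA-binding proteins Nrd1 and Nab3
recognise short consensus sequences in nascent transcripts (UGUA, GUAG,
UGUAG for Nrd1; UCUU, CUUG, UCUUG for Nab3), terminate RNA polymerase II
and hand the transcript to the nuclear exosome for degradation.  Cryptic
unstable transcripts (CUTs) carry many such sites and are destroyed
rapidly; stable unannotated transcripts (SUTs) largely escape.  Many of
these non-coding RNAs are transcribed antisense to protein-coding genes,
so the same DNA must encode a protein on one strand and a degradation
propensity on the other.  Because the genetic code is degenerate, a gene
can modulate how many Nrd1/Nab3 sites appear on its antisense strand
purely through its choice of synonymous codons, without changing the
protein.  This package provides the machinery to quantify that encoding:
motif scanning, ORF classification by antisense ncRNA overlap, metagene
profiling, expression-normalised PAR-CLIP occupancy, and a codon-usage
expectation model.

## Motif scanning and the longest-match rule

Sites are predicted by exact matching of the six consensus motifs
(written as DNA) on both strands.  Two rules define a "site":

* **Longest match.** Each 4-mer of a set is a substring of a 5-mer of the
  same set, so a 4-mer occurrence whose span lies inside a reported 5-mer
  occurrence is suppressed; only the 5-mer is counted.
* **Partial overlaps count separately.** Occurrences that overlap without
  containment are all reported (e.g. `TGTAGTAG` holds TGTAG at 1 and GTAG
  at 5).

A site is assigned to windows and bins by its 5'-most base on the strand
of the scan; this makes window counts unambiguous for sites straddling a
boundary and makes counts additive over a partition of the sequence.
`N` never matches.

## ORF classification

Transcripts shorter than 200 bp are removed.  An ORF is labelled
`ORF_CUT` if an antisense CUT overlaps its transcript interval by at
least 100 bp (and no SUT does), `ORF_SUT` symmetrically, `EXCLUDED` when
both transcript types overlap by at least 100 bp, and `ORF_CLEAR`
otherwise — including antisense overlaps below 100 bp.  When several
antisense ncRNAs of one type overlap one ORF we use the maximum
single-transcript overlap, not the union, because classification is by
"an overlapping antisense transcript".  Overlap is computed on transcript
intervals (UTRs included).  For codon-usage and PAR-CLIP work we
additionally drop ORFs that overlap another ORF by more than 10 bp and
ORFs whose annotated CDS does not begin with ATG or is not a multiple of
3 — the reading frame would be undefined.

Internally the package uses `GRanges` (1-based, closed intervals), the
standard container for genomic intervals in this ecosystem; BED-dialect
input (0-based half-open) is converted on load and a `coords` reader
option declares the dialect of other tables.

Intergenic control regions are built from maximal intervals covered by no
transcript on either strand: every gap of at least 400 bp contributes its
centred 400 bp window, one per gap.  This construction is a declared
choice — the published analyses use a 400 bp intergenic control set whose
exact construction is not specified.

## The codon-usage expectation model

The model asks: given the amino-acid sequence and the synonymous-codon
usage of an ORF class, how many predicted sites do we *expect* on each
strand?

**Universes.** Adjacent amino-acid pairs are drawn from a 440-key
universe: ordered pairs over the 20 amino acids plus a termination symbol
in either (but not both) slots — only this reading yields 400 + 40.  The
termination symbol is allowed combinatorially in both positions even
though biological CDSs realise it only terminally.  A 5-mer can also span
three codons, but only when the middle codon equals the motif's central
trinucleotide; enumeration shows the only such middle codons are GTA and
CTT (valine, leucine) in sense and TAC and AAG (tyrosine, lysine) in
antisense, giving a 4 × 440 = 1760-key triplet universe.  Brute-force
enumeration over every synonymous combination finds 71 pairs that can
host a motif only in sense, 82 only in antisense, 10 in both directions,
and 150 / 210 motif-encoding triplets — `enumerationSummary()` recomputes
all of this in under a second and the test suite checks it against an
independent oracle.

**Span accounting.** A motif occurrence inside a CDS spans either two
codons (all 4-mers, and 5-mers at 6-mer offsets 1–2) or three codons
(5-mers through an eligible middle codon).  Pair terms count the
*number* of surviving motif sites fully contained in the 6-mer after
within-6-mer longest-match suppression — a count, not a 0/1 indicator,
because a 6-mer such as `CTTGTA` holds two non-nested sites.  A
three-codon-spanning 5-mer needs care: it is one site, but under the
longest-match rule it suppresses its two flanking 4-mers — and both of
those are always counted by the adjacent pair terms, since for each
consensus 5-mer the prefix/suffix 4-mers sit at 6-mer offsets where no
same-set 5-mer can contain them.  The triplet term therefore carries a
net contribution of 1 − 2 = −1 per core occurrence.  With this
accounting the pair + triplet decomposition reproduces the scanner's
longest-match count exactly: on model-matched simulations the class-total
expected count equals the class-total observed count to machine
precision, and residuals centre on zero.

**Fitting and expectation.** `fitCodonUsage()` tabulates, per ORF class,
the codon combinations of every adjacent pair (including the terminal
residue–termination pair) and eligible triplet, normalised within each
key.  The expected site count of an ORF is the sum over its pairs and
triplets of the class's per-key expected site count.  A key never
observed in the class falls back to the uniform-synonymous-usage prior
for that key (logged); an explicit pooled model can be supplied instead.
Observed counts for residuals are taken on the CDS only, where the frame
is defined.  The comparison statistic of interest is the *delta*:
expected sites under the ORF's own class usage minus expected sites under
the background (`ORF_CLEAR`) usage — positive when the class's synonymous
choices make motifs more likely than background usage would.

**Estimator variance.** Because the fitted per-key frequencies make the
class-total expected count identically equal to the class-total realised
count, the class mean of the delta equals (realised total − background
prediction) / n.  Its sampling standard deviation at a few hundred ORFs
is of order 0.3 sites per ORF even when the generating process is exactly
neutral in that direction; class-mean deltas within roughly ±2 of that
noise floor should not be read as codon-usage signal.  The antisense
separations produced by the default simulation (tens of sites per ORF)
are far above it; sense deltas sit inside it, as the neutral construction
predicts.

**Single-codon comparator.** `fitSingleCodonUsage()` implements the
simpler model with independent per-codon marginals.  On data generated
with independent codons the two models agree; when adjacent codons are
coupled, the pair/triplet model attains a lower sum of squared residuals,
which is why it is the primary model and the single-codon model is kept
only as a comparator.  `residualNormality()` (Anderson–Darling, from
**nortest**) checks that residuals behave like random error.

## Codon adaptation index

`cai()` is the geometric mean of per-codon relative adaptiveness
weights.  The weights ship as a versioned TSV
(`inst/extdata/cai_weights_sharp_li_1987_sc.tsv`) holding the Sharp & Li
(1987) *S. cerevisiae* reference values, with the preferred codon of each
amino acid at weight 1; the code never hardcodes them.  Following the
same convention, termination codons and the non-degenerate ATG and TGG
are excluded from the mean.  The test suite cross-checks `cai()` against
the independent **seqinr** implementation to full numerical precision.

## Metagene profiles and PAR-CLIP occupancy

Density profiles average predicted-site counts in 10 bp bins across
±400 bp of the start or stop codon.  The stop-codon anchor places `r
= 0` at the first base after the CDS, so bins `[-400, 0)` are the last
400 bp of coding sequence.  Each bin is normalised by the number of ORFs
able to contribute: for body bins, ORFs whose coding region covers the
whole bin (the denominator therefore never increases deeper into the
body); for flank bins, ORFs with chromosome sequence under the whole bin.
Boxplot-style window counts (`countWindow()`) return `NA` for ORFs whose
window does not fit rather than mixing truncated windows into the
distribution.

PAR-CLIP occupancy uses read midpoints, `floor((start + end)/2)` in
0-based terms, binned identically; each ORF's binned counts are divided
by its strand-appropriate expression level (the mean of 5 bp expression
windows overlapping the ORF) before averaging.  ORF/strand combinations
with expression below `exprFloor` (default 1e-6) are skipped — unbounded
ratios are worse than a slightly smaller class.  Upstream read cleaning
and alignment are out of scope: the loader consumes BED6 alignments (or
BAM via **Rsamtools**) and skips unmapped records.  Intergenic occupancy
pools both strands for counts and expression alike.

## What the synthetic generator emulates

`makeDataset()` builds a chromosome of interleaved ORFs (random strand,
yeast-like lognormal protein lengths around 330 codons, 38% GC background,
UTRs of 20–100 / 50–150 bp), plants an antisense CUT or SUT over the 3'
end of every CUT/SUT-class ORF (overlap 100–250 bp, always clearing the
classification threshold; total ncRNA length always ≥ 200 bp so the
length filter never removes it), writes a strand-resolved 5 bp expression
track, and draws read midpoints.  All randomness flows from the single
`seed`; the caller's RNG state is restored afterwards, and one seed
reproduces every emitted file byte-identically.

**Class codon usage.** All classes share one protein model and uniform
synonymous marginals.  The class difference is imposed by Metropolis
synonymous re-sampling: proposed synonymous swaps are accepted with
probability `min(1, coupling^d)` where `d` is the change in antisense
motif count, and any swap that would change a *sense* motif count at an
affected junction or triplet core is rejected outright.  CUT-like ORFs
use coupling 3 (antisense-enriched), SUT-like 1/3 (depleted).  This
construction preserves each CDS's sense-motif decomposition exactly and
leaves amino-acid spectra identical across classes by construction — the
configuration the codon-usage analysis is designed to detect.  An earlier
marginal-bias mechanism (up-weighting antisense-prone codons such as CTA,
TTA, TAC, AAG) is retained in `codonUsageParams()` for sensitivity work,
but it inevitably bleeds into sense encoding and is not the default.

**Reads.** Midpoints are generated in one genome-wide pass per strand:
an expression-proportional background per 10 bp bin plus site-driven
reads Poisson-placed exactly at each predicted site at a rate
proportional to the local expression — emulating PAR-CLIP crosslink
pile-ups at bound sites.  Inside an ORF this realises the intended law
"antisense reads ∝ expression × (1 + antisense site count)".  A single
pass guarantees no region is generated twice where metagene windows of
neighbouring genes overlap.

**Validating normalization.** Checking that expression normalisation
recovers the density landscape via a profile correlation needs the
density signal to stand above per-bin counting noise; with ~80 profile
bins the per-bin standard error must sit well below the body-versus-flank
density contrast.  `occupancyValidationConfig()` therefore commits to a
dedicated high-contrast configuration — 300 CUT-like ORFs at coupling 8,
expression on a common scale inside and outside transcripts so the
normalised profile is linear in (1 + density) across the whole window,
and a deep library (~4 × 10^5 midpoints).  The scale-invariance property
(doubling reads and expression jointly leaves the profile unchanged) is
exact and is tested separately at machine precision.

**What the generator does not emulate.** Chromatin structure and
nucleosome-free regions, read-length and sequencing-error models,
UTR-specific codon-independent motif biases, introns (ORFs with
discontinuous CDSs are excluded from codon analyses in real annotations),
overlapping genes beyond the 10 bp tolerance, and tiling-array
background-subtraction artefacts in the expression track.  Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
recoverability of the encoded biases, not biological effect sizes:
simulated couplings produce antisense deltas of tens of sites per ORF,
an order of magnitude beyond the subtle shifts in real genomes.

## Numerical and design choices

* Coordinates: `GRanges` 1-based closed internally; BED input converted
  on load; the transcript-table dialect is a reader option.
* Ties and degenerate input: the Wilcoxon comparison uses the normal
  approximation with continuity correction (conventional for tied count
  data) and returns p = 1 with a warning on all-tied input; the
  Anderson–Darling test refuses constant samples and n < 8.
* `cai()` errors on non-positive or missing weights rather than flooring.
* CDS validation failures (no ATG, internal stop, frame) exclude an ORF
  from codon analyses with a logged reason; interval analyses keep it.
* Problem sizes in the validation suite: the standard recovery simulation
  uses 300/150/150 CLEAR/CUT/SUT ORFs; scanner oracle checks use 1000
  random kilobases; the occupancy check uses the dedicated configuration
  above.  These sizes give the checks their intended statistical power
  while keeping the full suite to a few minutes.
* The pipeline's orchestration is exposed as functions
  (`runPipeline()`, `enumerationSummary()`, `pipelineReport()`); a thin
  command-line wrapper ships in `inst/scripts/antisense-pipeline.R` for
  shell use.  Configuration files are flat `key=value` documents;
  explicit arguments override file values.

## Known limitations

* The triplet term's −1 net accounting is exact for the canonical
  Nrd1/Nab3 motif sets (whose 4-mers are substrings of their 5-mers);
  custom motif sets without that nesting structure would need their own
  cross-span accounting.
* Genome-scale reproduction of published statistics requires the sacCer2
  genome and the Xu et al. transcript annotation, which are not
  redistributed; the genome-scale test checks those numbers only when a
  local copy is supplied (option `antisenseMotifs.sacCer2`).
* The class-mean delta estimator's noise floor (above) limits how small a
  real codon-usage effect can be certified at a few hundred ORFs.

## Session info

```{r}
sessionInfo()
```
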