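---
title: "venomtx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{venomtx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtx)
```

## The problem

Spider venom glands express peptide toxins as precursors: a secretory
signal peptide, often a short acidic propeptide, and a cysteine-rich mature
peptide that is released during exocytosis, sometimes with a C-terminal
amide. Venom-gland cDNA libraries and transcriptome assemblies are a cheap
window on this diversity: a few hundred single-pass reads (ESTs) typically
cover the high-copy toxin transcripts, and each precursor can be decoded to
a predicted mature peptide, its cysteine scaffold and its theoretical mass
— which can in turn be cross-checked against MALDI-TOF peaks measured from
chromatographic fractions of the actual venom.

`venomtx` implements this decoding pipeline end to end, together with a
synthetic library generator that plants known precursors so every stage can
be validated against ground truth.

## Pipeline stages and their models

### Quality control

An EST passes QC when its insert is *strictly* longer than `qc_min_len`
(default 300 nt). The filter assumes vector and adapter have been removed
upstream: cloning-site context is library chemistry, not analysis, so the
package only optionally trims a user-supplied flanking-motif pair.

### Translation and annotation

All six reading frames are scanned. Open reading frames are
methionine-to-stop, or open-ended at either sequence terminus so that 5'-
and 3'-truncated fragments still contribute their partial protein. Codons
containing an undetermined base are never called: an ORF that would span
one is discarded rather than fabricating residues.

Each ORF is aligned against a bundled reference protein set by
Smith–Waterman (BLOSUM62, gap open 11, extend 1 — the de-facto standard
for protein database search). The EST inherits the category of the
best-scoring hit whose e-value passes the cutoff (default `1e-5`);
otherwise it is a no-match. Ties on score prefer a methionine-started ORF,
then higher identity, then the lexicographically first reference id, so
annotation is deterministic. When several ORFs of one EST pass the cutoff
the best-scoring one wins and the record is flagged, since the resolution
of multi-ORF conflicts is genuinely ambiguous.

E-values use the Karlin–Altschul form `E = K · m · n · exp(-λ·S)`. Because
the alignment engine is not BLAST, λ and K were fitted once by the method
of moments against an empirical null of 600 locally aligned
shuffled-composition protein pairs (120 aa × 120 aa), giving λ = 0.2968,
K = 0.0618 — close to the published gapped BLOSUM62 values. The fitted
constants are frozen in the package so results do not drift.

The bundled reference set is deliberately small and ships with the
package: thirteen synthetic toxin exemplars (one per family scaffold,
constructed to be mutually below 22% global identity so they cannot blur
family boundaries), the two real mature toxin sequences determined
chemically (Edman degradation plus mass matching), and ten synthetic
housekeeping exemplars. It stands in for a large public protein database;
swapping in a custom FASTA with `category=` header tags is supported.

### Clustering

ESTs of one category are grouped by single-linkage under "best local
nucleotide alignment spans ≥ 100 nt at ≥ 95% identity". Single linkage is
the transitive closure a chain of overlapping fragments needs; 95% merges
natural mutants that differ by a few substitutions while separating
paralogous genes, whose independently drifted codons fall far below it.
Exact duplicates are collapsed first and candidate pairs are pre-screened
by a shared informative 15-mer (poly-A and other low-complexity words
excluded); any pair that can reach the linkage thresholds shares many
exact words, so the screen prunes hopeless alignments only.

Within a contig, *unique genes* are distinct nucleotide sequences after
poly-A trimming and *unique proteins* are distinct predicted precursor
proteins. Under this operational reading the gap between the two counts is
exactly synonymous variation, which is what the count pair is meant to
expose; the definitions are recorded in output metadata rather than
asserted as the only possible reading.

### Precursor segmentation

*Signal peptide.* Neural predictors are out of scope, so the package uses
an explicit two-feature score: the length of the hydrophobic core (longest
run of residues in positions 4–18 whose 3-residue Kyte–Doolittle window
average is ≥ 1.6) plus bonuses for small residues (A/G/S/C/T) at the −1
and −3 positions of a candidate cut, constrained to positions 15–35.
Candidates below a score of 7 (no credible core) give no call. The −1/−3
small-residue rule is the classical signal-peptidase constraint; the
earliest position wins ties so the call is deterministic. Users with
cleavage sites from an external predictor can pass them via
`signal_override`, which takes precedence.

*Propeptide.* The propeptide–mature boundary follows the processing
quadruplet motif: a four-residue motif ending in arginine with at least
one acidic residue among the three preceding positions. The scan accepts
both E and D as the acidic partner by default (switchable to E only, since
the literature motif is glutamate-enriched), considers at most
`max_pro_len = 40` residues, and takes the *latest* qualifying arginine
before the first cysteine — cutting into the cysteine scaffold is never
allowed. Absence of a qualifying arginine means no propeptide, which is a
legitimate family feature, not an error.

*Amidation.* A terminal `G`, `GK`, `GR` or `GKR` is an amidation signal:
the glycine is the amide donor and trailing K/R are excision residues. The
tail is stripped (longest form first) and the preceding residue becomes
the amidated C-terminus. Stripping is idempotent by construction because
mature peptides ending in a bare amidation-like motif are exactly what the
signal is.

*Completeness.* Met-start plus stop codon is full length; a missing stop
is a 3'-truncation; a missing start is an N-truncation unless the ORF
opens essentially at the cysteine scaffold (first cysteine within 12
residues), which is reported as mature-only. Premature stops and
stop-codon readthrough cannot be seen from one sequence alone, so they are
flagged contig-relative: a member whose protein is a proper prefix of the
contig's modal protein (≥ 4 residues shorter) carries a premature stop,
and a member extending the modal protein a readthrough.

### Cysteine frameworks and disulfide templates

The framework of a mature peptide is its ordered cysteine positions
written in adjacency notation: sequence-adjacent cysteines are juxtaposed
(`C3C4`), all others dash-separated. Template assignment keys on the full
notation, not the cysteine count, because two 10-cysteine frameworks with
different spacing patterns carry different connectivities. The bundled
registry holds the inhibitor-cystine-knot 6-cysteine mode (C1–C4, C2–C5,
C3–C6), the Kunitz and disulfide-directed β-hairpin 6-cysteine modes, an
MIT1-like 10-cysteine mode (C1–C4, C2–C5, C3–C7, C6–C9, C8–C10), a second
10-cysteine mode (C1–C7, C2–C8, C3–C6, C4–C10, C5–C9) and an ICK-like
8-cysteine mode (C1–C4, C2–C5, C3–C8, C6–C7). Two design points: the plain
`C1-C2-C3-C4-C5-C6` notation is shared by the Kunitz and DDH
connectivities, which adjacency alone cannot distinguish, so it is
assigned to neither — connectivity is never guessed; and odd cysteine
counts yield no template plus an unpaired-cysteine note.

Framework distance — used to let homology evidence cross a single
framework perturbation such as a lost cysteine — is the Levenshtein
distance between adjacency signatures plus the difference in cysteine
counts; both parts are metrics, so the sum is one.

### Family grouping

Families are single-linkage clusters under "global identity ≥ 40%, or
≥ 25% with framework distance ≤ 1". The strict threshold alone groups
obvious homologs; the relaxed arm lets a shared scaffold support weaker
sequence evidence, mirroring how such families are drawn by hand. Both
thresholds are configuration-exposed and recorded in the run summary, and
inputs are canonically sorted before linkage so the partition cannot
depend on input order. Family labels (A, B, …) are positional —
descending family size, then first-member name — and claim no
correspondence to any published family lettering.

### Masses and peak matching

Theoretical masses are residue sums plus water, minus 2 × 1.00794 Da per
disulfide bond and 0.98476 Da for a C-terminal amide (average scale; the
monoisotopic analogues are carried in parallel). Average masses are the
default because linear-mode MALDI-TOF of unresolved isotope envelopes
reports average mass. The disulfide count defaults to the assigned
template's pair count, falling back to `floor(n_cys / 2)`.

Peaks are interpreted both as singly protonated (`M = m/z − 1.00728`) and
as doubly protonated printed at half mass (`M = 2·m/z − 2·1.00728`); all
pairings within the tolerance (default 2 Da, linear-mode accuracy) are
reported, best error first. Edman-prefix identification matches a
chemically sequenced N-terminal prefix against the mature peptides
(exactly, falling back to at most one mismatch) and cross-checks each
candidate's theoretical mass against the observed one.

## The synthetic library generator

The generator emits what the pipeline expects to decode, with every
ground-truth fact in a manifest:

* toxin precursor cDNAs: `5'UTR + ATG`, a planted signal peptide
  (charged n-region, 9–12 residue hydrophobic core, small residues at
  −3/−1), optionally a propeptide ending in a qualifying quadruplet
  motif, a mature peptide whose cysteines realize a family scaffold, an
  amidation tail, `TGA`, an in-frame-stop-bearing 3'UTR and a poly-A
  tail; codons are drawn uniformly over synonymous sets;
* cellular transcripts reverse-translated from diverged housekeeping
  exemplars, and no-match transcripts made by composition-preserving
  codon shuffling of housekeeping genes — a harder negative control than
  uniform random sequence;
* copy-number skew by Zipf weights (exponent 1.2) over genes, so most
  toxin ESTs fall in multi-member contigs, with every planted family
  represented at least once;
* per-copy noise: point mutations (default 0.001 per nt, matching
  libraries where family members are natural mutants differing by a few
  residues), rare cysteine loss (0.02), premature stop gain (0.005) and
  stop-codon readthrough (0.005, TGA→CGA), 5'/3' fragmentation (0.05)
  and short transcriptome-style fragments (0.05);
* per-fraction peak lists carrying the planted mature masses as M+H⁺ (a
  random 30% also as (M+2H⁺)/2) plus uniform noise peaks in the
  1–10 kDa acquisition window.

Default proportions are 0.54 / 0.26 / 0.20 toxin / cellular / no-match
over 1000 transcripts, and 3'UTR lengths are drawn so cDNAs average
roughly 0.5 kb — the scale of a real venom-gland library. Two generator
constraints are worth stating plainly. First, matures never contain
arginine before the first cysteine and un-amidated matures never end in
G/K/R, so the planted truth is unambiguous under the package's own rules;
real data does not honor such guarantees, which is precisely why the
segmentation heuristics remain heuristics there. Second, family seeds and
paralogous genes are drawn with rejection until every cross-family mature
pair sits below 22% global identity — families are planted as separable
groups, since for short cysteine-rich peptides the global-identity
statistic is noisy enough that unconstrained draws occasionally straddle
the 25% relaxed linkage threshold.

What passing the synthetic suite shows, and what it does not: it
demonstrates that every rule is implemented exactly and that the pipeline
inverts the generative model it was built against, including under
realistic noise. It does not certify the signal-peptide heuristic or the
family thresholds against real venom-gland data, where signal peptides,
propeptides and family boundaries are messier than any generative model.

## Validation problem sizes

The test suite checks alignment scores against an exhaustive affine-gap
dynamic-programming oracle on peptides up to 30 aa, clustering against an
all-pairs union-find oracle on libraries of up to 50 sequences, ORF
finding against a brute-force six-frame scanner on sequences up to 3 kb,
and end-to-end parameter recovery on generated libraries of 1000
transcripts (with a 400-transcript zero-noise library for exact family
partition recovery). Signal-peptide recovery rates are estimated over 500
generated precursors.

## Known limitations

* The signal-peptide rule is a transparent approximation, not a trained
  predictor; the `signal_override` import path exists for exactly that
  reason.
* Disulfide connectivity comes from notation templates only; no
  structural or energetic validation is attempted, and ambiguous
  notations stay unassigned.
* The e-value calibration assumes typical globular composition; strongly
  biased queries (e.g. poly-acidic propeptides) are handled by the
  alignment score itself, not by composition-adjusted statistics.
* Consensus sequences of contigs are representative members (the longest),
  not base-called consensi; trace qualities are out of scope.
* Peak matching reports all within-tolerance interpretations; it does not
  deconvolve overlapping peaks or model isotope envelopes, and fragment
  hypotheses (subsequence masses) are not generated.
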