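---
title: "Homology-based miRNA discovery in genomic survey reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based miRNA discovery in genomic survey reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsurvey)
```

## The problem

Conserved plant microRNAs can be predicted directly from genomic sequence:
a known mature miRNA from a related species is located on genomic reads by
sequence similarity, and each matching locus is then vetted by asking
whether its surrounding sequence can fold into a pre-miRNA stem-loop in
which the mature sits in one arm of a near-complementary duplex with its
star strand. This two-stage homology-plus-structure strategy is the
standard route for surveying miRNA content in large, unassembled genomes
(for example chromosome-arm survey sequencing of bread wheat), where no
small-RNA expression libraries are available and assembly is impractical.

`mirsurvey` implements the full desk-side pipeline: mismatch-bounded
homology search, hairpin folding and validation, representation counting,
repeat-overlap classification, and EST/protein evidence filtering —
together with a seeded synthetic-data generator so that every stage can be
tested against known ground truth without any external downloads.

## Homology search

Mature plant miRNAs are 18–26 nt. At these lengths a gapped local
alignment adds nothing over ungapped full-length comparison, and the
published screening rule is phrased purely as a mismatch cap, so the
search is defined exactly: a hit is any full-length placement of the
mature query on either strand of a read with Hamming distance at most
`max_mismatches` (default 3; `max_mismatches = 0` reproduces the strict
mode used for cross-species synteny scans). Positions carrying `N` on
either side never match — the conservative choice for survey-quality
reads. Indel-containing homologs are out of scope by design; this makes
the mismatch rule exact and testable against a brute-force oracle.

The implementation seeds with exact words (default length 7). A query of
length $L$ searched at mismatch budget $k$ is split into $k+1$ disjoint
blocks of length $\lfloor L/(k+1)\rfloor$; by pigeonhole at least one
block is exact in any surviving placement, so seeds of length
$\min(7, \lfloor L/(k+1)\rfloor)$ taken at the block starts can never
produce a false negative. The test suite asserts set equality between
this seeded search and an independent sliding-window scan across random
instances at every budget in $\{0,1,2,3\}$.

BLAST-style e-values and complexity filtering are not modeled: at these
query lengths, with the dust filter off and a permissive e-value, the
operative filter in the original screen is the mismatch cap alone.

## Folding engine

Candidate reads are folded with a deterministic Zuker-style dynamic
program over a loop-based nearest-neighbor model:

* a 6×6 stacking-energy table over the canonical pairs (Watson–Crick and
  G–U wobble), with published-style values in kcal/mol;
* affine hairpin penalties, `4.5 + 0.25 (s − 3)` kcal/mol for loop size
  `s` (minimum 3 nt);
* affine interior/bulge penalties, `2.0 + 0.3 s`, capped at 30 unpaired
  nt (larger interior loops are disallowed, as in standard
  implementations — this cap is part of the model definition);
* a linear multibranch term `4.6 + 0.4 b + 0.1 u` for `b` helices and `u`
  unpaired nucleotides in the loop;
* no dangling ends, coaxial stacking, or terminal-pair corrections; `N`
  never pairs.

All arithmetic is done in integer tenths of kcal/mol, so minimum free
energies are bit-reproducible across platforms and can be compared for
*exact* equality with an independent exhaustive enumeration of all
pseudoknot-free structures on short sequences — the strongest oracle
available, and one of the package's acceptance checks (200 random
sequences up to 16 nt per run).

Among co-optimal structures the traceback applies a fixed preference
order: stacking/interior continuations are examined before hairpin
closure and multibranch decomposition, smaller indices first. This is a
deterministic tie-break; it does not attempt to find the globally
lexicographically smallest dot-bracket string, which would require
comparing complete continuations at every branch point. Identical inputs
always produce identical structures.

The engine is pluggable: `fold()` accepts any function implementing the
`(sequence, params) -> list(structure, mfe)` contract, and all downstream
criteria consume only the returned structure and energy. Energy-level
parity with any specific external thermodynamic package is explicitly not
promised; the shipped parameter set is the package's own versioned model
(`mirsurvey-nn-1`).

## Hairpin validation

For each hit the whole read is folded (minus-strand hits on the reverse
complement, so the mature always appears in sense). Validation then
mirrors the classical screen:

1. **Duplex location.** The star region is the span of positions paired
   with the mature, extended across interior loops and bulges. *Star
   mismatches* count the mature positions left unpaired in the structure
   (bulged or mismatched, one each) — the only per-nucleotide mismatch
   notion a dot-bracket supports, and the interpretation consistent with
   standard miRNA annotation practice. A hit whose mature is entirely
   unpaired has no duplex and is rejected.
2. **Duplex mismatch cap.** Candidates with more than
   `max_star_mismatches` (default 6) unpaired mature positions are
   removed. The screen applies both to the whole-read fold and to the
   re-fold of the trimmed precursor.
3. **Trimming and re-folding.** The precursor is the smallest interval
   bounded by the outermost base pair of the stem containing the
   mature:star duplex, found by ascending the pairing tree while each
   enclosing loop carries a single helix; the trimmed sequence is
   re-folded and all criteria re-evaluated on the re-fold. The precursor
   interval is widened, if necessary, to contain the full mature.
4. **Single-arm placement.** Mature positions inside a terminal hairpin
   loop beyond `max_mature_loop_overlap` (default 0) disqualify the
   candidate.
5. **Multibranch exclusion.** A multibranch loop closed inside the
   mature:star span disqualifies the candidate. Historically this
   elimination was done manually; here it is automated, with
   `keep_flagged` retaining flagged rows in written tables for human
   review.
6. **MFEI.** For the trimmed precursor the pipeline reports MFE (ΔG,
   kcal/mol), GC%, AMFE (`|MFE|/length × 100`) and MFEI (`AMFE / GC%`).
   The MFEI threshold 0.67 — above the characterized levels of tRNA
   (0.64), rRNA (0.59) and mRNA (0.62–0.66) — is *report-only by
   default*: candidates below it are flagged `low_mfei` but kept, because
   the survey literature reports a minimum accepted MFEI rather than
   stating a hard filter. `enforce_mfei = TRUE` makes it disqualifying.

Every rejection is data, not an error: each candidate row carries
`accepted` and a machine-readable `reject_reason`. When several
placements of one miRNA land on one read, the accepted candidate with the
lowest re-folded MFE wins (ties: leftmost precursor start), which keeps
tables deterministic.

Coordinates are 1-based inclusive throughout — internally and in files —
following R and Bioconductor convention, so there is no conversion layer
between the two.

## Post-processing

**Representation.** The number of distinct candidate loci per family per
sequence set, after collapsing identical hits: by byte-identical precursor
sequence (default) or by read identity — the published description
("identical hits … removed") is ambiguous between the two, so both keys
are exposed. Families present in two or more sets are labeled shared,
otherwise set-specific; the labels partition the family list.

**Repeat overlap.** A candidate is repeat-associated when its precursor
interval overlaps a masked interval from a RepeatMasker-style `.out`
table by ≥ 1 nt — the least-assumption rule, with the overlap fraction
reported so stricter thresholds can be applied downstream. Class
composition summaries follow the Class I retroelement / Class II DNA
transposon split.

**EST evidence.** ESTs aligned to a precursor at query coverage ≥ 99%
and identity ≥ 98% (both inclusive, as printed in the source thresholds)
count as transcription evidence, unless the EST also matches a protein at
e ≤ 10⁻³, in which case it is treated as protein-coding and eliminated.
The package consumes pre-computed tabular alignment results; running the
aligners themselves is out of scope.

## The synthetic-data generator

`generate_fixture()` emulates the study's inputs at desk scale:

* **Reads**: lengths drawn from normal(350, 50) truncated to [100, 600] nt
  (454-style), background composition from an order-1 Markov chain at a
  configurable GC fraction (default 0.44, wheat-like) with mild
  homopolymer persistence.
* **Implants**: 10 synthetic families at copy numbers 1…10 by default.
  Each copy is a designed precursor — A/C unpairable tails, a loop-distal
  stem extension, the mature, a GC-rich loop-side extension, an 8-nt
  terminal loop, and the star — embedded at a seeded random position and
  strand with unique flanks, so every copy is a distinct locus. Designed
  star mismatches use substitutions that can pair with neither the mature
  base nor its wobble partner, and the GC-rich loop-side extension
  anchors the duplex register so each designed mismatch reliably leaves
  exactly one mature position unpaired.
* **Decoys** map one-to-one to rejection reasons: `mismatch_overflow`
  (8 designed star mismatches, validated to leave ≥ 8 mature positions
  unpaired in the folded precursor, failing the ≤ 6 cap), `multibranch`
  (two GC-rich stems inserted between mature and star), and `shuffle`
  (the hairpin context dinucleotide-shuffled around an intact mature, an
  Altschul–Erickson Eulerian-walk shuffle preserving mono- and
  dinucleotide counts). Because the read context is random, it can
  occasionally hand the mature an alternative duplex (register slips can
  rescue an edited star; random flanks can substitute for it; two random
  side hairpins can merge into one stem), so the generator *certifies*
  each emitted overflow and multibranch read against its designed
  rejection reason — classifying that single read and redrawing the
  random context until the designed outcome is realized — which keeps
  the emitted ground truth consistent with the emitted sequences by
  construction. Shuffled decoys are deliberately not certified: they are
  *statistical* controls — a shuffle occasionally refolds into a passable
  hairpin, which is exactly why MFEI is assessed against the median of
  shuffled controls rather than case by case.
* Generated matures are drawn at GC 0.5 with a guard against
  quasi-palindromes (Hamming distance to their own reverse complement
  ≥ 12), since a near-palindromic query would legitimately match its own
  star site within the mismatch budget and blur the designed ground
  truth. Caller-supplied mature sequences bypass this guard.
* **Repeats**: a MITE-like palindromic motif (18-nt arm + spacer +
  reverse complement) recurs across a third of background reads and is
  emitted in RepeatMasker-out layout, mimicking how transposon termini
  fold into hairpin-like decoys; implants flagged `in_repeat` are
  annotated as masked.
* **Evidence tables** cover the retained/eliminated cases of the EST
  filter, with the designed outcome recorded.

Everything derives from one seed; regeneration is byte-identical, which
the tests check by hashing every emitted file.

What the generator does *not* emulate: 454 homopolymer error profiles,
realistic transposon landscapes, genuine miRNA sequence biases, or
assembly chimeras. Passing the fixture suite therefore demonstrates the
*logic* of the pipeline — recall of true hairpins, rejection reasons,
count bookkeeping — not calibrated performance on real survey data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the folding oracle on 200
random sequences of length ≤ 16 (exhaustive enumeration is exponential,
and 16 nt keeps it exact and fast), the search oracle on 100 instances of
3 reads × 5 queries at every mismatch budget 0–3, and the end-to-end
fixture with 55 implanted loci plus 30 decoys on reads averaging 350 nt.
These sizes exercise every code path while a full run stays in the
minutes range on one core. Reads are folded whole (O(n³) in read length)
and the trimmed precursor re-folded; fold results are cached per read and
orientation.

Degenerate inputs are handled explicitly: empty FASTA files yield empty
tables with a warning; a single-observation `describe_stats()` reports
sd 0 with a `degenerate` flag; GC-0 precursors have undefined MFEI and
fail the MFEI criterion by flag; matures shorter than the seed word are
skipped with a warning; hits without 20 nt of flank on both sides are
rejected as `insufficient_flank` rather than folded.

## Known limitations

* Ungapped matching misses indel-containing homologs by design.
* The internal energy model is a compact nearest-neighbor set, not a
  full Turner-2004 parameterization: energies are realistic in scale and
  exactly reproducible, but not comparable kcal-for-kcal with UNAFold or
  ViennaRNA output. MFEI thresholds behave as expected on designed and
  shuffled fixtures, which is what the desk-scale validation requires.
* `require_full_length = FALSE` (partial-length hits) is not implemented;
  the constructor rejects it.
* Headline counts from any specific chromosome survey (total miRNAs,
  per-arm splits, masked percentages) are not reproducible here: they
  require the original multi-million-read accession and the original
  BLAST/UNAFold/RepeatMasker binaries. The package validates the method,
  at desk scale, by property: oracle equivalence, fixture recovery, and
  threshold boundary behavior.
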