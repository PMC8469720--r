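---
title: "Models and methods behind stwinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stwinscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stwinscan)
```

This vignette records the models, parameter choices and numerical
conventions the package commits to, and what its tests do and do not
establish. It is the place where genuinely open design decisions are argued;
the README shows the user-facing surface.

## 1. The motif grammar

A canonical fungal U2 intron is modelled as three degenerate elements: a
6-nt donor (default `GTRWGY`, the DNA form of the GURWGY consensus), a 6-nt
branch-point (BP) element (default `RCTRAC`, branch A at position 5) and a
3-nt acceptor (default `YAG`), with two distance constraints: total intron
length within 40–600 nt and 4–60 nt between the BP element's end and the
acceptor's start. The donor and acceptor consensus are well established for
fungi; **the BP consensus used by the original stwintron predictors is not
published**, so `RCTRAC` is this package's choice and every pattern and
window is configurable through `intron_model()`. The length window's lower
bound (40 nt) reflects the smallest credible fungal intron; the upper bound
(600 nt) is deliberately generous because each constituent intron of the
complex elements studied here stays around 100 nt.

Parsing uses *intron definition*: fungi with short introns pair a donor with
the BP element that excises the smallest possible intron, so
`find_canonical_introns()` returns, per donor, the minimal-length
satisfying intron (ties resolved toward the leftmost BP, then the leftmost
acceptor). An exhaustive mode returns every satisfying donor/acceptor pair
and is what the brute-force test oracle enumerates.

A (D1,2) stwintron is parsed as: a G (`G1`) immediately followed by a valid
internal-intron donor (`GT…`, or `GC…` when `allow_gc_internal_donor`,
reflecting the occasional 5'-GGC starts); a valid internal intron; the
requirement that `G1` plus the five nucleotides after the internal acceptor
reconstitute a donor; and a valid reconstructed external intron. Per `G1`
the shortest internal intron admitting a valid external intron wins, then
the shortest external intron. Both strands are scanned and reported; a
genuine element is only functional on the coding strand, but without
annotation that strand is unknown, so no reconciliation is attempted at scan
level (the pipeline resolves overlaps later, see §6).

**Coordinates.** All internal coordinates are 1-based and inclusive — the
IRanges/GFF3 convention — so GFF3 emission is the identity on coordinates.
(A 0-based half-open internal convention was considered and rejected: in R,
1-based inclusive indexing is what `substr()` and the Bioconductor stack
use, and a second convention would be a standing source of off-by-one
errors.)

## 2. Alignment

Family collection, TIR detection, crop inference and the seamless check all
rest on one global aligner: Needleman–Wunsch with affine gaps (match +2,
mismatch −1, a gap of length *k* costs 4 + *k*), implemented in C++ with a
fixed traceback preference (diagonal over up over left at equal score).
Percent identity is matches / aligned columns, gaps counting as columns.
The original analyses used BLASTN and Clustal-Omega defaults without
reporting parameters; the scheme above is therefore declared rather than
inherited, and identities reproduced from the literature are expected to
agree only to about ±2 percentage points. The deterministic traceback is a
contract: the same inputs always yield byte-identical alignments, which the
pipeline's double-run test relies on.

With this scheme, unrelated random DNA of the relevant lengths aligns at
roughly 43–49% identity, comfortably below every similarity floor used.

## 3. Family classification

The seed-centric family search admits candidates at ≥55% full-length global
identity to the seed. The published family spans 58–90% identity to its
query, so 55% sits just below the observed spread; it is a package default,
not a measured constant.

`classify_relative()` applies, in order:

1. **full sister** — the element parses as a full-span (D1,2) stwintron,
   global identity ≥55% over ≥80% of the template, *and each template
   section (internal intron; G1 + external remainder) independently clears
   the 55% floor*. The section-wise condition operationalises similarity
   "over the complete width": without it, an element whose internal half is
   conserved and whose external half is unrelated still reaches ~65% global
   identity and would masquerade as a full sister.
2. **cropped type-1 / type-2 / long intron** — the element parses as a
   full-span canonical intron and matches one of the template's three
   derivation products at ≥55% identity over ≥80% coverage; the best match
   wins. Type-2 calls also record the extra-G-before-acceptor subgroup
   attribute observed in a clade of the real type-2 introns.
3. **sheared sister** — the element is a full-span stwintron whose
   similarity is *restricted* to one section: that section's identity ≥60%,
   the other section's identity below the 55% floor, supported by a ≥40-nt
   high-identity alignment block inside the conserved section. A pure
   block-mapping rule (≥80% of a block in one section, <20% in the other)
   was tried first and misfires, because the "unrelated" section of any
   valid stwintron still carries canonical splice motifs and therefore
   never falls to random-sequence identity; section-identity dominance is
   robust to that floor effect.
4. **unrelated** otherwise.

## 4. Symmetry analysis

`find_tir()` aligns a sequence with its own reverse complement. That
alignment is intrinsically symmetric, so only the 5' arm is extracted: the
maximal prefix of columns whose every covering 10-column window reaches 60%
identity, refined to the prefix that maximises the cumulative excess of
matches over the 60% threshold (this stops chance matches in the spacer
from dragging the arm outward), and capped so that the two mirror-image
arms overlap by at most the 10-nt palindrome. The cap matters for type-2
cropped introns, which are essentially one overlapping TIR: without it the
"arm" would be the whole self-alignment. Reported arm identity is computed
over the retained prefix, so trailing mismatch columns are excluded; on
constructed perfect inverted repeats the detector reports the planted arm
length and 100% identity exactly when the spacer cannot chance-pair at the
boundary.

The palindrome scan scores every 10-nt window against `WTTCTAGAAA` and
calls a hit at ≥8 conserved positions (the published ">7 of 10" presence
criterion); overlapping hits are allowed and the W-position base is
recorded (5' copies are typically W=T and perfect, 3' copies W=A).

`duplex_score()` is an explicitly simplified surrogate for co-folding two
debranched intron RNAs: the best gapless antiparallel register of the
sequence against a second copy of itself, +2 per Watson–Crick pair, +1 per
G·U (evaluated as G·T on the DNA representation), normalised by twice the
length. No thermodynamics are computed; published minimum-free-energy
values are out of scope, and the score is only used comparatively (element
versus shuffled control, relative ranking).

## 5. Crop modelling

The type-2 crop implements the MMEJ central-deletion model: the deletion
runs from the end of the 5' palindrome copy through the end of the 3' copy,
the product drops the parental G1 (which becomes exonic — the required
compensatory mutations are reported as a note, never applied, because they
are context-dependent), and the single retained copy is written as the
perfect palindrome at the 5' copy's position. The data cannot distinguish
which copy physically survives; the 5'-position/perfect-sequence convention
is fixed here. Because a deletion between two near-identical repeats is
positionally ambiguous, breakpoints are *canonicalised by maximal right
shift within the microhomology* — both in `predict_type2_crop()` and in
`infer_crop_breakpoints()` — which is what makes the round trip
(predict, then infer from the parent/product pair) exact rather than
correct-up-to-slippage.

Type-1 products are the internal intron verbatim (the external intron,
including G1, is lost, so no frame note). The long-intron path removes only
G1 and additionally assumes degeneration of the internal BP element; the
generator models that by flipping the internal branch A, which also
prevents the internal splice sites from pre-empting the full-span parse.

## 6. The synthetic world

`make_template()` rejection-samples an ancestral element with: arm length
45–55 nt, spacer 90–110 nt (between-arm distance ~100 nt), 5' perfect and
3' W=A palindrome copies at the arm/centre boundaries, all six splice
elements instantiated from the model patterns, and the 3' arm generated as
a mutated reverse complement of the 5' arm topped up to a 27% arm
divergence dial (identities land in the low-to-mid seventies, as observed
for real elements). A candidate template is accepted only if the scanner
parses it as exactly one full-span stwintron with the planted
decomposition, the palindrome scan finds exactly the two planted copies,
the TIR detector reads the planted arm (±5 nt) at ≥70% identity, and all
three derivation products are themselves clean minimal-parse full-span
introns.

`evolve_copy()` applies substitutions and indels uniformly *outside*
protected motif positions (G1, both donors, both BP elements, both
acceptors). Motif protection is on by default because every published
family member is splice-competent. For the same reason the genome builder
additionally rejects evolved copies whose *minimal parse* has shifted away
from the planted coordinates — a mutation that creates a cryptic splice
site inside the element would change the splice product in vivo, so such
copies would not have persisted; this is modelled purifying selection, not
parameter tuning, and it is what makes "recovery with exact coordinates" a
meaningful target.

`build_genome()` plants, by default, the published census — 23 full
sisters, 13 sheared (half internal-, half external-conserved, the
non-conserved section regenerated with freshly instantiated motifs, since a
real sheared sister's other section is unique sequence), 2 type-1, 10
type-2 and 1 long intron — into random-CDS genes carrying 3–4 background
canonical introns each, at uniform-random coding offsets with seamless
insertion (no target-site duplication, no exonic loss). Per-copy divergence
is drawn uniformly from a configurable range (default 0–0.2
substitutions/nt plus 1% indels). Ground truth (category, coordinates,
CDS offset, phase, realised divergence) is recorded for every element.

What the generator does *not* emulate: codon structure and codon usage
(CDS sequence is random), transcription-linked strand asymmetries,
phylogenetic structure among copies (each is an independent draw from the
template), assembly artefacts, and base-composition heterogeneity. A green
end-to-end test therefore establishes that the pipeline recovers planted
elements under the stated noise model, not that it would on any real
assembly.

## 7. Pipeline overlap resolution

The scanner deliberately over-reports: one locus is often reachable from
several upstream candidate donors (giving lower-identity superspans of the
true element), and the elements' symmetry makes reverse-complement
re-detection common. `run_pipeline()` resolves this in two stages:
stwintron calls compete strand-agnostically by identity to their
best-matching reference (tie: tighter span); canonical-intron calls
(pre-filtered to those carrying a palindrome hit) then fill loci without a
positive stwintron call, and may displace an overlapping call classified
`unrelated` — never a positive one. Ranking by match identity alone is what
keeps a full sister from being shadowed by the type-1-like call on its own
internal intron.

## 8. Known limitations

* The BP element consensus is a package default; scanning a genome whose
  introns use a different BP signal requires overriding `intron_model()`.
* Identity values depend on the declared scoring scheme; comparisons with
  Clustal/BLAST-derived figures carry ±2-point slack.
* The duplex and hairpin reasoning is reduced to a complementarity score;
  no secondary-structure prediction is attempted.
* `infer_crop_breakpoints()` reports the single largest deletion; composite
  events (deletion plus nearby duplication, as seen in one published
  element) are classified but not mechanistically decomposed.
* Multiple sequence alignment and phylogenies of family members are out of
  scope; `collect_family()` is seed-centric.
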