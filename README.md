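# stwinscan

Detection and evolutionary analysis of **sister spliceosomal twin introns
(stwintrons)** and the canonical introns derived from them, in fungal genomic
DNA.

## The problem

Stwintrons are complex intervening sequences in which one canonical U2 intron
(the *internal* intron) interrupts a functional element of another (the
*external* intron); they are excised by two consecutive standard splicing
reactions, inside out. In the donor-disrupted **(D1,2)** class the internal
intron splits the external donor between its first and second nucleotide, so
the feature begins 5'-G·GT (occasionally G·GC). In several Hypoxylaceae
fungi, families of (D1,2) stwintrons with high mutual sequence similarity
have proliferated to new, seamlessly integrated coding positions, and have
also given rise to proliferating canonical introns by three derivation
paths:

* **type-1 crop** — loss of the external intron (product = the internal
  intron);
* **type-2 crop** — microhomology-mediated (MMEJ) deletion of the central
  region between two copies of a 10-nt palindrome, 5'-WTTCTAGAAA, fusing the
  internal intron's 5' half to the external intron's 3' half;
* **long intron** — one-step excision of the whole feature minus its leading
  G1, after degeneration of the internal branch-point element.

The least divergent family members carry 45-55-nt **terminal inverted
repeats** (TIRs) overlapping the palindrome copies — a symmetry that may
allow two excised intron RNA molecules to anneal into a duplex, and that
distinguishes these elements from DNA transposons (whose insertion would
leave target-site duplications; none are found).

`stwinscan` re-implements this analysis as a tested pipeline:

| stage | what it does |
|---|---|
| `find_canonical_introns`, `find_d12_stwintrons`, `scan_genome` | degenerate-motif grammar scan (donor `GTRWGY`, BP `RCTRAC`, acceptor `YAG`, all configurable), smallest-intron ("intron definition") parsing |
| `splice_stwintron`, `make_junction_queries` | two-step excision simulation, splinter intermediate, alternative one-step product with exonised G1, 60-nt junction probes |
| `global_align`, `collect_family`, `classify_relative` | affine-gap global alignment (deterministic traceback), seed-centric family collection, classification into full sister / sheared / cropped type-1, type-2 / long intron / unrelated |
| `find_tir`, `find_palindrome_hits`, `duplex_score` | TIR detection by self-reverse-complement alignment, degenerate palindrome scan (>7/10 rule), gapless two-molecule duplex score |
| `predict_type1_crop`, `predict_type2_crop`, `predict_long_intron`, `infer_crop_breakpoints` | the three derivation paths and breakpoint inference for observed parent/derivative pairs |
| `intron_phase`, `tsd_scan`, `seamless_check`, `junction_matrix` | insertion-context analysis and the junction position-frequency matrix |
| `make_template`, `evolve_copy`, `build_genome` | synthetic-genome generator with machine-readable ground truth |
| `run_pipeline` | scan → classify → symmetry → crop orchestration with a JSON summary |

## Worked example

```r
library(stwinscan)

tpl <- make_template(seed = 42)   # ancestral (D1,2) template
print(tpl$stw)
#> (D1,2) stwintron template:1-198 (+)  internal 2-99  external G1=1 + 100-198  centre AGT

find_tir(tpl$seq)
#> TIR: arm 49 nt at 73.5% identity, spacer 100 nt; 2 palindrome hit(s); duplex 0.54

find_palindrome_hits(tpl$seq)
#>   start end matches   observed w_base
#> 1    41  50      10 TTTCTAGAAA      T
#> 2   149 158      10 ATTCTAGAAA      A

ev <- predict_type2_crop(tpl$stw)
#> crop event [type2]: breakpoints 51..158, product 89 nt (valid intron)
#>   [g1_exonised_requires_compensation]

infer_crop_breakpoints(tpl$seq, ev$product)   # exact round trip
#> crop event [type2]: breakpoints 51..158, product 89 nt (valid intron) ...
```

Reading the numbers: the 198-nt template parses as one (D1,2) stwintron
(internal intron at 2-99, reconstructed external intron G1 + 100-198, the
diagnostic `AGT` centre where the two introns overlap by the terminal G).
Its self-reverse-complement alignment shows 49-nt terminal arms at 73.5%
identity separated by a 100-nt spacer, with the perfect 5' palindrome copy
(W=T) inside the internal intron and the imperfect 3' copy (W=A) inside the
external one. The MMEJ model deletes positions 51-158 (one palindrome copy
plus the central region, breakpoints canonically right-shifted within the
microhomology), leaving an 89-nt canonical intron with a single perfect
palindrome; breakpoint inference from the parent/product pair recovers the
deletion exactly.

End to end on a synthetic genome:

```r
g <- build_genome(sim_params(seed = 3, n_genes = 30, n_full_copies = 10,
                             n_sheared = 4, n_type1 = 1, n_type2 = 3,
                             n_long = 1, divergence = c(0, 0.1)))
print(g)
#> synthetic genome: 30 genes (54869 nt), 19 planted elements
#>    cropped_type1    cropped_type2      full_sister      long_intron
#>                1                3               10                1
#> sheared_external sheared_internal
#>                2                2
```

`run_pipeline()` on that genome recovers exactly these category counts (see
`tests/testthat/test-pipeline.R`).

A command-line front end covering
`scan | splice | family | symmetry | crop | simulate | run` is installed at
`inst/cli/stwinscan.R`.

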