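---
title: "Retargeting single-stranded DNA transposons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retargeting single-stranded DNA transposons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peelpaste)
```

This vignette documents the models behind `peelpaste`: what is computed, why
the defaults are what they are, what the synthetic fixtures do and do not
emulate, and where the package's conclusions stop.

## Coordinate conventions

Transposon-end positions are 1-based on the top strand written 5′→3′ and
referred to with a `+` prefix (`+16…+19` guide G_L, `+20…+41` subterminal
palindrome IP_L, `+42`/`+43` triplet-forming bases, `+44` onward the
engineerable extension, `+46…+60` the second hairpin). Target-oligo
positions are cleavage-relative: the C_T tetranucleotide occupies −4…−1 and
cleavage falls between −1 and +1. Genome coordinates in BED output are
0-based half-open. These conventions keep the package's labels aligned with
how the positions are named in the IS*608* literature while producing
interoperable genome output.

## The design model

`design_extension()` writes the reverse complement of the target window into
LE positions +44…+(43+L). The window sits `linker_len` nucleotides upstream
of C_T, so with the defaults (L = 8, linker = 3) the window is target
−15…−8 and the register pairs LE +44 with target −8, proceeding
antiparallel. The total specifically recognized site is `4 + L` nt.

Three numerical choices matter:

* **Linker = 3 nt (allowed 2–5, warning away from 3).** The duplex must
  reach from the extension to the cleavage site without strain; in the
  capture complex the target 5′ terminus (−5) lies 10.5 Å from the +44
  phosphate, and a 3-nt linker supported cleavage best experimentally. The
  register anchor (+44 against −(linker+5)) follows directly.
* **Extension length 8–13 (5–7 accepted with a warning).** Eight contiguous
  base pairs are the shortest demonstrated selective length; five gave no
  selection; thirteen is the longest demonstrated, so longer extensions are
  refused rather than extrapolated.
* **C_T resetting** is restricted to target positions −4 and −3, the two
  positions with structure-assigned guide partners (+17 and +16). Which
  guide base, if any, reads −2 or −1 is not established, so those positions
  are not guessable defaults; `gl_ct_map()` lets a user extend the map
  explicitly at their own risk. Whether +43 should co-vary when its triplet
  partner changes is likewise unresolved; the package leaves +43 fixed.

## The folding model

`fold()` maximizes total pair weight over nested pairings (AT = 2, GC = 3,
G:T wobble 1 when enabled, minimum loop 3). A full nearest-neighbor energy
model would be overkill here: the biology enters only through qualitative
questions — does a hairpin cover a window, is a window unpaired — and a
weighted pair-maximization answers those deterministically and testably
(the dynamic program is verified against exhaustive enumeration in the test
suite). Two conventions make the model usable:

* **No lonely pairs (`min_helix = 2`).** Under pure pair maximization every
  base with any complementary partner pairs somewhere, so single isolated
  pairs would dominate accessibility estimates of A/T-rich single strands.
  Requiring at least two stacked pairs per helix — the usual convention in
  secondary-structure prediction — restores the intended qualitative
  behaviour. Set `min_helix = 1` for the textbook recursion.
* **Deterministic tie-breaking.** Among co-optimal structures the traceback
  closes the 5′-most pair first and extends the current helix on ties, so
  identical inputs always give identical structures.

G:T wobble is off by default because the hairpins of the left end are
canonical; enabling it can only increase the optimal score (a property the
tests assert). The triplet-forming +42/+43 bases fold freely in the free
single strand: they are only engaged in triplets within the protein
complex, and the free-strand fold is what occludes or exposes the extension.

`accessibility()` reports the unpaired fraction of a window. A design's
extension is considered retargeting-competent at ≥ 0.9 — for an 8-nt window
this means fully unpaired. The strict cutoff mirrors the all-or-nothing
behaviour of hairpin manipulation in vitro: an extension is either free to
nucleate a duplex or it is not.

## Structural unlocking

`apply_structural_unlocking()` first sets +42 to T (T-A:T triplets are more
stable than A-A:T and the smaller base removes steric constraint), then, if
the extension window folds below threshold, greedily introduces single-base
substitutions confined to +55…+60 — the experimentally mutable window on the
hairpin's 3′ arm — refolding after each edit, transversions tried first,
positions scanned 5′→3′, up to `max_mut = 6` edits (enough to erase the
whole 6-bp fixture stem). G_L, IP_L, +43 and the extension itself are never
touched, so the positional diff of unlocking is always confined to
{+42} ∪ [+55, +60]. If the threshold is unreachable the design is returned
with `unlocking$pass = FALSE` and the best structure found — a reportable
design failure, not an exception, because some windows genuinely cannot be
freed by 3′-arm edits alone (their extensions pair elsewhere in the
junction); `validate_design()` then reports exactly that.

## The competition model

Predicted integration weights multiply three factors:

* `rel_conc`, the member's molar concentration;
* `plus1_weight`, an ordinal encoding of the +1 base preference
  (C = 1.0, T = 0.5, A = G = 0.15). These are gel-class conventions — C
  rescues poor targets and purines are disfavored by the tight +1 pocket —
  not measured rates; only their order is meaningful.
* `coop(m)`, a Hill curve over the longest contiguous run of correct
  Watson–Crick pairs between extension and target
  (`floor = 1`, `amp = 60`, `K = 6.8`, `h = 12`).

The Hill form is forced by the data it encodes: a per-base multiplicative
model cannot simultaneously make 5 matches worthless and 8 matches dominant
at 20-fold competitor excess. The shipped parameters satisfy
`coop(8)/coop(0) ≈ 53 ≥ 40` and `coop(5)/coop(0) ≈ 2.4 ≤ 3`; both
constraints are re-validated whenever a configuration loads, so a user
cannot silently ship an uncalibrated model. Contiguous run length (not
total matches) is used because pairing nucleates as a continuous duplex in
the register; non-contiguous partial complementarity is untested in vitro
and deliberately not modelled. Off-target scans flag sites with
`match_len ≥ 8` and +1 = C as high-risk — the demonstrated selective length
combined with the preferred cleavage context.

## Synthetic fixtures

All tests and the acceptance computation run on seeded synthetic sequences
that reproduce the published *architecture* without the (supplementary-only)
wild-type sequence: G_L = AAAG at +16…+19, a perfect 9-bp/4-nt-loop
palindrome at +20…+41, A/T at +42/+43, and optionally a 6-bp/3-nt-loop
second hairpin whose fold-detected span covers +46…+60. Stems are drawn
over G/C and filler over A, which keeps the maximum-weight fold on the
intended structure; each generator verifies its structural postconditions
with `fold()` and deterministically resamples until they hold. The
canonical assay junction places the joint cleavage motif so the 5′ labeled
segment is exactly 50 nt; complementary and random targets carry 38-nt and
30-nt 3′ segments so products resolve on a virtual gel; donors embed the
element between flanks ending in C_L (TTAC) and C_R (TCAA) drawn over a
T-free alphabet so the planted motifs are provably unique.

`make_target_locus()` additionally emulates the experimental practice of
choosing workable junction/target pairs: it draws candidate windows and
keeps the first whose finished design passes validation. Consequently,
passing tests show that the pipeline is internally consistent on designable
sites — they do not show that an arbitrary genomic window is designable
(many are not; that is `validate_design()`'s job to report), nor anything
about in vivo chromatin, replication context or host factors, which the
model does not attempt to describe.

Problem sizes throughout (600-nt loci, 65-nt ends, 115-nt junctions, pools
of six oligos, 200-donor conservation sweeps, 500-sequence folding-oracle
comparisons at length ≤ 12) were chosen as the smallest sizes at which every
architectural feature and invariant is exercised.

## Simulation bookkeeping

Cleavage positions are always recovered at run time — by motif search on
targets (exactly one C_T required; ambiguity is an error) or from the
feature map on junctions — never from stored lengths, so the reported 50/38/
30/16-nt segments are genuine computations. Excision conserves every
nucleotide (`sealed + junction = donor`) and retains C_L in the left flank;
reintegration of the circular junction at that retained TTAC reconstitutes
the donor byte-for-byte (the scarless cycle, property-tested over 200
fixtures). Only top-strand events are modelled: the transposition chemistry
of this family is single-stranded throughout, and bottom-strand states are
out of scope. Labeling follows the 5′ end: exactly one labeled species
exists before and after any single transfer.

## Structure validation

`capture_complex_geometry()` recomputes, for each complex copy of a
user-supplied deposited coordinate file, the target-(−5)-O5′ to LE-(+44)-P
distance (the 10.5 Å reach the linker bridges) and the tyrosine-OH to
scissile-phosphate distance, selecting the active copy as the one with the
shortest nucleophile distance (~3 Å; the other copies hold the +1 base
swung away). Chain identifiers and residue numbers follow each file's own
labeling and are supplied by the caller. The package ships only a synthetic
test structure with atoms planted at known coordinates; it validates the
geometry machinery, not the deposited model.

## Known limitations

* The fold is a qualitative pair-maximization, not a thermodynamic
  ensemble; no pseudoknots, no temperature dependence.
* Competition weights are relative; absolute integration rates and kinetics
  are out of scope.
* The +1 preference at the RE-side TCAA context is untested and therefore
  not applied at RE.
* Greedy unlocking can plateau below threshold for windows whose occlusion
  does not come from the 3′ hairpin arm; such designs are reported as
  failures rather than forced.
* Wild-type IS*608* sequences are not reproduced; all fixtures are synthetic
  with the published anchors fixed.
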