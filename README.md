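# peelpaste

Design and simulation toolkit for retargeting IS*608*-family single-stranded
DNA transposons to user-chosen 12–17 nt integration sites.

## The problem

IS*608* (IS*200*/IS*605* family, *Helicobacter pylori*) transposes through
single-stranded "peel-and-paste" intermediates and inserts precisely 3′ of a
TTAC tetranucleotide. The target is not read by protein: a 4-nt guide
sequence (G_L = AAAG, positions +16…+19 of the left end) base-pairs with the
target motif C_T, and two base triplets (A⁺¹⁶:T⁻³ with T⁺⁴³, A⁺¹⁷:T⁻⁴ with
A⁺⁴²) staple the duplex to the 3′ flank of the subterminal palindrome IP_L.
Because recognition is DNA–DNA pairing, it is programmable: replacing the
left-end bases from +44 onward with the reverse complement of the DNA lying
a 3-nt linker upstream of a chosen TTAC extends the recognized site from
4 nt to `4 + L` nt (L = 8–13), long enough to be unique in a genome. Two
features of the wild-type element must be removed for this to work: a second
hairpin at +46…+60 that buries the extension window in the folded single
strand, and the bulky triplet-forming A at +42 (mutated to T).

`peelpaste` implements that whole workflow in silico:

* **Design** — `design_extension()` builds the engineered left end/junction
  for any scanned site (`scan_sites()`), `apply_structural_unlocking()`
  mutates +42 and opens the occluding hairpin (edits confined to +55…+60),
  `reset_ct()` retargets the core tetranucleotide through the guide pairs,
  and `validate_design()` runs accessibility, self-complementarity,
  unintended-C_T and off-target checks.
* **Folding** — `fold()` is a weighted base-pair maximization (Nussinov-style
  dynamic program; AT = 2, GC = 3, optional G:T wobble, minimum loop 3,
  no lonely pairs) with `find_hairpins()` and `accessibility()` on top.
* **Selectivity** — `competition()` scores an oligo pool with
  `weight = rel_conc × plus1_weight(+1 base) × coop(match_len)`, where
  `coop(m) = floor + (amp − floor)·m^h/(m^h + K^h)` is calibrated so that 8
  contiguous matches dominate zero-match competitors at ≥ 40-fold weight
  while 5 matches gain ≤ 3-fold (both constraints re-checked at load), and
  the +1 weights encode the C > T > A/G cleavage preference.
* **Simulation** — `excise()`, `cleave_target()`, `cleave_end()` and
  `integrate()` do exact sequence bookkeeping of every transposition step
  (cleavage always 3′ of the motif, 5′-phosphotyrosine attachment on the
  downstream segment), and `virtual_gel()` renders labeled species as a
  band table.
* **Fixtures** — `make_synthetic_le()`, `make_canonical_junction()`,
  `make_target_locus()`, `make_target_fixtures()` and `make_donor()` generate
  seeded synthetic sequences with the published architecture, so everything
  runs without downloads.
* **Structure checks** — `read_structure()`, `atom_distance()` and
  `capture_complex_geometry()` recompute capture-complex geometry (the
  10.5 Å extension reach and the 3.0 Å nucleophile distance that identifies
  the active complex copy) from a user-supplied deposited coordinate file.

## Worked example

```r
library(peelpaste)

fx <- make_target_locus(seed = 1)     # locus + validated 8-nt design
glance(fx$design)
#>   ext_len linker_len recognized_len ct    n_unlock_edits accessibility overall_pass
#> 1       8          3             12 TTAC               2             1 TRUE

pool <- make_target_fixtures(1, fx$design, n_scrambled = 4)
pool$rel_conc[pool$id != "Tic"] <- 4  # 20-fold total excess of competitors
competition(pool, fx$design)[, c("id", "rel_conc", "match_len", "coop", "fraction")]
#>   id    rel_conc match_len  coop fraction
#> 1 Tic          1         8 52.7    0.725
#> 2 Tr           4         1  1.00   0.0550
#> 3 Ts1          4         3  1.00   0.0552
#> 4 Ts2          4         2  1.00   0.0550
#> 5 Ts3          4         1  1.00   0.0550
#> 6 Ts4          4         1  1.00   0.0550
```

The design recognizes a 12-nt site (4-nt TTAC plus the 8-nt extension at
+44…+51, 3-nt linker); unlocking needed two edits (+42 A→T plus one hairpin
edit) to make the extension window fully accessible. Even with the five
competitor targets at 20-fold total molar excess, the fully complementary
target Tic is predicted to receive 72% of integration events, because eight
contiguous matches carry ~53-fold the weight of background.

```r
j <- make_canonical_junction(1, design = fx$design)
virtual_gel(list(cleave_end(j),
                 integrate(j, setNames(pool$oligo[pool$id == "Tic"], "Tic")),
                 integrate(j, setNames(pool$oligo[pool$id == "Tr"], "Tr"))),
            substrates = list(j))
#>   id                  species             length
#> 1 substrate:junction  substrate              115
#> 2 transfer:Tic        integration_product     88
#> 3 transfer:Tr         integration_product     80
#> 4 cleaved:junction:CR cleavage_product        50
```

The 5′-labeled junction runs at 115 nt, its cleavage product at 50 nt (the
cut is located from the sequence features at run time), and the two
integration products at 88 nt (50 + 38-nt Tic 3′ segment) and 80 nt
(50 + 30-nt Tr 3′ segment) — all four bands resolvable, as on a sequencing
gel.

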