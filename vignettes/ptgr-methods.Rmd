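---
title: "Methods: how ptgr models restriction cloning under the pTGR standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how ptgr models restriction cloning under the pTGR standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptgr)
```

This vignette is the package's own account of its model: what is simulated,
what is assumed, which knobs matter, and what the synthetic fixtures do and
do not establish about real constructs.

## The chemistry model

A molecule is its top strand (5'→3', strict A/C/G/T; ambiguity codes are
rejected because all eleven shipped enzymes have unambiguous sites), a
topology, a feature table and — for linear molecules — two sticky ends.
Coordinates are 0-based and half-open on the top strand, with modular
arithmetic on circles; this makes slicing unambiguous and origin-spanning
sites well defined. The stored top strand includes a 5' overhang at the left
end and a 3' overhang at the right end, so top-strand lengths are exactly
conserved by digestion — the conservation law the property suite checks.

An enzyme is a recognition sequence plus two cut offsets (top and bottom
strand, both in top-strand coordinates); the overhang kind and sequence are
*derived* from the offsets, never stored. The shipped registry holds the
six cassette enzymes (XbaI, SpeI, NheI, AvrII, NdeI, EcoRI) and the five
backbone enzymes (BamHI, BglII, SphI, PstI, KpnI), all palindromic, so a
single-strand scan is complete; a non-palindromic extension would have to
scan both strands.

Digestion is always complete (the platform's procedures assume complete
cuts; partial digests are out of scope). A circular molecule with k cut
positions yields exactly k fragments, a linear one k+1. Two degenerate
inputs are handled explicitly: a circular molecule with no sites returns an
`uncut` signal distinct from an error, and cuts whose overhang regions
overlap — or coincide on the top strand — raise a *site-collision* error,
because complete digestion is chemically ill-defined there.

Ligation enumerates circularisations of one or two fragments only; the
platform's procedures never need three-fragment ligations, and bounding the
arity keeps enumeration deterministic and exhaustive. Both relative
orientations are reported whenever the ends allow them: orientation
selection is deliberately *not* chemistry's job. The assembly layer filters
products by grammar — measured site censuses and feature orientation on the
product, never assumptions — and logs discarded wrong-orientation and
self-ligation products. Junction scars are reconstructed from the parent
enzymes' retained recognition context (e.g. AvrII keeps `C`, an NheI-cut
fragment brings `CTAGC`, giving the dead `CCTAGC`), and regenerated sites
are detected by scanning the scar, not asserted.

Plasmid identity uses canonical rotation: the lexicographically minimal
rotation of the top strand or of its reverse complement, computed with
Booth's least-rotation algorithm and cross-checked in the tests against a
naive all-rotations minimum. This gives a rotation- and strand-invariant
equality for circles, used everywhere a simulated product is compared with
a monolithically written construct.

## The grammar and its defaults

The slot table is fixed by the standard: eight roles, each with a fixed
flanking pair, chained so adjacent slots share their boundary site. Three
choices the standard leaves open are made here, once:

* **EcoRI→AvrII spacer.** The region between the ORF's EcoRI and the
  terminator's AvrII is unspecified; the package uses a fixed neutral 6 nt
  sequence (`TTAACT`), free of all eleven sites in its assembled context,
  annotated `linker`.
* **Empty slots keep their flanks.** The promoterless and RBS-less control
  forms retain the empty slots' flanking sites (XbaI–NheI collapse to
  adjacency), so every control is still extendable and all eleven sites
  stay unique.
* **ORF cores start at ATG.** The NdeI flank contributes only `CAT`; the
  junction reads `CATATG` with the start codon in frame, matching the
  NdeI-start-codon cloning convention. ORF cores carry their own stop.

An inducible promoter (tac in the shipped metadata) requires the regulator
slot to be filled at assembly time, and a promoter swap onto a
regulator-less plasmid raises an advisory warning rather than an error:
the plasmid is chemically fine, just not repressible.

RBS native SD→ATG spacing is validated as *exact* equality (no tolerance),
since the platform preserves native spacing; the SD motif is located as the
last `AGGAG` in the core, and a missing motif is only an info finding
because short synthetic RBSs need not contain the canonical hexamer.

Construct ranking is deliberately a *partial* order: A ≥ B only when
promoter rank, RBS rank and copy number all agree in direction. No numeric
expression level is predicted from sequence — that is a stated non-goal —
so conflicting ranks are reported as incomparable rather than resolved.

## Planning and the cloning-step count

A "cloning step" is a stage: parallel, independent clonings count once.
Stage 1 inserts every gene of a design into its own configured single-TU
vector; each later stage is one cassette transfer. Operon extensions run
before TU transfers, so extension always acts on a single-TU plasmid — an
operon extension on a multi-TU acceptor is refused with an explicit error,
because the duplicated NheI/AvrII sites make the target ambiguous and the
standard defines no targeted variant. With this ordering a design of n
genes always costs exactly n stages (1 + Σ(kᵢ−1) + (m−1) = n for m TUs of
kᵢ genes).

Donor vectors for second and later operon genes are built promoterless
(the NheI–AvrII cassette excludes the promoter, so the donor's promoter
cannot reach the product); all vectors of one design share the backbone
configuration (replicon from the design; the fixture ColE1 ori, kanamycin
marker, tandem-terminator stand-in; LacI regulator included when any
promoter in the design is inducible). Fragment selection after donor
digestion uses feature annotations — the fragment carrying the `rbs`/`orf`
or TU features — never length, which can tie.

`execute_plan()` and `assemble_design()` are two independent code paths to
the same construct — full simulation versus writing the sequence down from
the grammar — and the package requires them to agree under canonical
rotation; this cross-check is run in the tests and the acceptance script
for the dual-gene operon and the dual-TU cluster.

## Gene design

`reverse_translate()` is greedy and deterministic: the most frequent codon
per residue, the table's preferred stop appended. `remove_forbidden_sites()`
repairs violations left to right; for each violating site the overlapping
codons are tried in order, each codon's synonymous alternatives in
descending usage, and the first substitution that strictly reduces the
total number of forbidden occurrences wins. The strict-decrease rule makes
termination a monotonicity argument rather than a hope; an unrepairable
site raises an error naming the site (for six-cutters spanning at most two
codons this should not occur, but the contract is kept). `design_orf()`
additionally scrubs the flank junction contexts (`CAT`+core and
core+`GAATTC`), whitelisting only the intended NdeI and EcoRI at the
boundaries. The default forbidden set is exactly the six cassette enzymes;
the fixture generator passes all eleven, because its parts must also keep
backbone sites unique plasmid-wide.

The bundled codon-usage table is a synthetic *C. glutamicum*-style table
(GC-biased third positions, frequencies summing to 1 per amino acid),
clearly fixture data: it produces valid, clean ORFs but not the codon
choices of any published optimizer run, which is why no attempt is made to
reproduce specific published gene sequences.

## What the synthetic fixtures emulate — and what they do not

The platform's real part sequences are not published (the assembled
reference plasmid exists as a database accession, but no sequence is
required here). The generator therefore emits, under a single seed:
site-clean random cores of realistic lengths (promoters ~200 nt, RBSs
~20 nt with a planted SD at the declared spacing — sod 7, lacZ 8, cspB
9 nt, themselves fixture choices — terminator ~150 nt, backbone parts
~1000 nt), reporter ORFs of eGFP/mCherry size designed through the
geneprep pipeline, and the published metadata: promoter ranks tac/cspB/sod
= high/medium/low, RBS ranks sod/lacZ/cspB = high/medium/low, copy numbers
pGA1 ≈ 30 and pCRY4/pNG2 1–2 per cell, brightness 34 and 16.

Passing tests on these fixtures establishes the *structural* claims — slot
grammar, scar arithmetic, site censuses, step counts, recursivity,
round-trip identity — which are sequence-independent theorems of the
standard. They establish nothing about expression levels, replication
biology or repression dynamics of real constructs; those are wet-lab
properties the package explicitly does not model. Real sequences can be
supplied through a user registry (JSON) and flow through every operation
unchanged.

## Problem sizes and determinism

All randomness flows through explicit seeds (`generate_fixtures(seed)`,
seeded property loops); identical seeds give byte-identical fixtures. The
test suite runs the digestion laws on 200 randomized molecules of 40–200
nt, the ligation oracle on dozens of ≤50 nt fragments, gene design on 200
random proteins of 15–60 aa, and the full 17-construct series (~4–6 kb
plasmids); these sizes exercise every code path, including origin-wrapping
sites and asymmetric-overhang flips, while keeping the suite quick to run.

## Known limitations

Methylation sensitivity, star activity, nicking and type IIS enzymes,
partial digests, ligation efficiency and concatemer products are out of
scope. Only ≤2-fragment ligations are enumerated. The GenBank reader
implements the package's own documented dialect (misc_feature + `/label` +
`/note="role=..."`, sticky ends in a structured COMMENT), not the full
flat-file grammar. SBOL serialisation is a future-format hook only.
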