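---
title: "Methods: SNP panel design and SNaPshot calling for fly species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel design and SNaPshot calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapanel)
```

## The assay this package models

Blow flies (Calliphoridae) and flesh flies (Sarcophagidae) are the first
colonisers of remains, and the age of their oldest immatures bounds the
minimum postmortem interval. Because development rates are species
specific, identification is mandatory — and often impossible
morphologically for larvae, pupae or damaged adults. The mitochondrial
*COI* barcode separates these species well, but full Sanger barcoding is
slow. The assay modelled here genotypes a few *interspecific* SNPs on
*COI* by multiplexed single-base extension (SBE/SNaPshot): after a
family-specific PCR, an extension primer anneals with its 3' end
immediately adjacent to each SNP and is extended by one labelled ddNTP.
On a capillary trace each product is a single peak whose **colour** gives
the base (A = dR6G/green, C = dTAMRA/black, G = dR110/blue,
T = dROX/red) and whose **size** gives the site, because each site's
primer carries a distinct 5' poly-T tail. The vector of bases across
sites identifies the species.

The package covers the dry-lab side of this method: consensus building,
site selection, primer design, peak interpretation, species calling, and
simulation. Wet-lab steps (extraction, cycling, clean-up) and raw `.fsa`
signal processing are out of scope; input peak tables are assumed
already sized against an internal standard (e.g. GeneScan-120 LIZ).

## Consensus model

`build_consensus()` reduces each species' aligned sequence set to one
string over the 15 IUPAC codes: per column, the minimal code whose base
set equals the union of observed bases. Three deliberate choices:

* **No frequency threshold.** Every observed base enters the consensus
  (a singleton variant makes the column degenerate). The design goal is
  to *exclude* intraspecifically variable positions from panels, and a
  threshold would hide exactly the variation that must disqualify a
  site. A minimum-count option could be added, but the default is 1 and
  the package takes no position on which GenBank variants are errors.
* **N is missing data**, not 4-fold degeneracy: an N-only column stays
  `N`, otherwise N contributes nothing. This avoids manufacturing
  degeneracy from low-quality reads.
* **Any gap makes the column a gap**, and gapped columns are ineligible
  as SNP candidates: the method assumes a shared ungapped coordinate
  system (1-based) on *COI*.

## Site selection as set cover

A candidate site must be concrete and ungapped in every species and
differ between at least two (`find_candidate_sites()`). Choosing the
smallest combination whose genotype vectors are pairwise distinct is a
minimum set cover over species *pairs*: a site "covers" each pair it
separates. `select_minimal_panel()` solves this exactly for up to 20
candidates (subsets enumerated by increasing size with bit-mask pair
coverage; 2^20 with early exit is desk scale) and certifies the result
with `exact = TRUE`; beyond that it falls back to greedy
largest-gain-first cover, explicitly flagged non-certified. Ties among
equal-size panels break to the lexicographically smallest sorted
position tuple, so results are reproducible run to run. Inseparable
species pairs abort the search and are reported by name.

The packaged SA panel illustrates why certification matters: all four of
its sites are essential — every 3-site subset collides at least one
species pair — so four is the true minimum, which the test suite proves
by independent brute-force enumeration. The package makes no claim that
the packaged panels are minimal over *all* of *COI*, only over their own
sites.

## Primer design

`design_sbe_primer()` takes the `flank_len` bases adjacent to the SNP on
the extension strand (5' of the SNP for forward sites; reverse
complement of the 3' flank for reverse sites), encodes cross-species and
intraspecific variation as minimal IUPAC codes, and fills to the
target ladder length with a 5' poly-T tail (T homopolymer only, as is
standard for SNaPshot ladders). Key parameters:

* **Degeneracy cap 64** realizations per primer. Beyond it the design
  fails loudly rather than emitting an unusable primer mix; the packaged
  CA panel instead carries manually authored `low-signal-alternate`
  primers for sites where one universal primer underperforms on some
  species. Alternates ride the same ladder rung and are excluded from
  in-silico extension by default.
* **Ladder** via `plan_size_ladder()`: arithmetic, default step 10 nt —
  an order of magnitude above observed capillary size jitter
  (SDs 0.18–0.85 nt), so windows cannot collide.
* **Structure screening** (`check_self_structure()`): the self-dimer
  score is the longest run of contiguous Watson–Crick pairs between two
  antiparallel copies over all ungapped offsets; the hairpin score is
  the longest stem with a loop of at least 3 nt. Degenerate positions
  count as pairable if any realization pairs (conservative). Thresholds
  default to 8 and 6. This is a screening heuristic by design — no
  nearest-neighbour thermodynamics, no melting temperatures — because
  the assay's primary specificity control is the PCR amplicon itself.

`amplicon_length()` is inclusive span arithmetic
(reverse end − forward start + 1); when a primer binds outside the
numbered reference region (the CA forward primer sits on tRNA-tyrosine)
the length is reported as `NA` with a reason, never guessed.

## Peak interpretation and calling

`assign_peaks()` formalises what an analyst does with GeneMapper bins,
since published assays rarely state bin configurations:

* **Noise floor**: peaks below 10% of the tallest peak in the run are
  discarded (`min_rel_height = 0.10`, GeneMapper-like practice; the
  threshold is a parameter, not a claim).
* **Windows**: a peak belongs to the site whose window
  `mean ± max(3·SD, 1 nt)` contains its size, using the panel's
  per-site observed calibration. With ladder spacing 10 nt and SDs
  below 1 nt, windows are disjoint by a wide margin; overlap is a load
  error. The 1-nt floor keeps windows usable when a site's SD is
  unrealistically tight (SA1479's 0.18 nt would give a 0.54-nt window).
* **One peak per site**: exactly one surviving peak calls the dye's
  base; none is missing; more than one flags the site ambiguous — never
  guessed, since two peaks in one window usually mean contamination or
  pull-up.

`call_species()` keeps only species whose complete reference vector
agrees with every non-missing observed base. One candidate is `unique`;
several are `ambiguous` with the candidate set listed (missing data only
ever *grows* the candidate set, never redirects it); zero is `no-match`,
with the nearest reference by Hamming distance attached strictly as a
labelled hint. Forensic use demands that failure modes stay visible:
the package never silently substitutes the nearest species.

In-silico genotyping (`in_silico_genotype()`) finds each universal
primer's footprint on either strand of the query allowing at most one
mismatch and none within the 3'-terminal 3 bases (the polymerase clamp);
the tolerance absorbs intraspecific variants the consensus missed while
the clamp preserves extension specificity. No binding, or bindings at
more than one locus with conflicting bases, leave the site missing.

## Reverse-direction sites and the detection channel

Genotype tables store **detection-channel bases** — what the dye
reports, i.e. the base the extension primer incorporates. For
forward-direction sites this equals the sense strand; for
reverse-direction sites (the whole SA panel) it is the complement. The
packaged tables are ingested verbatim in this convention, and it is
self-consistent with the printed primers: the degenerate codes inside
SBE primers whose footprints span a neighbouring SNP equal exactly the
set of that site's detection bases across species.

## What the simulators emulate — and what they do not

The true *COI* references behind the packaged panels are not
redistributed; `synthetic_reference()` constructs per-species stand-ins
(documented as synthetic) on a fixed seeded background, constrained so
that every primer footprint carries bases from the intersection of all
covering primers' IUPAC sets and every SNP position carries the species'
table base. These satisfy every sequence constraint the panel encodes —
which is precisely what primer binding and extension exercise — but they
are not real *COI*: codon structure, transition/transversion bias and
phylogenetic correlation are absent.

`simulate_sequences()` adds i.i.d. background substitutions (default 1%
per site) outside panel positions and primer footprints — a `hostile`
mode lifts the footprint protection to stress the mismatch tolerance —
and `simulate_profile()` draws peak sizes from a Normal at the site's
calibrated mean (SD from the panel's observed per-site SDs), truncated
at ±3σ, with lognormal heights (CV 0.25, median 2000 RFU — typical
mid-range capillary signal) and optional dropout. Truncation at ±3σ
guarantees simulated peaks fall inside their own window at default
settings; stress tests must raise the SD deliberately rather than rely
on tail luck. All generators take explicit seeds and leave the caller's
RNG state untouched.

Consequently, a 100% identification rate on simulated data shows that
the decision rules are internally coherent under calibrated noise — it
does not certify performance on degraded casework DNA, co-amplified
nuclear copies, or species outside the panels. The packaged validation
(the acceptance script) uses 100 profiles per species across all 18
species and 10 sequences per species at 1% background mutation; these
sizes give stable rates while keeping the default test run quick.

## Numerical and degenerate-input choices

* Exact-search bound 20 candidates; greedy ties break to the smallest
  position (deterministic).
* Peak windows never overlap by construction; `assign_peaks()` verifies
  and refuses otherwise.
* Empty profiles yield all-missing genotypes and an ambiguous call over
  all species (not an error): absence of signal is data.
* All-N columns stay `N`; all-gap columns stay `-`; both disqualify a
  position from candidacy and from primer flanks.
* Sequence queries may contain `N`; it never matches a primer column.

## Known limitations

* Panels cover the Korean Calliphoridae/Sarcophagidae fauna; specimens
  of other species will (correctly) return no-match or ambiguous, and
  the family must be known before choosing the panel, since the PCRs are
  family specific.
* Size calibration is instrument dependent (observed means sit 3–5 nt
  above nominal lengths due to dye mobility); a panel's calibration
  block should be re-estimated when porting to another analyzer.
* No mixture deconvolution: one specimen per reaction is assumed.
* The structure checks are screening heuristics; borderline primers
  deserve a proper thermodynamic check before synthesis.
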