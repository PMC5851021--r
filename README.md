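# snapanel

Molecular species identification of forensically important flies from a
handful of diagnostic SNPs, without Sanger sequencing.

## The problem

Estimating the minimum postmortem interval (PMI_min) from entomological
evidence requires knowing which fly species colonised the remains, because
development rates are species specific. Morphological identification fails
for damaged specimens, larvae and pupae, and conventional DNA barcoding of
the mitochondrial *COI* gene (Sanger sequencing plus phylogenetic
comparison) is slow and laborious. An alternative is to genotype a small
set of interspecific SNPs on *COI* by single-base extension (SBE, the
SNaPshot chemistry): an unlabelled primer anneals immediately adjacent to
a SNP and is extended by exactly one fluorescent dideoxynucleotide, so on
a capillary electrophoresis trace the **dye colour identifies the base**
(A = dR6G/green, C = dTAMRA/black, G = dR110/blue, T = dROX/red) and the
**primer length identifies the site** (staggered 5' poly-T tails form a
size ladder). The ordered bases across the panel's sites — the genotype
vector — is unique per species in a valid panel.

`snapanel` implements the full workflow for panel designers and caseworkers:

1. **Consensus** — per species, collapse an alignment of *COI* sequences
   into an IUPAC consensus: each column becomes the minimal degeneracy
   code covering every observed base, so intraspecific variation is
   carried explicitly.
2. **Site selection** — candidate sites are columns that are concrete and
   ungapped in every species and differ between at least two; a minimal
   discriminating combination is found by exact subset search (a set
   cover over species pairs; greedy fallback above 20 candidates, flagged
   non-certified).
3. **Primer design** — SBE primers that bind contiguously 5' of each SNP
   on the extension strand, degenerate where species differ, tailed to an
   arithmetic size ladder (e.g. 25, 35, ..., 75 nt), plus self-dimer and
   hairpin screening heuristics.
4. **Genotyping and calling** — from a GeneMapper-style peak table
   (`dye,size,height`) via calibrated size windows, or in silico from a
   query sequence; calls are `unique`, `ambiguous` (candidate set
   reported) or `no-match` (nearest reference is a labelled hint, never
   an identification — a deliberately conservative, forensics-first rule).
5. **Simulation** — seeded generators for species sequences and noisy
   peak profiles, so the whole pipeline is testable end to end.

Two validated panels ship with the package: **CA** (11 Calliphoridae
species, 6 forward-direction sites on the front of *COI*) and **SA**
(7 Sarcophagidae species, 4 reverse-direction sites near its end — each
of the four sites is provably essential). Panels are YAML documents with
primers, per-species genotype vectors, and per-site size calibration
(observed mean, range and SD); all invariants are enforced at load.

## Worked example

```r
library(snapanel)

ca <- load_panel("CA")
ca
#> <panel> CA (Calliphoridae): 11 species x 6 sites
#>   sites: CA90, CA72, CA168, CA261, CA252, CA243
#>   ladder: 25, 35, 45, 55, 65, 75 nt
#>   SBE primers: 11 (6 universal)

# a simulated capillary run for a black blow fly specimen
prof <- simulate_profile("Phormia regina", ca, sim_config(), seed = 11)
round(prof$size, 2)
#> [1] 27.98 37.94 49.06 57.39 67.32 78.55

assign_peaks(prof, ca)
#> <genotype_vector> (peaks)
#>  CA90  CA72 CA168 CA261 CA252 CA243
#>     A     T     A     A     A     T

call_from_peaks(prof, ca)
#> <species_call> status: unique
#>   species: Phormia regina
#>   sites used: 6/6
```

The six peaks land near the panel's calibrated means (28.73, 38.21,
48.59, 57.79, 67.66, 78.61 nt); binning them into the per-site windows
and mapping dye to base yields the genotype vector (A, T, A, A, A, T),
which matches exactly one reference species. The same call is available
from the command line (`inst/cli/snapanel call --panel CA --peaks
run.csv`), with exit codes 0/2/3 for unique/ambiguous/no-match so the
tool composes in pipelines.

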