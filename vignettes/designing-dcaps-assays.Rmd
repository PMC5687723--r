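---
title: "Designing CAPS and dCAPS assays for SNP and indel alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CAPS and dCAPS assays for SNP and indel alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcaps)
```

## The design procedure and its assumptions

A CAPS assay exploits a restriction site present in one allele's amplicon
and absent from the other's; a dCAPS assay manufactures that site by
amplifying with a primer that mismatches its template at one or more
deliberate positions. This package automates both, for allele pairs
differing by a SNP or a small indel, under two structural assumptions:

* **primers lie wholly in the shared region** of the two alleles, with the
  3' end anchored at the last shared base, so one oligo anneals identically
  to both templates and the amplicons differ only past its 3' end;
* **a diagnostic site must overlap both the shared and the unshared
  region** — a motif entirely inside the shared sequence can never
  discriminate (any completed site would appear in both amplicons), and
  one entirely inside an unshared region is a plain CAPS site needing no
  engineering.

The pipeline: decompose the alleles, slide every catalogue motif (and its
reverse complement, when distinct) across the junction in both input
orientations, keep alignments whose degeneracy-aware distance to one allele
is within the mismatch budget with every mismatch patchable under the
primer, verify the completed site is absent from the corresponding region
of the other allele, reject enzymes with an exact site in the shared
downstream part of the amplicon, then build and extend the primer and
predict fragment sizes. Candidate order is deterministic: ascending
mismatch count, then enzyme name, then position.

Sequence identity is judged by IUPAC set intersection throughout: two codes
match when their base sets overlap, so N matches everything and Y matches C
or T. The distance between equal-length strings counts non-intersecting
positions; on plain ACGT strings this is the ordinary Hamming distance. All
coordinates, internal and reported, are 1-based and inclusive — the natural
R convention.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_mismatch` | 1 | mismatches | each extra primer mismatch costs amplification efficiency; one is the conventional dCAPS compromise |
| `amplicon_len` | 150 | nt | how far downstream exact-site rejection and fragment prediction look; brackets a typical short diagnostic amplicon, with margin over the 90-bp worked geometry |
| primer mode | `target_tm` at 60 °C | — | a common annealing optimum for diagnostic PCR; `fixed_length` (25 nt) is available when predictable band sizes matter more than Tm |
| Tm search bounds | 18–36 | nt | standard synthesis practice for allele-specific oligos |
| `allow_3prime_GT` | FALSE | — | 3'-terminal mismatches are assumed not to amplify; optionally, a G:T wobble at the terminus is tolerated, since reports on its effect conflict |
| `primer_conc`, `na_conc` | 50 nM, 50 mM | mol/L | the defaults of the melting-temperature implementation this package follows |
| `loss_threshold` | 0 | fraction | screening mode keeps assays missing at most this weighted share of simulated events; the comparison is inclusive (loss == threshold is kept) |

## Melting temperature

Tm uses the nearest-neighbor model with the Sugimoto parameter set and the
Oligo Calc form of the equation,
Tm = ΔH·1000/(ΔS + R·ln(C/x)) − 273.15 + 16.6·log₁₀[Na⁺], with x = 4 for
ordinary and x = 1 for self-complementary oligos. Two deliberate
approximations: the primer is scored as if annealed to a perfectly
complementary strand (engineered mismatches are ignored — consistent with
the reference implementation, slightly optimistic for mismatched primers),
and no Mg²⁺/dNTP corrections are applied. The unit tests pin the routine to
independently hand-computed summations at ±0.01 °C and to strand symmetry.

## Screening mode

The Cas9 cut is placed at the −3 position of the supplied 20-nt
protospacer, which must occur exactly once in the wild type, on either
strand. The default editing profile is the stated spectrum of simple
outcomes: insertion of each of A, C, G, T at the cut bond and a 1-bp
deletion, **uniformly weighted** (0.2 each). Two choices here were open and
are ours: the deletion removes the base immediately 5' of the blunt cut
(the most commonly lost nucleotide; configurable via `edit_profile()`), and
weights are uniform per event rather than 4:1 insertion-biased. Custom
profiles (longer deletions, multi-base insertions, other weights) are
accepted because the loss machinery cannot be tested without them.

The last shared base is recomputed against *all* simulated variants — in a
homopolymer it retreats 5' of the naive cut position, which is exactly the
failure mode that makes SNP-oriented tools misplace indel primers. An
emitted assay must cleave the wild-type amplicon; each event's amplicon is
then re-scanned for **any** exact site of the enzyme, anywhere, not just at
the original coordinates — a gel cannot tell why a band was cut, and an
insertion against a degenerate motif position can restore the site in a
shifted register. The weighted share of still-cut events is the assay's
`loss_fraction`; with the default profile it lies on a grid of fifths.

## Numerical and tie-breaking choices

* **Homopolymer ambiguity** in the decomposition resolves by maximizing the
  shared prefix first, pushing the unshared region as far 3' as possible;
  when prefix and suffix claims overlap, the suffix is truncated. The
  prefix anchors the primer 3' end, which is the quantity that matters.
* **Inputs differing at two separated loci** are refused
  (`multiple_variant_regions`) rather than guessed at: the tool's contract
  is one local variant per run.
* **Patching** a motif position chooses the template base when compatible,
  otherwise the lexicographically first concrete base in the motif's set —
  deterministic and mismatch-minimal. Degenerate *template* bases under the
  primer are concretized the same way, with a warning, and not counted as
  mismatches.
* **Disrupting** a spurious exact site under the primer prefers a
  transversion that creates no new site for any catalogue enzyme within the
  primer; each disruption costs one mismatch against the budget. Only exact
  occurrences are disrupted, and downstream rejection likewise uses exact
  matches only — near-matches cut nothing.
* **Both-allele cutters** are reported (as `both_differently`) only when
  the two digests differ by at least 5 bp in some band, a pragmatic gel
  resolution limit; small shifts in band sizes are treated as
  indistinguishable. The same 5-bp rule drives the audit classifier.
* **Tm ties** between candidate lengths break toward the shorter primer.
* Every emitted design is re-validated against its definition: substituting
  the primer into the cleaved allele creates an exact site at the
  diagnostic position; substituting it into the other allele creates none
  near the junction.

## The audit classifier

`classify_assay()` reconstructs what a primer would actually amplify:
best ungapped placement on each allele (both strands), simulated amplicons
with the primer substituted, in-silico digestion. `non_productive` means no
gel-distinguishable digest exists (no site, or equivalent fragment
patterns); `problematic` means the digest would discriminate but the primer
has an amplification defect — a 3'-terminal mismatch, more than three
mismatches, or an alignment gap (detected when the primer halves place
consistently only if an indel is assumed between them); `productive` means
neither. The closure property — every assay the design pipeline emits
audits as productive — is enforced in the test suite over randomized
fixtures. The classifier is validated on constructed per-defect fixtures;
reproducing any third-party tool's historical output counts is out of
scope.

## What the synthetic data does and does not establish

The fixture generators produce uniform-random sequences with planted SNPs,
1-3 bp indels, unique protospacers, or planted near-sites. They emulate the
combinatorics of motif/junction geometry — which is what the scanner,
primer builder and loss machinery respond to — but not genomic base
composition, repeats, or real editing-outcome biases. A green randomized
test therefore establishes algorithmic correctness (agreement with
brute-force enumeration and digest oracles), not field performance on any
particular locus.

One named fixture deserves emphasis: the test suite's screening check of
the published assay geometry (a blunt cutter with an interrupted
palindromic motif spanning a Cas9 cut, one engineered mismatch, a 90-bp
amplicon digesting to 36+54 bp with all 1-bp insertions uncut) runs on a
**synthetic locus** built around the real protospacer, because the genuine
genomic sequence would require a network download that the build
environment does not allow. The geometry, not the locus, is what the check
exercises.

## Known limitations

* No primer-dimer, hairpin or genome-wide specificity screening; the
  reverse primer is the user's responsibility.
* Mismatch and dangling-end thermodynamics are not modelled in Tm.
* Methylation sensitivity, star activity and buffer compatibility are
  outside the enzyme model; enzymes without cut-offset annotation support
  presence/absence calls only.
* The packaged catalogue is a curated snapshot (~160 enzymes); assay counts
  depend on the catalogue version, and users with access to a current
  vendor list can supply their own TSV.
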