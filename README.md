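# dcaps

Design of CAPS and dCAPS genotyping assays for SNP and small-indel alleles,
with first-class support for the 1-bp insertions and deletions that
CRISPR/Cas9 mutagenesis typically produces.

## The problem

Genotyping a point mutation or a 1-2 bp indel on an agarose gel needs a
restriction digest that cuts one allele but not the other. When no natural
restriction site distinguishes the alleles (a **CAPS** assay), a **dCAPS**
assay engineers one: a PCR primer carrying one or more deliberate
template mismatches completes a recognition motif in the amplicon of one
allele only, so the digest again separates the genotypes. Existing
SNP-oriented design tools frequently fail on indels — their primers either do
not amplify (3' mismatches, alignment gaps) or do not discriminate. This
package designs indel-aware assays from first principles:

1. the two alleles are decomposed into **shared** and **unshared** regions
   (longest common prefix, then longest common suffix of the remainder);
2. every enzyme motif in a curated catalogue is slid across the junction and
   scored with a degeneracy-aware Hamming distance
   *d*(a, b) = #{ i : set(a_i) ∩ set(b_i) = ∅ } over the IUPAC codes —
   e.g. d(GCAT, GGTT) = 2 but d(GCAT, GYTT) = 1 since Y = {C,T} matches C;
3. a candidate must overlap at least one shared and one unshared base, with
   every mismatching base patchable by a primer lying wholly in the shared
   region, 3' end anchored at the last shared base;
4. enzymes with an exact site in the shared downstream region of the
   amplicon are rejected; both input orientations are scanned;
5. primers are extended 5' to a fixed length or to a target melting
   temperature, computed by the nearest-neighbor model with the Sugimoto
   parameter set: Tm = ΔH·1000 / (ΔS + R·ln(C/4)) − 273.15 + 16.6·log₁₀[Na⁺].

A **screening mode** designs assays before any editing outcome is known: a
20-nt protospacer locates the Cas9 cut at the −3 position, the default
editing profile (insertion of each base plus a 1-bp deletion, equal weights)
simulates the outcome spectrum, and assays are reported with the fraction of
events they would miss (the *acceptable loss threshold* filters them).
An **audit mode** classifies any primer/enzyme/allele-pair combination as
`productive`, `problematic` (would discriminate, but likely fails to
amplify) or `non_productive` by simulating both amplicons.

## Worked example

Two alleles differing by a SNP, neither carrying a natural EcoRI site:

```r
library(dcaps)
L <- "TGCCAGTCAGGTACCTGGACTGCAG"; R <- "CTGGACCTGGTGACAGTGCAAGTCC"
s1 <- paste0(L, "GTATTC", R)   # one base short of GAATTC
s2 <- paste0(L, "GTATAC", R)   # the SNP sits inside the would-be site
design_known(s1, s2, run_config(),
             filter_enzymes(load_enzymes(), include = c("EcoRI", "AccI", "BstZ17I")))
#> CAPS/dCAPS design report: 5 assay(s)
#>    enzyme        orientation cleaved_allele                       primer
#> 1    AccI            forward              2 GCCAGTCAGGTACCTGGACTGCAGGTAT
#> 2    AccI reverse_complement              2   GGACTTGCACTGTCACCAGGTCCAGG
#> 3 BstZ17I            forward              2 GCCAGTCAGGTACCTGGACTGCAGGTAT
#> 4 BstZ17I reverse_complement              2   GGACTTGCACTGTCACCAGGTCCAGG
#> 5   EcoRI            forward              1  CCAGTCAGGTACCTGGACTGCAGGAAT
#>   mismatch_count tm_celsius fragments_allele1 fragments_allele2
#> 1              0      60.75                55             26+29
#> 2              0      59.46                56             27+29
#> 3              0      60.75                55             27+28
#> 4              0      59.46                56             28+28
#> 5              1      59.40             24+30                54
```

Rows 1-4 are plain CAPS assays: the SNP itself creates an AccI/BstZ17I site
in allele 2 (`mismatch_count 0`), cutting its 55-56 bp amplicon into two
bands while allele 1 stays uncut. Row 5 is the dCAPS route: one engineered
mismatch near the primer 3' end (the final `AAT`) completes GAATTC in the
allele-1 amplicon only, giving 24+30 bp versus an uncut 54 bp. Fragment
sizes assume the reported amplicon window; the reverse (downstream) primer
is the user's choice.

Screening a CRISPR target before outcomes are known:

```r
res <- screen_assays(wt, protospacer, loss_threshold = 0)
res$loss_fraction       # fraction of simulated edits each assay would miss
res$per_event_calls     # cut/uncut per simulated editing event
```

The command-line wrapper mirrors the API
(`Rscript <pkg>/exec/dcaps.R known|screen|audit|fixtures ...`).

## Enzyme catalogue

A static snapshot of ~160 commercially common enzymes ships in
`inst/extdata/restriction_enzymes.tsv` with the dialect
`name<TAB>site[<TAB>extra]`: `G^AATTC` marks the top-strand cut inside the
motif, `GGTCTC(1/5)` gives top/bottom offsets past the motif, and `extra` is
a bottom-cut bond offset or a `nicking`/`double` flag (flagged enzymes are
excluded from scans). `#` lines are comments. Users can supply their own
table; reported assay counts naturally depend on the catalogue version.

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch against the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
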