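Package: dcaps
Title: Design of CAPS and dCAPS Genotyping Assays for SNP and Indel Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs cleaved amplified polymorphic sequence (CAPS) and derived
    CAPS (dCAPS) genotyping assays that distinguish two alleles differing by a
    SNP or a small insertion/deletion, with particular support for small indels
    of the kind produced by CRISPR/Cas9 mutagenesis. Sequences are decomposed
    into shared and unshared regions, a catalogue of restriction-enzyme
    recognition motifs is scanned with a degeneracy-aware Hamming distance, and
    diagnostic primers carrying a bounded number of engineered mismatches are
    constructed with their 3' end anchored at the last shared base. Includes a
    screening mode that simulates CRISPR editing outcomes at a protospacer cut
    site and designs assays cleaving wild type but not edited alleles, an
    in-silico digestion and fragment-size predictor, nearest-neighbor melting
    temperatures (Sugimoto parameters, Oligo Calc equation), and a rule-based
    classifier of primer/enzyme combinations as productive, problematic, or
    non-productive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
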