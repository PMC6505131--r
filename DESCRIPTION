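Package: divscan
Title: Inter-Species Divergence Scanning and Diagnostic Marker Design from
    SNV Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting two closely related populations or sister
    species from multi-sample SNV and indel calls: site-quality filtering of
    VCF genotypes, per-site and genome-wide Reich-Patterson F_ST, detection of
    genomic islands of divergence by score-shifted maximal-segment scanning
    (Ruzzo-Tompa), windowed nucleotide diversity and absolute divergence
    (d_XY), genotype-distance neighbour-joining trees and identity-by-state
    matrices, selection of fixed-difference PCR-ready diagnostic markers with
    in-silico RFLP assay design, and pathway over-representation with a
    randomization-based estimate of expected false discoveries. A bundled
    two-population genotype simulator with known ground truth (Balding-Nichols
    background differentiation, implanted divergence islands, fixed
    differences, indels, low-complexity tracts and assembly gaps) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
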