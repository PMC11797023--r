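Package: sbdrive
Title: Biased Social-Chromosome Transmission in Fire Ant Males
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference pipeline for detecting transmission-ratio distortion of
    the Solenopsis invicta social supergene (SB/Sb) in haploid males of the
    polygyne form. Classifies male ploidy and supergene genotype from a
    two-band Gp-9 PCR assay combined with multilocus microsatellite
    hemizygosity, quantifies the false-haploid misclassification probability,
    estimates haplotype frequencies and mean weights both pooled (with
    proportion bootstrap) and corrected for colony structure by one-male-per-
    colony resampling, computes nestmate relatedness and effective queen
    number from reference allele frequencies, and runs the accompanying test
    battery (exact binomial and Fisher tests, t-tests, two-way ANOVA of
    weight, execution-assay proportion comparisons). Includes a forward
    simulator of the polygyne breeding system (heterozygous SB/Sb queens,
    arrhenotokous haploid males with a tunable transmission-distortion
    parameter, diploid males from matched matings under single-locus
    complementary sex determination, weight-threshold sampling design) that
    produces tables with known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
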