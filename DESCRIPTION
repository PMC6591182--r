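Package: tractdensity
Title: Volume-Normalized Streamline Connectivity Density Profiles and
    Lateralization Testing for Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of diffusion MRI tractograms into quantitative
    seed-to-parcellation connectivity profiles. Reads MRtrix TCK tractograms
    and NIfTI label volumes, assigns each streamline exclusively to a single
    target region under inclusion/exclusion filtering semantics, computes
    streamline-count connectivity densities with ROI-volume normalization
    (delta and delta_NORM), screens pathway reliability across subjects by
    coefficient of variation with a density retention threshold, aggregates
    densities into cerebellar compartments, and tests hemispheric
    lateralization of bilateral pathways with a paired tmax permutation test.
    A synthetic tractogram phantom with known ground-truth connectivity
    makes the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
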