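Package: disconnectome
Title: Lesion-Derived Brain Disconnectome Mapping and Longitudinal
    Biomarker Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-subject brain disconnectome probability maps from
    binary white-matter lesion masks and normative streamline tractograms,
    summarises them into a global disconnectome (GD) statistic and lesion
    volumes, and relates them to serum neurofilament light chain (NfL) with
    cross-sectional linear models, longitudinal mixed models with subject and
    center random intercepts (plus a Huber-weighted robust refit), and
    voxel-wise permutation inference with threshold-free cluster enhancement
    (TFCE) and family-wise error control. Includes a synthetic phantom
    generator (template grids, fiber bundles, spherical lesions, multicenter
    longitudinal cohorts with planted effect sizes) so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
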