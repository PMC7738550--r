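Package: vocpipe
Title: Open-Source Preprocessing of Exhaled-Breath TD-GC/q-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Preprocessing workflow for untargeted volatilome analysis of
    exhaled breath by thermal desorption gas chromatography coupled to
    single-quadrupole mass spectrometry. Two independent routes lead from
    profile-mode chromatograms to compounds: matched-filter peak picking
    with retention-time alignment, cross-sample grouping, gap filling and
    similarity-network grouping of co-eluting features into pseudo-compounds;
    and segment-wise spectral deconvolution with cross-sample compound
    alignment and missing-compound recovery. The two routes are merged and
    cross-validated by a spectral dot product, duplicates are flagged, the
    final feature matrix is normalized, and compounds are putatively
    identified against an MSP spectral library using a weighted-cosine match
    factor and alkane-anchored retention-index error. A synthetic-data
    generator emulating breath-like cohorts with known ground truth makes the
    whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    igraph,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
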