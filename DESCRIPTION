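Package: dcequant
Title: Pharmacokinetic Quantification of Dynamic Contrast-Enhanced MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise pharmacokinetic quantification of dynamic
    contrast-enhanced (DCE) MRI for preclinical liver-tumor studies.
    Implements variable flip angle T1 mapping, conversion of spoiled
    gradient-echo signal to contrast-agent concentration, arterial input
    function extraction by curve-shape ranking, extended Kety (extended
    Tofts) model fitting of Ktrans, ve, vp and bolus-arrival delay,
    tumor-subregion summarization by 3x3 neighborhood averaging, and the
    correlation of pharmacokinetic parameters with microvessel density
    from CD31 histology. Ships a digital phantom generator emulating a
    coronal multi-slice acquisition over an ablated tumor with necrotic,
    partially necrotic and viable subregions, so the full pipeline is
    testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Visualization
RoxygenNote: 7.3.3
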